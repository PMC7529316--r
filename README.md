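# pathlogit

Multi-label inference of metabolic pathways from enzyme annotation
profiles.

## What problem this solves, and for whom

Annotating a genome or metagenome yields a *reactome*: a table of EC
numbers with abundances. The biological question is which metabolic
pathways that reactome encodes. Rule engines (PathoLogic) and parsimony
solvers (MinPath) answer it without probability scores; `pathlogit` is for
researchers who want a trainable, probabilistic alternative: one-vs-rest
logistic regression with an elastic-net penalty over rich engineered
pathway features, returning a per-pathway probability for every sample.

For a reference catalog of $t$ pathways over $r$ reactions, each sample
$x$ is transformed into a feature vector
$\Phi(x) = [\phi^a, \phi^f, \phi^y, \phi^c, \phi^d]$ (reaction abundance,
reaction evidence, pathway evidence, pathway common, possible pathway
blocks; $r + 68 + 32 + r + 2t$ dimensions), and pathway $j$ is scored as

$$q_j = \sigma(\theta_j^\top \Phi(x)),\qquad
  \hat y_j = \mathbf{1}[q_j \ge \tau]\ \text{or adaptively}\
  \mathbf{1}[q_j \ge \min(\tau,\ \beta \max_k q_k)],$$

with each $\theta_j$ trained by mini-batch subgradient ascent on the
elastic-net–penalized log-likelihood
$\frac1n\sum_i [y_j z - \log(1+e^{z})] - \lambda[\frac{1-\alpha}2\|\theta_j\|_2^2 + \alpha\|\theta_j\|_1]$.

The package also ships the surrounding apparatus: a JSON reference
interchange format, a Poisson-subsampling synthetic dataset generator
with feature-noise corruption, iterative multi-label stratified
splitting, coverage/naive/parsimony baseline predictors, sample-averaged
multi-label metrics and RLA/ELA robustness scores, and a command-line
interface (`exec/pathlogit`).

## Worked example

```r
library(pathlogit)

ref <- randomReference(nPathways = 20, nReactions = 120, seed = 101)
ds  <- generateDataset(ref, synthesisConfig(nSamples = 1000, pathwayMean = 3,
                                            seed = 102))
sp  <- stratifiedSplit(ds, c(0.70, 0.15, 0.15), seed = 103)

cfg <- featureConfig(c("AB", "RE", "PE"), scaling = "none")
hp  <- hyperParameters(lambda = 1e-4, alpha = 0.65, lambdaLR = 1,
                       batchSize = 100, epochs = 300, seed = 104)
model <- trainPathwayModel(sp$train, ref, cfg, hp)

res <- predictPathways(model, sp$test, ref)
multilabelMetrics(labelMatrix(sp$test), res$predicted)
#> Multi-label metrics over 150 samples x 20 pathways
#>   precision 0.9589  recall 0.9697  F1 0.9643  Hamming loss 0.0167

multilabelMetrics(labelMatrix(sp$test), naivePredict(sp$test, ref, seed = 105))
#> Multi-label metrics over 150 samples x 20 pathways
#>   precision 0.7429  recall 0.9922  F1 0.8496  Hamming loss 0.0740
```

The trained model recovers the held-out pathway sets with F1 0.96; the
randomized naive linker reaches the same recall but floods the result
with false positives (precision 0.74). On this *clean* synthetic corpus
the direct coverage baseline is perfect by construction — every labeled
pathway is fully covered — which is exactly why robustness under feature
noise is measured separately:

```r
trainNoisy <- corruptDataset(sp$train, ref, pIns = 0.05, pDel = 0.2, seed = 106)
testNoisy  <- corruptDataset(sp$test,  ref, pIns = 0.05, pDel = 0.2, seed = 107)
modelN <- trainPathwayModel(trainNoisy, ref, cfg, hp)
f1_clean <- multilabelMetrics(labelMatrix(sp$test),
                              predictPathways(model, sp$test, ref)$predicted)$f1
f1_noisy <- multilabelMetrics(labelMatrix(sp$test),
                              predictPathways(modelN, testNoisy, ref)$predicted)$f1
robustnessScores(f1_clean, f1_noisy)
#> s0 0.9643  s_rho 0.7745  RLA 0.1968  ELA 0.2339
```

`RLA` is the relative F1 loss caused by 20% reaction deletion plus 5%
spurious insertion; `ELA` additionally penalizes a weak clean-data start.

The same pipeline is available from a shell:

```sh
exec/pathlogit simulate --reference ref.json --out sim --n 1000 --mu 3 --seed 1
exec/pathlogit train    --reference ref.json --samples sim/samples.tsv \
                        --labels sim/labels.tsv --out model
exec/pathlogit predict  --reference ref.json --samples sim/samples.tsv \
                        --model model/model.json --out pred
exec/pathlogit evaluate --reference ref.json --predictions pred/predictions.tsv \
                        --labels sim/labels.tsv --out eval
```

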