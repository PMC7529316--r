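#' Sample-averaged multi-label metrics
#'
#' Computes average precision, average recall, average F1 and Hamming loss
#' between a binary truth matrix and a binary prediction matrix:
#' \deqn{Pr = \frac{1}{n}\sum_i \frac{y^{(i)\top}\hat y^{(i)}}{\sum_j \hat y_j^{(i)}},\quad
#'       Rc = \frac{1}{n}\sum_i \frac{y^{(i)\top}\hat y^{(i)}}{\sum_j y_j^{(i)}},\quad
#'       F1 = \frac{2\,Pr\,Rc}{Pr + Rc},\quad
#'       hloss = \frac{1}{nt}\sum_{i,j} 1(y_j^{(i)} \ne \hat y_j^{(i)}).}
#' Zero-denominator convention (documented, unit-tested): a sample with no
#' predicted (resp. true) labels contributes 1 to the precision (recall)
#' average when the other set is also empty, else 0; F1 is 0 when
#' \eqn{Pr + Rc = 0}.
#'
#' @param truth n x t binary matrix of true labels.
#' @param predicted n x t binary matrix of predicted labels.
#' @return list of class \code{"MetricsReport"}: \code{precision},
#'   \code{recall}, \code{f1}, \code{hamming_loss}, \code{n}, \code{t} and
#'   a \code{per_sample} data.frame of per-sample precision/recall.
#' @examples
#' Y <- rbind(c(1, 1, 0, 0))
#' multilabelMetrics(Y, rbind(c(1, 0, 1, 0)))$f1   # 0.5
#' @export
multilabelMetrics <- function(truth, predicted) {
  truth <- as.matrix(truth); predicted <- as.matrix(predicted)
  if (!identical(dim(truth), dim(predicted))) {
    stop("truth and prediction matrices must have identical dimensions", call. = FALSE)
  }
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop("matrices must be binary", call. = FALSE)
  }
  n <- nrow(truth); t <- ncol(truth)
  tp <- rowSums(truth * predicted)
  nPred <- rowSums(predicted)
  nTrue <- rowSums(truth)
  prec <- ifelse(nPred > 0, tp / nPred, as.numeric(nTrue == 0))
  rec <- ifelse(nTrue > 0, tp / nTrue, as.numeric(nPred == 0))
  Pr <- mean(prec); Rc <- mean(rec)
  F1 <- if (Pr + Rc > 0) 2 * Pr * Rc / (Pr + Rc) else 0
  hloss <- mean(truth != predicted)
  structure(list(precision = Pr, recall = Rc, f1 = F1, hamming_loss = hloss,
                 n = n, t = t,
                 per_sample = data.frame(precision = prec, recall = rec)),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("Multi-label metrics over %d samples x %d pathways\n", x$n, x$t))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  Hamming loss %.4f\n",
              x$precision, x$recall, x$f1, x$hamming_loss))
  invisible(x)
}

#' Robustness scores under feature noise
#'
#' Given a performance score without noise \eqn{s_0} and the score of the
#' model trained/evaluated under noise level \eqn{\rho}, computes the
#' relative loss of accuracy \eqn{RLA = (s_0 - s_\rho)/s_0} and the
#' equalized loss of accuracy \eqn{ELA = (1 - s_\rho)/s_0}. The identity
#' \eqn{ELA = RLA + (1 - s_0)/s_0} holds exactly and is recorded in the
#' result. A negative RLA means the noise-trained model outperformed the
#' clean one.
#'
#' @param s0 clean score in (0, 1]; 0 is a domain error.
#' @param sRho score under noise, in \eqn{[0, 1]}.
#' @return list of class \code{"RobustnessScores"}: \code{s0}, \code{s_rho},
#'   \code{rla}, \code{ela}, \code{baseline_term} (\eqn{(1 - s_0)/s_0}).
#' @examples
#' r <- robustnessScores(0.7280, 0.7275)
#' round(c(r$rla, r$ela), 4)
#' @export
robustnessScores <- function(s0, sRho) {
  .assertNumber(s0, "s0", upper = 1)
  if (s0 <= 0) stop("s0 must be > 0", call. = FALSE)
  .assertNumber(sRho, "sRho", 0, 1)
  structure(list(s0 = s0, s_rho = sRho,
                 rla = (s0 - sRho) / s0,
                 ela = (1 - sRho) / s0,
                 baseline_term = (1 - s0) / s0),
            class = "RobustnessScores")
}

#' @export
print.RobustnessScores <- function(x, ...) {
  cat(sprintf("s0 %.4f  s_rho %.4f  RLA %.4f  ELA %.4f\n",
              x$s0, x$s_rho, x$rla, x$ela))
  invisible(x)
}
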