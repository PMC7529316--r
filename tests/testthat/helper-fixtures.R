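# Shared in-code fixtures: tiny references and datasets built fresh per run.

# 3-pathway toy reference with shared and key reactions.
toyRef <- function() {
  PathwayRef(list(
    list(id = "P1", name = "alpha", reactions = c("1.1.1.1", "2.2.2.2", "3.3.3.3"),
         key_reactions = c("1.1.1.1")),
    list(id = "P2", name = "beta", reactions = c("1.1.1.1", "2.7.1.1"),
         key_reactions = c("2.7.1.1")),
    list(id = "P3", name = "gamma (no reactions)", reactions = character())
  ))
}

# Reference where every pathway has a single private reaction; convenient
# for arithmetic on label/reaction tallies.
singletonRef <- function(t) {
  PathwayRef(lapply(seq_len(t), function(j) {
    list(id = sprintf("P%04d", j), reactions = sprintf("1.1.%d.%d", (j - 1L) %% 50L + 1L, j))
  }))
}

toyAbund <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)))
  v
}

# small labeled dataset over toyRef: sample i carries pathway i
toyDataset <- function() {
  ref <- toyRef()
  ab <- list(
    s1 = c("1.1.1.1" = 2, "2.2.2.2" = 1, "3.3.3.3" = 4),
    s2 = c("1.1.1.1" = 1, "2.7.1.1" = 3),
    s3 = c("9.9.9.9" = 1)  # orphan only
  )
  Y <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  colnames(Y) <- pathwayIds(ref)
  list(ref = ref, ds = PathwayDataset(ab, sampleIds = names(ab), labels = Y))
}

writeTempReference <- function(ref) {
  path <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
  saveReference(ref, path)
  path
}
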