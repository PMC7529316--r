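#' @importFrom methods new validObject is slot
#' @importFrom stats rpois runif median sd plogis setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Regex for a normalized EC number: 4 dot-separated fields, first numeric,
# trailing fields numeric or "-" (partial EC).
.EC_PATTERN <- "^[0-9]+(\\.([0-9]+|-)){3}$"

#' Normalize EC number strings
#'
#' Strips an optional \code{"EC"} prefix and surrounding whitespace and
#' validates the four dot-separated fields (trailing fields may be
#' \code{"-"} for partial ECs). Comparison throughout the package is exact
#' string equality after normalization; no wildcard expansion is performed.
#'
#' @param x character vector of EC numbers, e.g. \code{"EC 1.1.1.1"}.
#' @return character vector of normalized EC strings.
#' @examples
#' normalizeEC(c("EC 1.1.1.1", " 2.7.1.-"))
#' @export
normalizeEC <- function(x) {
  x <- trimws(gsub("^[Ee][Cc][ :]*", "", trimws(as.character(x))))
  bad <- !grepl(.EC_PATTERN, x)
  if (any(bad)) {
    stop("malformed EC number(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

# Top-level EC class (integer); NA when outside 1..7.
.ecClass <- function(ec) {
  cls <- suppressWarnings(as.integer(sub("\\..*$", "", ec)))
  cls[!(cls %in% 1:7)] <- NA_integer_
  cls
}

.isPartialEC <- function(ec) grepl("-", ec, fixed = TRUE)

# Order-stable, locale-independent sort used for the reaction universe.
.ecSort <- function(x) sort(unique(x), method = "radix")

# Cheap deterministic fingerprint of a character vector; guards models
# against being applied to a mismatched feature layout or pathway order.
.fingerprint <- function(x) {
  s <- paste(x, collapse = "\x1f")
  v <- utf8ToInt(s)
  h <- sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647
  sprintf("%d-%.0f", length(x), h)
}

.assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be TRUE or FALSE", call. = FALSE)
  }
}

.assertNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(name, " must be a number in [", lower, ", ", upper, "]", call. = FALSE)
  }
}
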