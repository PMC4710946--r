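#' Derive a stage- or subject-level seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Sub-seeds
#' for stages and subjects are derived deterministically by hashing the
#' master seed together with a string key (e.g. `"cohort/subject/7"`), so any
#' stage can be re-run in isolation and two stages never share a stream.
#'
#' The hash is a polynomial rolling hash of the key, combined with the master
#' seed, reduced modulo 2^31 - 1 so the result is always a valid 32-bit
#' integer seed.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric key components, concatenated with "/".
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "cohort", "subject", 3)
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(key)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Column-standardize a matrix to zero mean, unit L2 norm (for correlation via
# crossprod). Zero-variance columns are flagged via the "dropped" attribute.
.standardize_columns <- function(x) {
  x <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(x^2))
  zero <- nrm <= .Machine$double.eps * nrow(x)
  nrm[zero] <- 1
  x <- sweep(x, 2L, nrm, "/")
  attr(x, "zero_variance") <- zero
  x
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
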