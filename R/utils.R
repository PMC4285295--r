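`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with any number of integer indices into a new seed
#' in `[1, 2^31 - 2]`. Used throughout the package so that, e.g., row `r`
#' of a reference table gets the same stream no matter how rows are
#' distributed over workers.
#'
#' @param seed master seed (single integer).
#' @param ... integer indices (model index, row index, ...).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(42, 3, 17)
derive_seed <- function(seed, ...) {
  m <- 2147483629
  h <- as.numeric(seed) %% m
  for (k in c(...)) h <- (h * 48271 + as.numeric(k) + 1) %% m
  as.integer(h + 1)
}

## Cheap deterministic string hash (31-polynomial mod prime); used only to
## fingerprint configurations in output manifests.
str_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Weighted median
#'
#' @param x numeric values.
#' @param w nonnegative weights (recycled to length of `x`).
#' @return the smallest `x` at which the cumulative weight reaches half
#'   the total.
#' @export
weighted_median <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  if (cw[length(cw)] <= 0) stop("weights sum to zero")
  x[which(cw >= cw[length(cw)] / 2)[1]]
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
}
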