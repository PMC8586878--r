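#' Exponential sampling keys
#'
#' The weighted-sampling kernel: drawing `m` items without replacement with
#' probabilities proportional to weights `w` is equivalent to assigning each
#' item an independent key `-log(u_i) / w_i` with `u_i ~ U(0, 1)` (an
#' exponential variate with rate `w_i`) and keeping the `m` smallest keys.
#' The log form is used rather than the equivalent `u^(1/w)` ordering because
#' it is numerically stable for small weights.  Zero-weight items receive key
#' `+Inf`, preserving index alignment while making them unselectable.
#'
#' Keys are drawn from the current R random number stream; call `set.seed()`
#' (or use [substream_seed()] for named substreams) for reproducibility.
#'
#' @param weights numeric vector of nonnegative weights, at least one `> 0`.
#' @return numeric vector of strictly positive keys (`+Inf` where the weight
#'   is zero).
#' @export
exp_keys <- function(weights) {
  if (!is.numeric(weights) || length(weights) == 0L)
    stop("weights must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(weights) || any(weights < 0))
    stop("weights must be nonnegative", call. = FALSE)
  if (all(weights == 0))
    stop("no positive sampling mass: all weights are zero", call. = FALSE)
  keys <- -log(stats::runif(length(weights))) / weights
  keys[weights == 0] <- Inf
  keys
}

#' Weighted sampling without replacement
#'
#' Draws `m` distinct indices with the law of sequential weighted draws
#' without replacement (each draw proportional to the remaining weights), by
#' taking the `m` smallest exponential keys of [exp_keys()].  If fewer than
#' `m` items have positive weight, all of them are returned.
#'
#' @param weights nonnegative weights, at least one `> 0`.
#' @param m number of items to draw (`>= 1`).
#' @return an object of class `weighted_sample`: list with `indices` (the
#'   selected 1-based indices, in increasing key order), `keys` (their keys)
#'   and `m`.
#' @export
weighted_sample_wor <- function(weights, m) {
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be >= 1", call. = FALSE)
  keys <- exp_keys(weights)
  take <- min(as.integer(m), sum(weights > 0))
  o <- order(keys)[seq_len(take)]
  structure(list(indices = o, keys = keys[o], m = as.integer(m)),
            class = "weighted_sample")
}

#' @export
print.weighted_sample <- function(x, ...) {
  cat(sprintf("weighted_sample: %d of m = %d requested; indices: %s\n",
              length(x$indices), x$m,
              paste(utils::head(x$indices, 10L), collapse = ", ")))
  invisible(x)
}

#' Merge partial weighted samples
#'
#' Combines samples built over disjoint index ranges (e.g. one per worker)
#' into the global top-`m`: because keys are independent exponential
#' variates, the `m` smallest keys of the concatenation follow exactly the
#' same law as a single pass over the whole weight vector.  Each partial
#' sample must carry globally unique indices.
#'
#' @param samples list of `weighted_sample` objects over disjoint index sets.
#' @param m global sample size.
#' @return a merged `weighted_sample`.
#' @export
merge_weighted_samples <- function(samples, m) {
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "weighted_sample")))
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("m must be >= 1", call. = FALSE)
  idx <- unlist(lapply(samples, `[[`, "indices"))
  keys <- unlist(lapply(samples, `[[`, "keys"))
  if (anyDuplicated(idx))
    stop("partial samples overlap: index ranges must be disjoint",
         call. = FALSE)
  take <- min(as.integer(m), length(idx))
  o <- order(keys)[seq_len(take)]
  structure(list(indices = idx[o], keys = keys[o], m = as.integer(m)),
            class = "weighted_sample")
}

#' Deterministic substream seeds
#'
#' Maps a base seed and a stream identifier (e.g. an index-range id) to a
#' derived seed in `[1, 2^31)`, so that work split across ranges can draw
#' from named, reproducible streams: the same `(seed, stream)` pair always
#' yields the same variates regardless of how many workers execute the
#' ranges.
#'
#' @param seed base integer seed.
#' @param stream nonnegative integer stream identifier.
#' @return an integer seed suitable for `set.seed()`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) == 1L, stream >= 0)
  # affine mix modulo a prime below 2^31; all arithmetic stays well inside
  # the 2^53 exact-integer range of doubles
  v <- (abs(as.double(seed)) %% 2147483647) * 48271 + as.double(stream) * 1000003
  as.integer(v %% 2147483563) + 1L
}
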