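#' Adjusted Rand Index
#'
#' Chance-corrected pairwise agreement between two partitions of the same
#' rows (Hubert-Arabie form).  From the contingency table `n_ij` of the two
#' labelings with marginals `a_i`, `b_j` and total `n`:
#' `ARI = (Index - Expected) / (Max - Expected)` where
#' `Index = sum_ij C(n_ij, 2)`, `Expected = sum_i C(a_i, 2) sum_j C(b_j, 2) / C(n, 2)`
#' and `Max = (sum_i C(a_i, 2) + sum_j C(b_j, 2)) / 2`.  The value is 1 for
#' identical partitions (up to label names), about 0 for independent random
#' labelings, and can be negative.  In the degenerate case `Max = Expected`
#' (e.g. both labelings put all rows in one cluster) the value is defined as
#' 0, so trivial clusterings are not rewarded.
#'
#' @param pred,truth vectors of equal length (`>= 2`); any atomic label type.
#' @return a single value in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("labelings have different lengths", call. = FALSE)
  if (length(pred) < 2L)
    stop("need at least two rows", call. = FALSE)
  tab <- table(pred, truth)
  n <- sum(tab)
  idx <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maxidx <- (a + b) / 2
  if (maxidx == expected) return(0)
  (idx - expected) / (maxidx - expected)
}

#' Clustering summary report
#'
#' Collects the headline quantities of a fitted clustering — `k`, measure,
#' prior, final objective cost, iterations/epochs, and (when reference labels
#' are supplied) the Adjusted Rand Index — into a machine-readable record
#' with stable key order.  Printed as human-readable text; optionally written
#' as JSON.
#'
#' @param result an `skm_result` or `sparse_kmeans` fit.
#' @param labels optional reference labels (length `n_rows`).
#' @param seed optional seed to record.
#' @param file optional path; when given the record is written there as JSON.
#' @return the report list, invisibly (classed `skm_report`).
#' @export
cluster_report <- function(result, labels = NULL, seed = NULL, file = NULL) {
  assign <- if (inherits(result, "sparse_kmeans")) result$cluster else result$assign
  rep <- list(
    k = result$k,
    measure = result$measure,
    prior = if (is.null(result$beta)) "none" else result$beta,
    final_cost = if (inherits(result, "sparse_kmeans")) result$tot_cost else result$tot_cost,
    iterations = result$iterations
  )
  if (!is.null(labels)) {
    if (length(labels) != length(assign))
      stop("labels length does not match the number of rows", call. = FALSE)
    rep$ari <- adjusted_rand_index(assign, labels)
  }
  if (!is.null(seed)) rep$seed <- seed
  class(rep) <- "skm_report"
  if (!is.null(file))
    jsonlite::write_json(unclass(rep), file, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' @export
print.skm_report <- function(x, ...) {
  cat(sprintf("k = %d | measure = %s | prior = %s | cost = %.6g | iters = %d",
              x$k, x$measure, format(x$prior), x$final_cost, x$iterations))
  if (!is.null(x$ari)) cat(sprintf(" | ARI = %.4f", x$ari))
  if (!is.null(x$seed)) cat(sprintf(" | seed = %d", x$seed))
  cat("\n")
  invisible(x)
}
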