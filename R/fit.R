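#' Sparse k-means clustering of count data
#'
#' Fits a k-means clustering to a sparse nonnegative count matrix (cells in
#' rows, genes in columns) under one of five dissimilarities, running the
#' full pipeline: optional highly-variable-gene preselection, k-means++
#' seeding with multi-candidate selection, localsearch++ swap refinement,
#' and either Lloyd's algorithm or mini-batch k-means.
#'
#' The probability measures (KLD, JSD, BATMET) treat each cell as a
#' distribution over genes under a Gamma(`prior`, `prior`) pseudo-count
#' prior, applied lazily so all distance work is proportional to the number
#' of stored entries.  SQE operates on raw counts and COS on L2-normalized
#' rows; both ignore the prior.
#'
#' @param x input matrix: a [csr_matrix()], base `matrix`, or any `Matrix`
#'   sparse matrix, rows = observations.
#' @param k number of clusters.
#' @param measure `"SQE"`, `"KLD"`, `"JSD"`, `"BATMET"` or `"COS"`
#'   (case-insensitive).
#' @param prior pseudo-count `beta > 0` for the probability measures, or
#'   `NULL` for no prior.  Default `0.01`.
#' @param hvg keep only the `hvg` most variable genes before clustering
#'   (`0` = keep all).
#' @param n_candidates k-means++ candidates per step
#'   (default `1 + floor(log2(k))`).
#' @param ls_rounds localsearch++ refinement rounds (default 25).
#' @param algorithm `"lloyd"` or `"minibatch"`.
#' @param batch_size mini-batch size.
#' @param max_iter,tol Lloyd iteration cap and relative cost-change
#'   convergence threshold.
#' @param max_epochs mini-batch passes over the data.
#' @param seed optional integer seed; when given, the fit is reproducible
#'   and the caller's RNG state is left untouched.
#' @return an object of class `sparse_kmeans`: a list with `cluster`
#'   (1-based assignments), `centers` (`k x d` matrix in the measure's
#'   working representation), `cost` (per-row), `tot_cost`, `trace` (the
#'   optimizer's objective trace), `seed_trace` (k-means++ step costs),
#'   `ls_trace` (localsearch++ trace), `iterations`, `converged`, `measure`,
#'   `prior`, `k`, `hvg_cols`, `algorithm`, `seed`, `n`, `d` and `call`.
#' @examples
#' sim <- generate_mixture(mixture_spec(n_per_cluster = 30, n_genes = 60,
#'                                      k = 3, seed = 7))
#' fit <- sparse_kmeans(sim$matrix, k = 3, measure = "KLD", seed = 1)
#' fit
#' adjusted_rand_index(fit$cluster, sim$labels)
#' @export
sparse_kmeans <- function(x, k, measure = "SQE", prior = 0.01, hvg = 0,
                          n_candidates = NULL, ls_rounds = 25,
                          algorithm = c("lloyd", "minibatch"),
                          batch_size = 1024, max_iter = 100, tol = 1e-4,
                          max_epochs = 10, seed = NULL) {
  algorithm <- match.arg(algorithm)
  measure <- match_measure(measure)
  m <- as_csr(x)
  run <- function() {
    hvg_cols <- NULL
    if (hvg > 0) {
      sel <- select_hvg(m, hvg)
      m <- sel$matrix
      hvg_cols <- sel$cols
    }
    prep <- skm_prep(m, measure, prior)
    seeds <- kmeanspp_impl(prep, k, n_candidates)
    seeds <- localsearchpp_impl(prep, seeds, ls_rounds)
    res <- if (algorithm == "lloyd") {
      lloyd_impl(prep, seeds, max_iter = max_iter, tol = tol)
    } else {
      minibatch_impl(prep, seeds, batch_size = batch_size,
                     max_epochs = max_epochs)
    }
    structure(
      list(cluster = res$assign, centers = res$centers, cost = res$cost,
           tot_cost = res$tot_cost, trace = res$trace,
           seed_trace = attr(seeds, "step_costs"),
           ls_trace = attr(seeds, "ls_trace"),
           iterations = res$iterations, converged = res$converged,
           measure = measure, beta = check_beta(prior), prior = prior,
           k = res$k, hvg_cols = hvg_cols, algorithm = algorithm,
           seed = seed, n = m$n_rows, d = m$n_cols, call = match.call()),
      class = "sparse_kmeans")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.sparse_kmeans <- function(x, ...) {
  cat(sprintf("Sparse k-means fit (%s)\n", x$algorithm))
  cat(sprintf("  data: %d rows x %d cols%s\n", x$n, x$d,
              if (!is.null(x$hvg_cols))
                sprintf(" (top %d variable genes)", length(x$hvg_cols)) else ""))
  cat(sprintf("  k = %d, measure = %s, prior = %s\n", x$k, x$measure,
              if (is.null(x$beta)) "none" else format(x$beta)))
  cat(sprintf("  total cost = %.6g after %d %s%s\n", x$tot_cost,
              x$iterations,
              if (x$algorithm == "minibatch") "epochs" else "iterations",
              if (isTRUE(x$converged)) " (converged)" else ""))
  sizes <- tabulate(x$cluster, nbins = x$k)
  cat("  cluster sizes: ", paste(sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.sparse_kmeans <- function(object, ...) {
  sizes <- tabulate(object$cluster, nbins = object$k)
  within <- vapply(seq_len(object$k), function(c)
    sum(object$cost[object$cluster == c]), numeric(1))
  out <- list(k = object$k, measure = object$measure, beta = object$beta,
              sizes = sizes, within_cost = within,
              tot_cost = object$tot_cost, trace = object$trace,
              iterations = object$iterations, converged = object$converged,
              algorithm = object$algorithm)
  class(out) <- "summary.sparse_kmeans"
  out
}

#' @export
print.summary.sparse_kmeans <- function(x, ...) {
  cat(sprintf("Sparse k-means (%s), k = %d, measure = %s\n",
              x$algorithm, x$k, x$measure))
  df <- data.frame(cluster = seq_len(x$k), size = x$sizes,
                   within_cost = signif(x$within_cost, 6))
  print(df, row.names = FALSE)
  cat(sprintf("total cost: %.6g  (%d %s%s)\n", x$tot_cost, x$iterations,
              if (x$algorithm == "minibatch") "epochs" else "iterations",
              if (isTRUE(x$converged)) ", converged" else ""))
  invisible(x)
}

#' @export
coef.sparse_kmeans <- function(object, ...) object$centers

#' Predict cluster membership for new rows
#'
#' Assigns new observations to the fitted centers under the fit's measure
#' and prior.  When the fit used highly-variable-gene preselection, the same
#' columns are sliced from the new data (which must have the original
#' width).
#'
#' @param object a `sparse_kmeans` fit.
#' @param newdata matrix-like with the same number of columns the fit was
#'   given.
#' @param type `"cluster"` for assignments, `"cost"` for the per-row minimum
#'   cost.
#' @param ... unused.
#' @return integer assignments or numeric costs.
#' @export
predict.sparse_kmeans <- function(object, newdata,
                                  type = c("cluster", "cost"), ...) {
  type <- match.arg(type)
  m <- as_csr(newdata)
  if (!is.null(object$hvg_cols)) {
    if (m$n_cols == object$d) {
      # already sliced to the fitted gene set
    } else {
      m <- csr_select_cols(m, object$hvg_cols)
    }
  }
  if (m$n_cols != object$d)
    stop("newdata has ", m$n_cols, " columns; the fit uses ", object$d,
         call. = FALSE)
  pc <- point_to_centers(m, object$centers, object$measure, object$beta)
  if (type == "cluster") pc$assign else pc$cost
}

#' @export
fitted.sparse_kmeans <- function(object, type = c("classes", "centers"), ...) {
  type <- match.arg(type)
  if (type == "classes") object$cluster
  else object$centers[object$cluster, , drop = FALSE]
}

#' Objective-trace plot
#'
#' Plots the optimizer's objective trace (per Lloyd iteration or mini-batch
#' epoch), prefixed by the localsearch++ trace when present.
#'
#' @param x a `sparse_kmeans` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sparse_kmeans <- function(x, ...) {
  ls <- x$ls_trace
  tr <- x$trace
  y <- c(ls, tr)
  phase <- c(rep("localsearch++", length(ls)), rep(x$algorithm, length(tr)))
  graphics::plot(seq_along(y), y, type = "b",
                 xlab = "refinement step", ylab = "objective cost",
                 main = sprintf("k = %d, %s", x$k, x$measure), ...)
  if (length(ls))
    graphics::abline(v = length(ls) + 0.5, lty = 2, col = "grey50")
  invisible(x)
}
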