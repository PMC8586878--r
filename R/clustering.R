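skm_result <- function(centers, assign, cost, trace, iterations, converged,
                       measure, beta, algorithm) {
  structure(list(centers = centers, assign = assign, cost = cost,
                 tot_cost = sum(cost), trace = trace,
                 iterations = iterations, converged = converged,
                 measure = measure, beta = beta, algorithm = algorithm,
                 k = nrow(centers)),
            class = "skm_result")
}

#' @export
print.skm_result <- function(x, ...) {
  cat(sprintf("%s k-means: k = %d, measure = %s, cost = %.6g after %d %s%s\n",
              x$algorithm, x$k, x$measure, x$tot_cost, x$iterations,
              if (x$algorithm == "minibatch") "epochs" else "iterations",
              if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

# reseed empty clusters to the rows with the largest current cost, in
# decreasing-cost order; deterministic given the cost array
reseed_empty <- function(prep, C, assign, cost, empty) {
  for (c in empty) {
    i <- which.max(cost)
    C[c, ] <- skm_row_rep(prep, i)
    assign[i] <- c
    cost[i] <- 0
  }
  list(C = C, assign = assign, cost = cost)
}

# mean of working representations per cluster, vectorized over clusters
cluster_means <- function(prep, assign, k, C_old) {
  sizes <- tabulate(assign, nbins = k)
  Z <- Matrix::sparseMatrix(i = assign, j = seq_along(assign), x = 1,
                            dims = c(k, length(assign)))
  C <- C_old
  occ <- sizes > 0
  if (prep$measure == "SQE") {
    M <- as.matrix(Z %*% prep$X)
  } else if (prep$measure == "COS") {
    Xn <- Matrix::Diagonal(x = 1 / prep$l2) %*% prep$X
    M <- as.matrix(Z %*% Xn)
  } else {
    M <- as.matrix(Z %*% prep$Ps) + as.vector(Z %*% prep$bg)
  }
  C[occ, ] <- M[occ, , drop = FALSE] / sizes[occ]
  if (prep$measure == "COS") {
    nrm <- sqrt(rowSums(C^2))
    pos <- nrm > 0
    C[pos, ] <- C[pos, , drop = FALSE] / nrm[pos]
  }
  C
}

#' Lloyd's k-means
#'
#' Alternates (a) assigning every row to its nearest center (ties toward the
#' lowest center index) and (b) recomputing each center as the arithmetic
#' mean of its members' working representations: raw counts for SQE,
#' prior-adjusted probability vectors for KLD/JSD/BATMET (for Bregman
#' divergences the mean is the exact cost-minimizing representative), and
#' re-normalized L2 unit vectors for COS.  Empty clusters are reseeded to the
#' row with the largest current cost.  Stops when the relative cost change
#' falls below `tol`, when the assignment reaches a fixed point, or after
#' `max_iter` iterations.  The objective trace is nonincreasing for the
#' Bregman measures (SQE, KLD).
#'
#' @param m a canonical `csr_matrix`.
#' @param centers a `center_set` (e.g. from [kmeanspp()]) or a dense
#'   `k x n_cols` matrix in the measure's working representation.
#' @param measure,beta used only when `centers` is a bare matrix.
#' @param max_iter maximum iterations (`0` returns the seeds unchanged).
#' @param tol relative cost-change convergence threshold.
#' @return an `skm_result`.
#' @export
lloyd <- function(m, centers, measure = "SQE", beta = NULL,
                  max_iter = 100, tol = 1e-4) {
  if (inherits(centers, "center_set")) {
    measure <- centers$measure; beta <- centers$beta
  }
  prep <- skm_prep(m, measure, beta)
  lloyd_impl(prep, centers, max_iter, tol)
}

lloyd_impl <- function(prep, centers, max_iter = 100, tol = 1e-4) {
  C <- if (inherits(centers, "center_set")) centers$centers else centers
  k <- nrow(C)
  n <- prep$n
  if (max_iter == 0) {
    D <- skm_cost_matrix(prep, C)
    a <- max.col(-D, ties.method = "first")
    return(skm_result(C, a, D[cbind(seq_len(n), a)], numeric(0), 0L, FALSE,
                      prep$measure, prep$beta, "lloyd"))
  }
  trace <- numeric(0)
  assign_prev <- NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- skm_cost_matrix(prep, C)
    assign <- max.col(-D, ties.method = "first")
    cost <- D[cbind(seq_len(n), assign)]
    empty <- which(tabulate(assign, nbins = k) == 0L)
    if (length(empty)) {
      rs <- reseed_empty(prep, C, assign, cost, empty)
      C <- rs$C; assign <- rs$assign; cost <- rs$cost
    }
    trace <- c(trace, sum(cost))
    if (!is.null(assign_prev) && identical(assign, assign_prev)) {
      converged <- TRUE
      break
    }
    if (length(trace) >= 2L) {
      prev <- trace[length(trace) - 1L]
      if (abs(prev - trace[length(trace)]) <= tol * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
    if (iter >= max_iter) break
    C_new <- cluster_means(prep, assign, k, C)
    if (all(C_new == C)) {       # exact fixed point: centers unchanged
      converged <- TRUE
      break
    }
    C <- C_new
    assign_prev <- assign
  }
  skm_result(C, assign, cost, trace, iter, converged,
             prep$measure, prep$beta, "lloyd")
}

#' Mini-batch k-means
#'
#' Stochastic k-means: each step draws a uniform batch of rows (without
#' replacement within the batch), assigns them to their nearest centers, and
#' moves every touched center toward the batch mean of its assigned rows
#' with a per-center learning rate `1 / N_c`, where `N_c` counts all batch
#' rows ever assigned to center `c`.  This is the streaming-mean update: with
#' `batch_size = n_rows` one epoch reproduces one full Lloyd update exactly.
#' The full-data objective is evaluated at the end of every epoch (an epoch
#' is `ceiling(n / batch_size)` batches); clusters empty on the full data at
#' an epoch end are reseeded to the largest-cost row.
#'
#' @param m a canonical `csr_matrix`.
#' @param centers a `center_set` or dense center matrix.
#' @param measure,beta used only when `centers` is a bare matrix.
#' @param batch_size rows per batch (clamped to `n_rows` with a warning).
#' @param max_epochs number of passes.
#' @return an `skm_result` with the per-epoch full-data objective as `trace`.
#' @export
minibatch_kmeans <- function(m, centers, measure = "SQE", beta = NULL,
                             batch_size = 1024, max_epochs = 10) {
  if (inherits(centers, "center_set")) {
    measure <- centers$measure; beta <- centers$beta
  }
  prep <- skm_prep(m, measure, beta)
  minibatch_impl(prep, centers, batch_size, max_epochs)
}

minibatch_impl <- function(prep, centers, batch_size = 1024, max_epochs = 10) {
  C <- if (inherits(centers, "center_set")) centers$centers else centers
  k <- nrow(C); n <- prep$n
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (batch_size > n) {
    warning("batch_size exceeds n_rows; clamped to ", n, call. = FALSE)
    batch_size <- n
  }
  batch_size <- as.integer(batch_size)
  # COS centers are used L2-normalized for distances, but the streaming mean
  # is maintained on the raw running mean M
  M <- C
  Ncount <- numeric(k)
  steps <- ceiling(n / batch_size)
  trace <- numeric(max_epochs)
  eval_centers <- function(M) {
    if (prep$measure != "COS") return(M)
    nrm <- sqrt(rowSums(M^2))
    pos <- nrm > 0
    M[pos, ] <- M[pos, , drop = FALSE] / nrm[pos]
    M
  }
  for (ep in seq_len(max_epochs)) {
    for (st in seq_len(steps)) {
      idx <- sample.int(n, batch_size)
      Db <- skm_cost_matrix(prep, eval_centers(M), rows = idx)
      ab <- max.col(-Db, ties.method = "first")
      for (c in unique(ab)) {
        rows_c <- idx[ab == c]
        nb <- length(rows_c)
        xbar <- skm_rep_mean(prep, rows_c)
        M[c, ] <- (Ncount[c] * M[c, ] + nb * xbar) / (Ncount[c] + nb)
        Ncount[c] <- Ncount[c] + nb
      }
    }
    D <- skm_cost_matrix(prep, eval_centers(M))
    assign <- max.col(-D, ties.method = "first")
    cost <- D[cbind(seq_len(n), assign)]
    empty <- which(tabulate(assign, nbins = k) == 0L)
    for (c in empty) {
      i <- which.max(cost)
      M[c, ] <- skm_row_rep(prep, i)
      assign[i] <- c
      cost[i] <- 0
      Ncount[c] <- 1
    }
    trace[ep] <- sum(cost)
  }
  Cfin <- eval_centers(M)
  D <- skm_cost_matrix(prep, Cfin)
  assign <- max.col(-D, ties.method = "first")
  cost <- D[cbind(seq_len(n), assign)]
  skm_result(Cfin, assign, cost, trace, as.integer(max_epochs), NA,
             prep$measure, prep$beta, "minibatch")
}
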