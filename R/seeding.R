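#' Center set
#'
#' Bundles `k` dense centers (rows of a `k x n_cols` matrix in the measure's
#' working representation), the data rows they came from (when centers are
#' data points), and the per-row minimum cost and assignment arrays.
#'
#' @param centers dense `k x n_cols` matrix.
#' @param source_rows integer vector of originating data rows, or `NA`.
#' @param cost per-row minimum cost.
#' @param assign per-row 1-based assigned center.
#' @param measure,beta the dissimilarity configuration the costs refer to.
#' @return an object of class `center_set`.
#' @export
center_set <- function(centers, source_rows, cost, assign, measure, beta) {
  structure(list(centers = centers, source_rows = source_rows,
                 cost = cost, assign = assign,
                 measure = match_measure(measure), beta = check_beta(beta),
                 k = nrow(centers)),
            class = "center_set")
}

#' @export
print.center_set <- function(x, ...) {
  cat(sprintf("center_set: k = %d, measure = %s, total cost = %.6g\n",
              x$k, x$measure, sum(x$cost)))
  invisible(x)
}

# internal: build a center_set from data rows, computing cost/assign
center_set_from_rows <- function(prep, rows) {
  C <- skm_row_rep(prep, rows)
  D <- skm_cost_matrix(prep, C)
  a <- max.col(-D, ties.method = "first")
  center_set(C, rows, D[cbind(seq_len(nrow(D)), a)], a,
             prep$measure, prep$beta)
}

#' k-means++ seeding
#'
#' Chooses `k` data rows as initial centers.  The first center is uniform
#' over rows; each subsequent center is drawn with probability proportional
#' to each row's current cost (its dissimilarity to the nearest already
#' chosen center), which yields an expected objective within an O(log k)
#' factor of the optimum for squared Euclidean distance and, more generally,
#' for Bregman divergences.  With `n_candidates > 1`, each step draws several
#' candidates without replacement from the cost distribution and keeps the
#' one whose acceptance gives the lowest total cost (greedy k-means++).
#'
#' After each step the per-row cost array is updated to the elementwise
#' minimum of the previous costs and the distances to the new center, so it
#' is monotone nonincreasing per row; the per-step total cost trace is
#' returned as attribute `"step_costs"`.
#'
#' @param m a canonical `csr_matrix`.
#' @param k number of centers (`1 <= k <= n_rows`).
#' @param measure,beta see [sparse_distance()].
#' @param n_candidates candidates per step; default `1 + floor(log2(k))`.
#' @return a `center_set`.
#' @export
kmeanspp <- function(m, k, measure = "SQE", beta = NULL, n_candidates = NULL) {
  prep <- skm_prep(m, measure, beta)
  kmeanspp_impl(prep, k, n_candidates)
}

kmeanspp_impl <- function(prep, k, n_candidates = NULL) {
  n <- prep$n
  if (length(k) != 1L || is.na(k) || k < 1 || k > n)
    stop("k must satisfy 1 <= k <= n_rows", call. = FALSE)
  k <- as.integer(k)
  if (is.null(n_candidates)) n_candidates <- 1L + floor(log2(k))
  if (n_candidates < 1) stop("n_candidates must be >= 1", call. = FALSE)

  rows <- integer(k)
  rows[1L] <- sample.int(n, 1L)
  C <- matrix(0, k, prep$d)
  C[1L, ] <- skm_row_rep(prep, rows[1L])
  cost <- as.vector(skm_cost_matrix(prep, C[1L, , drop = FALSE]))
  assign <- rep.int(1L, n)
  step_costs <- numeric(k)
  step_costs[1L] <- sum(cost)

  for (step in seq_len(k)[-1L]) {
    if (all(cost == 0)) {
      warning("fewer than k distinct rows: duplicating centers", call. = FALSE)
      cand <- sample.int(n, 1L)
      dz <- as.vector(skm_cost_matrix(
        prep, skm_row_rep(prep, cand)))
      best_row <- cand; best_dz <- dz
    } else {
      cand <- weighted_sample_wor(cost, n_candidates)$indices
      best_tot <- Inf; best_row <- NA_integer_; best_dz <- NULL
      Dc <- skm_cost_matrix(prep, skm_row_rep(prep, cand))
      for (j in seq_along(cand)) {
        tot <- sum(pmin(cost, Dc[, j]))
        if (tot < best_tot) {
          best_tot <- tot; best_row <- cand[j]; best_dz <- Dc[, j]
        }
      }
    }
    rows[step] <- best_row
    C[step, ] <- skm_row_rep(prep, best_row)
    improved <- best_dz < cost
    cost[improved] <- best_dz[improved]
    assign[improved] <- step
    step_costs[step] <- sum(cost)
  }
  out <- center_set(C, rows, cost, assign, prep$measure, prep$beta)
  attr(out, "step_costs") <- step_costs
  out
}

#' localsearch++ center refinement
#'
#' Refines a seeded center set by cost-proportional swap moves.  Each round:
#' (1) a candidate row `z` is drawn with probability proportional to the
#' current per-row cost, using the exponential-key sampling kernel; (2) for
#' every current center `c`, the objective of the swapped set
#' `(centers - c) + z` is evaluated exactly, using each row's best and
#' second-best center costs; (3) the best swap is applied only if it strictly
#' lowers the total cost.  The total objective is therefore nonincreasing
#' across rounds; the per-round trace is returned as attribute `"ls_trace"`.
#'
#' @param m a canonical `csr_matrix`.
#' @param centers a `center_set` (centers must be data rows of `m`).
#' @param rounds number of refinement rounds (`>= 0`).
#' @return the refined `center_set`.
#' @export
localsearchpp <- function(m, centers, rounds) {
  prep <- skm_prep(m, centers$measure, centers$beta)
  localsearchpp_impl(prep, centers, rounds)
}

localsearchpp_impl <- function(prep, cs, rounds) {
  if (length(rounds) != 1L || is.na(rounds) || rounds < 0)
    stop("rounds must be >= 0", call. = FALSE)
  rounds <- as.integer(rounds)
  if (rounds == 0L) {
    attr(cs, "ls_trace") <- sum(cs$cost)
    return(cs)
  }
  n <- prep$n; k <- cs$k
  D <- skm_cost_matrix(prep, cs$centers)
  idx1 <- max.col(-D, ties.method = "first")
  c1 <- D[cbind(seq_len(n), idx1)]
  total <- sum(c1)
  trace <- numeric(rounds + 1L)
  trace[1L] <- total

  second_best <- function(D, idx1) {
    D2 <- D
    D2[cbind(seq_len(n), idx1)] <- Inf
    i2 <- max.col(-D2, ties.method = "first")
    D2[cbind(seq_len(n), i2)]
  }
  c2 <- second_best(D, idx1)
  moves <- data.frame(round = seq_len(rounds), z = NA_integer_,
                      center = NA_integer_, accepted = FALSE,
                      total = NA_real_)

  for (r in seq_len(rounds)) {
    if (all(c1 == 0)) {           # perfect covering: no sampling mass
      trace[r + 1L] <- total
      moves$total[r] <- total
      next
    }
    z <- weighted_sample_wor(c1, 1L)$indices
    dz <- as.vector(skm_cost_matrix(prep, skm_row_rep(prep, z)))
    # cost of each row if center c were removed: second best where c is its
    # best, unchanged otherwise
    B <- matrix(c1, n, k)
    B[cbind(seq_len(n), idx1)] <- c2
    tot_swap <- colSums(pmin(B, dz))
    cstar <- which.min(tot_swap)
    moves$z[r] <- z
    if (tot_swap[cstar] < total) {
      moves$center[r] <- cstar
      moves$accepted[r] <- TRUE
      cs$centers[cstar, ] <- skm_row_rep(prep, z)
      cs$source_rows[cstar] <- z
      D[, cstar] <- dz
      idx1 <- max.col(-D, ties.method = "first")
      c1 <- D[cbind(seq_len(n), idx1)]
      c2 <- second_best(D, idx1)
      total <- sum(c1)
    }
    trace[r + 1L] <- total
    moves$total[r] <- total
  }
  cs$cost <- c1
  cs$assign <- idx1
  attr(cs, "ls_trace") <- trace
  attr(cs, "ls_moves") <- moves
  cs
}
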