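#' @keywords internal
"_PACKAGE"

# package-level state for the entry-touch instrumentation
.skm_env <- new.env(parent = emptyenv())
.skm_env$touch <- 0
.skm_env$count_touches <- FALSE

MEASURES <- c("SQE", "KLD", "JSD", "BATMET", "COS")
PROB_MEASURES <- c("KLD", "JSD", "BATMET")

match_measure <- function(measure) {
  m <- toupper(measure[1L])
  if (!m %in% MEASURES)
    stop("unknown measure '", measure, "'; must be one of ",
         paste(MEASURES, collapse = ", "), call. = FALSE)
  m
}

check_beta <- function(beta) {
  if (is.null(beta)) return(NULL)
  if (length(beta) != 1L || is.na(beta) || !is.finite(beta) || beta <= 0)
    stop("prior beta must be a single finite value > 0 (or NULL for no prior)",
         call. = FALSE)
  as.double(beta)
}

#' Pseudo-count prior configuration
#'
#' The probability-based measures (KLD, JSD, BATMET) view each row as a
#' probability vector over genes.  Zero counts would make these divergences
#' infinite or undefined, so a Gamma(beta, beta) prior adds a pseudo-count
#' `beta > 0` to every feature: the posterior estimate of feature `i` is
#' `(X_i + beta) / (S + d * beta)`.  `beta = 1` is the Dirichlet (Laplace)
#' case; smaller values penalize missing observations more.  `beta = NULL`
#' disables the prior (rows are normalized by their raw totals; zero-sum rows
#' are then rejected for probability measures).
#'
#' @param beta pseudo-count (`> 0`) or `NULL`.
#' @return an object of class `skm_prior`.
#' @export
prior_config <- function(beta = NULL) {
  structure(list(beta = check_beta(beta)), class = "skm_prior")
}

#' @export
print.skm_prior <- function(x, ...) {
  if (is.null(x$beta)) cat("no prior (raw normalization)\n")
  else cat(sprintf("Gamma(beta, beta) pseudo-count prior, beta = %g%s\n",
                   x$beta, if (x$beta == 1) " (Dirichlet)" else ""))
  invisible(x)
}

#' Entry-touch instrumentation
#'
#' When enabled, every pairwise distance evaluation adds the number of stored
#' entries it actually visited to a package-level counter.  This exposes the
#' O(nnz) complexity contract: the counter grows with the union support of
#' the two rows, never with the feature count `d`.
#'
#' @param on logical; enable or disable counting.
#' @return `touch_count()` returns the current counter value.
#' @export
count_touches <- function(on = TRUE) {
  .skm_env$count_touches <- isTRUE(on)
  invisible(on)
}

#' @rdname count_touches
#' @export
reset_touch_count <- function() {
  .skm_env$touch <- 0
  invisible(0)
}

#' @rdname count_touches
#' @export
touch_count <- function() .skm_env$touch

touch_add <- function(k) {
  if (.skm_env$count_touches) .skm_env$touch <- .skm_env$touch + k
  invisible(NULL)
}

# z * log(z) with 0 log 0 = 0
xlogx <- function(z) {
  out <- numeric(length(z))
  p <- z > 0
  out[p] <- z[p] * log(z[p])
  out
}

# coerce a distance operand into a sparse triple (1-based cols, vals, d)
as_sparse_row <- function(x) {
  if (inherits(x, "csr_matrix")) {
    if (x$n_rows != 1L) stop("expected a single-row matrix", call. = FALSE)
    r <- csr_row(x, 1L)
    return(list(cols = r$cols, vals = r$vals, d = x$n_cols))
  }
  if (is.numeric(x)) {
    if (any(x < 0)) stop("negative values are not allowed", call. = FALSE)
    nz <- which(x != 0)
    return(list(cols = nz, vals = as.double(x[nz]), d = length(x)))
  }
  if (is.list(x) && all(c("cols", "vals", "d") %in% names(x))) return(x)
  stop("cannot interpret operand as a sparse row", call. = FALSE)
}

#' Prior-adjusted probability view of a row
#'
#' Returns the normalized representation of row `i` under the active prior
#' without materializing the dense vector: the support values
#' `(X_i + beta) / (S + d * beta)`, the shared background value
#' `beta / (S + d * beta)` taken by every zero feature, and the dimensions
#' needed to reconstruct the full vector.  The full vector sums to one:
#' the `d - nnz` zero features contribute `(d - nnz) * bg` in aggregate.
#'
#' @param m a canonical `csr_matrix`.
#' @param i row index.
#' @param beta prior pseudo-count, or `NULL` to normalize by the raw total
#'   (rejected when the row sum is zero).
#' @return list with `cols` (1-based support), `prob` (support values), `bg`
#'   (background value), `d`, `nnz`.
#' @export
normalized_row <- function(m, i, beta = NULL) {
  beta <- check_beta(beta)
  r <- csr_row(m, i)
  s <- sum(r$vals)
  if (is.null(beta)) {
    if (s <= 0)
      stop("zero-sum row has no probability representation without a prior",
           call. = FALSE)
    list(cols = r$cols, prob = r$vals / s, bg = 0, d = m$n_cols,
         nnz = length(r$vals))
  } else {
    t <- s + m$n_cols * beta
    list(cols = r$cols, prob = (r$vals + beta) / t, bg = beta / t,
         d = m$n_cols, nnz = length(r$vals))
  }
}

#' Sparse dissimilarity between two rows
#'
#' Evaluates one of the five supported measures between two sparse
#' nonnegative vectors in time and space proportional to the number of
#' stored entries (`nnz`), never to the feature count `d`.  Probability
#' measures (KLD, JSD, BATMET) operate on the prior-adjusted probability
#' views of the rows; the `d - |supp(x) u supp(y)|` features where both rows
#' are zero share one background value per row, so their total contribution
#' is a single closed-form term.  SQE and COS operate on the raw values and
#' ignore the prior.
#'
#' Formulas (natural log throughout):
#' \itemize{
#'   \item SQE: `sum_i (X_i - Y_i)^2`
#'   \item KLD: `sum_i xh_i log(xh_i / yh_i)`
#'   \item JSD: `(KLD(xh, m) + KLD(yh, m)) / 2` with `m = (xh + yh) / 2`;
#'     bounded by `log 2`
#'   \item BATMET: `sqrt(1 - sum_i sqrt(xh_i yh_i))` (Bhattacharyya metric,
#'     clamped at 0 against floating-point negatives)
#'   \item COS: `1 - (x . y) / (|x| |y|)`
#' }
#' where `xh`, `yh` are the prior-adjusted probability vectors.
#'
#' @param x,y operands: numeric vectors, single-row `csr_matrix` objects, or
#'   `list(cols, vals, d)` sparse triples.
#' @param measure one of `"SQE"`, `"KLD"`, `"JSD"`, `"BATMET"`, `"COS"`
#'   (case-insensitive).
#' @param beta pseudo-count prior for the probability measures, or `NULL`.
#' @return a single nonnegative dissimilarity.
#' @examples
#' sparse_distance(c(1, 2, 0), c(3, 4, 0), "SQE")  # 8
#' @export
sparse_distance <- function(x, y, measure = "SQE", beta = NULL) {
  measure <- match_measure(measure)
  beta <- check_beta(beta)
  x <- as_sparse_row(x); y <- as_sparse_row(y)
  if (x$d != y$d) stop("operands have different feature counts", call. = FALSE)
  d <- x$d

  u <- sort(unique(c(x$cols, y$cols)))
  a <- numeric(length(u)); b <- numeric(length(u))
  a[match(x$cols, u)] <- x$vals
  b[match(y$cols, u)] <- y$vals
  touch_add(length(x$cols) + length(y$cols) + length(u))

  if (measure == "SQE") return(sum((a - b)^2))
  if (measure == "COS") {
    nx <- sqrt(sum(x$vals^2)); ny <- sqrt(sum(y$vals^2))
    if (nx == 0 || ny == 0)
      stop("cosine distance is undefined for an all-zero row", call. = FALSE)
    return(max(0, 1 - sum(a * b) / (nx * ny)))
  }

  sx <- sum(x$vals); sy <- sum(y$vals)
  if (is.null(beta)) {
    if (sx <= 0 || sy <= 0)
      stop("probability measures need a prior or strictly positive row sums",
           call. = FALSE)
    p <- a / sx; q <- b / sy; bx <- 0; by <- 0
  } else {
    tx <- sx + d * beta; ty <- sy + d * beta
    p <- (a + beta) / tx; q <- (b + beta) / ty
    bx <- beta / tx; by <- beta / ty
  }
  z <- d - length(u)  # features where both rows are zero

  if (measure == "KLD") {
    sup <- sum(ifelse(p > 0, p * log(p / q), 0))
    agg <- if (z > 0 && bx > 0) z * bx * log(bx / by) else 0
    return(max(0, sup + agg))
  }
  if (measure == "JSD") {
    m2 <- (p + q) / 2
    sup <- sum(0.5 * (xlogx(p) + xlogx(q)) - xlogx(m2))
    mb <- (bx + by) / 2
    agg <- if (z > 0) z * (0.5 * (xlogx(bx) + xlogx(by)) - xlogx(mb)) else 0
    return(max(0, sup + agg))
  }
  # BATMET
  bc <- sum(sqrt(p * q)) + z * sqrt(bx * by)
  sqrt(max(0, 1 - bc))
}

# ---------------------------------------------------------------------------
# vectorized machinery: per-matrix "prep" and n x k cost matrices

# Precompute everything the vectorized cost kernels need for matrix `m`
# under prior `beta`.  X is the raw dgCMatrix; for probability measures we
# also keep the negative entropy H of each prior-adjusted row, computed from
# the support plus the aggregate background term.
skm_prep <- function(m, measure, beta) {
  measure <- match_measure(measure)
  beta <- check_beta(beta)
  X <- csr_to_dgc(m)
  n <- m$n_rows; d <- m$n_cols
  s <- Matrix::rowSums(X)
  nnz <- csr_row_nnz(m)
  prep <- list(measure = measure, beta = beta, X = X, n = n, d = d,
               s = s, nnz = nnz)
  if (measure == "SQE") {
    prep$sq <- Matrix::rowSums(X^2)
  } else if (measure == "COS") {
    prep$l2 <- sqrt(Matrix::rowSums(X^2))
    if (any(prep$l2 == 0))
      stop("cosine distance is undefined for an all-zero row", call. = FALSE)
  } else {
    if (is.null(beta)) {
      if (any(s <= 0))
        stop("probability measures need a prior or strictly positive row sums",
             call. = FALSE)
      prep$t <- s
      prep$bg <- numeric(n)
    } else {
      prep$t <- s + d * beta
      prep$bg <- beta / prep$t
    }
    # support values of the prior-adjusted rows, as two sparse pieces:
    # Ps = X / t (the increment over the background) and the scalar bg.
    prep$Ps <- Matrix::Diagonal(x = 1 / prep$t) %*% X
    # negative entropy H = sum xh log xh, support + aggregate background
    row <- rep.int(seq_len(n), diff(m$indptr))
    xh <- (m$data + if (is.null(beta)) 0 else beta) / prep$t[row]
    hsup <- numeric(n)
    if (length(xh)) {
      agg <- rowsum(xlogx(xh), row, reorder = FALSE)
      hsup[as.integer(rownames(agg))] <- agg[, 1L]
    }
    prep$H <- hsup + (d - nnz) * xlogx(prep$bg)
  }
  prep
}

# n x k matrix of distances from every row to every dense center.
# Centers live in the measure's working representation: raw counts for SQE,
# L2-normalized vectors for COS, probability vectors for KLD/JSD/BATMET.
# `rows` optionally restricts to a subset of rows (indices into 1..n).
skm_cost_matrix <- function(prep, C, rows = NULL) {
  if (ncol(C) != prep$d) stop("center width does not match feature count",
                              call. = FALSE)
  X <- prep$X
  sub <- !is.null(rows)
  if (sub) X <- X[rows, , drop = FALSE]
  k <- nrow(C)
  measure <- prep$measure

  if (measure == "SQE") {
    sq <- if (sub) prep$sq[rows] else prep$sq
    D <- outer(sq, rowSums(C^2), "+") - 2 * as.matrix(X %*% t(C))
    return(pmax(D, 0))
  }
  if (measure == "COS") {
    l2 <- if (sub) prep$l2[rows] else prep$l2
    cn <- sqrt(rowSums(C^2))
    if (any(cn == 0)) stop("all-zero center in cosine distance", call. = FALSE)
    D <- 1 - as.matrix(X %*% t(C)) / outer(l2, cn)
    return(pmax(D, 0))
  }

  t_ <- if (sub) prep$t[rows] else prep$t
  bg <- if (sub) prep$bg[rows] else prep$bg
  H <- if (sub) prep$H[rows] else prep$H

  if (measure == "KLD") {
    if (any(C <= 0))
      stop("KLD needs strictly positive centers (use a prior)", call. = FALSE)
    logC <- log(C)
    L <- rowSums(logC)
    cross <- as.matrix(X %*% t(logC)) / t_ + outer(bg, L)
    return(pmax(H - cross, 0))
  }
  if (measure == "BATMET") {
    sqrtC <- sqrt(C)
    Sc <- rowSums(sqrtC)
    Ps <- if (sub) prep$Ps[rows, , drop = FALSE] else prep$Ps
    # sqrt(xh) on the support minus the background sqrt, same pattern as X
    Q <- Ps
    Tq <- methods::as(Q, "TsparseMatrix")
    qv <- sqrt(Tq@x + bg[Tq@i + 1L]) - sqrt(bg[Tq@i + 1L])
    Q <- Matrix::sparseMatrix(i = Tq@i + 1L, j = Tq@j + 1L, x = qv,
                              dims = dim(Q))
    BC <- as.matrix(Q %*% t(sqrtC)) + outer(sqrt(bg), Sc)
    return(sqrt(pmax(1 - BC, 0)))
  }
  # JSD: 0.5 H_x + 0.5 H_c - 0.5 G + log 2, with
  # G = sum_j (xh_j + c_j) log(xh_j + c_j) split into a background part that
  # depends on the row only through its scalar background bg (grouped over
  # unique bg values) and an O(nnz) support correction.
  Hc <- apply(C, 1L, function(cc) sum(xlogx(cc)))
  nn <- nrow(X)
  G <- matrix(0, nn, k)
  ub <- unique(bg)
  for (u in ub) {
    ridx <- which(bg == u)
    bgrow <- vapply(seq_len(k),
                    function(a) sum(xlogx(u + C[a, ])), numeric(1))
    G[ridx, ] <- matrix(bgrow, length(ridx), k, byrow = TRUE)
  }
  Tx <- methods::as(if (sub) prep$Ps[rows, , drop = FALSE] else prep$Ps,
                    "TsparseMatrix")
  if (length(Tx@x)) {
    irow <- Tx@i + 1L; jcol <- Tx@j + 1L
    bge <- bg[irow]
    for (a in seq_len(k)) {
      ce <- C[a, jcol]
      corr <- xlogx(Tx@x + bge + ce) - xlogx(bge + ce)
      agg <- rowsum(corr, irow, reorder = FALSE)
      G[as.integer(rownames(agg)), a] <- G[as.integer(rownames(agg)), a] + agg[, 1L]
    }
  }
  D <- 0.5 * H + rep(0.5 * Hc, each = nn) - 0.5 * G + log(2)
  pmax(matrix(D, nn, k), 0)
}

# dense working-representation vectors for a set of data rows (k x d)
skm_row_rep <- function(prep, rows) {
  X <- prep$X[rows, , drop = FALSE]
  if (prep$measure == "SQE") return(as.matrix(X))
  if (prep$measure == "COS")
    return(as.matrix(Matrix::Diagonal(x = 1 / prep$l2[rows]) %*% X))
  as.matrix(prep$Ps[rows, , drop = FALSE]) + prep$bg[rows]
}

# mean of the working representations of `members`; for COS the mean is
# re-normalized to unit length
skm_rep_mean <- function(prep, members) {
  if (prep$measure == "SQE") {
    v <- Matrix::colSums(prep$X[members, , drop = FALSE]) / length(members)
    return(as.numeric(v))
  }
  if (prep$measure == "COS") {
    v <- Matrix::colSums(
      Matrix::Diagonal(x = 1 / prep$l2[members]) %*%
        prep$X[members, , drop = FALSE]) / length(members)
    v <- as.numeric(v)
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    return(v)
  }
  as.numeric(Matrix::colSums(prep$Ps[members, , drop = FALSE])) /
    length(members) + mean(prep$bg[members])
}

#' Per-row cost against a set of centers
#'
#' For each row of `m`, the minimum dissimilarity over the given centers and
#' the index of the achieving center (ties broken toward the lowest center
#' index).
#'
#' @param m a canonical `csr_matrix`.
#' @param centers a dense `k x n_cols` matrix in the measure's working
#'   representation, or a `center_set`.
#' @param measure,beta see [sparse_distance()].
#' @return list with `cost` (length `n_rows`), `assign` (1-based center
#'   index) and `cost_matrix` (`n_rows x k`).
#' @export
point_to_centers <- function(m, centers, measure = "SQE", beta = NULL) {
  if (inherits(centers, "center_set")) {
    measure <- centers$measure; beta <- centers$beta
    centers <- centers$centers
  }
  prep <- skm_prep(m, measure, beta)
  D <- skm_cost_matrix(prep, centers)
  assign <- max.col(-D, ties.method = "first")
  list(cost = D[cbind(seq_len(nrow(D)), assign)], assign = assign,
       cost_matrix = D)
}

#' Total clustering objective
#'
#' Sum of per-row minimum costs.
#'
#' @param costs numeric vector of nonnegative per-row costs.
#' @return a single nonnegative number.
#' @export
total_cost <- function(costs) {
  stopifnot(is.numeric(costs))
  sum(costs)
}
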