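#' Row-major sparse count matrix
#'
#' `csr_matrix()` builds a compressed-sparse-row (CSR) matrix, the container
#' every clustering routine in this package consumes.  Rows are observations
#' (cells), columns are features (genes).  The stored representation is the
#' canonical CSR triple: `data` (stored values), `indices` (0-based column
#' index per stored value) and `indptr` (`n_rows + 1` monotone offsets into
#' the other two arrays).
#'
#' A matrix is *canonical* when, within each row, column indices are strictly
#' increasing, no explicit zeros are stored, and no column appears twice.
#' The constructor always canonicalizes: entries are sorted, duplicate
#' (row, column) entries are summed, and zero entries are dropped.  Negative
#' values, out-of-range indices and non-monotone `indptr` are errors.
#'
#' @param data numeric vector of stored values (all `>= 0`).
#' @param indices integer vector of 0-based column indices, parallel to `data`.
#' @param indptr integer vector of length `n_rows + 1`; `indptr[1] == 0` and
#'   `indptr[n_rows + 1] == length(data)`.
#' @param n_rows,n_cols matrix dimensions.
#' @param dtype `"integer"` if the values are counts, `"double"` for
#'   real-valued data (e.g. after dimensionality reduction).  Values are held
#'   as doubles either way; the flag records provenance.
#' @return An object of class `csr_matrix`.
#' @examples
#' m <- csr_matrix(data = c(2, 5), indices = c(0L, 1L), indptr = c(0L, 1L, 1L, 2L),
#'                 n_rows = 3, n_cols = 3)
#' dim(m)
#' as.matrix(m)
#' @export
csr_matrix <- function(data, indices, indptr, n_rows, n_cols,
                       dtype = c("integer", "double")) {
  dtype <- match.arg(dtype)
  m <- structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         data = as.double(data), indices = as.integer(indices),
         indptr = as.integer(indptr), dtype_kind = dtype),
    class = "csr_matrix")
  validate_csr(m)
}

#' Validate and canonicalize a CSR matrix
#'
#' Checks the structural invariants (consistent array lengths, monotone
#' `indptr`, in-range indices, nonnegative values) and returns the canonical
#' form: per-row sorted indices, duplicates summed, explicit zeros dropped.
#' Canonicalization is a fixed point: `validate_csr(validate_csr(m))` is
#' identical to `validate_csr(m)`.
#'
#' @param m a `csr_matrix` (possibly non-canonical).
#' @return The canonicalized `csr_matrix`.
#' @export
validate_csr <- function(m) {
  stopifnot(inherits(m, "csr_matrix"))
  n <- m$n_rows; d <- m$n_cols
  if (is.na(n) || is.na(d) || n < 0L || d < 0L)
    stop("invalid dimensions", call. = FALSE)
  if (length(m$indptr) != n + 1L)
    stop("indptr must have length n_rows + 1", call. = FALSE)
  if (length(m$data) != length(m$indices))
    stop("data and indices must have equal length", call. = FALSE)
  if (m$indptr[1L] != 0L || m$indptr[n + 1L] != length(m$data))
    stop("indptr must start at 0 and end at nnz", call. = FALSE)
  if (any(diff(m$indptr) < 0L))
    stop("indptr must be nondecreasing", call. = FALSE)
  if (anyNA(m$data) || anyNA(m$indices))
    stop("NA entries are not allowed", call. = FALSE)
  if (any(m$data < 0))
    stop("negative values are not allowed in a count matrix", call. = FALSE)
  if (length(m$indices) && (min(m$indices) < 0L || max(m$indices) >= d))
    stop("column index out of range", call. = FALSE)

  # canonicalize: sort within rows, sum duplicates, drop zeros
  row <- rep.int(seq_len(n), diff(m$indptr))
  o <- order(row, m$indices)
  row <- row[o]; col <- m$indices[o]; val <- m$data[o]
  if (length(val)) {
    new_grp <- c(TRUE, row[-1L] != row[-length(row)] | col[-1L] != col[-length(col)])
    grp <- cumsum(new_grp)
    val <- as.vector(rowsum(val, grp, reorder = FALSE))
    row <- row[new_grp]; col <- col[new_grp]
    keep <- val != 0
    val <- val[keep]; row <- row[keep]; col <- col[keep]
  }
  m$data <- as.double(val)
  m$indices <- as.integer(col)
  m$indptr <- as.integer(c(0L, cumsum(tabulate(row, nbins = n))))
  m
}

#' Convert to a CSR matrix
#'
#' Accepts a base `matrix`, any `Matrix` package sparse matrix, or an existing
#' `csr_matrix`.
#'
#' @param x object to convert.
#' @param dtype value-kind flag, see [csr_matrix()].  Defaults to
#'   `"integer"` when all values are whole numbers.
#' @return a canonical `csr_matrix`.
#' @export
as_csr <- function(x, dtype = NULL) {
  if (inherits(x, "csr_matrix")) return(validate_csr(x))
  if (is.matrix(x)) {
    if (is.null(dtype))
      dtype <- if (all(x == floor(x))) "integer" else "double"
    nz <- which(t(x) != 0)                 # row-major order
    row1 <- (nz - 1L) %/% ncol(x) + 1L
    col0 <- (nz - 1L) %% ncol(x)
    return(csr_matrix(data = t(x)[nz], indices = col0,
                      indptr = c(0L, cumsum(tabulate(row1, nbins = nrow(x)))),
                      n_rows = nrow(x), n_cols = ncol(x), dtype = dtype))
  }
  if (inherits(x, "sparseMatrix")) {
    x <- methods::as(methods::as(x, "generalMatrix"), "TsparseMatrix")
    val <- if (methods::.hasSlot(x, "x")) x@x else rep(1, length(x@i))
    if (is.null(dtype))
      dtype <- if (all(val == floor(val))) "integer" else "double"
    o <- order(x@i, x@j)
    row1 <- x@i[o] + 1L
    return(csr_matrix(data = val[o], indices = x@j[o],
                      indptr = c(0L, cumsum(tabulate(row1, nbins = nrow(x)))),
                      n_rows = nrow(x), n_cols = ncol(x), dtype = dtype))
  }
  stop("cannot convert object of class ", paste(class(x), collapse = "/"),
       " to csr_matrix", call. = FALSE)
}

#' @export
dim.csr_matrix <- function(x) c(x$n_rows, x$n_cols)

#' @export
as.matrix.csr_matrix <- function(x, ...) {
  out <- matrix(0, x$n_rows, x$n_cols)
  if (length(x$data)) {
    row <- rep.int(seq_len(x$n_rows), diff(x$indptr))
    out[cbind(row, x$indices + 1L)] <- x$data
  }
  out
}

#' @export
print.csr_matrix <- function(x, ...) {
  cat(sprintf("csr_matrix: %d x %d, nnz = %d (%s), density = %.3g\n",
              x$n_rows, x$n_cols, length(x$data), x$dtype_kind,
              if (x$n_rows * as.double(x$n_cols) > 0)
                length(x$data) / (x$n_rows * as.double(x$n_cols)) else 0))
  invisible(x)
}

# nnz per row
csr_row_nnz <- function(m) diff(m$indptr)

# stored entries of one row; columns returned 1-based for R-level math
csr_row <- function(m, i) {
  from <- m$indptr[i] + 1L; to <- m$indptr[i + 1L]
  if (to < from) list(cols = integer(0), vals = double(0))
  else list(cols = m$indices[from:to] + 1L, vals = m$data[from:to])
}

# dgCMatrix view for vectorized linear algebra
csr_to_dgc <- function(m) {
  row <- rep.int(seq_len(m$n_rows), diff(m$indptr))
  Matrix::sparseMatrix(i = row, j = m$indices + 1L, x = m$data,
                       dims = c(m$n_rows, m$n_cols))
}

#' Per-row cached statistics
#'
#' Precomputes, for every row, the total count, the number of stored entries,
#' and — when a pseudo-count prior is active — the prior-adjusted normalizer
#' `row_sum + n_cols * beta`.  These are the O(1)-per-row quantities that let
#' all probability-based divergences run in time proportional to the number
#' of stored entries: under a Gamma(beta, beta) prior the normalized row is
#' `(X_i + beta) / (S + d * beta)`, and the cache holds the denominator.
#'
#' @param m a canonical `csr_matrix`.
#' @param beta pseudo-count prior (`> 0`), or `NULL` for no prior.
#' @return a list with `row_sum`, `row_nnz` and (when a prior is active)
#'   `prior_norm`.
#' @examples
#' m <- as_csr(matrix(c(2, 0, 0), 1, 3))
#' row_cache(m, beta = 0.01)$prior_norm  # 2 + 3 * 0.01
#' @export
row_cache <- function(m, beta = NULL) {
  beta <- check_beta(beta)
  row <- rep.int(seq_len(m$n_rows), diff(m$indptr))
  s <- numeric(m$n_rows)
  if (length(m$data)) {
    agg <- rowsum(m$data, row, reorder = FALSE)
    s[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out <- list(row_sum = s, row_nnz = csr_row_nnz(m))
  if (!is.null(beta)) out$prior_norm <- s + m$n_cols * beta
  out
}

#' Select the most variable genes
#'
#' Ranks columns by the per-gene variance of raw counts over all cells,
#' computed sparse-aware as `E[X^2] - E[X]^2` (population variance), and
#' returns the top `n_top` together with the column-sliced matrix.  Ties are
#' broken toward the lower column index.  Selected columns are returned in
#' their original (ascending) order, so `n_top = n_cols` is the identity and
#' the operation is idempotent.
#'
#' @param m a canonical `csr_matrix`.
#' @param n_top number of columns to keep (`1 <= n_top <= n_cols`).
#' @return list with `cols` (1-based original column indices, ascending) and
#'   `matrix` (the filtered `csr_matrix`).
#' @export
select_hvg <- function(m, n_top) {
  if (length(n_top) != 1L || is.na(n_top) || n_top <= 0)
    stop("n_top must be a positive integer", call. = FALSE)
  if (n_top > m$n_cols)
    stop("n_top exceeds the number of columns", call. = FALSE)
  n <- m$n_rows
  col1 <- m$indices + 1L
  s1 <- numeric(m$n_cols); s2 <- numeric(m$n_cols)
  if (length(m$data)) {
    a1 <- rowsum(m$data, col1, reorder = FALSE)
    s1[as.integer(rownames(a1))] <- a1[, 1L]
    a2 <- rowsum(m$data^2, col1, reorder = FALSE)
    s2[as.integer(rownames(a2))] <- a2[, 1L]
  }
  score <- s2 / n - (s1 / n)^2
  keep <- sort(order(-score, seq_along(score))[seq_len(n_top)])
  list(cols = keep, matrix = csr_select_cols(m, keep))
}

# column subset (1-based `cols`, strictly increasing), preserving row order
csr_select_cols <- function(m, cols) {
  stopifnot(!is.unsorted(cols, strictly = TRUE))
  pos <- match(m$indices + 1L, cols)
  keep <- !is.na(pos)
  row <- rep.int(seq_len(m$n_rows), diff(m$indptr))[keep]
  csr_matrix(data = m$data[keep], indices = pos[keep] - 1L,
             indptr = c(0L, cumsum(tabulate(row, nbins = m$n_rows))),
             n_rows = m$n_rows, n_cols = length(cols), dtype = m$dtype_kind)
}

#' Sparsity summary
#'
#' @param m a `csr_matrix`.
#' @return list with overall `density` and the per-row `row_nnz` vector.
#' @export
sparsify_stats <- function(m) {
  cells <- m$n_rows * as.double(m$n_cols)
  list(density = if (cells > 0) length(m$data) / cells else 0,
       row_nnz = csr_row_nnz(m))
}
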