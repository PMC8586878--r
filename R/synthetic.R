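#' Planted multinomial mixture specification
#'
#' Describes a synthetic sparse count matrix with known cluster structure:
#' `k` clusters, each with a gene-probability vector drawn from a symmetric
#' Dirichlet with concentration `alpha`, and each cell drawn multinomially
#' from its cluster's probabilities.  Small `alpha` concentrates mass on few
#' genes, giving peaked, well-separated clusters; large `alpha` approaches
#' uniform profiles that are hard to tell apart, so `alpha` is the separation
#' knob (recovery difficulty is monotone in it).  `disjoint = TRUE` gives
#' every cluster its own block of genes (disjoint supports), the maximally
#' separated case.  An optional Dirichlet-multinomial overdispersion adds
#' per-cell wobble around the cluster profile.
#'
#' @param n_per_cluster cells per cluster (scalar or length-`k`).
#' @param n_genes number of genes (`d`).
#' @param k number of planted clusters.
#' @param alpha Dirichlet concentration of the cluster profiles.
#' @param total_counts counts per cell (mean when `total_sdlog > 0`).
#' @param total_sdlog log-normal sd of per-cell totals; `0` = fixed totals.
#' @param disjoint give each cluster a disjoint gene block.
#' @param overdispersion `NULL` for pure multinomial cells; otherwise the
#'   Dirichlet-multinomial precision (smaller = more overdispersed).
#' @param seed integer seed; generation is deterministic per seed.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_per_cluster, n_genes, k, alpha = 0.05,
                         total_counts = 500, total_sdlog = 0,
                         disjoint = FALSE, overdispersion = NULL,
                         seed = 1L) {
  if (k < 1 || n_genes < k) stop("need n_genes >= k >= 1", call. = FALSE)
  n_per_cluster <- rep_len(as.integer(n_per_cluster), k)
  if (any(n_per_cluster < 1)) stop("n_per_cluster must be >= 1", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (total_counts < 1) stop("total_counts must be >= 1", call. = FALSE)
  structure(list(n_per_cluster = n_per_cluster, n_genes = as.integer(n_genes),
                 k = as.integer(k), alpha = alpha,
                 total_counts = total_counts, total_sdlog = total_sdlog,
                 disjoint = isTRUE(disjoint), overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

# run `expr` under a private RNG state seeded with `seed`; the caller's
# stream is untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1   # degenerate tiny-alpha draw
  g / sum(g)
}

#' Generate a planted mixture
#'
#' Draws the matrix described by a [mixture_spec()]: cluster gene-probability
#' profiles, per-cell totals, then one multinomial draw per cell.  Rows are
#' grouped by cluster (labels returned alongside); the matrix is returned in
#' canonical CSR form and always passes [validate_csr()].
#'
#' @param spec a `mixture_spec`.
#' @return list with `matrix` (a `csr_matrix`), `labels` (integer vector of
#'   planted cluster ids) and `prob` (the `k x n_genes` profile matrix).
#' @export
generate_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  with_seed(spec$seed, {
    d <- spec$n_genes; k <- spec$k
    P <- matrix(0, k, d)
    if (spec$disjoint) {
      block <- split(seq_len(d), cut(seq_len(d), k, labels = FALSE))
      for (c in seq_len(k))
        P[c, block[[c]]] <- rdirichlet1(rep(1, length(block[[c]])))
    } else {
      for (c in seq_len(k)) P[c, ] <- rdirichlet1(rep(spec$alpha, d))
    }
    n <- sum(spec$n_per_cluster)
    labels <- rep.int(seq_len(k), spec$n_per_cluster)
    totals <- if (spec$total_sdlog > 0) {
      pmax(1, round(stats::rlnorm(n, log(spec$total_counts),
                                  spec$total_sdlog)))
    } else rep(round(spec$total_counts), n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      p <- P[labels[i], ]
      if (!is.null(spec$overdispersion))
        p <- rdirichlet1(spec$overdispersion * p)
      cnt <- stats::rmultinom(1L, totals[i], p)[, 1L]
      nz <- which(cnt > 0)
      rows[[i]] <- cbind(nz, cnt[nz])
    }
    nnz_row <- vapply(rows, nrow, integer(1))
    all <- do.call(rbind, rows)
    m <- csr_matrix(data = all[, 2L], indices = all[, 1L] - 1L,
                    indptr = c(0L, cumsum(nnz_row)),
                    n_rows = n, n_cols = d, dtype = "integer")
    list(matrix = m, labels = labels, prob = P)
  })
}
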