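# Independent oracles used across the suite.  Everything here works on
# densified vectors or by exhaustive enumeration, deliberately sharing no
# code with the package's sparse implementations.

# dissimilarity on fully densified, prior-adjusted vectors
dense_div <- function(x, y, measure, beta = NULL) {
  measure <- toupper(measure)
  if (measure == "SQE") return(sum((x - y)^2))
  if (measure == "COS")
    return(1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2))))
  d <- length(x)
  if (is.null(beta)) {
    p <- x / sum(x); q <- y / sum(y)
  } else {
    p <- (x + beta) / (sum(x) + d * beta)
    q <- (y + beta) / (sum(y) + d * beta)
  }
  f <- function(z) ifelse(z > 0, z * log(z), 0)
  if (measure == "KLD") return(sum(ifelse(p > 0, p * log(p / q), 0)))
  if (measure == "JSD") {
    mm <- (p + q) / 2
    return(sum(f(p) + f(q)) / 2 - sum(f(mm)))
  }
  sqrt(max(0, 1 - sum(sqrt(p * q))))  # BATMET
}

# random sparse count vector of length d with `nnz` nonzero entries
random_sparse_vec <- function(d, nnz) {
  x <- numeric(d)
  x[sample.int(d, nnz)] <- stats::rpois(nnz, 5) + 1
  x
}

# exhaustive law of sequential weighted draws without replacement:
# probability of every unordered m-subset, enumerated over ordered draws
enum_swor_probs <- function(weights, m) {
  n <- length(weights)
  probs <- new.env(parent = emptyenv())
  recurse <- function(chosen, remaining, p) {
    if (length(chosen) == m) {
      key <- paste(sort(chosen), collapse = "-")
      probs[[key]] <- (if (is.null(probs[[key]])) 0 else probs[[key]]) + p
      return(invisible(NULL))
    }
    tot <- sum(weights[remaining])
    for (i in remaining) {
      if (weights[i] > 0)
        recurse(c(chosen, i), setdiff(remaining, i), p * weights[i] / tot)
    }
  }
  recurse(integer(0), seq_len(n), 1)
  out <- unlist(as.list(probs))
  out[order(names(out))]
}

subset_key <- function(idx) paste(sort(idx), collapse = "-")

# ARI by direct enumeration of all row pairs
ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 0 else num / den
}

# every partition of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1))
      recurse(c(prefix, v), max(maxv, v))
  }
  recurse(integer(0), 0L)
  out
}

# exact optimal k-means cost for 1-D points: the optimum is attained by a
# contiguous partition of the sorted values, enumerated exhaustively
opt_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (s in seq_len(ncol(splits))) {
    bounds <- c(0, splits[, s], n)
    cost <- 0
    for (b in seq_len(k)) cost <- cost + sse(x[(bounds[b] + 1):bounds[b + 1]])
    best <- min(best, cost)
  }
  best
}

# total objective of a set of data-row centers, via the package's pairwise
# distance only (no vectorized path): used to cross-check swap decisions
brute_total_cost <- function(m, center_rows, measure, beta) {
  dense <- as.matrix(m)
  n <- nrow(dense)
  tot <- 0
  for (i in seq_len(n)) {
    best <- Inf
    for (r in center_rows) {
      dv <- dense_div_rep(dense[i, ], dense[r, ], measure, beta)
      best <- min(best, dv)
    }
    tot <- tot + best
  }
  tot
}

# dense divergence where the second argument is a raw data row that must be
# taken in the measure's working representation
dense_div_rep <- function(x, yraw, measure, beta) {
  measure <- toupper(measure)
  if (measure == "SQE") return(sum((x - yraw)^2))
  if (measure == "COS") {
    cc <- yraw / sqrt(sum(yraw^2))
    return(1 - sum(x * cc) / (sqrt(sum(x^2)) * sqrt(sum(cc^2))))
  }
  dense_div(x, yraw, measure, beta)
}

# small dense Lloyd reference with the same update rules, used as an
# independent implementation for trace comparison
dense_lloyd_ref <- function(dense, C, measure, beta, iters) {
  n <- nrow(dense); k <- nrow(C)
  trace <- numeric(0)
  rep_of <- function(x) {
    if (toupper(measure) == "SQE") return(x)
    if (toupper(measure) == "COS") return(x / sqrt(sum(x^2)))
    (x + beta) / (sum(x) + length(x) * beta)
  }
  for (it in seq_len(iters)) {
    D <- matrix(0, n, k)
    for (i in seq_len(n)) for (j in seq_len(k))
      D[i, j] <- dense_div_center(dense[i, ], C[j, ], measure, beta)
    a <- apply(D, 1, which.min)
    cost <- D[cbind(seq_len(n), a)]
    trace <- c(trace, sum(cost))
    for (j in seq_len(k)) {
      mem <- which(a == j)
      if (length(mem)) {
        reps <- t(apply(dense[mem, , drop = FALSE], 1, rep_of))
        cj <- colMeans(reps)
        if (toupper(measure) == "COS") cj <- cj / sqrt(sum(cj^2))
        C[j, ] <- cj
      }
    }
  }
  list(trace = trace, centers = C, assign = a)
}

# dense divergence against an already-represented center vector
dense_div_center <- function(x, cc, measure, beta) {
  measure <- toupper(measure)
  if (measure == "SQE") return(sum((x - cc)^2))
  if (measure == "COS")
    return(1 - sum(x * cc) / (sqrt(sum(x^2)) * sqrt(sum(cc^2))))
  d <- length(x)
  p <- if (is.null(beta)) x / sum(x) else (x + beta) / (sum(x) + d * beta)
  f <- function(z) ifelse(z > 0, z * log(z), 0)
  if (measure == "KLD") return(sum(ifelse(p > 0, p * log(p / cc), 0)))
  if (measure == "JSD") {
    mm <- (p + cc) / 2
    return(sum(f(p) + f(cc)) / 2 - sum(f(mm)))
  }
  sqrt(max(0, 1 - sum(sqrt(p * cc))))
}

ALL_MEASURES <- c("SQE", "KLD", "JSD", "BATMET", "COS")
PROB <- c("KLD", "JSD", "BATMET")

beta_for <- function(measure, beta = 0.01)
  if (toupper(measure) %in% PROB) beta else NULL
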