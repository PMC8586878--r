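test_that("hand-checked distance values", {
  expect_equal(sparse_distance(c(1, 2, 0), c(3, 4, 0), "SQE"), 8)
  # identity of indiscernibles under an active prior; BATMET's sqrt(1 - BC)
  # amplifies coefficient round-off near BC = 1, hence its looser tolerance
  x <- c(0, 3, 1, 0, 2)
  expect_equal(sparse_distance(x, x, "KLD", beta = 0.01), 0, tolerance = 1e-12)
  expect_equal(sparse_distance(x, x, "JSD", beta = 0.01), 0, tolerance = 1e-12)
  expect_lt(sparse_distance(x, x, "BATMET", beta = 0.01), 1e-6)
  expect_equal(sparse_distance(x, x, "COS"), 0, tolerance = 1e-12)
  # disjoint supports, no prior: maximally divergent distributions
  expect_equal(sparse_distance(c(2, 0, 0, 0), c(0, 0, 1, 3), "JSD"), log(2),
               tolerance = 1e-12)
})

test_that("measure parsing is case-insensitive and strict", {
  expect_equal(sparse_distance(c(1, 0), c(1, 0), "sqe"), 0)
  expect_error(sparse_distance(c(1, 0), c(1, 0), "euclid"), "unknown measure")
  expect_error(sparse_distance(c(1, 0), c(1, 0, 0), "SQE"), "different feature")
})

test_that("degenerate inputs raise rather than produce silent garbage", {
  zero <- c(0, 0, 0)
  for (meas in PROB)
    expect_error(sparse_distance(zero, c(1, 0, 2), meas), "prior")
  expect_error(sparse_distance(zero, c(1, 0, 2), "COS"), "all-zero")
  expect_equal(sparse_distance(zero, zero, "SQE"), 0)
  expect_error(sparse_distance(c(1, 0), c(1, 0), "KLD", beta = 0), "beta")
})

test_that("lazy sparse evaluation equals densified evaluation", {
  set.seed(101)
  for (d in c(10, 1000, 1e5)) {
    nnz <- min(d %/% 2, 20)
    for (rep in 1:10) {
      x <- random_sparse_vec(d, nnz)
      y <- random_sparse_vec(d, nnz)
      for (meas in ALL_MEASURES) for (beta in c(0.01, 0.1, 1)) {
        b <- beta_for(meas, beta)
        got <- sparse_distance(x, y, meas, beta = b)
        want <- dense_div(x, y, meas, beta = b)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("normalized rows sum to one, including all-zero rows under a prior", {
  set.seed(5)
  m <- as_csr(rbind(matrix(rpois(5 * 50, 0.4), 5, 50), 0))
  for (beta in c(0.01, 1)) {
    for (i in seq_len(dim(m)[1])) {
      nv <- normalized_row(m, i, beta = beta)
      total <- sum(nv$prob) + (nv$d - nv$nnz) * nv$bg
      expect_equal(total, 1, tolerance = 1e-12)
    }
  }
  # all-zero row under an active prior is the uniform distribution
  nv <- normalized_row(m, 6, beta = 1)
  expect_equal(nv$bg, 1 / 50)
  expect_error(normalized_row(m, 6), "zero-sum")
})

test_that("bounds and symmetry hold on random sparse pairs", {
  set.seed(11)
  for (rep in 1:20) {
    x <- random_sparse_vec(300, 12)
    y <- random_sparse_vec(300, 12)
    jsd <- sparse_distance(x, y, "JSD", beta = 0.01)
    expect_gte(jsd, 0); expect_lte(jsd, log(2) + 1e-12)
    bat <- sparse_distance(x, y, "BATMET", beta = 0.01)
    expect_gte(bat, 0); expect_lte(bat, 1)
    expect_gte(sparse_distance(x, y, "SQE"), 0)
    expect_gte(sparse_distance(x, y, "KLD", beta = 0.01), 0)
    expect_gte(sparse_distance(x, y, "COS"), 0)
    for (meas in c("SQE", "JSD", "BATMET", "COS")) {
      b <- beta_for(meas)
      expect_equal(sparse_distance(x, y, meas, beta = b),
                   sparse_distance(y, x, meas, beta = b), tolerance = 1e-12)
    }
  }
  # KLD is generally asymmetric
  set.seed(12)
  asym <- replicate(10, {
    x <- random_sparse_vec(100, 8); y <- random_sparse_vec(100, 8)
    abs(sparse_distance(x, y, "KLD", beta = 0.01) -
          sparse_distance(y, x, "KLD", beta = 0.01))
  })
  expect_gt(max(asym), 1e-6)
})

test_that("BATMET and sqrt(JSD) satisfy the triangle inequality", {
  set.seed(13)
  for (rep in 1:2000) {
    x <- random_sparse_vec(60, 6)
    y <- random_sparse_vec(60, 6)
    z <- random_sparse_vec(60, 6)
    bxy <- sparse_distance(x, y, "BATMET", beta = 0.01)
    bxz <- sparse_distance(x, z, "BATMET", beta = 0.01)
    bzy <- sparse_distance(z, y, "BATMET", beta = 0.01)
    expect_lte(bxy, bxz + bzy + 1e-12)
    jxy <- sqrt(sparse_distance(x, y, "JSD", beta = 0.01))
    jxz <- sqrt(sparse_distance(x, z, "JSD", beta = 0.01))
    jzy <- sqrt(sparse_distance(z, y, "JSD", beta = 0.01))
    expect_lte(jxy, jxz + jzy + 1e-12)
  }
})

test_that("distance work scales with nnz, not dimension", {
  d <- 1e5
  set.seed(14)
  x <- random_sparse_vec(d, 10)
  y <- random_sparse_vec(d, 10)
  count_touches(TRUE)
  on.exit(count_touches(FALSE))
  for (meas in ALL_MEASURES) {
    reset_touch_count()
    sparse_distance(x, y, meas, beta = beta_for(meas))
    expect_lt(touch_count(), 100 * 10)
  }
})

test_that("point-to-center costs match a pairwise loop and break ties low", {
  set.seed(15)
  sim <- generate_mixture(mixture_spec(10, 30, 3, seed = 16,
                                       total_sdlog = 0.3))
  m <- sim$matrix
  dense <- as.matrix(m)
  for (meas in ALL_MEASURES) {
    b <- beta_for(meas)
    cs <- kmeanspp(m, 4, meas, b)
    pc <- point_to_centers(m, cs$centers, meas, b)
    for (i in seq_len(nrow(dense))) {
      want <- vapply(seq_len(4), function(j)
        dense_div_center(dense[i, ], cs$centers[j, ], meas, b), numeric(1))
      expect_equal(pc$cost_matrix[i, ], want, tolerance = 1e-8)
      expect_equal(pc$cost[i], min(want), tolerance = 1e-8)
    }
    # a row used as a center has cost ~0 to its own representation
    own <- cs$source_rows[1]
    expect_equal(pc$cost[own], 0, tolerance = 1e-10)
  }
  # duplicated centers: identical costs, argmin goes to the lower index
  cs <- kmeanspp(m, 2, "SQE")
  dup <- rbind(cs$centers[1, ], cs$centers[1, ])
  pc <- point_to_centers(m, dup, "SQE")
  expect_true(all(pc$assign == 1L))
})

test_that("total cost is the plain sum of per-row costs", {
  expect_equal(total_cost(numeric(5)), 0)
  set.seed(17)
  v <- runif(10)
  expect_equal(total_cost(v), sum(v))
  expect_equal(total_cost(sample(v)), total_cost(v))
})
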