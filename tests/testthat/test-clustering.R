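test_that("Lloyd finds the analytic optimum on {0, 1, 9, 10}", {
  m <- as_csr(matrix(c(0, 1, 9, 10), 4, 1))
  res <- lloyd(m, matrix(c(0, 9), 2, 1), "SQE")
  expect_equal(sort(res$centers[, 1]), c(0.5, 9.5))
  expect_equal(res$tot_cost, 1.0)
  expect_true(res$converged)
})

test_that("optimal centers are a fixed point reached in one iteration", {
  m <- as_csr(matrix(c(0, 1, 9, 10), 4, 1))
  res <- lloyd(m, matrix(c(0.5, 9.5), 2, 1), "SQE")
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
  expect_equal(res$centers[, 1], c(0.5, 9.5))
  # max_iter = 0 returns the seeds untouched
  res0 <- lloyd(m, matrix(c(0, 9), 2, 1), "SQE", max_iter = 0)
  expect_equal(res0$centers, matrix(c(0, 9), 2, 1))
  expect_equal(res0$iterations, 0L)
})

test_that("Lloyd under KLD matches an independent dense implementation", {
  set.seed(51)
  sim <- generate_mixture(mixture_spec(20, 30, 4, seed = 52,
                                       total_sdlog = 0.3))
  m <- sim$matrix
  cs <- kmeanspp(m, 4, "KLD", 0.01)
  res <- lloyd(m, cs, max_iter = 12, tol = 0)
  ref <- dense_lloyd_ref(as.matrix(m), cs$centers, "KLD", 0.01, 12)
  len <- min(length(res$trace), length(ref$trace))
  expect_equal(res$trace[seq_len(len)], ref$trace[seq_len(len)],
               tolerance = 1e-8)
})

test_that("Lloyd cost trace is nonincreasing for Bregman measures on fuzzed instances", {
  set.seed(53)
  for (rep in 1:6) {
    sim <- generate_mixture(mixture_spec(sample(8:20, 1), sample(20:60, 1),
                                         sample(2:4, 1), seed = 530 + rep,
                                         alpha = runif(1, 0.05, 1),
                                         total_sdlog = runif(1, 0, 0.5)))
    for (meas in c("SQE", "KLD")) {
      cs <- kmeanspp(sim$matrix, 3, meas, beta_for(meas))
      res <- lloyd(sim$matrix, cs, max_iter = 30)
      expect_true(all(diff(res$trace) <= 1e-8 * max(res$trace[1], 1)))
    }
  }
})

test_that("final assignments are a fixed point of the final centers", {
  set.seed(54)
  sim <- generate_mixture(mixture_spec(15, 40, 3, seed = 55))
  for (meas in ALL_MEASURES) {
    b <- beta_for(meas)
    res <- lloyd(sim$matrix, kmeanspp(sim$matrix, 3, meas, b))
    pc <- point_to_centers(sim$matrix, res$centers, meas, b)
    expect_identical(pc$assign, res$assign)
  }
})

test_that("empty clusters are reseeded deterministically, never an error", {
  m <- as_csr(matrix(c(0, 1, 9, 10), 4, 1))
  # a center far from every point guarantees an empty cluster
  res <- lloyd(m, matrix(c(5, 100), 2, 1), "SQE")
  expect_equal(length(unique(res$assign)), 2L)
  expect_lt(res$tot_cost, sum((c(0, 1, 9, 10) - 5)^2))
})

test_that("a full-coverage batch reproduces one Lloyd update exactly", {
  set.seed(56)
  sim <- generate_mixture(mixture_spec(25, 35, 3, seed = 57))
  m <- sim$matrix
  for (meas in ALL_MEASURES) {
    b <- beta_for(meas)
    set.seed(58)
    cs <- kmeanspp(m, 3, meas, b)
    mb <- minibatch_kmeans(m, cs, batch_size = dim(m)[1], max_epochs = 1)
    prep <- sparsekm:::skm_prep(m, meas, b)
    want <- sparsekm:::cluster_means(prep, cs$assign, 3, cs$centers)
    if (meas == "COS") want <- want / sqrt(rowSums(want^2))
    expect_equal(mb$centers, want, tolerance = 1e-12)
  }
})

test_that("k = 1 mini-batch converges to the global mean after a full pass", {
  set.seed(59)
  sim <- generate_mixture(mixture_spec(30, 20, 1, seed = 60))
  m <- sim$matrix
  cs <- kmeanspp(m, 1, "SQE")
  mb <- minibatch_kmeans(m, cs, batch_size = dim(m)[1], max_epochs = 1)
  expect_equal(mb$centers[1, ], colMeans(as.matrix(m)), tolerance = 1e-12)
})

test_that("oversized batches are clamped with a warning", {
  set.seed(61)
  sim <- generate_mixture(mixture_spec(5, 15, 2, seed = 62))
  cs <- kmeanspp(sim$matrix, 2, "SQE")
  expect_warning(minibatch_kmeans(sim$matrix, cs, batch_size = 1e6,
                                  max_epochs = 1), "clamped")
})

test_that("mini-batch epochs improve the full-data objective on planted mixtures", {
  set.seed(63)
  deltas <- replicate(8, {
    sim <- generate_mixture(mixture_spec(60, 50, 4,
                                         seed = sample.int(1e6, 1)))
    cs <- kmeanspp(sim$matrix, 4, "SQE", n_candidates = 1)
    mb <- minibatch_kmeans(sim$matrix, cs, batch_size = 40, max_epochs = 5)
    mb$trace[5] - mb$trace[1]
  })
  expect_lte(stats::median(deltas), 0)
})
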