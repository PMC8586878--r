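test_that("k equal to n gives zero total cost for every measure", {
  set.seed(31)
  sim <- generate_mixture(mixture_spec(4, 25, 2, seed = 32))
  for (meas in ALL_MEASURES) {
    cs <- kmeanspp(sim$matrix, 8, meas, beta_for(meas))
    expect_lt(sum(cs$cost), 1e-6)
    expect_setequal(cs$source_rows, 1:8)
  }
})

test_that("two far-separated groups get one center each", {
  set.seed(33)
  sim <- generate_mixture(mixture_spec(15, 40, 2, disjoint = TRUE,
                                       seed = 34))
  for (meas in ALL_MEASURES) {
    cs <- kmeanspp(sim$matrix, 2, meas, beta_for(meas))
    expect_equal(adjusted_rand_index(cs$assign, sim$labels), 1)
  }
})

test_that("per-step seeding cost is monotone and the arrays are consistent", {
  set.seed(35)
  sim <- generate_mixture(mixture_spec(12, 50, 3, seed = 36,
                                       total_sdlog = 0.3))
  for (meas in ALL_MEASURES) {
    b <- beta_for(meas)
    cs <- kmeanspp(sim$matrix, 5, meas, b)
    steps <- attr(cs, "step_costs")
    expect_true(all(diff(steps) <= 1e-9))
    # stored cost/assign agree with a fresh recomputation
    pc <- point_to_centers(sim$matrix, cs$centers, meas, b)
    expect_equal(cs$cost, pc$cost, tolerance = 1e-9)
    expect_true(all(cs$cost >= 0))
    expect_true(all(cs$assign %in% seq_len(5)))
  }
  expect_error(kmeanspp(sim$matrix, 0, "SQE"), "k must")
  expect_error(kmeanspp(sim$matrix, 999, "SQE"), "k must")
})

test_that("k-means++ beats uniform seeding on average", {
  set.seed(37)
  sim <- generate_mixture(mixture_spec(40, 30, 4, seed = 38))
  m <- sim$matrix
  n <- dim(m)[1]
  reps <- 200
  pp <- numeric(reps); unif <- numeric(reps)
  for (r in seq_len(reps)) {
    pp[r] <- sum(kmeanspp(m, 4, "SQE", n_candidates = 1)$cost)
    rows <- sample.int(n, 4)
    unif[r] <- sum(point_to_centers(
      m, sparsekm:::skm_row_rep(sparsekm:::skm_prep(m, "SQE", NULL), rows),
      "SQE")$cost)
  }
  expect_lt(mean(pp), mean(unif))
})

test_that("localsearch++ is a no-op at rounds = 0 and on perfect coverings", {
  set.seed(39)
  sim <- generate_mixture(mixture_spec(8, 30, 2, seed = 40))
  cs <- kmeanspp(sim$matrix, 3, "KLD", 0.01)
  out <- localsearchpp(sim$matrix, cs, 0)
  expect_equal(out$centers, cs$centers)
  expect_equal(out$source_rows, cs$source_rows)
  expect_error(localsearchpp(sim$matrix, cs, -1), "rounds")

  # every point is a center: no swap is ever accepted
  cs0 <- kmeanspp(sim$matrix, 16, "SQE")
  out0 <- localsearchpp(sim$matrix, cs0, 10)
  expect_equal(out0$source_rows, cs0$source_rows)
  expect_equal(sum(out0$cost), 0)
})

test_that("localsearch++ cost is nonincreasing and swaps match the exhaustive oracle", {
  set.seed(41)
  sim <- generate_mixture(mixture_spec(6, 24, 3, seed = 42,
                                       total_sdlog = 0.2))  # 18 rows
  m <- sim$matrix
  for (meas in ALL_MEASURES) {
    b <- beta_for(meas)
    cs <- kmeanspp(m, 3, meas, b)
    out <- localsearchpp(m, cs, 25)
    tr <- attr(out, "ls_trace")
    expect_true(all(diff(tr) <= 1e-9))
    expect_lte(sum(out$cost), sum(cs$cost) + 1e-9)

    # replay every round against brute-force evaluation of all k swaps
    moves <- attr(out, "ls_moves")
    centers <- cs$source_rows
    total <- brute_total_cost(m, centers, meas, b)
    for (r in seq_len(nrow(moves))) {
      if (is.na(moves$z[r])) next
      cand <- vapply(seq_along(centers), function(ci) {
        trial <- centers; trial[ci] <- moves$z[r]
        brute_total_cost(m, trial, meas, b)
      }, numeric(1))
      best <- which.min(cand)
      if (moves$accepted[r]) {
        expect_equal(moves$center[r], best)
        expect_lt(cand[best], total - 1e-12)
        centers[best] <- moves$z[r]
        total <- cand[best]
      } else {
        expect_gte(min(cand), total - 1e-9)
      }
      expect_equal(moves$total[r], total, tolerance = 1e-6)
    }
  }
})

test_that("localsearch++ repairs deliberately bad seeding", {
  set.seed(43)
  sim <- generate_mixture(mixture_spec(10, 30, 2, disjoint = TRUE, seed = 44))
  m <- sim$matrix
  prep <- sparsekm:::skm_prep(m, "SQE", NULL)
  # both initial centers inside the first planted group
  bad <- sparsekm:::center_set_from_rows(prep, c(1L, 2L))
  out <- localsearchpp(m, bad, 25)
  expect_lt(sum(out$cost), sum(bad$cost))
  expect_equal(adjusted_rand_index(out$assign, sim$labels), 1)
})
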