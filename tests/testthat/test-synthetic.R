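test_that("uncorrelated spec produces near-zero sample correlations", {
  spec <- cohort_spec(n_channels = 10, n_samples = 10000,
                      block_partition = as.list(1:10),
                      within_block_r = 0, between_block_r = 0, seed = 1)
  rec <- generate_cohort_recording(spec)
  r <- cor(t(rec$signals))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)   # ~ 5 / sqrt(n)
})

test_that("generation is deterministic under the seed and leaves the RNG alone", {
  spec <- cohort_spec(n_channels = 8, n_samples = 300,
                      block_partition = list(1:4, 5:8), seed = 42)
  set.seed(99)
  before <- .Random.seed
  a <- generate_cohort_recording(spec)
  expect_identical(.Random.seed, before)
  b <- generate_cohort_recording(spec)
  expect_identical(a$signals, b$signals)
  c_ <- generate_cohort_recording(cohort_spec(n_channels = 8,
                                              n_samples = 300,
                                              block_partition = list(1:4, 5:8),
                                              seed = 43))
  expect_false(identical(a$signals, c_$signals))
})

test_that("block correlation structure is recovered from samples", {
  spec <- cohort_spec(n_channels = 10, n_samples = 5000,
                      block_partition = list(1:5, 6:10),
                      within_block_r = 0.8, between_block_r = 0.2, seed = 7)
  rec <- generate_cohort_recording(spec)
  r <- cor(t(rec$signals))
  within1 <- r[1:5, 1:5][upper.tri(r[1:5, 1:5])]
  within2 <- r[6:10, 6:10][upper.tri(r[6:10, 6:10])]
  between <- r[1:5, 6:10]
  expect_lt(abs(mean(c(within1, within2)) - 0.8), 0.05)
  tol <- 3 / sqrt(5000)
  expect_lt(abs(mean(within1) - 0.8), tol)
  expect_lt(abs(mean(within2) - 0.8), tol)
  expect_lt(abs(mean(between) - 0.2), tol)
})

test_that("non-PSD implied correlation is rejected with a named cause", {
  expect_error(cohort_spec(n_channels = 10, n_samples = 100,
                           block_partition = list(1:10),
                           within_block_r = -0.5),
               "positive semidefinite.*within_block_r = -0.5")
  expect_error(cohort_spec(n_channels = 6, block_partition = list(1:3, 5:6)),
               "cover channels")
  expect_error(cohort_spec(within_block_r = 1.2), "in \\(-1, 1\\)")
})

test_that("square fixture has unit-square geometry", {
  pc <- generate_fixture("square", noise_sd = 0)
  d <- sort(as.vector(dist(pc$coordinates)))
  expect_equal(d, c(1, 1, 1, 1, sqrt(2), sqrt(2)))
})

test_that("circle fixture spacing follows the chord-length formula", {
  pc <- generate_fixture("circle", n_points = 20, noise_sd = 0)
  d <- as.matrix(dist(pc$coordinates))
  adjacent <- d[cbind(1:19, 2:20)]
  expect_equal(adjacent, rep(2 * sin(pi / 20), 19))
  expect_equal(unname(sqrt(rowSums(pc$coordinates^2))), rep(1, 20))
})

test_that("sphere fixture lies on the unit sphere, quasi-uniformly", {
  pc <- generate_fixture("sphere", n_points = 40)
  expect_equal(unname(sqrt(rowSums(pc$coordinates^2))), rep(1, 40))
  # quasi-uniformity: every point has a neighbour within a modest multiple
  # of the mean nearest-neighbour spacing
  d <- as.matrix(dist(pc$coordinates)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_lt(max(nn) / mean(nn), 2)
})

test_that("degenerate and invalid fixtures behave as documented", {
  expect_equal(generate_fixture("circle", n_points = 1)$coordinates[1, ],
               c(0, 0), ignore_attr = TRUE)
  expect_error(geometric_fixture("torus"), "unknown fixture.*circle")
  expect_error(geometric_fixture("circle", noise_sd = -1), ">= 0")
  line <- generate_fixture("line", n_points = 4)
  expect_equal(as.vector(line$coordinates), c(0, 1, 2, 3))
  noisy1 <- generate_fixture("circle", n_points = 10, noise_sd = 0.1,
                             seed = 5)
  noisy2 <- generate_fixture("circle", n_points = 10, noise_sd = 0.1,
                             seed = 5)
  expect_identical(noisy1$coordinates, noisy2$coordinates)
})
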