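rec_from <- function(...) {
  m <- rbind(...)
  recording(m, srate = 100)
}

test_that("pearson matrix matches hand-computed correlations", {
  r <- pearson_matrix(rec_from(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(r[1, 2], 9 / (2 * sqrt(21)), tolerance = 1e-12)
  x <- rnorm(50)
  r2 <- pearson_matrix(rec_from(x, x, -x))
  expect_equal(r2[1, 2], 1)
  expect_equal(r2[1, 3], -1)
  expect_equal(diag(r2), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unclass(r2), t(unclass(r2)), ignore_attr = TRUE)
})

test_that("pearson matrix is invariant to positive affine rescaling", {
  set.seed(4)
  rec <- rec_from(rnorm(100), rnorm(100), rnorm(100))
  scaled <- recording(rec$signals * c(2, 5, 0.1) + c(-3, 0, 7), srate = 100)
  expect_equal(unclass(pearson_matrix(rec)), unclass(pearson_matrix(scaled)),
               tolerance = 1e-12)
})

test_that("zero-variance and short records are rejected by name", {
  rec <- recording(rbind(rnorm(10), rep(2, 10)), srate = 10,
                   labels = c("good", "flat"))
  expect_error(pearson_matrix(rec), "zero-variance channel.*flat")
  expect_error(pearson_matrix(rec_from(c(1, 2), c(3, 4))), "at least 3")
})

test_that("reciprocal distance follows 1/|r| with a cap", {
  r <- matrix(c(1, 0.98198, 0.98198, 1), 2)
  d <- reciprocal_distance(r)
  expect_equal(d[1, 2], 1 / 0.98198, tolerance = 1e-6)
  r2 <- matrix(c(1, 1, 0, 1, 1, -0.5, 0, -0.5, 1), 3)
  d2 <- reciprocal_distance(r2, cap = 100)
  expect_equal(d2[1, 2], 1)       # perfect correlation -> distance 1
  expect_equal(d2[1, 3], 100)     # vanishing correlation -> cap
  expect_equal(d2[2, 3], 2)       # anti-correlation uses the magnitude
  expect_equal(diag(d2), rep(0, 3), ignore_attr = TRUE)
  expect_error(reciprocal_distance(r, cap = 1), "exceed 1")
})

test_that("reciprocal distance is antitone in |r| below the cap", {
  set.seed(8)
  rs <- sort(runif(10, 0.1, 0.99))
  n <- 11
  m <- diag(n)
  m[1, 2:n] <- rs; m[2:n, 1] <- rs
  d <- reciprocal_distance(m, cap = 1000)
  expect_true(all(diff(d[1, 2:n]) < 0))   # larger |r| => smaller d
})

test_that("density thresholding keeps the strongest pairs", {
  r <- diag(4)
  vals <- c("12" = 0.9, "13" = 0.8, "14" = 0.7, "23" = 0.6, "24" = 0.5,
            "34" = 0.4)
  r[1, 2] <- r[2, 1] <- 0.9; r[1, 3] <- r[3, 1] <- 0.8
  r[1, 4] <- r[4, 1] <- 0.7; r[2, 3] <- r[3, 2] <- 0.6
  r[2, 4] <- r[4, 2] <- 0.5; r[3, 4] <- r[4, 3] <- 0.4
  A <- threshold_by_density(r, 0.5)
  expect_equal(sum(A) / 2, 3)
  expect_equal(A[1, 2] + A[1, 3] + A[1, 4], 3L)
  expect_equal(sum(threshold_by_density(r, 1)) / 2, 6)
  expect_equal(sum(threshold_by_density(r, 0)), 0)
  expect_error(threshold_by_density(r, 1.2), "\\[0, 1\\]")
  # tie group at the cutoff is included whole
  rt <- diag(3)
  rt[1, 2] <- rt[2, 1] <- 0.5; rt[1, 3] <- rt[3, 1] <- 0.5
  rt[2, 3] <- rt[3, 2] <- 0.2
  At <- threshold_by_density(rt, 1 / 3)
  expect_equal(sum(At) / 2, 2)
  expect_equal(attr(At, "realized_density"), 2 / 3)
})

test_that("edge-weight lists are complete, ordered and lossless", {
  set.seed(5)
  rec <- generate_cohort_recording(cohort_spec(n_channels = 6,
                                               n_samples = 200,
                                               block_partition = list(1:6),
                                               seed = 5))
  d <- reciprocal_distance(pearson_matrix(rec))
  ew <- edge_weight_list(d)
  expect_equal(nrow(ew), choose(6, 2))
  expect_true(all(ew$i < ew$j))
  expect_true(!is.unsorted(order(ew$i, ew$j)))
  path <- tempfile(fileext = ".txt")
  write_edge_weights(d, path)
  back <- edge_weights_to_distance(read_edge_weights(path),
                                   labels = rownames(d))
  expect_equal(unclass(back), unclass(d), tolerance = 1e-15,
               ignore_attr = TRUE)
  # 60-node count
  r60 <- matrix(0.5, 60, 60); diag(r60) <- 1
  expect_equal(nrow(edge_weight_list(reciprocal_distance(r60))), 1770)
})

test_that("max_threshold returns the largest inter-node distance", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1; m[1, 3] <- m[3, 1] <- 2; m[2, 3] <- m[3, 2] <- 3
  expect_equal(max_threshold(m), 3)
  mc <- matrix(2, 4, 4); diag(mc) <- 0
  expect_equal(max_threshold(mc), 2)
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.5; r[1, 3] <- r[3, 1] <- 1e-9
  r[2, 3] <- r[3, 2] <- 0.4
  expect_equal(max_threshold(reciprocal_distance(r, cap = 100)), 100)
  expect_error(max_threshold(matrix(0, 1, 1)), "at least 2")
})

test_that("matrix TSV round-trips with labels", {
  set.seed(6)
  rec <- generate_cohort_recording(cohort_spec(n_channels = 5,
                                               n_samples = 100,
                                               block_partition = list(1:5),
                                               seed = 6))
  r <- pearson_matrix(rec)
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(r, path)
  back <- read_matrix_tsv(path)
  expect_equal(back, unclass(r), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colnames(back), rec$labels)
})
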