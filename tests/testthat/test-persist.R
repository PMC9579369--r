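square_diagram <- function() {
  persistent_homology(rips_filtration(generate_fixture("square"),
                                      max_dim = 2, eps_max = 2))
}

test_that("hand-analysed fixtures give the expected intervals", {
  # single point: one essential component
  single <- rips_filtration(point_cloud(matrix(0, 1, 1)), max_dim = 0,
                            eps_max = 1)
  dg1 <- persistent_homology(single)
  expect_equal(nrow(dg1), 1)
  expect_equal(dg1$dimension, 0L)
  expect_equal(dg1$death, Inf)

  # unit square: three [0,1) components + essential; loop [1, sqrt(2))
  dg <- square_diagram()
  d0 <- dg[dg$dimension == 0, ]
  expect_equal(nrow(d0), 4)
  expect_equal(sum(is.finite(d0$death)), 3)
  expect_equal(d0$death[is.finite(d0$death)], rep(1, 3))
  d1 <- dg[dg$dimension == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$birth, d1$death), c(1, sqrt(2)), tolerance = 1e-12)

  # equilateral triangle: loop and filling appear together -> no Dim1 bar
  tri <- point_cloud(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  dgt <- persistent_homology(rips_filtration(tri, max_dim = 2, eps_max = 2))
  expect_equal(sum(dgt$dimension == 1), 0)
  expect_equal(sum(dgt$dimension == 0 & is.finite(dgt$death)), 2)
})

test_that("reduction and brute-force oracle agree on fixtures and random clouds", {
  fixtures <- list(
    rips_filtration(generate_fixture("square"), max_dim = 2, eps_max = 2),
    rips_filtration(generate_fixture("circle", n_points = 8), max_dim = 2,
                    eps_max = 2.1),
    rips_filtration(generate_fixture("line", n_points = 5), max_dim = 2,
                    eps_max = 5))
  for (f in fixtures)
    expect_same_intervals(persistent_homology(f), ph_oracle(f))
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    f <- rips_filtration(as.matrix(dist(random_cloud(n))), max_dim = 2,
                         eps_max = sqrt(2))
    expect_same_intervals(persistent_homology(f), ph_oracle(f))
  }
})

test_that("dimension-0 intervals count the vertices", {
  set.seed(32)
  for (n in c(2, 5, 9)) {
    f <- rips_filtration(as.matrix(dist(random_cloud(n))), max_dim = 2,
                         eps_max = sqrt(2))
    dg <- persistent_homology(f)
    expect_equal(sum(dg$dimension == 0), n)
    expect_equal(sum(dg$dimension == 0 & !is.finite(dg$death)), 1)
  }
})

test_that("betti numbers read off the diagram match the complex", {
  dg <- square_diagram()
  expect_equal(betti_numbers_at(dg, 1.2), c(beta0 = 1L, beta1 = 1L))
  expect_equal(betti_numbers_at(dg, 0.5), c(beta0 = 4L, beta1 = 0L))
  expect_equal(betti_numbers_at(dg, 2), c(beta0 = 1L, beta1 = 0L))
  expect_error(betti_numbers_at(dg, 3), "must lie in")

  circ <- persistent_homology(rips_filtration(
    generate_fixture("circle", n_points = 20), max_dim = 2, eps_max = 2.1))
  expect_equal(betti_numbers_at(circ, 1), c(beta0 = 1L, beta1 = 1L))
})

test_that("Euler characteristic is consistent at every threshold", {
  # max_dim = n - 1, so no truncation artifacts exist at any scale
  set.seed(33)
  for (cloud in list(generate_fixture("square")$coordinates,
                     random_cloud(6))) {
    n <- nrow(cloud)
    d <- as.matrix(dist(cloud))
    f <- rips_filtration(d, max_dim = n - 1, eps_max = max(d))
    dg <- persistent_homology(f, drop_top = FALSE)
    for (eps in unique(f$value)) {
      chi_simp <- sum((-1)^f$dim[f$value <= eps])
      alive <- dg$birth <= eps & dg$death > eps
      chi_homo <- sum((-1)^dg$dimension[alive])
      expect_equal(chi_simp, chi_homo)
    }
  }
})

test_that("sphere point cloud shows a single dominant void", {
  ps <- generate_fixture("sphere", n_points = 40)
  dg <- persistent_homology(rips_filtration(ps, max_dim = 3, eps_max = 2.1))
  d2 <- dg[dg$dimension == 2, ]
  len <- sort(d2$death - d2$birth, decreasing = TRUE)
  expect_gte(length(len), 1)
  expect_gt(len[1], 5 * max(len[-1], 0))
  expect_equal(sum(dg$dimension == 0 & !is.finite(dg$death)), 1)
})

test_that("interval classification splits features from noise", {
  dg <- square_diagram()
  both <- classify_intervals(dg, 0)
  expect_equal(nrow(both$persistent), nrow(dg))
  expect_equal(nrow(both$noise), 0)
  split <- classify_intervals(dg, 0.5)
  expect_equal(sum(split$noise$dimension == 1), 1)   # length ~ 0.414 < 0.5
  high <- classify_intervals(dg, 10)
  expect_true(all(!is.finite(high$persistent$death)))
  expect_error(classify_intervals(dg, -1), ">= 0")
})

test_that("diagrams survive a text round trip including essential classes", {
  dg <- square_diagram()
  path <- tempfile(fileext = ".csv")
  write_diagram(dg, path)
  back <- read_diagram(path)
  expect_same_intervals(dg, back, tol = 1e-15)
  expect_equal(attr(back, "eps_max"), attr(dg, "eps_max"))
  expect_equal(attr(back, "max_dimension"), attr(dg, "max_dimension"))
})

test_that("closure violations and oversized oracle inputs are refused", {
  bad <- structure(list(vertices = list(c(1L, 2L)), dim = 1L, value = 0.5,
                        n_points = 2L, max_dimension = 1L, eps_max = 1,
                        fs = NULL, labels = NULL),
                   class = "phnet_filtration")
  expect_error(persistent_homology(bad), "closure")
  big <- rips_filtration(as.matrix(dist(random_cloud(30))), max_dim = 2,
                         eps_max = sqrt(2))
  expect_error(ph_oracle(big), "2000")
})

test_that("empty and vertex-only filtrations are handled", {
  f <- as_filtration(list(1L, 2L), c(0, 0), eps_max = 1)
  dg <- persistent_homology(f, drop_top = FALSE)
  expect_equal(nrow(dg), 2)
  expect_true(all(!is.finite(dg$death)))
  o <- ph_oracle(f, drop_top = FALSE)
  expect_same_intervals(dg, o)
})
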