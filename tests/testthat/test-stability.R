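test_that("assignment solver matches exhaustive permutation search", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n)
    got <- phnet:::solve_assignment(C)
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (k in seq_along(v))
        for (p in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], p)
      out
    }
    best <- min(vapply(perms(seq_len(n)), function(p)
      sum(C[cbind(seq_len(n), p)]), numeric(1)))
    expect_equal(got$total, best, tolerance = 1e-12)
    expect_equal(sort(got$match), seq_len(n))
  }
})

test_that("Wasserstein distance reproduces hand-computed matchings", {
  X <- make_diagram(0, 2)
  expect_equal(wasserstein_distance(X, empty_diagram()), 1)
  expect_equal(wasserstein_distance(make_diagram(c(0, 0), c(2, 1)), X), 0.5)
  expect_equal(wasserstein_distance(X, X), 0)
  # p = 2 on the same pair: single diagonal projection of (0,1)
  expect_equal(wasserstein_distance(make_diagram(c(0, 0), c(2, 1)), X,
                                    p = 2), 0.5)
  # matches brute-force enumeration on random small diagrams
  set.seed(42)
  for (i in 1:15) {
    A <- random_diagram(sample(0:4, 1))
    B <- random_diagram(sample(0:4, 1))
    expect_equal(wasserstein_distance(A, B, p = 1),
                 wasserstein1_brute(A, B), tolerance = 1e-10)
  }
})

test_that("bottleneck distance reproduces hand-computed matchings", {
  X <- make_diagram(0, 2)
  expect_equal(bottleneck_distance(X, empty_diagram()), 1)
  expect_equal(bottleneck_distance(X, make_diagram(0.1, 2.1)), 0.1,
               tolerance = 1e-10)
  expect_equal(bottleneck_distance(X, X), 0)
  expect_error(bottleneck_distance(X, X, e = -1), ">= 0")
  expect_error(wasserstein_distance(X, X, p = 0.5), ">= 1")
})

test_that("exact bottleneck equals exhaustive matching enumeration", {
  set.seed(43)
  for (i in 1:20) {
    A <- random_diagram(sample(0:3, 1))
    B <- random_diagram(sample(0:3, 1))
    expect_equal(bottleneck_distance(A, B, e = 0),
                 bottleneck_brute(A, B), tolerance = 1e-10)
  }
})

test_that("diagram distances satisfy the metric axioms", {
  set.seed(44)
  diagrams <- lapply(1:6, function(i) random_diagram(sample(2:8, 1)))
  for (i in 1:5) {
    a <- sample(6, 1); b <- sample(6, 1); c_ <- sample(6, 1)
    A <- diagrams[[a]]; B <- diagrams[[b]]; C <- diagrams[[c_]]
    bd <- bottleneck_distance
    wd <- function(x, y) wasserstein_distance(x, y, p = 1)
    expect_gte(bd(A, B), 0)
    expect_equal(bd(A, B), bd(B, A), tolerance = 1e-12)
    expect_equal(wd(A, B), wd(B, A), tolerance = 1e-10)
    expect_lte(bd(A, C), bd(A, B) + bd(B, C) + 1e-10)
    expect_lte(wd(A, C), wd(A, B) + wd(B, C) + 1e-8)
    expect_gte(wd(A, B) + 1e-12, bd(A, B))          # W1 >= W_inf
    expect_equal(bd(A, A), 0)
  }
})

test_that("approximate bottleneck honours its accuracy parameter", {
  set.seed(45)
  for (i in 1:20) {
    A <- random_diagram(sample(5:30, 1))
    B <- random_diagram(sample(5:30, 1))
    exact <- bottleneck_distance(A, B, e = 0)
    approx <- bottleneck_distance(A, B, e = 0.01)
    expect_lte(abs(approx - exact), 0.01)
  }
})

test_that("small point-cloud perturbations move diagrams by at most 2*delta", {
  set.seed(46)
  base <- generate_fixture("circle", n_points = 12)$coordinates
  d0 <- as.matrix(dist(base))
  for (delta in c(0.05, 0.1)) {
    for (rep in 1:5) {
      ang <- runif(12, 0, 2 * pi)
      rad <- delta * sqrt(runif(12))
      pert <- base + cbind(rad * cos(ang), rad * sin(ang))
      dp <- as.matrix(dist(pert))
      em <- max(d0, dp)
      f0 <- rips_filtration(d0, max_dim = 2, eps_max = em)
      fp <- rips_filtration(dp, max_dim = 2, eps_max = em)
      g0 <- persistent_homology(f0)
      gp <- persistent_homology(fp)
      for (dm in 0:1)
        expect_lte(bottleneck_distance(g0, gp, dim = dm), 2 * delta + 1e-9)
    }
  }
})

test_that("group comparison tables are consistent with direct calls", {
  sq <- persistent_homology(rips_filtration(generate_fixture("square"),
                                            max_dim = 2, eps_max = 2))
  tri <- persistent_homology(rips_filtration(
    point_cloud(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))),
    max_dim = 2, eps_max = 2))
  same <- compare_groups(list(a = sq), list(a = sq))
  expect_equal(same$bottleneck_dim0_exact, 0)
  expect_equal(same$wasserstein1_dim0, 0)
  tab <- compare_groups(list(x = sq), list(x = tri))
  expect_equal(tab$bottleneck_dim0_exact,
               bottleneck_distance(sq, tri, dim = 0))
  expect_equal(tab$wasserstein1_dim1,
               wasserstein_distance(sq, tri, p = 1, dim = 1))
  expect_error(compare_groups(list(), list(sq)), "non-empty")
  path <- tempfile(fileext = ".tsv")
  write_distance_table(tab, path)
  expect_match(readLines(path)[1], "bottleneck_dim0_exact")
})

test_that("essential classes can be truncated into the comparison", {
  A <- persistence_diagram(data.frame(dimension = 0L, birth = 0,
                                      death = Inf),
                           max_dimension = 0L, eps_max = 4)
  B <- persistence_diagram(data.frame(dimension = 0L, birth = 2,
                                      death = Inf),
                           max_dimension = 0L, eps_max = 4)
  expect_equal(bottleneck_distance(A, B), 0)          # dropped by default
  # truncated to (0,4) vs (2,4): direct match costs |0-2| = 2, double
  # diagonal projection costs max(2, 1) = 2 as well
  expect_equal(bottleneck_distance(A, B, essential = "truncate"), 2)
})
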