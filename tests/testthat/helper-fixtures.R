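# Shared helpers: hand-built diagrams, random diagrams/clouds, and
# brute-force matching oracles independent of the package's algorithms.

make_diagram <- function(birth, death, dim = 0L, eps_max = 10) {
  persistence_diagram(
    data.frame(dimension = rep(as.integer(dim), length.out = length(birth)),
               birth = birth, death = death),
    max_dimension = max(dim, 0L), eps_max = eps_max)
}

empty_diagram <- function(eps_max = 10) {
  persistence_diagram(data.frame(dimension = integer(0), birth = numeric(0),
                                 death = numeric(0)),
                      max_dimension = 0L, eps_max = eps_max)
}

random_diagram <- function(n, eps_max = 10) {
  b <- stats::runif(n, 0, eps_max * 0.7)
  d <- b + stats::runif(n, 0.01, eps_max * 0.3)
  make_diagram(b, pmin(d, eps_max), dim = 0L, eps_max = eps_max)
}

random_cloud <- function(n, dim = 2) matrix(stats::runif(n * dim), nrow = n)

linf <- function(a, b) unname(max(abs(a - b)))

# exhaustive bottleneck: enumerate every injective partial matching X -> Y,
# unmatched points projected to the diagonal
bottleneck_brute <- function(X, Y, dim = 0) {
  PX <- phnet:::diagram_points(X, dim)
  PY <- phnet:::diagram_points(Y, dim)
  nx <- nrow(PX); ny <- nrow(PY)
  if (nx == 0 && ny == 0) return(0)
  dgx <- (PX[, 2] - PX[, 1]) / 2
  dgy <- (PY[, 2] - PY[, 1]) / 2
  if (nx == 0) return(max(dgy))
  if (ny == 0) return(max(dgx))
  C <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny))
    C[i, j] <- linf(PX[i, ], PY[j, ])
  best <- Inf
  rec <- function(i, used, cur) {
    if (cur >= best) return()
    if (i > nx) {
      tot <- max(cur, if (any(!used)) max(dgy[!used]) else 0)
      if (tot < best) best <<- tot
      return()
    }
    rec(i + 1, used, max(cur, dgx[i]))          # x_i to the diagonal
    for (j in which(!used)) {
      used[j] <- TRUE
      rec(i + 1, used, max(cur, C[i, j]))
      used[j] <- FALSE
    }
  }
  rec(1, logical(ny), 0)
  unname(best)
}

# exhaustive 1-Wasserstein by the same enumeration, summing costs
wasserstein1_brute <- function(X, Y, dim = 0) {
  PX <- phnet:::diagram_points(X, dim)
  PY <- phnet:::diagram_points(Y, dim)
  nx <- nrow(PX); ny <- nrow(PY)
  if (nx == 0 && ny == 0) return(0)
  dgx <- (PX[, 2] - PX[, 1]) / 2
  dgy <- (PY[, 2] - PY[, 1]) / 2
  if (nx == 0) return(sum(dgy))
  if (ny == 0) return(sum(dgx))
  C <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny))
    C[i, j] <- linf(PX[i, ], PY[j, ])
  best <- Inf
  rec <- function(i, used, cur) {
    if (cur >= best) return()
    if (i > nx) {
      tot <- cur + sum(dgy[!used])
      if (tot < best) best <<- tot
      return()
    }
    rec(i + 1, used, cur + dgx[i])
    for (j in which(!used)) {
      used[j] <- TRUE
      rec(i + 1, used, cur + C[i, j])
      used[j] <- FALSE
    }
  }
  rec(1, logical(ny), 0)
  unname(best)
}

expect_same_intervals <- function(a, b, tol = 1e-10) {
  da <- as.data.frame(a); db <- as.data.frame(b)
  ord <- function(d) d[order(d$dimension, d$birth, d$death), , drop = FALSE]
  da <- ord(da); db <- ord(db)
  expect_equal(nrow(da), nrow(db))
  if (nrow(da)) {
    expect_equal(da$dimension, db$dimension)
    expect_equal(da$birth, db$birth, tolerance = tol)
    expect_equal(da$death, db$death, tolerance = tol)
  }
}
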