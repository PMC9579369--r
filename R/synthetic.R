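# Synthetic cohorts and geometric fixtures. Signals are stationary Gaussian
# processes drawn from an explicit block-structured correlation matrix, so the
# population Pearson structure of the output is exactly the specification and
# every downstream stage can be tested without clinical data.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic recording cohort
#'
#' Describes a block-structured multichannel recording: channels are grouped
#' into blocks, correlation is `within_block_r` inside a block and
#' `between_block_r` across blocks. The implied correlation matrix is checked
#' for positive semidefiniteness at construction, so an inconsistent
#' specification fails early rather than at sampling time.
#'
#' The defaults emulate the geometry of a 60-electrode task recording:
#' six functional modules of ten channels, moderately strong coupling inside
#' a module and weak coupling across modules, sized so that the
#' reciprocal-correlation distances span roughly 1.5-7 (the scale on which
#' full-range Vietoris-Rips filtering of such networks operates).
#'
#' @param n_channels number of channels (default 60).
#' @param n_samples samples per channel.
#' @param sampling_rate sampling rate in Hz.
#' @param block_partition list of integer vectors partitioning
#'   `1:n_channels`; defaults to equal consecutive blocks of 10 (or a single
#'   block if `n_channels < 10`).
#' @param within_block_r,between_block_r target Pearson correlation inside /
#'   across blocks, each in (-1, 1).
#' @param noise_sd marginal standard deviation of each channel.
#' @param seed integer seed; the same spec and seed always reproduce the same
#'   recording bit for bit.
#' @param carrier_amp optional oscillator mode: if > 0, each block
#'   additionally receives a shared sinusoidal carrier of this relative
#'   amplitude (frequencies spread over 5-38 Hz), giving band filtering
#'   realistic narrow-band content. Carriers perturb the exact correlation
#'   targets and are off by default.
#' @return A `phnet_cohort_spec`.
#' @seealso [generate_cohort_recording()]
#' @export
cohort_spec <- function(n_channels = 60, n_samples = 4000,
                        sampling_rate = 250, block_partition = NULL,
                        within_block_r = 0.6, between_block_r = 0.2,
                        noise_sd = 1, seed = 1, carrier_amp = 0) {
  if (n_channels < 1) stop("`n_channels` must be >= 1")
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  if (is.null(block_partition)) {
    size <- if (n_channels >= 10) 10 else n_channels
    starts <- seq(1, n_channels, by = size)
    block_partition <- lapply(starts, function(s)
      seq(s, min(s + size - 1, n_channels)))
  }
  idx <- sort(unlist(block_partition))
  if (!identical(as.integer(idx), seq_len(n_channels)))
    stop("`block_partition` must cover channels 1..", n_channels,
         " exactly once")
  for (r in c(within_block_r, between_block_r))
    if (!is.numeric(r) || abs(r) >= 1)
      stop("block correlations must lie in (-1, 1)")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")

  R <- matrix(between_block_r, n_channels, n_channels)
  for (b in block_partition) R[b, b] <- within_block_r
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied correlation matrix is not positive semidefinite ",
         sprintf("(min eigenvalue %.3g) for within_block_r = %g, ",
                 min(ev), within_block_r),
         sprintf("between_block_r = %g with %d blocks",
                 between_block_r, length(block_partition)))
  structure(list(n_channels = n_channels, n_samples = n_samples,
                 sampling_rate = sampling_rate,
                 block_partition = block_partition,
                 within_block_r = within_block_r,
                 between_block_r = between_block_r,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 carrier_amp = carrier_amp, correlation = R),
            class = "phnet_cohort_spec")
}

#' Generate a recording from a cohort specification
#'
#' Draws a stationary Gaussian multichannel signal whose population
#' inter-channel correlation matrix equals the spec's implied block matrix
#' (by a Cholesky transform of i.i.d. normals). Deterministic under the
#' spec's seed; the global RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @return A [recording()].
#' @examples
#' rec <- generate_cohort_recording(cohort_spec(n_channels = 10,
#'                                              n_samples = 500, seed = 7))
#' dim(rec$signals)
#' @export
generate_cohort_recording <- function(spec) {
  stopifnot(inherits(spec, "phnet_cohort_spec"))
  n <- spec$n_channels
  L <- t(chol(spec$correlation + diag(1e-12, n)))
  sig <- with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(n * spec$n_samples), nrow = n)
    X <- spec$noise_sd * (L %*% Z)
    if (spec$carrier_amp > 0) {
      tt <- seq_len(spec$n_samples) / spec$sampling_rate
      freqs <- seq(5, 38, length.out = length(spec$block_partition))
      for (k in seq_along(spec$block_partition)) {
        carrier <- spec$carrier_amp * spec$noise_sd *
          sin(2 * pi * freqs[k] * tt + stats::runif(1, 0, 2 * pi))
        X[spec$block_partition[[k]], ] <-
          X[spec$block_partition[[k]], ] + rep(carrier, each =
                                                 length(spec$block_partition[[k]]))
      }
    }
    X
  })
  recording(sig, srate = spec$sampling_rate)
}

#' Specify a geometric point-cloud fixture
#'
#' Small point clouds with homology known a priori, used as oracles for the
#' Vietoris-Rips / persistence stack: `circle` (evenly spaced on the unit
#' circle), `sphere` (Fibonacci lattice on the unit sphere -- deterministic
#' quasi-uniformity), `square` (the 4 unit-square corners), `line` (collinear
#' points, default positions `0:(n_points-1)` or explicit `positions`), and
#' `random` (uniform in the unit cube).
#'
#' @param name fixture name.
#' @param n_points number of points (forced to 4 for `square`).
#' @param ambient_dim ambient dimension; defaults to the fixture's natural
#'   dimension (2 for circle/square/random, 3 for sphere, 1 for line).
#' @param noise_sd standard deviation of i.i.d. Gaussian coordinate noise.
#' @param seed integer seed for noise / random clouds.
#' @param positions optional explicit 1-d positions for `line`.
#' @return A `phnet_fixture_spec`.
#' @export
geometric_fixture <- function(name = c("circle", "sphere", "square", "line",
                                       "random"),
                              n_points = 20, ambient_dim = NULL,
                              noise_sd = 0, seed = 1, positions = NULL) {
  if (is.character(name) && length(name) == 1 &&
      !name %in% c("circle", "sphere", "square", "line", "random"))
    stop("unknown fixture '", name, "'; supported: circle, sphere, square, ",
         "line, random")
  name <- match.arg(name)
  if (n_points < 1) stop("`n_points` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(ambient_dim))
    ambient_dim <- switch(name, sphere = 3L, line = 1L, 2L)
  if (name == "square") n_points <- 4L
  structure(list(name = name, n_points = as.integer(n_points),
                 ambient_dim = as.integer(ambient_dim),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 positions = positions),
            class = "phnet_fixture_spec")
}

#' Generate a fixture point cloud
#'
#' @param fix a [geometric_fixture()], or a fixture name (other arguments
#'   forwarded to [geometric_fixture()]).
#' @param ... forwarded to [geometric_fixture()] when `fix` is a name.
#' @return A `phnet_pointcloud` (see [point_cloud()]).
#' @examples
#' pc <- generate_fixture("circle", n_points = 12)
#' dim(pc$coordinates)
#' @export
generate_fixture <- function(fix, ...) {
  if (is.character(fix)) fix <- geometric_fixture(fix, ...)
  stopifnot(inherits(fix, "phnet_fixture_spec"))
  n <- fix$n_points
  base <- switch(fix$name,
    circle = {
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(cos(th), sin(th))
    },
    sphere = {
      # Fibonacci lattice: z equally spaced, azimuth by the golden angle
      i <- seq_len(n) - 0.5
      z <- 1 - 2 * i / n
      r <- sqrt(pmax(0, 1 - z^2))
      ga <- pi * (3 - sqrt(5))
      cbind(r * cos(ga * (seq_len(n) - 1)), r * sin(ga * (seq_len(n) - 1)), z)
    },
    square = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    line = {
      pos <- if (is.null(fix$positions)) seq_len(n) - 1 else fix$positions
      matrix(pos, ncol = 1)
    },
    random = NULL)
  m <- fix$ambient_dim
  coords <- with_seed(fix$seed, {
    pts <- if (fix$name == "random") {
      matrix(stats::runif(n * m), nrow = n)
    } else {
      b <- base
      if (n == 1 && fix$name %in% c("circle", "sphere"))
        b <- matrix(0, 1, ncol(b))       # a 1-point "circle" is just a point
      if (ncol(b) < m)                   # pad into a higher ambient space
        b <- cbind(b, matrix(0, nrow(b), m - ncol(b)))
      b
    }
    if (fix$noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, fix$noise_sd),
                          nrow = nrow(pts))
    pts
  })
  point_cloud(coords, source_note = sprintf("fixture:%s n=%d noise=%g seed=%d",
                                            fix$name, n, fix$noise_sd,
                                            fix$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
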