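# Vietoris-Rips filtration. A simplex [x0..xk] enters the complex at the
# largest pairwise distance among its vertices; running the threshold from 0
# to eps_max yields the nested family of complexes whose homology the
# persistence stage tracks. Construction is by incremental expansion in C++;
# an optional Fs-step grid snaps appearance values upward onto
# {i * eps_max / Fs}, mirroring the discrete filtering-step convention of
# standard persistence software.

#' Vietoris-Rips filtration
#'
#' @param d a distance source: a `phnet_dist` / symmetric matrix, a `dist`,
#'   or a [point_cloud()] (Euclidean distances are taken).
#' @param max_dim maximum simplex dimension (default 2: triangles, enough to
#'   track components and loops; use 3 to track voids).
#' @param eps_max maximum filtering threshold; default
#'   [max_threshold()] of `d`, i.e. the full scale of the data.
#' @param fs optional number of filtering steps; appearance values are
#'   snapped up to the grid `i * eps_max / fs` so a simplex never appears
#'   before it exists. `NULL` (default) keeps exact values.
#' @return A `phnet_filtration`: simplices sorted by (value, dimension,
#'   vertex tuple), with fields `vertices` (list of 1-based sorted integer
#'   vectors), `dim`, `value`, `n_points`, `max_dimension`, `eps_max`, `fs`.
#' @examples
#' pc <- generate_fixture("square")
#' f <- rips_filtration(pc, max_dim = 2, eps_max = 2)
#' count_by_dimension(f)
#' @export
rips_filtration <- function(d, max_dim = 2, eps_max = NULL, fs = NULL) {
  if (inherits(d, "phnet_pointcloud")) d <- stats::dist(d$coordinates)
  if (inherits(d, "dist")) d <- as.matrix(d)
  m <- unclass(as.matrix(d))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("`d` must be a symmetric distance matrix, a dist, or a point cloud")
  if (max_dim < 0) stop("`max_dim` must be >= 0")
  if (is.null(eps_max)) eps_max <- max(m[upper.tri(m)])
  if (!is.numeric(eps_max) || eps_max <= 0) stop("`eps_max` must be > 0")
  if (!is.null(fs) && (fs < 1 || fs != round(fs)))
    stop("`fs` must be a positive integer count of filtering steps")

  res <- rips_complex_cpp(m, as.integer(max_dim), as.numeric(eps_max))
  f <- structure(list(vertices = res$vertices, dim = res$dim,
                      value = res$value, n_points = nrow(m),
                      max_dimension = as.integer(max_dim),
                      eps_max = eps_max, fs = fs,
                      labels = rownames(m)),
                 class = "phnet_filtration")
  if (!is.null(fs)) f <- snap_filtration(f, fs)
  f
}

snap_filtration <- function(f, fs) {
  step <- f$eps_max / fs
  # snap upward; the 1e-9 relative guard keeps exact grid values in place
  snapped <- step * ceiling(f$value / step - 1e-9)
  snapped[f$value == 0] <- 0
  f$value <- snapped
  f$fs <- fs
  sort_filtration(f)
}

sort_filtration <- function(f) {
  key <- vapply(f$vertices, function(v)
    paste(sprintf("%06d", v), collapse = ""), "")
  ord <- order(f$value, f$dim, key)
  f$vertices <- f$vertices[ord]
  f$dim <- f$dim[ord]
  f$value <- f$value[ord]
  f
}

#' Assemble a filtration from explicit simplices
#'
#' For hand-built test complexes: sorts by (value, dimension, vertex tuple)
#' and records the bookkeeping fields. Closure is checked downstream by
#' [persistent_homology()].
#'
#' @param vertices list of sorted 1-based integer vectors.
#' @param values appearance value per simplex.
#' @param eps_max maximum threshold (default: largest value).
#' @return A `phnet_filtration`.
#' @export
as_filtration <- function(vertices, values, eps_max = max(values)) {
  stopifnot(length(vertices) == length(values))
  vertices <- lapply(vertices, function(v) sort(as.integer(v)))
  f <- structure(list(vertices = vertices,
                      dim = lengths(vertices) - 1L,
                      value = as.numeric(values),
                      n_points = max(unlist(vertices)),
                      max_dimension = max(lengths(vertices)) - 1L,
                      eps_max = eps_max, fs = NULL, labels = NULL),
                 class = "phnet_filtration")
  sort_filtration(f)
}

#' @export
print.phnet_filtration <- function(x, ...) {
  cnt <- count_by_dimension(x)
  cat(sprintf(paste0("<phnet_filtration> %d points, %d simplices up to ",
                     "dim %d, eps_max %.4g%s\n"),
              x$n_points, length(x$value), x$max_dimension, x$eps_max,
              if (is.null(x$fs)) " (exact values)"
              else sprintf(" (Fs = %d grid)", x$fs)))
  print(cnt)
  invisible(x)
}

#' Simplex counts by dimension
#'
#' The per-dimension complex-size diagnostic of a filtration (with the total
#' as the last element).
#'
#' @param f a `phnet_filtration`.
#' @return Named integer vector `dim0`, `dim1`, ..., `total`.
#' @export
count_by_dimension <- function(f) {
  stopifnot(inherits(f, "phnet_filtration"))
  dims <- 0:f$max_dimension
  counts <- vapply(dims, function(p) sum(f$dim == p), integer(1))
  c(stats::setNames(counts, paste0("dim", dims)), total = sum(counts))
}

#' Export a filtration as text
#'
#' One simplex per row: appearance value, dimension, then the 1-based vertex
#' list, in the filtration's deterministic (value, dimension, vertex tuple)
#' order.
#'
#' @param f a `phnet_filtration`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filtration <- function(f, path) {
  stopifnot(inherits(f, "phnet_filtration"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# value dimension vertices... (1-based)", con)
  writeLines(vapply(seq_along(f$value), function(i)
    paste(c(sprintf("%.17g", f$value[i]), f$dim[i], f$vertices[[i]]),
          collapse = " "), ""), con)
  invisible(path)
}
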