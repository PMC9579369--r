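# ISOMAP embedding of the inter-node distance matrix: symmetric k-nearest-
# neighbour graph, exact all-pairs geodesic (shortest-path) distances, then
# classical multidimensional scaling of the geodesic matrix. This recovers a
# low-dimensional point cloud whose Euclidean geometry approximates the
# network's intrinsic geometry, ready for Vietoris-Rips filtering.

#' Point-cloud container
#'
#' @param coordinates numeric n x m matrix of point coordinates.
#' @param labels optional point labels.
#' @param source_note provenance string.
#' @return A `phnet_pointcloud`.
#' @export
point_cloud <- function(coordinates, labels = NULL, source_note = "") {
  coordinates <- as.matrix(coordinates)
  if (!nrow(coordinates) || !ncol(coordinates))
    stop("point cloud needs at least one point and one coordinate")
  if (any(!is.finite(coordinates)))
    stop("point cloud contains non-finite coordinates")
  if (is.null(labels)) labels <- sprintf("p%02d", seq_len(nrow(coordinates)))
  rownames(coordinates) <- labels
  structure(list(coordinates = coordinates, labels = labels,
                 source_note = source_note),
            class = "phnet_pointcloud")
}

#' @export
print.phnet_pointcloud <- function(x, ...) {
  cat(sprintf("<phnet_pointcloud> %d points in %d dimensions%s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              if (nzchar(x$source_note)) paste0(" (", x$source_note, ")")
              else ""))
  invisible(x)
}

#' ISOMAP embedding of a distance matrix
#'
#' Builds the symmetric k-nearest-neighbour graph (an edge is kept if either
#' endpoint ranks it among its `k` nearest), computes exact all-pairs
#' shortest-path distances on it, and embeds the geodesic matrix by
#' classical multidimensional scaling. With a complete neighbour graph
#' (`k = n - 1`) the geodesics equal the input distances and the procedure
#' reduces to classical MDS.
#'
#' The embedding dimension is data-driven by default: all components whose
#' MDS eigenvalue exceeds `1e-8` times the largest are kept (capped at
#' `n - 1`). Negative eigenvalues -- the signature of non-Euclidean geodesic
#' geometry -- are dropped and their total magnitude reported.
#'
#' @param d a distance matrix ([reciprocal_distance()] or any symmetric
#'   matrix with zero diagonal), or a `dist` object.
#' @param k neighbour count (default 7).
#' @param target_dim `"auto"` (eigenvalue threshold) or an explicit
#'   dimension.
#' @return A list with elements `points` (a [point_cloud()]) and `report`
#'   (an embedding report: `chosen_dim`, `eigenvalues`, `residual_variance`
#'   per candidate dimension, `neighbor_param`,
#'   `negative_eigenvalue_mass`).
#' @examples
#' pc <- generate_fixture("circle", n_points = 12)
#' emb <- isomap_embed(as.matrix(dist(pc$coordinates)), k = 3)
#' emb$report$chosen_dim
#' @export
isomap_embed <- function(d, k = 7, target_dim = "auto") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- validate_dist(d)
  n <- nrow(d)
  if (k < 1) stop("`k` must be >= 1")
  k <- min(k, n - 1)

  g <- knn_graph(d, k)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    kmin <- k
    while (kmin < n - 1 &&
           igraph::components(knn_graph(d, kmin))$no > 1) kmin <- kmin + 1
    stop("k-nearest-neighbour graph with k = ", k, " is disconnected (",
         comp$no, " components); the smallest connecting k is ", kmin)
  }
  geo <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(geo) <- dimnames(d)

  # cmdscale warns when < k eigenvalues are positive; component selection is
  # handled explicitly below, so the warning carries no information here
  mds <- suppressWarnings(stats::cmdscale(geo, k = n - 1, eig = TRUE))
  ev <- mds$eig
  pos <- which(ev > 1e-8 * max(ev))
  avail <- ncol(mds$points)
  keep <- if (identical(target_dim, "auto")) {
    length(pos)
  } else {
    td <- as.integer(target_dim)
    if (td < 1 || td > n - 1)
      stop("`target_dim` must be in 1..", n - 1)
    if (td > avail) {
      warning("only ", avail, " informative components available; using ",
              avail, " instead of ", td)
      avail
    } else td
  }
  keep <- max(1L, min(keep, avail))
  coords <- mds$points[, seq_len(keep), drop = FALSE]

  evpos <- ev[ev > 0]
  resid <- 1 - cumsum(evpos) / sum(evpos)
  report <- structure(list(
    chosen_dim = keep,
    eigenvalues = sort(ev, decreasing = TRUE),
    residual_variance = resid,
    neighbor_param = k,
    negative_eigenvalue_mass = sum(abs(ev[ev < 0]))),
    class = "phnet_embedding_report")
  list(points = point_cloud(coords, labels = rownames(d),
                            source_note = sprintf("isomap k=%d dim=%d",
                                                  k, keep)),
       report = report)
}

knn_graph <- function(d, k) {
  n <- nrow(d)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])               # ties broken by node index
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)                    # symmetric union rule
  w <- unclass(d)
  w[!adj] <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' @export
print.phnet_embedding_report <- function(x, ...) {
  cat(sprintf(paste0("<phnet_embedding_report> dim %d (k = %d), leading ",
                     "eigenvalues %s, negative mass %.3g\n"),
              x$chosen_dim, x$neighbor_param,
              paste(signif(utils::head(x$eigenvalues, 3), 4),
                    collapse = ", "),
              x$negative_eigenvalue_mass))
  invisible(x)
}

#' Write / read a point cloud as whitespace-delimited text
#'
#' One point per row, coordinates separated by single spaces, no header --
#' the plain coordinate layout consumed by standard persistence software.
#' Values round-trip through a decimal representation losslessly.
#'
#' @param pc a [point_cloud()].
#' @param path file path.
#' @return `path` invisibly (write); a [point_cloud()] (read).
#' @export
write_point_cloud <- function(pc, path) {
  stopifnot(inherits(pc, "phnet_pointcloud"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(pc$coordinates, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  coords <- do.call(rbind, lapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "[ \t]+")[[1]])))
  point_cloud(coords, source_note = paste("read from", basename(path)))
}
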