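# Network construction: Pearson correlation between channels, the
# reciprocal-correlation distance on which the full-scale filtration runs,
# density-thresholded binary views for conventional single-threshold
# comparison, and the edge-weight-list text interchange format.

#' Inter-channel Pearson correlation matrix
#'
#' @param rec a [recording()] (at least 3 samples; no zero-variance channel).
#' @return A `phnet_corr`: symmetric correlation matrix with unit diagonal,
#'   channel labels as dimnames, and the recording's band tag as an
#'   attribute.
#' @examples
#' rec <- generate_cohort_recording(cohort_spec(n_channels = 6,
#'                                              n_samples = 200))
#' pearson_matrix(rec)[1:3, 1:3]
#' @export
pearson_matrix <- function(rec) {
  stopifnot(inherits(rec, "phnet_recording"))
  if (n_samples(rec) < 3)
    stop("need at least 3 samples to estimate correlations, got ",
         n_samples(rec))
  v <- apply(rec$signals, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance channel(s): ",
         paste(rec$labels[v == 0], collapse = ", "))
  r <- stats::cor(t(rec$signals))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rec$labels, rec$labels)
  structure(r, class = c("phnet_corr", "matrix"), band = rec$band)
}

#' Reciprocal-correlation distance matrix
#'
#' Converts correlations to inter-node distances by `d_ij = 1 / |r_ij|`:
#' strongly (anti-)correlated channels are close, weakly correlated channels
#' far apart. Distances are capped at `cap` so near-zero correlations stay
#' finite. The magnitude is used because a distance must be positive and
#' anti-correlation is still functional coupling.
#'
#' @param corr a [pearson_matrix()] result (or a plain symmetric correlation
#'   matrix).
#' @param cap upper bound for the distance (must exceed 1, the distance at
#'   perfect correlation); default 1000.
#' @return A `phnet_dist`: symmetric matrix with zero diagonal and positive
#'   finite off-diagonal entries.
#' @export
reciprocal_distance <- function(corr, cap = 1000) {
  corr <- validate_corr(corr)
  if (cap <= 1)
    stop("`cap` must exceed 1 (the distance at |r| = 1); got ", cap)
  d <- 1 / abs(unclass(corr))
  d[d > cap] <- cap
  diag(d) <- 0
  structure(d, class = c("phnet_dist", "matrix"),
            band = attr(corr, "band"), cap = cap)
}

validate_corr <- function(corr) {
  m <- unclass(as.matrix(corr))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-10)
    stop("correlation matrix must be symmetric")
  if (any(abs(m) > 1 + 1e-10)) stop("correlations must lie in [-1, 1]")
  if (any(abs(diag(m) - 1) > 1e-10))
    stop("correlation matrix must have unit diagonal")
  if (is.null(dimnames(m)))
    dimnames(m) <- list(sprintf("ch%02d", seq_len(nrow(m))),
                        sprintf("ch%02d", seq_len(nrow(m))))
  structure(m, class = c("phnet_corr", "matrix"),
            band = attr(corr, "band") %||% "full")
}

validate_dist <- function(d) {
  if (inherits(d, "phnet_dist")) return(d)
  m <- unclass(as.matrix(d))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix must have zero diagonal")
  off <- m[upper.tri(m)]
  if (length(off) && (any(!is.finite(off)) || any(off <= 0)))
    stop("off-diagonal distances must be positive and finite")
  if (is.null(dimnames(m)))
    dimnames(m) <- list(sprintf("ch%02d", seq_len(nrow(m))),
                        sprintf("ch%02d", seq_len(nrow(m))))
  structure(m, class = c("phnet_dist", "matrix"))
}

#' Density-thresholded binary adjacency matrix
#'
#' The conventional single-threshold view the full-scale analysis replaces:
#' keeps the `floor(density * n(n-1)/2)` edges of largest absolute
#' correlation. Ties at the cutoff are included as a whole group (the
#' realized density is then recorded in the `realized_density` attribute), so
#' the output is deterministic and independent of sort order.
#'
#' @param corr a correlation matrix.
#' @param density fraction of retained edges in `[0, 1]`.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
threshold_by_density <- function(corr, density) {
  corr <- validate_corr(corr)
  if (!is.numeric(density) || density < 0 || density > 1)
    stop("`density` must lie in [0, 1]")
  n <- nrow(corr)
  ut <- which(upper.tri(corr))
  w <- abs(unclass(corr))[ut]
  m <- floor(density * length(ut))
  A <- matrix(0L, n, n, dimnames = dimnames(corr))
  if (m > 0) {
    cutoff <- sort(w, decreasing = TRUE)[m]
    keep <- ut[w >= cutoff]              # whole tie group at the cutoff
    A[keep] <- 1L
    A <- A + t(A)
  }
  structure(A, realized_density = sum(A) / (n * (n - 1)))
}

#' Edge-weight list of a distance matrix
#'
#' One row per unordered node pair `(i, j)`, `i < j`, in lexicographic order,
#' with the distance as weight -- the interchange layout used to feed the
#' point-cloud construction. Node indices are 1-based.
#'
#' @param d a [reciprocal_distance()] matrix.
#' @return A data.frame with columns `i`, `j`, `weight`.
#' @export
edge_weight_list <- function(d) {
  d <- validate_dist(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  idx <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  data.frame(i = idx[ord, 1], j = idx[ord, 2],
             weight = unclass(d)[idx[ord, , drop = FALSE]])
}

#' @rdname edge_weight_list
#' @param path output file path; whitespace-delimited rows `i j weight`
#'   (1-based indices, stated in the header).
#' @export
write_edge_weights <- function(d, path) {
  ew <- if (is.data.frame(d)) d else edge_weight_list(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# i j weight (node indices 1-based)", con)
  writeLines(sprintf("%d %d %.17g", ew$i, ew$j, ew$weight), con)
  invisible(path)
}

#' @rdname edge_weight_list
#' @export
read_edge_weights <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("i", "j", "weight"))
  tab
}

#' Rebuild a distance matrix from an edge-weight list
#'
#' Inverse of [edge_weight_list()]; the round trip is lossless.
#'
#' @param ew data.frame with columns `i`, `j`, `weight`.
#' @param labels optional node labels.
#' @return A `phnet_dist` matrix.
#' @export
edge_weights_to_distance <- function(ew, labels = NULL) {
  n <- max(ew$i, ew$j)
  m <- matrix(0, n, n)
  m[cbind(ew$i, ew$j)] <- ew$weight
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  validate_dist(m)
}

#' Maximum filtering threshold
#'
#' The largest inter-node distance: running the Vietoris-Rips filtration up
#' to this value covers the full scale of the network, which is what makes
#' the analysis threshold-free.
#'
#' @param d a distance matrix.
#' @return A single distance.
#' @export
max_threshold <- function(d) {
  d <- validate_dist(d)
  if (nrow(d) < 2) stop("need at least 2 nodes to define a threshold")
  max(d[upper.tri(d)])
}

#' Write / read a labelled square matrix as delimited text
#'
#' Tab-separated, one header row of channel labels; used for both
#' correlation and distance matrices.
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read), invisibly for write.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(format(unclass(m), digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = colnames(m))
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab)
  dimnames(m) <- list(colnames(m), colnames(m))
  m
}
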