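# Persistent homology over the two-element field. The production path is
# boundary-matrix column reduction in filtration order (C++); the oracle path
# recomputes every interval from persistent Betti numbers obtained by GF(2)
# rank computations on boundary submatrices -- two genuinely different
# algorithms whose agreement is asserted in the tests.

#' Persistence diagram container
#'
#' A data.frame of intervals (`dimension`, `birth`, `death`; `death = Inf`
#' for essential classes) carrying `max_dimension`, `eps_max` and
#' `provenance` attributes. Zero-length intervals are never present: a class
#' born and killed at the same threshold is invisible in barcodes.
#'
#' @param intervals data.frame with columns `dimension`, `birth`, `death`.
#' @param max_dimension largest homology dimension the diagram can report.
#' @param eps_max maximum filtration threshold the diagram was computed to.
#' @param provenance free-text source note.
#' @return A `phnet_diagram`.
#' @export
persistence_diagram <- function(intervals, max_dimension, eps_max,
                                provenance = "") {
  intervals <- as.data.frame(intervals)[, c("dimension", "birth", "death")]
  if (nrow(intervals)) {
    if (any(intervals$birth < 0)) stop("births must be >= 0")
    fin <- is.finite(intervals$death)
    if (any(intervals$death[fin] <= intervals$birth[fin]))
      stop("finite deaths must exceed births")
    if (any(intervals$death[fin] > eps_max + 1e-9))
      stop("finite deaths must not exceed eps_max")
    ord <- order(intervals$dimension, intervals$birth, intervals$death)
    intervals <- intervals[ord, , drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(intervals,
            class = c("phnet_diagram", "data.frame"),
            max_dimension = max_dimension, eps_max = eps_max,
            provenance = provenance)
}

#' @export
print.phnet_diagram <- function(x, ...) {
  cat(sprintf("<phnet_diagram> %d intervals (eps_max %.4g, %s)\n",
              nrow(x), attr(x, "eps_max"),
              attr(x, "provenance") %||% ""))
  print(as.data.frame(x))
  invisible(x)
}

#' Persistent homology of a filtration
#'
#' Computes the birth/death intervals of homology classes over the
#' two-element field by column reduction of the boundary matrix in
#' filtration order. Dimension 0 tracks connected components, dimension 1
#' loops (tunnels), dimension 2 voids. Classes alive at `eps_max` are
#' essential (`death = Inf`); there is exactly one essential dimension-0
#' class per connected component, and the dimension-0 interval count
#' (finite plus essential) equals the vertex count.
#'
#' Classes in the filtration's top simplex dimension are dropped by default:
#' a Rips `d`-skeleton contains no `(d+1)`-simplices, so every dimension-`d`
#' class is an essential truncation artifact, not a feature of the data. To
#' measure dimension-`p` homology, build the filtration with
#' `max_dim >= p + 1`.
#'
#' @param f a `phnet_filtration` (faces must precede cofaces; violated
#'   closure raises an error naming the offending simplex position).
#' @param drop_top drop classes in the top simplex dimension (default TRUE).
#' @return A [persistence_diagram()].
#' @examples
#' f <- rips_filtration(generate_fixture("square"), max_dim = 2, eps_max = 2)
#' persistent_homology(f)
#' @export
persistent_homology <- function(f, drop_top = TRUE) {
  stopifnot(inherits(f, "phnet_filtration"))
  iv <- reduce_filtration_cpp(f$vertices, f$dim, f$value)
  iv$death[is.na(iv$death)] <- Inf
  top <- f$max_dimension
  report_max <- top
  if (drop_top && top >= 1) {
    iv <- iv[iv$dimension < top, , drop = FALSE]
    report_max <- top - 1L
  }
  persistence_diagram(iv, max_dimension = report_max, eps_max = f$eps_max,
                      provenance = sprintf("reduction n=%d", f$n_points))
}

#' Betti numbers at a threshold
#'
#' `beta_p(eps)` = number of dimension-`p` intervals with
#' `birth <= eps < death`: components, loops and voids of the complex at
#' scale `eps`, read directly off the diagram.
#'
#' @param diag a [persistence_diagram()].
#' @param eps threshold in `[0, eps_max]`.
#' @return Named integer vector `beta0`, `beta1`, ...
#' @export
betti_numbers_at <- function(diag, eps) {
  stopifnot(inherits(diag, "phnet_diagram"))
  if (eps < 0 || eps > attr(diag, "eps_max"))
    stop("`eps` must lie in [0, ", attr(diag, "eps_max"), "]")
  dims <- 0:attr(diag, "max_dimension")
  b <- vapply(dims, function(p)
    sum(diag$dimension == p & diag$birth <= eps & diag$death > eps),
    integer(1))
  stats::setNames(b, paste0("beta", dims))
}

#' Split intervals into persistent features and noise
#'
#' Long bars are persistent topological features; short bars are noise. The
#' split is by bar length `death - birth >= min_length`; essential intervals
#' are always persistent.
#'
#' @param diag a [persistence_diagram()].
#' @param min_length non-negative length cutoff.
#' @return List with `persistent` and `noise` (both `phnet_diagram`s).
#' @export
classify_intervals <- function(diag, min_length) {
  stopifnot(inherits(diag, "phnet_diagram"))
  if (min_length < 0) stop("`min_length` must be >= 0")
  len <- diag$death - diag$birth
  keep <- !is.finite(diag$death) | len >= min_length
  mk <- function(rows, tag)
    persistence_diagram(as.data.frame(diag)[rows, , drop = FALSE],
                        max_dimension = attr(diag, "max_dimension"),
                        eps_max = attr(diag, "eps_max"),
                        provenance = paste(attr(diag, "provenance"), tag))
  list(persistent = mk(keep, "| persistent"), noise = mk(!keep, "| noise"))
}

# ---- brute-force oracle -----------------------------------------------------

gf2_rank <- function(M) {
  if (is.null(M) || !length(M) || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M != 0
  nr <- nrow(M)
  used <- logical(nr)
  r <- 0L
  for (j in seq_len(ncol(M))) {
    rows <- which(M[, j] & !used)
    if (!length(rows)) next
    p <- rows[1]
    used[p] <- TRUE
    r <- r + 1L
    others <- which(M[p, ])
    others <- others[others != j]
    if (length(others))
      M[, others] <- xor(M[, others, drop = FALSE], M[, j])
  }
  r
}

#' Brute-force persistence oracle
#'
#' Independent verification path for [persistent_homology()]: persistent
#' Betti numbers `beta_p(i, j)` are computed from GF(2) ranks of boundary
#' submatrices at every pair of distinct filtration values, and interval
#' multiplicities are recovered by the standard inclusion-exclusion over the
#' persistent Betti table. No reduction, no pairing -- only rank identities.
#' Restricted to small complexes (<= 2000 simplices).
#'
#' @inheritParams persistent_homology
#' @return A [persistence_diagram()].
#' @export
ph_oracle <- function(f, drop_top = TRUE) {
  stopifnot(inherits(f, "phnet_filtration"))
  m_total <- length(f$value)
  if (m_total > 2000)
    stop("oracle is restricted to <= 2000 simplices (got ", m_total, ")")
  if (m_total == 0)
    return(persistence_diagram(
      data.frame(dimension = integer(0), birth = numeric(0),
                 death = numeric(0)),
      max_dimension = 0L, eps_max = f$eps_max, provenance = "oracle empty"))

  V <- sort(unique(f$value))
  m <- length(V)
  top <- f$max_dimension
  dims_report <- if (drop_top && top >= 1) 0:(top - 1) else 0:top

  # index simplices by dimension, remember values
  by_dim <- lapply(0:top, function(p) which(f$dim == p))
  val_p <- lapply(by_dim, function(ix) f$value[ix])

  # boundary matrix D_p: rows = (p-1)-simplices, cols = p-simplices
  key <- vapply(f$vertices, function(v) paste(v, collapse = "-"), "")
  pos_in_dim <- integer(m_total)
  for (p in 0:top) pos_in_dim[by_dim[[p + 1]]] <- seq_along(by_dim[[p + 1]])
  D <- vector("list", top + 1)           # D[[p+1]] = boundary of p-simplices
  for (p in seq_len(top)) {
    rows <- by_dim[[p]]
    cols <- by_dim[[p + 1]]
    mat <- matrix(0L, length(rows), length(cols))
    if (length(cols)) {
      lut <- stats::setNames(seq_along(rows), key[rows])
      for (cc in seq_along(cols)) {
        v <- f$vertices[[cols[cc]]]
        for (kk in seq_along(v)) {
          fk <- paste(v[-kk], collapse = "-")
          mat[lut[[fk]], cc] <- 1L
        }
      }
    }
    D[[p + 1]] <- mat
  }

  # persistent Betti numbers: beta_p(i, j) for value indices 1..m (0 = empty)
  beta <- lapply(dims_report, function(p) matrix(0L, m, m))
  for (di in seq_along(dims_report)) {
    p <- dims_report[di]
    cv <- val_p[[p + 1]]                 # values of p-simplices
    dv <- if (p + 2 <= top + 1) val_p[[p + 2]] else numeric(0)
    Dp <- D[[p + 1]]                     # boundary of p-simplices (NULL p=0)
    Dq <- if (p + 2 <= top + 1) D[[p + 2]] else NULL
    rk_full <- vapply(seq_len(m), function(j) {
      if (is.null(Dq) || !any(dv <= V[j])) 0L
      else gf2_rank(Dq[, dv <= V[j], drop = FALSE])
    }, integer(1))
    for (i in seq_len(m)) {
      n_p <- sum(cv <= V[i])
      z_p <- if (p == 0) n_p else
        n_p - gf2_rank(Dp[, cv <= V[i], drop = FALSE])
      for (j in i:m) {
        b <- 0L
        if (!is.null(Dq) && any(dv <= V[j])) {
          sub <- Dq[cv > V[i], dv <= V[j], drop = FALSE]
          b <- rk_full[j] - gf2_rank(sub)
        }
        beta[[di]][i, j] <- z_p - b
      }
    }
  }

  # inclusion-exclusion over the persistent Betti table
  out <- list()
  for (di in seq_along(dims_report)) {
    p <- dims_report[di]
    B <- beta[[di]]
    g <- function(i, j) if (i < 1) 0L else B[i, j]
    for (i in seq_len(m)) {
      for (j in i:m) {
        if (j > i) {
          mult <- (g(i, j - 1) - g(i, j)) - (g(i - 1, j - 1) - g(i - 1, j))
          if (mult > 0)
            out[[length(out) + 1]] <-
              data.frame(dimension = p, birth = rep(V[i], mult),
                         death = V[j])
        }
      }
      ess <- g(i, m) - g(i - 1, m)
      if (ess > 0)
        out[[length(out) + 1]] <-
          data.frame(dimension = p, birth = rep(V[i], ess), death = Inf)
    }
  }
  iv <- if (length(out)) do.call(rbind, out) else
    data.frame(dimension = integer(0), birth = numeric(0),
               death = numeric(0))
  persistence_diagram(iv,
                      max_dimension = max(dims_report),
                      eps_max = f$eps_max,
                      provenance = sprintf("oracle n=%d", f$n_points))
}

# ---- diagram I/O ------------------------------------------------------------

#' Write / read a persistence diagram as delimited text
#'
#' CSV columns `dimension,birth,death` with the token `inf` for essential
#' classes; `# eps_max:` and `# max_dimension:` header lines make the reload
#' loss-free.
#'
#' @param diag a [persistence_diagram()].
#' @param path file path.
#' @return `path` invisibly (write); a [persistence_diagram()] (read).
#' @export
write_diagram <- function(diag, path) {
  stopifnot(inherits(diag, "phnet_diagram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# eps_max: %.17g", attr(diag, "eps_max")),
               sprintf("# max_dimension: %d", attr(diag, "max_dimension")),
               "dimension,birth,death"), con)
  if (nrow(diag))
    writeLines(sprintf("%d,%.17g,%s", diag$dimension, diag$birth,
                       ifelse(is.finite(diag$death),
                              sprintf("%.17g", diag$death), "inf")), con)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  eps_max <- as.numeric(sub("^#\\s*eps_max:\\s*", "",
                            grep("eps_max", hdr, value = TRUE)[1]))
  maxd <- as.integer(sub("^#\\s*max_dimension:\\s*", "",
                         grep("max_dimension", hdr, value = TRUE)[1]))
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         colClasses = c("integer", "numeric", "character"))
  tab$death <- ifelse(tab$death == "inf", Inf, as.numeric(tab$death))
  persistence_diagram(tab, max_dimension = maxd, eps_max = eps_max,
                      provenance = paste("read from", basename(path)))
}
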