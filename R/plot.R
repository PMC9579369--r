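# Barcode and persistence-diagram plots, one panel per homological
# dimension. Essential classes are drawn as arrows running to eps_max.

#' Barcode plot
#'
#' Horizontal bars, one per interval, grouped in one panel per dimension.
#' Long bars are persistent topological features, short bars noise;
#' essential classes get an arrowhead at `eps_max`.
#'
#' @param diag a [persistence_diagram()].
#' @param dims dimensions to draw (default: all present).
#' @param main title prefix.
#' @return `diag`, invisibly.
#' @export
plot_barcode <- function(diag, dims = NULL, main = "Barcode") {
  stopifnot(inherits(diag, "phnet_diagram"))
  eps_max <- attr(diag, "eps_max")
  if (is.null(dims)) dims <- 0:attr(diag, "max_dimension")
  old <- graphics::par(mfrow = c(length(dims), 1),
                       mar = c(3.2, 3.2, 2, 0.8), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(old))
  for (p in dims) {
    d <- as.data.frame(diag)
    d <- d[d$dimension == p, , drop = FALSE]
    d <- d[order(d$birth, d$death), , drop = FALSE]
    n <- max(1L, nrow(d))
    graphics::plot(NULL, xlim = c(0, eps_max), ylim = c(0.5, n + 0.5),
                   xlab = expression(epsilon), ylab = "",
                   yaxt = "n", main = sprintf("%s  Dim%d", main, p))
    if (nrow(d)) {
      y <- seq_len(nrow(d))
      fin <- is.finite(d$death)
      if (any(fin))
        graphics::segments(d$birth[fin], y[fin], d$death[fin], y[fin],
                           lwd = 2, col = "steelblue4")
      if (any(!fin))
        graphics::arrows(d$birth[!fin], y[!fin], eps_max, y[!fin],
                         lwd = 2, col = "firebrick", length = 0.08)
    }
  }
  invisible(diag)
}

#' Persistence-diagram plot
#'
#' Birth on the abscissa, death on the ordinate, the diagonal drawn for
#' reference: points far from the diagonal are persistent features, points
#' near it noise. Essential classes are drawn as upward triangles at
#' `eps_max`.
#'
#' @inheritParams plot_barcode
#' @return `diag`, invisibly.
#' @export
plot_diagram <- function(diag, dims = NULL, main = "Persistence diagram") {
  stopifnot(inherits(diag, "phnet_diagram"))
  eps_max <- attr(diag, "eps_max")
  if (is.null(dims)) dims <- 0:attr(diag, "max_dimension")
  cols <- c("steelblue4", "darkorange3", "forestgreen", "purple3")
  graphics::plot(NULL, xlim = c(0, eps_max), ylim = c(0, eps_max),
                 xlab = expression(epsilon[birth]),
                 ylab = expression(epsilon[death]), main = main, asp = 1)
  graphics::abline(0, 1, col = "grey60", lty = 2)
  for (k in seq_along(dims)) {
    p <- dims[k]
    d <- as.data.frame(diag)
    d <- d[d$dimension == p, , drop = FALSE]
    if (!nrow(d)) next
    fin <- is.finite(d$death)
    col <- cols[(k - 1) %% length(cols) + 1]
    if (any(fin))
      graphics::points(d$birth[fin], d$death[fin], pch = 19, col = col)
    if (any(!fin))
      graphics::points(d$birth[!fin], rep(eps_max, sum(!fin)),
                       pch = 24, bg = col, col = col)
  }
  graphics::legend("bottomright", legend = sprintf("Dim%d", dims),
                   col = cols[(seq_along(dims) - 1) %% length(cols) + 1],
                   pch = 19, bty = "n")
  invisible(diag)
}

save_plot <- function(path, expr, width = 7, height = 6) {
  if (grepl("\\.svg$", path)) grDevices::svg(path, width = width,
                                             height = height)
  else grDevices::png(path, width = width * 100, height = height * 100)
  on.exit(grDevices::dev.off())
  force(expr)
  invisible(path)
}
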