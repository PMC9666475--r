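.module_palette <- function(labels) {
  # conventional module colours: nurse cyan, intermediate black,
  # peripheral magenta, forager yellow
  base <- c(N = "cyan3", N1 = "cyan3", N2 = "cyan4", I = "grey20",
            P = "magenta3", F = "gold2")
  out <- base[labels]
  out[is.na(out)] <- grDevices::hcl.colors(max(1, sum(is.na(out))), "Dark 3")
  stats::setNames(out, labels)
}

#' Plot the planted landscape of a simulation nest
#'
#' @param x a `sim_nest`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sim_nest <- function(x, ...) {
  ctr <- site_centers(x$grid, seq_len(x$grid$n_base))
  pal <- .module_palette(x$labels)
  graphics::plot(ctr, col = pal[x$primary], pch = 15,
                 cex = 0.5, asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  graphics::legend("topleft", legend = x$labels, col = pal, pch = 15,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Map the primary module of each site
#'
#' @param x a `module_scores` object.
#' @param grid the `hex_grid` the scores refer to.
#' @param ... passed to [graphics::plot()].
#' @export
plot.module_scores <- function(x, grid, ...) {
  ids <- as.integer(rownames(x$sites))
  ctr <- site_centers(grid, ids)
  pm <- primary_module(x, "sites")
  pal <- .module_palette(x$labels)
  graphics::plot(ctr, col = pal[pm], pch = 15, cex = 0.5, asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  graphics::legend("topleft", legend = x$labels, col = pal[x$labels],
                   pch = 15, bty = "n", cex = 0.8)
  invisible(x)
}

#' Arrow map of a module gradient field
#'
#' @param x a `gradient_field`.
#' @param grid the `hex_grid`.
#' @param module module label (default first).
#' @param thin plot every `thin`-th site (default 4).
#' @param scale arrow length scale.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gradient_field <- function(x, grid, module = colnames(x$gx)[1],
                                thin = 4L, scale = NULL, ...) {
  ctr <- site_centers(grid, x$sites)
  keep <- which(x$defined[, module])
  keep <- keep[seq(1, length(keep), by = thin)]
  if (is.null(scale))
    scale <- 0.5 * grid$body_length / max(x$mag[keep, module])
  graphics::plot(ctr, col = "grey80", pch = ".", asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  graphics::arrows(ctr[keep, 1], ctr[keep, 2],
                   ctr[keep, 1] + scale * x$gx[keep, module],
                   ctr[keep, 2] + scale * x$gy[keep, module],
                   length = 0.02, col = "steelblue")
  invisible(x)
}
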