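#' @export
plot.pore_profile <- function(x, xlab = "z relative to pore center (A)",
                              ylab = "pore radius (A)", type = "l", ...) {
  plot(x$z, x$radius, type = type, xlab = xlab, ylab = ylab, ...)
  if (!is.null(x$sd_of_mean)) {
    ok <- is.finite(x$radius) & is.finite(x$sd_of_mean)
    polygon(c(x$z[ok], rev(x$z[ok])),
            c((x$radius + x$sd_of_mean)[ok], rev((x$radius - x$sd_of_mean)[ok])),
            border = NA, col = grey(0.5, 0.3))
  }
  invisible(x)
}

#' @export
plot.axial_profile <- function(x, xlab = "z relative to pore center (A)",
                               ylab = "waters per bin", type = "l", ...) {
  mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  plot(mid, x$mean, type = type, xlab = xlab, ylab = ylab, ...)
  polygon(c(mid, rev(mid)),
          c(x$mean + x$sd_of_mean, rev(x$mean - x$sd_of_mean)),
          border = NA, col = grey(0.5, 0.3))
  invisible(x)
}

#' @export
plot.hydropathy_profile <- function(x, xlab = "residue position",
                                    ylab = "hydropathy", type = "l", ...) {
  plot(x$positions, x$score, type = type, xlab = xlab, ylab = ylab, ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
plot.scalar_series <- function(x, xlab = "time (ns)", ylab = NULL, ...) {
  if (is.null(ylab)) ylab <- paste0(x$metric, " (", x$unit, ")")
  matplot(x$times, x$values, type = "l", lty = 1, xlab = xlab,
          ylab = ylab, ...)
  legend("topright", legend = x$subunit_ids, lty = 1,
         col = seq_along(x$subunit_ids), cex = 0.7, bty = "n")
  invisible(x)
}

#' @export
plot.shell_count_distribution <- function(x, xlab = "waters in shell",
                                          ylab = "frequency", ...) {
  barplot(x$frequency, names.arg = names(x$frequency), xlab = xlab,
          ylab = ylab, ...)
  invisible(x)
}

#' @export
plot.descriptor_series <- function(x, xlab = NULL, ylab = "frequency",
                                   type = "h", ...) {
  if (is.null(xlab)) xlab <- paste0(x$metric, " (", x$unit, ")")
  plot(x$histogram$mids, x$histogram$density, type = type, xlab = xlab,
       ylab = ylab, ...)
  invisible(x)
}
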