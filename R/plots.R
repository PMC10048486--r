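#' @export
plot.dva_curve <- function(x, which = c("variance", "Q"), ...) {
  which <- match.arg(which)
  if (which == "variance") {
    plot(x$lags, x$variance, log = "xy", xlab = "lag (s)",
         ylab = "differential variance (counts^2)", ...)
    if (is.finite(x$plateau)) abline(h = x$plateau, lty = 2)
  } else {
    plot(x$lags, x$q_values, log = "x", xlab = "lag (s)",
         ylab = "Q(t, lag)", ylim = c(-0.05, 1.05), ...)
  }
  invisible(x)
}

#' @export
plot.isf_curve <- function(x, ...) {
  plot(x$lags, x$f_values, log = "x", xlab = "lag (s)",
       ylab = sprintf("f(q = %.3g 1/um, lag)", x$q),
       ylim = c(-0.1, 1.1), ...)
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$lags, x$msd, log = "xy", xlab = "lag (s)", ylab = "MSD (um^2)", ...)
  # guide lines: normal diffusion (slope 1) and strong subdiffusion (1/3)
  lm0 <- median(x$msd) / median(x$lags)
  lines(range(x$lags), lm0 * range(x$lags), lty = 3)
  invisible(x)
}

#' @export
plot.mobility_curve <- function(x, ...) {
  plot(x$elapsed_times, x$values, type = "b", xlab = "elapsed time (min)",
       ylab = sprintf("normalized mobility (lag %.3g s)", x$lag),
       ylim = c(0, max(1, x$values)), ...)
  invisible(x)
}

#' Displacement-magnitude heat map of one PIV frame pair
#'
#' Renders the block displacement magnitudes (um) of one analysed pair as a
#' filled image -- the quantitative counterpart of a PIV mobility heat map
#' (brightness = displacement before any colormapping).
#'
#' @param x a \code{"piv_fields"}.
#' @param pair index of the frame pair to draw.
#' @param ... passed to \code{image}.
#' @export
plot.piv_fields <- function(x, pair = 1L, ...) {
  f <- x$fields[[pair]]
  xs <- sort(unique(f$block_x)); ys <- sort(unique(f$block_y))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(f$block_x, xs), match(f$block_y, ys))] <-
    sqrt(f$u_px^2 + f$v_px^2) * x$pixel_size
  graphics::image(xs, ys, z, xlab = "x (px)", ylab = "y (px)", ...)
  invisible(x)
}

#' @export
plot.rheo_trace <- function(x, omega = NULL, ...) {
  omega <- omega %||% min(x$omega_per_s)
  sub <- x[abs(x$omega_per_s - omega) < 1e-12, ]
  sub <- sub[sub$g_prime_pa > 0 & sub$g_double_prime_pa > 0 & sub$t_min > 0, ]
  matplot(sub$t_min, cbind(sub$g_prime_pa, sub$g_double_prime_pa),
          log = "y", type = "l", lty = 1:2, col = 1,
          xlab = "elapsed time (min)", ylab = "modulus (Pa)", ...)
  legend("bottomright", c("G'", "G''"), lty = 1:2, bty = "n")
  invisible(x)
}
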