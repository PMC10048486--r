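#' Loss tangent of a rheology trace
#'
#' Populates \eqn{\tan\delta = G''/G'} elementwise.  Cells with a missing
#' modulus stay missing; nonpositive moduli are a domain error reporting
#' the offending (t, omega) cells.
#'
#' @param trace a \code{"rheo_trace"} (long data.frame with columns
#'   \code{t_min}, \code{omega_per_s}, \code{g_prime_pa},
#'   \code{g_double_prime_pa}).
#' @return the trace with a \code{tan_delta} column.
#' @export
loss_tangent <- function(trace) {
  .assert(all(c("t_min", "omega_per_s", "g_prime_pa", "g_double_prime_pa")
              %in% names(trace)), "not a rheology trace")
  gp <- trace$g_prime_pa; gpp <- trace$g_double_prime_pa
  present <- !is.na(gp) & !is.na(gpp)
  bad <- present & (gp <= 0 | gpp <= 0)
  if (any(bad)) {
    cells <- paste(sprintf("(t=%g, w=%g)", trace$t_min[bad],
                           trace$omega_per_s[bad])[seq_len(min(5, sum(bad)))],
                   collapse = " ")
    stop(sprintf("loss_tangent: nonpositive modulus at %d cell(s): %s%s",
                 sum(bad), cells, if (sum(bad) > 5) " ..." else ""),
         call. = FALSE)
  }
  trace$tan_delta <- ifelse(present, gpp / gp, NA_real_)
  trace
}

#' Winter-Chambon gel-point detection
#'
#' Finds the critical gelation time as the time at which the loss tangent
#' becomes independent of frequency: per time point the coefficient of
#' variation (sd/mean) of \eqn{\tan\delta} across frequencies is computed,
#' and the gel point is the dispersion minimum.  When the minimum is
#' strictly positive and interior it is refined by parabolic interpolation
#' between grid points (experimental grids can be coarse); an exact zero on
#' the grid is returned as-is.  A shallow minimum -- dispersion that never
#' really collapses -- yields a no-gel warning flag rather than a
#' confidently wrong time.
#'
#' @param trace a \code{"rheo_trace"}; the loss tangent is computed on the
#'   fly if absent.
#' @param shallow_fraction the minimum is flagged shallow unless it is
#'   below \code{shallow_fraction} times the median dispersion.
#' @return an object of class \code{"gel_point_result"}: \code{tc} (min),
#'   \code{tan_delta_at_tc} (averaged over frequencies),
#'   \code{dispersion_at_tc}, \code{shallow}, \code{method}.
#' @export
detect_gel_point_winter <- function(trace, shallow_fraction = 0.5) {
  if (is.null(trace$tan_delta)) trace <- loss_tangent(trace)
  times <- sort(unique(trace$t_min))
  omegas <- sort(unique(trace$omega_per_s))
  if (length(omegas) < 2L)
    stop(paste0("detect_gel_point_winter: a single-frequency trace cannot ",
                "show frequency independence; use the mobility-curve ",
                "changepoint instead"), call. = FALSE)
  .assert(length(times) >= 4L, "need >= 4 time points")

  td <- matrix(NA_real_, length(times), length(omegas))
  for (j in seq_along(omegas)) {
    sub <- trace[trace$omega_per_s == omegas[j], ]
    td[match(sub$t_min, times), j] <- sub$tan_delta
  }
  m <- rowMeans(td)
  cv <- apply(td, 1, sd) / m
  ok <- is.finite(cv)
  i <- which(ok)[which.min(cv[ok])]

  tc <- times[i]; cv_tc <- cv[i]; td_tc <- m[i]
  if (cv[i] > 1e-12 && i > 1L && i < length(times) &&
      is.finite(cv[i - 1L]) && is.finite(cv[i + 1L])) {
    den <- cv[i - 1L] - 2 * cv[i] + cv[i + 1L]
    if (den > 1e-15) {
      # parabolic vertex on a (possibly non-uniform) local grid
      x <- times[(i - 1L):(i + 1L)]; y <- cv[(i - 1L):(i + 1L)]
      p <- lm(y ~ poly(x, 2, raw = TRUE))
      cf <- coef(p)
      if (is.finite(cf[3]) && cf[3] > 0) {
        v <- -cf[2] / (2 * cf[3])
        if (v >= x[1] && v <= x[3]) {
          tc <- v
          cv_tc <- max(unname(cf[1] + cf[2] * v + cf[3] * v^2), 0)
          td_tc <- stats::approx(times, m, xout = v)$y
        }
      }
    }
  }
  shallow <- cv_tc > shallow_fraction * median(cv[ok])
  if (shallow)
    warning("detect_gel_point_winter: dispersion minimum is shallow; no clear gel point (tan-delta curves may never intersect)")
  structure(list(tc = tc, tan_delta_at_tc = td_tc,
                 dispersion_at_tc = cv_tc, shallow = shallow,
                 method = "winter_chambon"),
            class = "gel_point_result")
}

#' Externally supplied gel point (e.g. a pH-threshold time)
#'
#' Wraps a gel time obtained outside the trace (such as the time at which
#' the pH crossed a gelation threshold) in the same result container, so
#' reports can carry either detection method.
#'
#' @param tc gel time, min.
#' @param trace optional trace used to read off \eqn{\tan\delta} at tc.
#' @return a \code{"gel_point_result"} with method
#'   \code{"ph_threshold_external"}.
#' @export
gel_point_external <- function(tc, trace = NULL) {
  td <- NA_real_
  if (!is.null(trace)) {
    if (is.null(trace$tan_delta)) trace <- loss_tangent(trace)
    times <- sort(unique(trace$t_min))
    m <- vapply(times, function(t)
      mean(trace$tan_delta[trace$t_min == t], na.rm = TRUE), 0)
    td <- stats::approx(times, m, xout = tc, rule = 2)$y
  }
  structure(list(tc = tc, tan_delta_at_tc = td,
                 dispersion_at_tc = NA_real_, shallow = NA,
                 method = "ph_threshold_external"),
            class = "gel_point_result")
}

#' @export
print.gel_point_result <- function(x, ...) {
  cat(sprintf("<gel_point_result> tc = %.4g min, tan(delta) = %.4g (dispersion %.3g)%s [%s]\n",
              x$tc, x$tan_delta_at_tc, x$dispersion_at_tc,
              if (isTRUE(x$shallow)) " SHALLOW" else "", x$method))
  invisible(x)
}

#' Aging power laws of a gel
#'
#' Fits power laws of elapsed time to \eqn{G'}, \eqn{G''} and
#' \eqn{\tan\delta} over the post-peak aging window at one frequency.  The
#' window defaults to everything from the \eqn{G'} maximum onward; a window
#' reaching into the growth stage (before that maximum) is an error, since
#' a power law has no meaning there.  For exact power-law moduli the
#' \eqn{\tan\delta} exponent equals the difference of the two moduli
#' exponents.
#'
#' @param trace a \code{"rheo_trace"}.
#' @param window optional length-2 time window, min.
#' @param omega frequency to analyse (default: the lowest in the trace).
#' @return list of three \code{"power_law_fit"} objects
#'   (\code{storage}, \code{loss}, \code{tan_delta}) plus \code{omega} and
#'   \code{window}.
#' @export
aging_power_laws <- function(trace, window = NULL, omega = NULL) {
  if (is.null(trace$tan_delta)) trace <- loss_tangent(trace)
  omega <- omega %||% min(trace$omega_per_s)
  sub <- trace[abs(trace$omega_per_s - omega) < 1e-12 &
                 complete.cases(trace[c("g_prime_pa", "g_double_prime_pa")]), ]
  .assert(nrow(sub) >= 3L, "no (or too few) rows at the requested frequency")
  sub <- sub[order(sub$t_min), ]
  t_max <- sub$t_min[which.max(sub$g_prime_pa)]
  if (is.null(window)) window <- c(t_max, max(sub$t_min))
  if (window[1] < t_max - 1e-9)
    stop(sprintf("aging_power_laws: window starts at %g min but G' still grows until %g min; the aging fit must start at/after the modulus maximum",
                 window[1], t_max), call. = FALSE)
  keep <- sub$t_min >= window[1] & sub$t_min <= window[2] & sub$t_min > 0
  .assert(sum(keep) >= 2L, "aging window contains fewer than 2 usable points")
  x <- sub$t_min[keep]
  list(storage = fit_power_law(x, sub$g_prime_pa[keep]),
       loss = fit_power_law(x, sub$g_double_prime_pa[keep]),
       tan_delta = fit_power_law(x, sub$tan_delta[keep]),
       omega = omega, window = window)
}
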