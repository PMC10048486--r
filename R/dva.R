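#' Differential variance analysis of an image stack
#'
#' For each lag \eqn{\Delta t}, forms all overlapping frame differences
#' \eqn{\Delta I = I(t+\Delta t) - I(t)} and records the mean over start
#' frames of the per-difference pixel variance -- the DVA curve
#' \eqn{I(t, \Delta t)}.  For freely relaxing samples the curve grows from 0
#' and saturates at a plateau once probes have moved further than the
#' optical correlation length; the plateau normalises the dynamic order
#' parameter (\code{\link{order_parameter}}).
#'
#' Maximal (overlapping) pair averaging is used and the number of pairs per
#' lag is reported: variance estimates at long lags are limited by ensemble
#' size, and \code{n_pairs} is the observability handle for that artifact.
#'
#' The plateau is estimated as the mean of the variance over the top
#' half-decade of lags, accepted only when the local log-log slope there is
#' below \code{plateau_slope_tol} (default 0.05 per decade); otherwise the
#' plateau is recorded as \code{NA} and \code{\link{order_parameter}} raises
#' a diagnostic error.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param lags lag times in s (integer multiples of the frame interval).
#'   Default: 20 log-spaced lags from the frame interval to a quarter of the
#'   movie duration.
#' @param max_pairs cap on start frames per lag (default all overlapping).
#' @param plateau_slope_tol plateau acceptance threshold, per decade.
#' @return an object of class \code{"dva_curve"}: \code{lags},
#'   \code{variance}, \code{n_pairs}, \code{plateau}, \code{q_values}
#'   (NA until \code{\link{order_parameter}}), \code{elapsed_time}.
#' @export
differential_variance_curve <- function(stack, lags = NULL, max_pairs = Inf,
                                        plateau_slope_tol = 0.05) {
  .assert(inherits(stack, "image_stack"), "'stack' must be an image_stack")
  d <- dim(stack$frames)
  nf <- d[1]
  if (is.null(lags)) lags <- .lag_grid(nf, stack$frame_interval)
  ks <- .lags_to_frames(lags, stack$frame_interval, nf)

  variance <- numeric(length(ks))
  n_pairs <- integer(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    starts <- seq_len(nf - k)
    if (is.finite(max_pairs) && length(starts) > max_pairs)
      starts <- unique(round(seq(1, nf - k, length.out = max_pairs)))
    v <- vapply(starts, function(t0) {
      di <- stack$frames[t0 + k, , ] - stack$frames[t0, , ]
      v0 <- var(as.vector(di))
      v0
    }, 0)
    variance[i] <- mean(v)
    n_pairs[i] <- length(starts)
  }
  lag_s <- ks * stack$frame_interval
  plateau <- .dva_plateau(lag_s, variance, plateau_slope_tol)
  structure(list(lags = lag_s, variance = variance, n_pairs = n_pairs,
                 plateau = plateau$value, plateau_slope = plateau$slope,
                 q_values = rep(NA_real_, length(lag_s)),
                 elapsed_time = stack$elapsed_time),
            class = "dva_curve")
}

# Plateau over the top half-decade of lags; NA when the local slope is too
# steep (curve still rising: insufficient lag range / ensemble averaging).
.dva_plateau <- function(lags, values, slope_tol) {
  win <- lags >= max(lags) / sqrt(10)
  if (sum(win) < 2L) win[length(lags)] <- TRUE
  v <- values[win]; l <- lags[win]
  if (any(v <= 0)) return(list(value = NA_real_, slope = NA_real_))
  slope <- if (length(unique(l)) >= 2L)
    unname(coef(lm(log10(v) ~ log10(l)))[2]) else 0
  if (!is.finite(slope) || abs(slope) >= slope_tol)
    return(list(value = NA_real_, slope = slope))
  list(value = mean(v), slope = slope)
}

#' Dynamic order parameter of a DVA curve
#'
#' Populates \eqn{Q(\Delta t) = 1 - I(\Delta t) / I_\infty}, the DVA dynamic
#' order parameter: 1 when nothing has moved, decaying toward 0 as the probe
#' configuration decorrelates.  Requires an accepted plateau \eqn{I_\infty};
#' when the variance curve never flattened (the long-lag ensemble artifact),
#' this raises an error carrying the measured residual slope.
#'
#' @param curve a \code{"dva_curve"} from
#'   \code{\link{differential_variance_curve}}, or a list with fields
#'   \code{lags}, \code{variance} and optionally \code{plateau}.
#' @param plateau optional explicit plateau override, counts^2.
#' @return the curve with \code{q_values} populated.
#' @export
order_parameter <- function(curve, plateau = NULL) {
  .assert(!is.null(curve$lags) && !is.null(curve$variance),
          "'curve' must carry lags and variance")
  plateau <- plateau %||% curve$plateau
  if (is.null(plateau) || !is.finite(plateau) || plateau <= 0)
    stop(sprintf(paste0(
      "order_parameter: plateau not estimable (residual log-log slope %s ",
      "per decade over the top half-decade of lags); the variance curve has ",
      "not relaxed -- extend the lag range or the ensemble averaging"),
      format(signif(curve$plateau_slope %||% NA_real_, 3))), call. = FALSE)
  curve$plateau <- plateau
  curve$q_values <- 1 - curve$variance / plateau
  if (!inherits(curve, "dva_curve")) class(curve) <- c("dva_curve", class(curve))
  curve
}

#' @export
print.dva_curve <- function(x, ...) {
  cat(sprintf("<dva_curve> %d lags (%.3g..%.3g s), plateau %s, t = %s min\n",
              length(x$lags), min(x$lags), max(x$lags),
              format(signif(x$plateau, 4)), format(x$elapsed_time)))
  invisible(x)
}

#' @export
as.data.frame.dva_curve <- function(x, ...) {
  data.frame(elapsed_min = x$elapsed_time, lag_s = x$lags,
             variance = x$variance, n_pairs = x$n_pairs,
             plateau = x$plateau, Q = x$q_values)
}
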