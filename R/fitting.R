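#' Fit a stretched-exponential relaxation
#'
#' Nonlinear least squares of \eqn{\exp[-(\Delta t/\tau)^\beta]} to a
#' relaxation curve (a DVA order parameter or an intermediate scattering
#' function).  A deterministic multi-start strategy is used: every
#' combination of a decade grid of \eqn{\tau} values spanning the lag range
#' and \eqn{\beta \in \{0.5, 1, 1.5\}} seeds a bounded Levenberg-Marquardt
#' fit, and the lowest-residual convergent fit wins.  \eqn{\beta} is bounded
#' to [0.2, 2]: lower values are degenerate on a short movie and higher ones
#' are compressed-exponential territory outside this package's scope.
#'
#' @param lags lag times, s.
#' @param values relaxation values (expected within [-0.2, 1.2]).
#' @param weights optional least-squares weights (e.g. per-lag pair counts).
#' @return an object of class \code{"relaxation_fit"}: fields \code{tau} (s),
#'   \code{beta}, \code{residual_rms}, \code{n_points}, \code{converged},
#'   \code{boundary} (TRUE when tau ended on the search boundary) and
#'   \code{diffusion_coefficient} (NA until filled by a q-aware caller via
#'   \eqn{D = 1/(\tau q^2)}).
#' @examples
#' lags <- exp(seq(log(0.01), log(10), length.out = 25))
#' fit_stretched_exponential(lags, exp(-(lags / 2)))
#' @export
fit_stretched_exponential <- function(lags, values, weights = NULL) {
  .assert(is.numeric(lags) && is.numeric(values) &&
            length(lags) == length(values), "lags/values length mismatch")
  keep <- is.finite(lags) & is.finite(values)
  lags <- lags[keep]; values <- values[keep]
  if (!is.null(weights)) weights <- weights[keep]
  .assert(length(lags) >= 5L, "fit_stretched_exponential needs >= 5 points")
  .assert(all(lags > 0), "lags must be > 0")
  if (any(values < -0.2 - 1e-9) || any(values > 1.2 + 1e-9))
    stop("relaxation values outside [-0.2, 1.2]; not a normalized curve",
         call. = FALSE)

  tau_lo <- min(lags) / 100; tau_hi <- max(lags) * 100
  tau_grid <- 10^seq(ceiling(log10(min(lags))) - 1,
                     floor(log10(max(lags))) + 1, by = 1)
  tau_grid <- unique(c(tau_grid, sqrt(min(lags) * max(lags))))
  dat <- data.frame(x = lags, y = values)
  w <- weights %||% rep(1, length(lags))

  best <- NULL
  for (t0 in tau_grid) for (b0 in c(0.5, 1, 1.5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ exp(-(x / tau)^beta), data = dat,
                        start = list(tau = t0, beta = b0),
                        lower = c(tau_lo, 0.2), upper = c(tau_hi, 2),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(w * residuals(fit)^2)
    if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
  }
  if (is.null(best))
    stop(sprintf("stretched-exponential fit failed to converge from all %d starts (n = %d, value range %.3g..%.3g)",
                 3L * length(tau_grid), length(lags), min(values), max(values)),
         call. = FALSE)
  cf <- coef(best$fit)
  boundary <- cf[["tau"]] <= tau_lo * 1.0001 || cf[["tau"]] >= tau_hi * 0.9999
  if (boundary)
    warning("fitted tau lies on the search boundary; treat with caution")
  structure(list(tau = unname(cf[["tau"]]), beta = unname(cf[["beta"]]),
                 diffusion_coefficient = NA_real_,
                 residual_rms = sqrt(mean(residuals(best$fit)^2)),
                 n_points = length(lags),
                 converged = TRUE, boundary = boundary),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("<relaxation_fit> tau = %.4g s, beta = %.3f (rms %.2e, n = %d%s)\n",
              x$tau, x$beta, x$residual_rms, x$n_points,
              if (x$boundary) ", BOUNDARY" else ""))
  invisible(x)
}

#' Fit a power law by least squares in log-log space
#'
#' @param x abscissa (must be > 0 within the window).
#' @param y ordinate (must be > 0 within the window).
#' @param window length-2 range of \code{x} to fit over (default: all).
#' @return an object of class \code{"power_law_fit"}: \code{exponent},
#'   \code{prefactor}, \code{window}, \code{r_squared}, \code{n_points}.
#' @export
fit_power_law <- function(x, y, window = range(x)) {
  .assert(length(x) == length(y), "x/y length mismatch")
  keep <- is.finite(x) & is.finite(y) & x >= window[1] & x <= window[2]
  .assert(sum(keep) >= 2L, "power-law window contains fewer than 2 points")
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0) || any(y <= 0))
    stop("fit_power_law: nonpositive values inside the window", call. = FALSE)
  fit <- lm(ly ~ lx, data = data.frame(lx = log(x), ly = log(y)))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((log(y) - mean(log(y)))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(exponent = unname(coef(fit)[2]),
                 prefactor = exp(unname(coef(fit)[1])),
                 window = window, r_squared = r2, n_points = length(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g (r2 = %.4f, n = %d)\n",
              x$prefactor, x$exponent, x$r_squared, x$n_points))
  invisible(x)
}

#' Microscopic viscosity from a probe relaxation time
#'
#' Inverts the relaxation-time relation \eqn{\tau = 6\pi\eta R^3 / (k_B T)}
#' (the time for a probe of radius R to diffuse a distance comparable to its
#' own size) to the microscopic viscosity
#' \eqn{\eta_\tau = k_B T \tau / (6\pi R^3)}.  The constant is applied
#' verbatim and lives in a single site; note that a relaxation time read off
#' a wavevector-resolved decay at \eqn{q = 2\pi/R} is \eqn{(2\pi)^2} shorter
#' than this definition, so viscosities from the two routes differ by that
#' fixed convention factor (see the methods vignette).
#'
#' @param fit a \code{"relaxation_fit"}, or a bare relaxation time in s.
#' @param probe_radius probe radius R, um.
#' @param temperature temperature T, K.
#' @param method label recording which stage produced tau ("dva" or "ddm").
#' @return an object of class \code{"viscosity_estimate"} with \code{eta} in
#'   mPa s.
#' @examples
#' tau <- 6 * pi * 1e-3 * (0.57e-6)^3 / (1.380649e-23 * 298.15)
#' microscopic_viscosity(tau, 0.57, 298.15)$eta  # exactly 1 mPa s
#' @export
microscopic_viscosity <- function(fit, probe_radius, temperature = 298.15,
                                  method = c("dva", "ddm")) {
  method <- match.arg(method)
  .assert(.is_pos(probe_radius), "'probe_radius' must be > 0")
  .assert(.is_pos(temperature), "'temperature' must be > 0")
  if (inherits(fit, "relaxation_fit")) {
    if (!isTRUE(fit$converged))
      stop("microscopic_viscosity: relaxation fit did not converge",
           call. = FALSE)
    tau <- fit$tau
  } else {
    .assert(.is_pos(fit), "'fit' must be a relaxation_fit or a positive tau")
    tau <- fit
  }
  # eta [Pa s] = kB T tau / (6 pi R^3); R in m; reported in mPa s
  eta_pa_s <- .kB * temperature * tau / (6 * pi * (probe_radius * 1e-6)^3)
  structure(list(eta = eta_pa_s * 1e3, tau = tau,
                 probe_radius = probe_radius, temperature = temperature,
                 method = method),
            class = "viscosity_estimate")
}

#' @export
print.viscosity_estimate <- function(x, ...) {
  cat(sprintf("<viscosity_estimate> eta = %.4g mPa s (tau = %.4g s, R = %.3g um, T = %.5g K, %s)\n",
              x$eta, x$tau, x$probe_radius, x$temperature, x$method))
  invisible(x)
}

#' Detect an abrupt-decay changepoint in a short curve
#'
#' Fits a continuous two-segment piecewise-linear model (hinge regression)
#' to y(x), scanning candidate knees over the interior sample positions and
#' refining each bracket continuously.  Suited to curves with only a handful
#' of points, such as a per-movie mobility curve over a gelation run.
#'
#' @param x abscissa (e.g. elapsed times, min), or a
#'   \code{"mobility_curve"} (then \code{y} is ignored).
#' @param y ordinate.
#' @return an object of class \code{"changepoint_fit"}: \code{changepoint}
#'   (x units), \code{slope_before}, \code{slope_after}, \code{sse},
#'   \code{degenerate} (TRUE when a single line already explains the data,
#'   i.e. no abrupt decay).
#' @export
detect_changepoint <- function(x, y = NULL) {
  if (inherits(x, "mobility_curve")) {
    y <- x$values; x <- x$elapsed_times
  }
  .assert(length(x) == length(y), "x/y length mismatch")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  .assert(n >= 4L, "detect_changepoint needs >= 4 points")
  o <- order(x); x <- x[o]; y <- y[o]

  hinge_sse <- function(k) {
    X <- cbind(1, x, pmax(0, x - k))
    f <- lm.fit(X, y)
    sum(f$residuals^2)
  }
  # scan interior data positions, then refine continuously in the best bracket
  cand <- x[2:(n - 1L)]
  sses <- vapply(cand, hinge_sse, 0)
  i <- which.min(sses)
  lo <- if (i == 1L) x[1] else cand[i - 1L]
  hi <- if (i == length(cand)) x[n] else cand[i + 1L]
  opt <- optimize(hinge_sse, c(lo, hi))
  k <- if (opt$objective < sses[i]) opt$minimum else cand[i]
  sse2 <- min(opt$objective, sses[i])
  X <- cbind(1, x, pmax(0, x - k))
  cf <- lm.fit(X, y)$coefficients
  fit1 <- lm.fit(cbind(1, x), y)
  sse1 <- sum(fit1$residuals^2)
  scale <- sum((y - mean(y))^2)
  degenerate <- sse1 <= max(1e-20, 1e-10 * scale) ||
    (scale > 0 && (sse1 - sse2) / scale < 1e-3)
  structure(list(changepoint = k,
                 slope_before = unname(cf[2]),
                 slope_after = unname(cf[2] + cf[3]),
                 sse = sse2, sse_single = sse1,
                 degenerate = degenerate),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf("<changepoint_fit> knee at %.4g (slopes %.4g -> %.4g)%s\n",
              x$changepoint, x$slope_before, x$slope_after,
              if (x$degenerate) " [degenerate: no abrupt decay]" else ""))
  invisible(x)
}
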