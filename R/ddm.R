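#' Image structure function (differential dynamic microscopy)
#'
#' Computes \eqn{D(q, \Delta t) = \langle |FFT(\Delta I)|^2 \rangle_t /
#' N_{px}}, the azimuthally averaged power spectrum of frame differences.
#' The transform convention is fixed and recorded: forward DFT unscaled,
#' power divided by the pixel count, so that a difference image of i.i.d.
#' noise with per-pixel variance \eqn{v} gives \eqn{D = v} at every q
#' (and the Parseval identity reads
#' \eqn{\sum_q |FFT(\Delta I)|^2 / N_{px} = \sum_{px} \Delta I^2}).
#'
#' Frame FFTs are computed once and cached; for each lag the difference
#' spectrum uses the linearity of the DFT,
#' \eqn{FFT(\Delta I) = F(t+\Delta t) - F(t)}.  Radial bins are annuli one
#' q-spacing \eqn{2\pi/(L\,\mathrm{pixel\_size})} wide; the DC term is
#' excluded and partial annuli beyond the Nyquist circle are dropped.
#'
#' @param stack an \code{\link{image_stack}} with square frames (crop with
#'   \code{\link{crop_roi}} first otherwise).
#' @param lags lag times in s; default 20 log-spaced lags up to a quarter of
#'   the movie duration.
#' @param max_pairs cap on start frames averaged per lag (default 100,
#'   evenly spaced).
#' @param parseval also record, per lag, the summed unbinned spectrum and
#'   the pixel-domain sum of \eqn{\Delta I^2} (for consistency checks).
#' @return an object of class \code{"structure_function"}: \code{q_bins}
#'   (um^-1, bin centres), \code{lags} (s), \code{values} (n_q x n_lag,
#'   counts^2), \code{n_pairs}, \code{normalization}, \code{elapsed_time};
#'   \code{amplitude_A}, \code{noise_floor_B} and \code{usable} are NA until
#'   \code{\link{estimate_noise_and_amplitude}}.
#' @export
structure_function <- function(stack, lags = NULL, max_pairs = 100L,
                               parseval = FALSE) {
  .assert(inherits(stack, "image_stack"), "'stack' must be an image_stack")
  d <- dim(stack$frames)
  nf <- d[1]
  if (d[2] != d[3])
    stop(sprintf("structure_function: frames are %dx%d but must be square; crop_roi() first",
                 d[2], d[3]), call. = FALSE)
  L <- d[2]
  if (is.null(lags)) lags <- .lag_grid(nf, stack$frame_interval)
  ks <- .lags_to_frames(lags, stack$frame_interval, nf)

  dq <- 2 * pi / (L * stack$pixel_size)
  # radial bin index of each DFT cell (0 = DC, dropped; > L/2 dropped)
  f1d <- c(0:(L %/% 2), -((L - L %/% 2 - 1):1))
  if (L %% 2 == 0) f1d <- c(0:(L %/% 2 - 1), -(L %/% 2), -((L %/% 2 - 1):1))
  fx <- matrix(f1d, L, L, byrow = TRUE)
  fy <- matrix(f1d, L, L, byrow = FALSE)
  bin <- as.integer(round(sqrt(fx^2 + fy^2)))
  nq <- L %/% 2
  keep <- bin >= 1L & bin <= nq
  binv <- bin[keep]
  counts <- tabulate(binv, nbins = nq)

  # which frames are needed; FFT each once
  starts_by_lag <- lapply(ks, function(k) {
    s <- seq_len(nf - k)
    if (is.finite(max_pairs) && length(s) > max_pairs)
      s <- unique(round(seq(1, nf - k, length.out = max_pairs)))
    s
  })
  needed <- sort(unique(unlist(lapply(seq_along(ks), function(i)
    c(starts_by_lag[[i]], starts_by_lag[[i]] + ks[i])))))
  cache <- vector("list", nf)
  for (t in needed) cache[[t]] <- fft(stack$frames[t, , ])

  npix <- L * L
  values <- matrix(0, nq, length(ks))
  n_pairs <- integer(length(ks))
  pv <- if (parseval)
    data.frame(lag_s = ks * stack$frame_interval, spectral_sum = 0,
               pixel_sum = 0) else NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    starts <- starts_by_lag[[i]]
    acc <- numeric(sum(keep))
    sp_sum <- 0; px_sum <- 0
    for (t0 in starts) {
      dP <- cache[[t0 + k]] - cache[[t0]]
      pw <- Re(dP * Conj(dP))
      acc <- acc + pw[keep]
      if (parseval) {
        sp_sum <- sp_sum + sum(pw)
        di <- stack$frames[t0 + k, , ] - stack$frames[t0, , ]
        px_sum <- px_sum + sum(di * di)
      }
    }
    acc <- acc / length(starts)
    values[, i] <- as.vector(rowsum(acc, binv)) / counts / npix
    n_pairs[i] <- length(starts)
    if (parseval) {
      pv$spectral_sum[i] <- sp_sum / length(starts) / npix
      pv$pixel_sum[i] <- px_sum / length(starts)
    }
  }
  structure(list(q_bins = dq * seq_len(nq), lags = ks * stack$frame_interval,
                 values = values, n_pairs = n_pairs,
                 amplitude_A = rep(NA_real_, nq),
                 noise_floor_B = NA_real_,
                 usable = rep(NA, nq),
                 normalization = "forward DFT unscaled; power / n_pixels",
                 pixel_size = stack$pixel_size,
                 elapsed_time = stack$elapsed_time,
                 parseval = pv),
            class = "structure_function")
}

#' @export
print.structure_function <- function(x, ...) {
  cat(sprintf("<structure_function> %d q-bins (%.3g..%.3g um^-1) x %d lags (%.3g..%.3g s), t = %s min\n",
              length(x$q_bins), min(x$q_bins), max(x$q_bins),
              length(x$lags), min(x$lags), max(x$lags),
              format(x$elapsed_time)))
  if (is.finite(x$noise_floor_B))
    cat(sprintf("  B = %.4g counts^2; %d/%d q-bins usable\n",
                x$noise_floor_B, sum(x$usable, na.rm = TRUE),
                length(x$usable)))
  invisible(x)
}

#' Estimate the noise floor B and amplitude A(q) of a structure function
#'
#' The decorrelated camera-noise floor is taken as a single scalar
#' \eqn{B}: the median of \eqn{D(q, \Delta t_{min})} over the top 10\% of
#' wavevectors at the smallest lag, where (for adequately band-limited
#' optics) no sample signal survives.  \eqn{A(q)} is the per-q plateau of
#' \eqn{D} over the top half-decade of lags minus \eqn{B}, floored at 0; a
#' q-bin is marked unusable when its plateau has not flattened (local
#' log-log slope >= \code{plateau_slope_tol} per decade) -- the same
#' long-lag ensemble caveat as in DVA, made explicit rather than silently
#' extrapolated.
#'
#' @param sf a \code{"structure_function"}.
#' @param plateau_slope_tol per-decade slope acceptance threshold.
#' @param top_q_fraction fraction of the q-range treated as noise-only.
#' @return \code{sf} with \code{noise_floor_B}, \code{amplitude_A} and
#'   \code{usable} populated.
#' @export
estimate_noise_and_amplitude <- function(sf, plateau_slope_tol = 0.05,
                                         top_q_fraction = 0.1) {
  .assert(inherits(sf, "structure_function"),
          "'sf' must be a structure_function")
  .assert(length(sf$lags) >= 3L, "need >= 3 lags to separate A and B")
  qtop <- sf$q_bins >= (1 - top_q_fraction) * max(sf$q_bins)
  B <- median(sf$values[qtop, which.min(sf$lags)])
  win <- sf$lags >= max(sf$lags) / sqrt(10)
  if (sum(win) < 2L) win[which.max(sf$lags)] <- TRUE
  llag <- log10(sf$lags[win])
  A <- rep(NA_real_, length(sf$q_bins))
  usable <- logical(length(sf$q_bins))
  for (j in seq_along(sf$q_bins)) {
    v <- sf$values[j, win]
    if (any(v <= 0)) { usable[j] <- FALSE; next }
    slope <- unname(coef(lm(log10(v) ~ llag))[2])
    plateau <- mean(v)
    A[j] <- max(plateau - B, 0)
    usable[j] <- is.finite(slope) && abs(slope) < plateau_slope_tol
  }
  if (!any(usable))
    stop(paste0("estimate_noise_and_amplitude: no q-bin passed plateau ",
                "acceptance; the structure function has not relaxed within ",
                "the lag range (insufficient ensemble averaging at long lags)"),
         call. = FALSE)
  sf$noise_floor_B <- B
  sf$amplitude_A <- A
  sf$usable <- usable
  sf
}

#' Extract the intermediate scattering function at one wavevector
#'
#' \eqn{f(q, \Delta t) = 1 - (D(q, \Delta t) - B) / A(q)} at the q-bin whose
#' centre is nearest the requested wavevector (the bin centre actually used
#' is always reported).  Values are clipped to [-0.2, 1.2] with clip events
#' counted.  The conventional probe-scale choice is \eqn{q = 2\pi/R}.
#'
#' @param sf a \code{"structure_function"}; A and B are estimated on the fly
#'   if absent.
#' @param q requested wavevector, um^-1.
#' @return an object of class \code{"isf_curve"}: \code{q} (bin centre
#'   used), \code{q_requested}, \code{lags}, \code{f_values},
#'   \code{n_clipped}, \code{amplitude_A}, \code{noise_floor_B},
#'   \code{elapsed_time}.
#' @export
extract_isf <- function(sf, q) {
  .assert(inherits(sf, "structure_function"),
          "'sf' must be a structure_function")
  .assert(.is_pos(q), "'q' must be > 0")
  if (!is.finite(sf$noise_floor_B)) sf <- estimate_noise_and_amplitude(sf)
  j <- which.min(abs(sf$q_bins - q))
  if (!isTRUE(sf$usable[j]))
    stop(sprintf("extract_isf: q-bin %.4g um^-1 (nearest to %.4g) failed plateau acceptance; A(q) is not defined there",
                 sf$q_bins[j], q), call. = FALSE)
  A <- sf$amplitude_A[j]; B <- sf$noise_floor_B
  if (A <= 0)
    stop(sprintf("extract_isf: amplitude A = 0 at q = %.4g um^-1 (no signal above the noise floor)",
                 sf$q_bins[j]), call. = FALSE)
  if (A < 5 * B)
    message(sprintf("extract_isf: A(q) = %.3g is < 5*B (B = %.3g) at q = %.4g um^-1; f will be noisy",
                    A, B, sf$q_bins[j]))
  f <- 1 - (sf$values[j, ] - B) / A
  n_clip <- sum(f < -0.2 | f > 1.2)
  f <- pmin(pmax(f, -0.2), 1.2)
  structure(list(q = sf$q_bins[j], q_requested = q, lags = sf$lags,
                 f_values = f, n_clipped = n_clip,
                 amplitude_A = A, noise_floor_B = B,
                 elapsed_time = sf$elapsed_time),
            class = "isf_curve")
}

#' @export
print.isf_curve <- function(x, ...) {
  cat(sprintf("<isf_curve> q = %.4g um^-1, %d lags, f in [%.3g, %.3g], t = %s min\n",
              x$q, length(x$lags), min(x$f_values), max(x$f_values),
              format(x$elapsed_time)))
  invisible(x)
}

#' Invert an intermediate scattering function to a mean-square displacement
#'
#' Applies \eqn{\langle r^2(\Delta t)\rangle = (4/q^2)(-\log f)^{1/\beta}}.
#' With the default \code{beta = 1} this is the Gaussian-dynamics inversion
#' \eqn{MSD = -(4/q^2)\log f}, exact whenever probe displacements are
#' Gaussian at every lag (normal diffusion and fractional Brownian motion
#' alike), and it is the form that exposes sub-diffusive MSD slopes.
#' Supplying the stretch exponent fitted to \eqn{f} instead applies the
#' strict model inversion of the stretched-exponential Brownian form; note
#' that doing so linearises any Gaussian sub-diffusion by construction, so
#' it is only meaningful when \eqn{\beta} reflects dynamics that are
#' genuinely non-Gaussian rather than sub-diffusive (see the methods
#' vignette).
#'
#' Lags are retained while \eqn{f} stays inside \code{f_range}; the curve is
#' truncated at its first crossing below the floor, because once the signal
#' has decorrelated the remaining \eqn{f} values are pure noise about zero
#' and must not re-enter the fit when a fluctuation happens to be positive.
#' Dropped lags are counted.  The log-log MSD exponent is a weighted
#' least-squares slope over the retained lags with weights
#' \eqn{(f\,\log f)^2}: for near-constant noise on \eqn{f} this is the
#' inverse-variance weighting of \eqn{\log} MSD, and it concentrates the fit
#' on the central part of the decay (both the barely-decayed and the
#' nearly-decorrelated ends of the curve carry vanishing weight).
#'
#' @param isf an \code{"isf_curve"}.
#' @param beta exponent used in the inversion (default 1: Gaussian).
#' @param f_range usable f interval (default (0.005, 0.98)).
#' @param max_lag optional cap (s) on the lags entering the MSD fit: when
#'   the lag list deliberately includes long plateau-anchor lags (used only
#'   to pin the structure-function amplitude), exclude them here so that
#'   post-decorrelation noise cannot re-enter the slope fit.
#' @return an object of class \code{"msd_curve"}: \code{lags}, \code{msd}
#'   (um^2), \code{q_used}, \code{beta_used}, \code{exponent} (fitted
#'   log-log slope), \code{n_dropped}, \code{elapsed_time}.
#' @export
isf_to_msd <- function(isf, beta = 1, f_range = c(0.005, 0.98),
                       max_lag = NULL) {
  .assert(inherits(isf, "isf_curve"), "'isf' must be an isf_curve")
  .assert(.is_pos(beta), "'beta' must be > 0")
  o <- order(isf$lags)
  isf$lags <- isf$lags[o]; isf$f_values <- isf$f_values[o]
  if (!is.null(max_lag)) {
    sel <- isf$lags <= max_lag
    isf$lags <- isf$lags[sel]; isf$f_values <- isf$f_values[sel]
  }
  keep <- isf$f_values > f_range[1] & isf$f_values < f_range[2]
  below <- which(isf$f_values <= f_range[1])
  if (length(below)) keep[below[1]:length(keep)] <- FALSE
  if (sum(keep) < 5L)
    stop(sprintf("isf_to_msd: only %d lag(s) have f inside (%.3g, %.3g); need >= 5",
                 sum(keep), f_range[1], f_range[2]), call. = FALSE)
  lags <- isf$lags[keep]
  f <- isf$f_values[keep]
  msd <- (4 / isf$q^2) * (-log(f))^(1 / beta)
  # inverse-variance weights of log msd under near-constant noise on f
  w <- (f * log(f))^2
  expo <- unname(coef(lm(log(msd) ~ log(lags), weights = w))[2])
  structure(list(lags = lags, msd = msd, q_used = isf$q,
                 beta_used = beta, exponent = expo,
                 n_dropped = sum(!keep),
                 elapsed_time = isf$elapsed_time),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, exponent %.3f (q = %.4g um^-1, beta = %.3g, %d dropped), t = %s min\n",
              length(x$lags), x$exponent, x$q_used, x$beta_used,
              x$n_dropped, format(x$elapsed_time)))
  invisible(x)
}

#' @export
as.data.frame.structure_function <- function(x, ...) {
  data.frame(elapsed_min = x$elapsed_time,
             q_um_inv = rep(x$q_bins, times = length(x$lags)),
             lag_s = rep(x$lags, each = length(x$q_bins)),
             value = as.vector(x$values))
}
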