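#' Synthesize a gelation rheology trace with known ground truth
#'
#' Builds a storage/loss-moduli table \eqn{G'(t,\omega)},
#' \eqn{G''(t,\omega)} reproducing the canonical three stages of an
#' acid-induced milk gelation run:
#' \enumerate{
#'   \item incubation (t <= tc): tiny solid response, liquid-like loss
#'     tangent \eqn{\tan\delta \gg 1};
#'   \item network growth (tc < t <= t_peak): \eqn{G'} rises steeply from
#'     the sol baseline to its local maximum;
#'   \item aging (t > t_peak): exact power laws
#'     \eqn{G' \propto t^{a}} and \eqn{G'' \propto t^{b}} (defaults
#'     a = -0.23, b = -0.38), hence \eqn{\tan\delta \propto t^{b-a}}.
#' }
#' The loss tangent is constructed as
#' \eqn{\tan\delta(t,\omega) = \exp[\psi(t)\,h(\omega)]} with
#' \eqn{\psi(t_c) = 0}, so all frequency curves intersect exactly at
#' \eqn{t = t_c} with common value 1 -- the Winter-Chambon gel-point
#' signature by construction.
#'
#' @param tc gel point, min (must lie on the time grid for an exact
#'   noise-free crossover).
#' @param aging_exponent_storage aging exponent a of \eqn{G'} (< 0).
#' @param aging_exponent_loss aging exponent b of \eqn{G''} (< 0).
#' @param omegas angular frequencies, 1/s (>= 2 for a Winter-Chambon
#'   crossover to be identifiable).
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   noise applied to both moduli (0 = noise-free).
#' @param seed RNG seed (used only when \code{noise_cv > 0}).
#' @param times time grid, min.
#' @param t_peak time of the \eqn{G'} local maximum, min.
#' @param g_sol sol-stage storage modulus, Pa.
#' @param g_peak peak storage modulus, Pa.
#' @param tau_pre,tau_post time scales (min) of the loss-tangent approach
#'   to / departure from 1 around tc.
#' @param freq_sensitivity strength of the frequency dependence of
#'   \eqn{\tan\delta} away from the gel point.
#' @return an object of class \code{"rheo_trace"}: a long data.frame
#'   (\code{t_min}, \code{omega_per_s}, \code{g_prime_pa},
#'   \code{g_double_prime_pa}) with the generator parameters attached as
#'   attributes (\code{params}).
#' @export
synthesize_rheology <- function(tc = 32,
                                aging_exponent_storage = -0.23,
                                aging_exponent_loss = -0.38,
                                omegas = c(1, 5, 10, 50, 100),
                                noise_cv = 0, seed = 0L,
                                times = seq(0, 90, by = 1),
                                t_peak = 45, g_sol = 0.02, g_peak = 100,
                                tau_pre = 10, tau_post = 20,
                                freq_sensitivity = 0.25) {
  .assert(.is_pos(tc), "'tc' must be > 0")
  .assert(aging_exponent_storage < 0 && aging_exponent_loss < 0,
          "aging exponents must be < 0")
  if (length(omegas) < 2L)
    stop("synthesize_rheology: at least 2 frequencies are required for a Winter-Chambon crossover",
         call. = FALSE)
  .assert(noise_cv >= 0, "'noise_cv' must be >= 0")
  .assert(t_peak > tc, "'t_peak' must exceed 'tc'")
  .assert(max(times) > t_peak, "the time grid must extend beyond 't_peak'")
  a <- aging_exponent_storage; b <- aging_exponent_loss

  lz <- log(omegas)
  h <- 1 + freq_sensitivity * (lz - mean(lz)) / max(sd(lz), 1e-12)
  .assert(all(h > 0), "'freq_sensitivity' too large: tan-delta shape h(omega) must stay positive")

  psi <- ifelse(times <= tc, (tc - times) / tau_pre, (tc - times) / tau_post)
  psi_p <- (tc - t_peak) / tau_post

  gp_t <- function(t) {
    ifelse(t <= tc, g_sol,
      ifelse(t <= t_peak, {
        u <- pmin(pmax((t - tc) / (t_peak - tc), 0), 1)
        g_sol * (g_peak / g_sol)^(u * u * (3 - 2 * u))
      },
      g_peak * (t / t_peak)^a))
  }
  gp1 <- gp_t(times)

  grid <- expand.grid(t_min = times, omega_per_s = omegas)
  gp <- rep(gp1, times = length(omegas))
  tan_d <- numeric(nrow(grid))
  for (j in seq_along(omegas)) {
    idx <- grid$omega_per_s == omegas[j]
    td <- exp(psi * h[j])
    aging <- times > t_peak
    td[aging] <- exp(psi_p * h[j]) * (times[aging] / t_peak)^(b - a)
    tan_d[idx] <- td
  }
  gpp <- gp * tan_d

  if (noise_cv > 0) {
    set.seed(seed)
    s_ln <- sqrt(log(1 + noise_cv^2))
    gp <- gp * exp(rnorm(length(gp), sd = s_ln))
    gpp <- gpp * exp(rnorm(length(gpp), sd = s_ln))
  }
  out <- data.frame(t_min = grid$t_min, omega_per_s = grid$omega_per_s,
                    g_prime_pa = gp, g_double_prime_pa = gpp)
  structure(out,
            params = list(tc = tc, aging_exponent_storage = a,
                          aging_exponent_loss = b, omegas = omegas,
                          noise_cv = noise_cv, seed = seed,
                          t_peak = t_peak, g_sol = g_sol, g_peak = g_peak,
                          tau_pre = tau_pre, tau_post = tau_post,
                          freq_sensitivity = freq_sensitivity),
            class = c("rheo_trace", "data.frame"))
}

#' Read / write rheology traces as CSV
#'
#' Plain CSV with columns \code{t_min}, \code{omega_per_s},
#' \code{g_prime_pa}, \code{g_double_prime_pa}.
#'
#' @param trace a \code{"rheo_trace"} (or compatible data.frame).
#' @param path CSV path.
#' @return \code{write_rheology}: the path, invisibly;
#'   \code{read_rheology}: a \code{"rheo_trace"}.
#' @export
write_rheology <- function(trace, path) {
  cols <- c("t_min", "omega_per_s", "g_prime_pa", "g_double_prime_pa")
  .assert(all(cols %in% names(trace)), "trace lacks the rheology CSV columns")
  write.csv(as.data.frame(trace)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rheology
#' @export
read_rheology <- function(path) {
  df <- read.csv(path)
  cols <- c("t_min", "omega_per_s", "g_prime_pa", "g_double_prime_pa")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("read_rheology: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(df[cols], class = c("rheo_trace", "data.frame"))
}
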