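#' Probe motion models
#'
#' Constructs a motion model for the trajectory simulator.  Three kinds are
#' supported:
#' \describe{
#'   \item{\code{"brownian"}}{normal diffusion; 2-D MSD \eqn{= 4 D \Delta t}.
#'     Requires \code{diffusion_coefficient} (\eqn{\mu m^2/s}).}
#'   \item{\code{"fbm"}}{fractional Brownian motion with Hurst exponent
#'     \eqn{H \in (0,1)}; 2-D MSD \eqn{= 4 D \Delta t^{2H}} with \code{D} in
#'     \eqn{\mu m^2/s^{2H}}.  \eqn{H = 1/2} reduces exactly to the Brownian
#'     case.  Models the sub-diffusive motion of probes in a developing gel
#'     network.}
#'   \item{\code{"trapped"}}{overdamped motion in a harmonic well
#'     (Ornstein-Uhlenbeck position process): relaxation rate
#'     \code{trap_stiffness} (1/s) and thermal noise intensity
#'     \code{noise_scale} (\eqn{\mu m^2/s}).  The MSD saturates at the plateau
#'     \eqn{4\,\mathrm{noise\_scale}/\mathrm{trap\_stiffness}} -- an arrested
#'     probe caged by the surrounding network.}
#' }
#'
#' @param kind one of \code{"brownian"}, \code{"fbm"}, \code{"trapped"}.
#' @param diffusion_coefficient diffusion coefficient (brownian, fbm).
#' @param hurst_exponent Hurst exponent in (0, 1) (fbm only).
#' @param trap_stiffness relaxation rate of the well, 1/s (trapped only).
#' @param noise_scale noise intensity, um^2/s (trapped only).
#' @return an object of class \code{"motion_model"}.
#' @examples
#' motion_model("brownian", diffusion_coefficient = 0.4)
#' motion_model("fbm", diffusion_coefficient = 0.04, hurst_exponent = 1/6)
#' @export
motion_model <- function(kind = c("brownian", "fbm", "trapped"),
                         diffusion_coefficient = NULL,
                         hurst_exponent = NULL,
                         trap_stiffness = NULL,
                         noise_scale = NULL) {
  kind <- match.arg(kind)
  m <- list(kind = kind)
  if (kind == "brownian") {
    .assert(!is.null(diffusion_coefficient),
            "brownian model requires 'diffusion_coefficient'")
    .assert(is.numeric(diffusion_coefficient) && diffusion_coefficient >= 0,
            "'diffusion_coefficient' must be >= 0")
    m$diffusion_coefficient <- diffusion_coefficient
  } else if (kind == "fbm") {
    .assert(!is.null(diffusion_coefficient) && !is.null(hurst_exponent),
            "fbm model requires 'diffusion_coefficient' and 'hurst_exponent'")
    .assert(is.numeric(diffusion_coefficient) && diffusion_coefficient >= 0,
            "'diffusion_coefficient' must be >= 0")
    .assert(is.numeric(hurst_exponent) && hurst_exponent > 0 &&
              hurst_exponent < 1, "'hurst_exponent' must lie in (0, 1)")
    m$diffusion_coefficient <- diffusion_coefficient
    m$hurst_exponent <- hurst_exponent
  } else {
    .assert(!is.null(trap_stiffness) && !is.null(noise_scale),
            "trapped model requires 'trap_stiffness' and 'noise_scale'")
    .assert(.is_pos(trap_stiffness), "'trap_stiffness' must be > 0")
    .assert(is.numeric(noise_scale) && noise_scale >= 0,
            "'noise_scale' must be >= 0")
    m$trap_stiffness <- trap_stiffness
    m$noise_scale <- noise_scale
  }
  structure(m, class = "motion_model")
}

#' Gel-state subdiffusive motion preset
#'
#' Fractional Brownian motion with \eqn{H = 1/6} (MSD log-log slope 1/3,
#' matching the sub-diffusive guide slope reported for arrested-gel probes)
#' and amplitude chosen so the probe-scale intermediate scattering function
#' decays fully within a 10 s, 50 Hz movie.
#'
#' @return a \code{"motion_model"}.
#' @export
gel_state_motion <- function() {
  motion_model("fbm", diffusion_coefficient = 0.04, hurst_exponent = 1 / 6)
}

#' @export
print.motion_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("<motion_model>", x$kind, ":",
      paste(names(pars), unlist(pars), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Gelation schedule
#'
#' An ordered set of imaging conditions along a gelation run: at each elapsed
#' time (the minutes since the acidulant was added) the probes move according
#' to a stage motion model.  For Brownian stages the diffusion coefficient may
#' be given implicitly as a medium viscosity (mPa s), converted through the
#' Stokes-Einstein relation \eqn{D = k_B T / (6\pi\eta R)} at the schedule's
#' probe radius and temperature.
#'
#' @param stages a list; each element a list with fields \code{elapsed_time}
#'   (min), \code{motion} (a \code{\link{motion_model}}) and optionally
#'   \code{viscosity} (mPa s, Brownian stages only -- overrides the model's
#'   diffusion coefficient via Stokes-Einstein).
#' @param probe_radius probe radius in um (default 0.57, the mean fat-globule
#'   radius of the emulated experiments).
#' @param temperature temperature in K (default 298.15).
#' @return an object of class \code{"gelation_schedule"}.
#' @seealso \code{\link{default_gelation_schedule}}
#' @export
gelation_schedule <- function(stages, probe_radius = 0.57,
                              temperature = 298.15) {
  .assert(.is_pos(probe_radius), "'probe_radius' must be > 0")
  .assert(.is_pos(temperature), "'temperature' must be > 0")
  .assert(is.list(stages) && length(stages) >= 1L,
          "'stages' must be a non-empty list")
  et <- vapply(stages, function(s) as.numeric(s$elapsed_time), 0)
  .assert(all(is.finite(et)) && all(diff(et) > 0),
          "stage elapsed_time labels must be strictly increasing")
  stages <- lapply(stages, function(s) {
    .assert(inherits(s$motion, "motion_model"),
            "each stage needs a 'motion' of class motion_model")
    if (!is.null(s$viscosity)) {
      .assert(.is_pos(s$viscosity), "stage viscosity must be > 0")
      .assert(s$motion$kind == "brownian",
              "stage viscosity is only meaningful for brownian stages")
      s$motion$diffusion_coefficient <-
        stokes_einstein_d(s$viscosity, probe_radius, temperature)
    }
    s
  })
  structure(list(stages = stages, probe_radius = probe_radius,
                 temperature = temperature),
            class = "gelation_schedule")
}

#' Stokes-Einstein diffusion coefficient
#'
#' @param viscosity medium viscosity, mPa s.
#' @param probe_radius probe radius, um.
#' @param temperature temperature, K.
#' @return diffusion coefficient in um^2/s.
#' @export
stokes_einstein_d <- function(viscosity, probe_radius, temperature = 298.15) {
  # eta [Pa s] = viscosity*1e-3 ; R [m] = probe_radius*1e-6 ; D [m^2/s] -> um^2/s
  d_m2 <- .kB * temperature / (6 * pi * viscosity * 1e-3 * probe_radius * 1e-6)
  d_m2 * 1e12
}

#' Default six-movie gelation schedule
#'
#' Emulates a GDL-type acid-gelation run imaged at 0, 10, 20, 30, 40 and
#' 50 min: four pre-gel Brownian stages with a mildly rising milk-like
#' viscosity (2.0 to 3.2 mPa s), a sub-diffusive gel stage
#' (\code{\link{gel_state_motion}}) at 40 min, and an arrested (trapped)
#' stage at 50 min whose MSD plateau of \eqn{(0.02\,\mu m)^2} renders the
#' probes effectively frozen at the imaging lag.
#'
#' @param probe_radius probe radius in um.
#' @param temperature temperature in K.
#' @return a \code{"gelation_schedule"}.
#' @export
default_gelation_schedule <- function(probe_radius = 0.57,
                                      temperature = 298.15) {
  eta <- c(2.0, 2.2, 2.6, 3.2)
  pre <- lapply(seq_along(eta), function(i)
    list(elapsed_time = (i - 1L) * 10,
         motion = motion_model("brownian", diffusion_coefficient = 1),
         viscosity = eta[i]))
  gel <- list(elapsed_time = 40, motion = gel_state_motion())
  frozen <- list(elapsed_time = 50,
                 motion = motion_model("trapped", trap_stiffness = 20,
                                       noise_scale = 0.002))
  gelation_schedule(c(pre, list(gel, frozen)),
                    probe_radius = probe_radius, temperature = temperature)
}

#' @export
print.gelation_schedule <- function(x, ...) {
  cat("<gelation_schedule>", length(x$stages), "stages; probe R =",
      x$probe_radius, "um; T =", x$temperature, "K\n")
  for (s in x$stages)
    cat(sprintf("  t = %4g min : %s\n", s$elapsed_time, s$motion$kind))
  invisible(x)
}
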