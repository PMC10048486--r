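#' Imaging optics model for the synthetic renderer
#'
#' Describes how probe positions are turned into a microscopy movie: each
#' probe is rendered as a 2-D Gaussian spot (analytically evaluated at
#' sub-pixel position), spots are summed, then background, optional shot
#' noise and Gaussian read noise are applied and the frame is quantised to
#' the chosen bit depth.
#'
#' The default spot width (psf_sigma = 0.7 px = 0.07 um at the default
#' 0.1 um/px sampling) places the centre of the rendered-image passband at
#' the probe wavevector \eqn{q_R = 2\pi/R} for the default 0.57 um probe, so
#' that broadband (DVA) and wavevector-resolved (DDM) analyses of the same
#' movie interrogate the same dynamics.
#'
#' @param pixel_size pixel size, um/px.
#' @param image_shape image size in px, length-2 (ny, nx) or scalar.
#' @param psf_sigma Gaussian spot sigma, px.
#' @param peak_intensity spot peak amplitude, counts.
#' @param background constant background level, counts.
#' @param read_noise_sigma Gaussian read noise sigma, counts (0 = none).
#' @param shot_noise apply Poisson noise to the noiseless image?
#' @param bit_depth 8 or 16.
#' @return an object of class \code{"optics_model"}.
#' @export
optics_model <- function(pixel_size = 0.1, image_shape = c(256L, 256L),
                         psf_sigma = 0.7, peak_intensity = 300,
                         background = 100, read_noise_sigma = 3,
                         shot_noise = FALSE, bit_depth = 16L) {
  if (length(image_shape) == 1L) image_shape <- rep(image_shape, 2L)
  .assert(.is_pos(pixel_size), "'pixel_size' must be > 0")
  .assert(.is_pos(psf_sigma), "'psf_sigma' must be > 0")
  .assert(bit_depth %in% c(8L, 16L), "'bit_depth' must be 8 or 16")
  .assert(peak_intensity >= 0 && background >= 0 && read_noise_sigma >= 0,
          "intensities and noise levels must be >= 0")
  .assert(peak_intensity + background <= 2^bit_depth - 1,
          "peak_intensity + background exceeds the bit-depth range")
  structure(list(pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 psf_sigma = psf_sigma, peak_intensity = peak_intensity,
                 background = background,
                 read_noise_sigma = read_noise_sigma,
                 shot_noise = isTRUE(shot_noise),
                 bit_depth = as.integer(bit_depth)),
            class = "optics_model")
}

#' Render a trajectory ensemble into a synthetic microscopy movie
#'
#' Positions are wrapped periodically into the imaging box, each probe is
#' drawn as an analytic Gaussian spot of width \code{psf_sigma} centred at
#' its (sub-pixel) position, spots and background are summed, noise is
#' applied, and the frame is rounded and clipped to the bit-depth range.
#' Clipped pixels are counted in the render report
#' (\code{attr(stack, "render_report")}), with a warning when any occur.
#'
#' @param traj a \code{"trajectory_ensemble"}.
#' @param optics an \code{\link{optics_model}}.
#' @param seed RNG seed for the noise.
#' @param elapsed_time elapsed-time label of the movie, min.
#' @return an \code{\link{image_stack}}.
#' @export
render_movie <- function(traj, optics, seed = 0L, elapsed_time = 0) {
  .assert(inherits(traj, "trajectory_ensemble"),
          "'traj' must be a trajectory_ensemble")
  .assert(inherits(optics, "optics_model"), "'optics' must be an optics_model")
  ny <- optics$image_shape[1]; nx <- optics$image_shape[2]
  px <- optics$pixel_size
  sig <- optics$psf_sigma
  # 6-sigma stamp window: truncating tighter leaves step edges whose
  # high-wavevector power contaminates the DDM noise floor
  halfw <- max(1L, ceiling(6 * sig))
  nf <- traj$n_frames; np <- traj$n_particles
  boxx <- traj$box[1]; boxy <- traj$box[2]
  set.seed(seed)
  frames <- array(0, dim = c(nf, ny, nx))
  ceiling_val <- 2^optics$bit_depth - 1
  n_clipped <- 0L

  # when the trajectory box coincides with the field of view, spots wrap
  # periodically at the edges (matching the periodic trajectory wrapping);
  # otherwise out-of-view tails are simply not drawn
  periodic <- abs(boxx - nx * px) < 1e-9 && abs(boxy - ny * px) < 1e-9

  for (t in seq_len(nf)) {
    img <- matrix(0, ny, nx)
    # wrapped positions in px units (0-based, pixel centres at integers)
    cx <- (traj$positions[t, , 1] %% boxx) / px
    cy <- (traj$positions[t, , 2] %% boxy) / px
    for (p in seq_len(np)) {
      i0 <- floor(cy[p]); j0 <- floor(cx[p])
      ii <- (i0 - halfw):(i0 + halfw)
      jj <- (j0 - halfw):(j0 + halfw)
      gy <- exp(-((ii - cy[p])^2) / (2 * sig^2))
      gx <- exp(-((jj - cx[p])^2) / (2 * sig^2))
      if (periodic) {
        ri <- (ii %% ny) + 1L; rj <- (jj %% nx) + 1L
        img[ri, rj] <- img[ri, rj] +
          optics$peak_intensity * outer(gy, gx)
      } else {
        keep_i <- ii >= 0L & ii < ny
        keep_j <- jj >= 0L & jj < nx
        if (!any(keep_i) || !any(keep_j)) next
        ri <- ii[keep_i] + 1L; rj <- jj[keep_j] + 1L
        img[ri, rj] <- img[ri, rj] +
          optics$peak_intensity * outer(gy[keep_i], gx[keep_j])
      }
    }
    img <- img + optics$background
    if (optics$shot_noise)
      img <- matrix(rpois(ny * nx, lambda = pmax(img, 0)), ny, nx)
    if (optics$read_noise_sigma > 0)
      img <- img + matrix(rnorm(ny * nx, sd = optics$read_noise_sigma), ny, nx)
    img <- round(img)
    over <- img > ceiling_val | img < 0
    n_clipped <- n_clipped + sum(over)
    img[img > ceiling_val] <- ceiling_val
    img[img < 0] <- 0
    frames[t, , ] <- img
  }
  if (n_clipped > 0L)
    warning(sprintf("render_movie: %d pixel(s) clipped at the %d-bit ceiling/floor",
                    n_clipped, optics$bit_depth))
  st <- image_stack(frames, pixel_size = px,
                    frame_interval = traj$frame_interval,
                    elapsed_time = elapsed_time, source = "synthetic")
  attr(st, "render_report") <- list(n_clipped = n_clipped, seed = seed,
                                    bit_depth = optics$bit_depth)
  st
}
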