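#' Simulate probe trajectories
#'
#' Generates an ensemble of independent 2-D probe trajectories under a
#' \code{\link{motion_model}}.  Initial positions are uniform in the box.
#' Unwrapped coordinates are stored (the renderer wraps them periodically at
#' the box edges), so ensemble mean-square displacements computed from the
#' output obey the model's closed form:
#' Brownian \eqn{4D\Delta t}; fbm \eqn{4D\Delta t^{2H}}; trapped saturating
#' at \eqn{4\,\mathrm{noise\_scale}/\mathrm{trap\_stiffness}}.
#'
#' Fractional Gaussian noise is synthesised exactly from its covariance:
#' Cholesky factorisation up to 2048 steps, Davies-Harte circulant embedding
#' beyond that.
#'
#' @param model a \code{\link{motion_model}}.
#' @param n_particles number of probes.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval frame interval in s.
#' @param box box side(s) in um; scalar or length-2 (x, y).
#' @param seed integer RNG seed.
#' @return an object of class \code{"trajectory_ensemble"} with fields
#'   \code{positions} (array \code{[n_frames, n_particles, 2]}, um,
#'   unwrapped), \code{frame_interval}, \code{box}, \code{model},
#'   \code{seed}.
#' @examples
#' tr <- simulate_trajectories(motion_model("brownian",
#'   diffusion_coefficient = 0.4), 50, 100, 0.02, box = 25.6, seed = 1)
#' msd <- ensemble_msd(tr)
#' @export
simulate_trajectories <- function(model, n_particles, n_frames,
                                  frame_interval, box, seed) {
  .assert(inherits(model, "motion_model"), "'model' must be a motion_model")
  .assert(.is_count(n_particles), "'n_particles' must be a positive integer")
  .assert(.is_count(n_frames) && n_frames >= 2, "'n_frames' must be >= 2")
  .assert(.is_pos(frame_interval), "'frame_interval' must be > 0")
  if (length(box) == 1L) box <- c(box, box)
  .assert(all(box > 0), "'box' sides must be > 0")
  set.seed(seed)

  n_steps <- n_frames - 1L
  origin <- cbind(runif(n_particles, 0, box[1]),
                  runif(n_particles, 0, box[2]))
  pos <- array(0, dim = c(n_frames, n_particles, 2L))

  if (model$kind == "brownian") {
    s <- sqrt(2 * model$diffusion_coefficient * frame_interval)
    for (ax in 1:2) {
      inc <- matrix(rnorm(n_steps * n_particles, sd = s), n_steps, n_particles)
      pos[, , ax] <- rbind(0, apply(inc, 2, cumsum)) +
        matrix(origin[, ax], n_frames, n_particles, byrow = TRUE)
    }
  } else if (model$kind == "fbm") {
    H <- model$hurst_exponent
    sigma2 <- 2 * model$diffusion_coefficient * frame_interval^(2 * H)
    for (ax in 1:2) {
      inc <- .fgn_matrix(n_steps, n_particles, H) * sqrt(sigma2)
      pos[, , ax] <- rbind(0, apply(inc, 2, cumsum)) +
        matrix(origin[, ax], n_frames, n_particles, byrow = TRUE)
    }
  } else { # trapped: exact OU discretisation around the trap centre
    k <- model$trap_stiffness
    ns <- model$noise_scale
    phi <- exp(-k * frame_interval)
    svar <- ns / k                       # stationary per-axis variance
    sinc <- sqrt(svar * (1 - phi^2))
    for (ax in 1:2) {
      x <- matrix(0, n_frames, n_particles)
      x[1, ] <- rnorm(n_particles, sd = sqrt(svar))
      if (n_steps >= 1L) {
        z <- matrix(rnorm(n_steps * n_particles, sd = sinc), n_steps)
        for (i in seq_len(n_steps)) x[i + 1L, ] <- x[i, ] * phi + z[i, ]
      }
      pos[, , ax] <- x + matrix(origin[, ax], n_frames, n_particles,
                                byrow = TRUE)
    }
  }
  structure(list(positions = pos, frame_interval = frame_interval,
                 n_particles = n_particles, n_frames = n_frames,
                 box = box, model = model, seed = seed),
            class = "trajectory_ensemble")
}

# n_steps x n_particles matrix of standard fractional Gaussian noise
# (unit single-step variance).  Exact covariance synthesis.
.fgn_matrix <- function(n_steps, n_particles, H) {
  if (abs(H - 0.5) < 1e-12)
    return(matrix(rnorm(n_steps * n_particles), n_steps, n_particles))
  if (n_steps <= 2048L) {
    g <- .fgn_acf(n_steps, H)
    C <- stats::toeplitz(g)
    L <- t(chol(C))
    L %*% matrix(rnorm(n_steps * n_particles), n_steps, n_particles)
  } else {
    apply(matrix(seq_len(n_particles)), 1,
          function(i) .fgn_davies_harte(n_steps, H))
  }
}

# fGn autocovariance at lags 0..n-1 for unit variance.
.fgn_acf <- function(n, H) {
  k <- 0:(n - 1)
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Davies-Harte circulant embedding; returns one fGn path of length n.
.fgn_davies_harte <- function(n, H) {
  m <- 2L * n
  g <- .fgn_acf(n + 1L, H)
  circ <- c(g[1:(n + 1L)], rev(g[2:n]))
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop("Davies-Harte embedding failed: negative eigenvalue", call. = FALSE)
  lam <- pmax(lam, 0)
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  # enforce Hermitian structure for a real-valued output
  z[1] <- complex(real = Re(z[1]) * sqrt(2), imaginary = 0)
  z[n + 1L] <- complex(real = Re(z[n + 1L]) * sqrt(2), imaginary = 0)
  z[(n + 2L):m] <- Conj(z[2:n][rev(seq_len(n - 1L))])
  w <- fft(sqrt(lam / (2 * m)) * z)
  Re(w)[1:n]
}

#' Ensemble mean-square displacement of a trajectory ensemble
#'
#' Averages squared 2-D displacements over all particles and all start
#' frames, at a set of frame lags -- the ground-truth MSD of the simulator.
#'
#' @param traj a \code{"trajectory_ensemble"}.
#' @param lag_frames integer frame lags (default: all up to a quarter of the
#'   movie, capped at 50 values).
#' @return data.frame with columns \code{lag} (s) and \code{msd} (um^2).
#' @export
ensemble_msd <- function(traj, lag_frames = NULL) {
  .assert(inherits(traj, "trajectory_ensemble"),
          "'traj' must be a trajectory_ensemble")
  nf <- traj$n_frames
  if (is.null(lag_frames)) {
    kmax <- max(1L, floor((nf - 1L) / 4))
    lag_frames <- unique(round(exp(seq(0, log(kmax), length.out = 50L))))
  }
  lag_frames <- as.integer(lag_frames[lag_frames >= 1L & lag_frames < nf])
  p <- traj$positions
  msd <- vapply(lag_frames, function(k) {
    dx <- p[(k + 1L):nf, , 1, drop = FALSE] - p[1:(nf - k), , 1, drop = FALSE]
    dy <- p[(k + 1L):nf, , 2, drop = FALSE] - p[1:(nf - k), , 2, drop = FALSE]
    mean(dx * dx + dy * dy)
  }, 0)
  data.frame(lag = lag_frames * traj$frame_interval, msd = msd)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble>", x$n_particles, "particles x", x$n_frames,
      "frames @", 1 / x$frame_interval, "Hz;", x$model$kind,
      "motion; box", paste(x$box, collapse = " x "), "um\n")
  invisible(x)
}

#' Write ground-truth trajectories to CSV
#'
#' @param traj a \code{"trajectory_ensemble"}.
#' @param path output CSV path (columns particle_id, frame, x_um, y_um).
#' @return the path, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  p <- traj$positions
  df <- data.frame(
    particle_id = rep(seq_len(traj$n_particles), each = traj$n_frames),
    frame = rep(seq_len(traj$n_frames), traj$n_particles),
    x_um = as.vector(p[, , 1]),
    y_um = as.vector(p[, , 2]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
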