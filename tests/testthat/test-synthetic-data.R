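test_that("motion models validate their parameters", {
  expect_error(motion_model("brownian"), "diffusion_coefficient")
  expect_error(motion_model("fbm", diffusion_coefficient = 1,
                            hurst_exponent = 1.2), "hurst_exponent")
  expect_error(motion_model("trapped", trap_stiffness = -1,
                            noise_scale = 1), "trap_stiffness")
  expect_error(
    simulate_trajectories(motion_model("brownian",
                                       diffusion_coefficient = 1),
                          10, 1, 0.02, 10, seed = 1), "n_frames")
})

test_that("zero-diffusion trajectories are exactly static", {
  tr <- simulate_trajectories(
    motion_model("brownian", diffusion_coefficient = 0),
    20, 30, 0.02, box = 10, seed = 1)
  expect_equal(max(abs(apply(tr$positions, c(2, 3), function(p)
    diff(range(p))))), 0)
})

test_that("Brownian ensemble MSD follows 4 D dt", {
  tr <- simulate_trajectories(
    motion_model("brownian", diffusion_coefficient = 0.4),
    500, 500, 0.02, box = 25.6, seed = 1)
  m <- ensemble_msd(tr, lag_frames = 5L)  # dt = 0.1 s
  expect_lt(abs(m$msd - 0.16) / 0.16, 0.05)
  # log-log linearity across a D staircase
  for (D in c(0.1, 1.0)) {
    trd <- simulate_trajectories(
      motion_model("brownian", diffusion_coefficient = D),
      400, 250, 0.02, box = 25.6, seed = round(100 * D))
    md <- ensemble_msd(trd)
    expect_lt(abs(loglog_slope(md$lag, md$msd) - 1), 0.05)
  }
})

test_that("fbm MSD exponent equals 2H and H = 1/2 reduces to Brownian", {
  for (H in c(1 / 6, 1 / 4, 1 / 2)) {
    tr <- simulate_trajectories(
      motion_model("fbm", diffusion_coefficient = 0.2, hurst_exponent = H),
      400, 250, 0.02, box = 25.6, seed = round(1000 * H))
    m <- ensemble_msd(tr)
    expect_lt(abs(loglog_slope(m$lag, m$msd) - 2 * H), 0.05)
  }
  # H = 1/2 magnitude agrees with the closed Brownian form
  tr <- simulate_trajectories(
    motion_model("fbm", diffusion_coefficient = 0.2, hurst_exponent = 0.5),
    400, 250, 0.02, box = 25.6, seed = 7)
  m <- ensemble_msd(tr, lag_frames = c(2L, 10L))
  expect_lt(max(abs(m$msd - 4 * 0.2 * m$lag) / (4 * 0.2 * m$lag)), 0.1)
})

test_that("exact fGn synthesis matches the analytic covariance", {
  # oracle: lag-1 autocorrelation of fractional Gaussian noise
  for (H in c(1 / 6, 0.75)) {
    set.seed(3)
    inc <- gelscope:::.fgn_matrix(200L, 400L, H)
    rho1 <- mean(inc[-1, ] * inc[-200, ]) / mean(inc * inc)
    expect_lt(abs(rho1 - gelscope:::.fgn_acf(2, H)[2]), 0.02)
  }
  # Davies-Harte path (used beyond the Cholesky size limit)
  set.seed(4)
  x <- replicate(30, gelscope:::.fgn_davies_harte(3000L, 0.25))
  expect_lt(abs(var(as.vector(x)) - 1), 0.05)
  rho1 <- mean(x[-1, ] * x[-3000, ]) / mean(x * x)
  expect_lt(abs(rho1 - gelscope:::.fgn_acf(2, 0.25)[2]), 0.02)
})

test_that("trapped motion saturates at the harmonic-well plateau", {
  tr <- simulate_trajectories(
    motion_model("trapped", trap_stiffness = 20, noise_scale = 0.002),
    400, 400, 0.02, box = 25.6, seed = 2)
  m <- ensemble_msd(tr, lag_frames = c(50L, 99L))
  plateau <- 4 * 0.002 / 20
  expect_lt(max(abs(m$msd - plateau) / plateau), 0.1)
})

test_that("identical seeds give bit-identical trajectories and movies", {
  mk <- function() {
    tr <- simulate_trajectories(
      motion_model("brownian", diffusion_coefficient = 0.3),
      20, 20, 0.02, box = 6.4, seed = 99)
    list(tr = tr, st = render_movie(tr, optics_model(image_shape = 64),
                                    seed = 42))
  }
  a <- mk(); b <- mk()
  expect_identical(a$tr$positions, b$tr$positions)
  expect_identical(a$st$frames, b$st$frames)
})

test_that("renderer: static scenes, empty scenes and sub-pixel centroids", {
  opt <- optics_model(image_shape = 64, psf_sigma = 1.5,
                      read_noise_sigma = 0, background = 100)
  tr <- simulate_trajectories(
    motion_model("brownian", diffusion_coefficient = 0),
    5, 3, 0.02, box = 6.4, seed = 3)
  st <- render_movie(tr, opt, seed = 1)
  expect_identical(st$frames[1, , ], st$frames[2, , ])
  expect_identical(st$frames[1, , ], st$frames[3, , ])

  # empty ensemble: every pixel exactly the background
  tre <- simulate_trajectories(
    motion_model("brownian", diffusion_coefficient = 0),
    1, 2, 0.02, box = 6.4, seed = 3)
  tre$positions[] <- 1e6          # far outside a non-periodic view
  tre$box <- c(1e7, 1e7)
  ste <- render_movie(tre, opt, seed = 1)
  expect_true(all(ste$frames == 100))

  # one particle displaced 3 px between frames: centroid moves 3.00 px
  trc <- simulate_trajectories(
    motion_model("brownian", diffusion_coefficient = 0),
    1, 2, 0.02, box = 6.4, seed = 8)
  trc$positions[, 1, ] <- 3.05           # interior position, um
  trc$positions[2, 1, 1] <- 3.05 + 0.3   # +3 px in x
  opt0 <- optics_model(image_shape = 64, psf_sigma = 1.5,
                       read_noise_sigma = 0, background = 0)
  stc <- render_movie(trc, opt0, seed = 1)
  cen <- function(m) c(sum(col(m) * m), sum(row(m) * m)) / sum(m)
  d <- cen(stc$frames[2, , ]) - cen(stc$frames[1, , ])
  expect_lt(abs(d[1] - 3), 0.05)
  expect_lt(abs(d[2]), 0.05)
})

test_that("renderer is linear: union scene = sum of scenes minus background", {
  opt <- optics_model(image_shape = 64, psf_sigma = 1, read_noise_sigma = 0,
                      background = 50, peak_intensity = 200)
  mk <- function(seed) simulate_trajectories(
    motion_model("brownian", diffusion_coefficient = 0.3),
    8, 4, 0.02, box = 6.4, seed = seed)
  a <- mk(1); b <- mk(2)
  u <- a
  u$positions <- array(0, c(4, 16, 2))
  u$positions[, 1:8, ] <- a$positions
  u$positions[, 9:16, ] <- b$positions
  u$n_particles <- 16L
  fa <- render_movie(a, opt, seed = 0)$frames
  fb <- render_movie(b, opt, seed = 0)$frames
  fu <- render_movie(u, opt, seed = 0)$frames
  # rounding is the only nonlinearity: allow 1 count
  expect_lt(max(abs(fu - (fa + fb - 50))), 1 + 1e-9)
})

test_that("overlapping spots above the bit ceiling raise a clipping warning", {
  tr <- simulate_trajectories(
    motion_model("brownian", diffusion_coefficient = 0),
    2, 2, 0.02, box = 6.4, seed = 1)
  tr$positions[, , 1] <- 3.2; tr$positions[, , 2] <- 3.2  # coincident
  opt <- optics_model(image_shape = 64, psf_sigma = 1, peak_intensity = 150,
                      background = 50, read_noise_sigma = 0, bit_depth = 8)
  expect_warning(st <- render_movie(tr, opt, seed = 1), "clipped")
  expect_gt(attr(st, "render_report")$n_clipped, 0)
  expect_lte(max(st$frames), 255)
})

test_that("synthetic rheology reproduces its programmed structure", {
  tr <- loss_tangent(synthesize_rheology(noise_cv = 0))
  # tan-delta curves for every frequency pass through 1 exactly at tc
  at_tc <- tr$tan_delta[tr$t_min == 32]
  expect_equal(at_tc, rep(1, length(unique(tr$omega_per_s))))
  # aging stage: exact power laws at every frequency
  for (w in c(1, 100)) {
    sub <- tr[tr$omega_per_s == w & tr$t_min >= 45, ]
    expect_lt(abs(fit_power_law(sub$t_min, sub$g_prime_pa)$exponent -
                    (-0.23)), 1e-10)
    expect_lt(abs(fit_power_law(sub$t_min, sub$g_double_prime_pa)$exponent -
                    (-0.38)), 1e-10)
  }
  # noisy refit recovers the exponent
  trn <- synthesize_rheology(noise_cv = 0.01, seed = 5)
  sub <- trn[trn$omega_per_s == 1 & trn$t_min >= 45, ]
  expect_lt(abs(fit_power_law(sub$t_min, sub$g_prime_pa)$exponent -
                  (-0.23)), 0.02)
  expect_error(synthesize_rheology(omegas = 1), "2 frequencies")
})

test_that("trajectory and rheology CSV round trips", {
  tr <- simulate_trajectories(
    motion_model("brownian", diffusion_coefficient = 0.2),
    3, 4, 0.02, box = 5, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_trajectories(tr, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 12L)
  expect_equal(df$x_um[df$particle_id == 2], tr$positions[, 2, 1])

  rt <- synthesize_rheology(noise_cv = 0)
  f2 <- tempfile(fileext = ".csv")
  write_rheology(rt, f2)
  back <- read_rheology(f2)
  expect_equal(back$g_prime_pa, rt$g_prime_pa)
})
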