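test_that("a static noiseless movie has an identically zero structure function", {
  set.seed(3)
  base <- matrix(runif(32 * 32, 0, 200), 32, 32)
  fr <- array(0, c(5, 32, 32))
  for (t in 1:5) fr[t, , ] <- base
  st <- image_stack(fr, 0.1, 0.02)
  sf <- structure_function(st, lags = c(0.02, 0.04))
  expect_equal(max(abs(sf$values)), 0, tolerance = 1e-18)
})

test_that("FFT structure function equals the brute-force DFT bin by bin", {
  set.seed(11)
  fr <- array(sample(0:255, 8 * 8 * 3, TRUE), c(3, 8, 8))
  st <- image_stack(fr, 0.1, 0.02)
  sf <- structure_function(st, lags = c(0.02, 0.04))

  # oracle: direct double-sum DFT, azimuthally binned the same way
  brute_bins <- function(k) {
    L <- 8L
    acc <- matrix(0, L, L); n <- 0L
    for (t0 in seq_len(3 - k)) {
      di <- fr[t0 + k, , ] - fr[t0, , ]
      F <- matrix(0 + 0i, L, L)
      for (u in 0:(L - 1)) for (v in 0:(L - 1)) {
        s <- 0 + 0i
        for (y in 0:(L - 1)) for (x in 0:(L - 1))
          s <- s + di[y + 1, x + 1] * exp(-2i * pi * (u * y + v * x) / L)
        F[u + 1, v + 1] <- s
      }
      acc <- acc + Mod(F)^2; n <- n + 1L
    }
    acc <- acc / n / (L * L)
    f1d <- c(0:3, -4, -(3:1))
    bin <- round(sqrt(outer(f1d^2, f1d^2, "+")))
    keep <- bin >= 1 & bin <= 4
    as.vector(rowsum(acc[keep], bin[keep])) / tabulate(bin[keep], 4)
  }
  for (i in 1:2) {
    b <- brute_bins(i)
    expect_lt(max(abs(b - sf$values[, i]) / pmax(b, 1e-12)), 1e-10)
  }
})

test_that("Parseval: binned-domain power equals pixel-domain power", {
  set.seed(4)
  fr <- array(rnorm(16 * 16 * 4, 100, 10), c(4, 16, 16))
  st <- image_stack(fr, 0.1, 0.02)
  sf <- structure_function(st, lags = c(0.02, 0.04), parseval = TRUE)
  expect_lt(max(abs(sf$parseval$spectral_sum - sf$parseval$pixel_sum) /
                  sf$parseval$pixel_sum), 1e-8)
})

test_that("white noise yields a flat spectrum and near-zero amplitude", {
  set.seed(5)
  sigma <- 4
  fr <- array(0, c(30, 64, 64))
  for (t in 1:30) fr[t, , ] <- round(100 + rnorm(64 * 64, sd = sigma))
  st <- image_stack(fr, 0.1, 0.02)
  sf <- structure_function(st, lags = c(0.02, 0.06, 0.1, 0.2))
  hi <- sf$q_bins >= max(sf$q_bins) / 2
  sl <- coef(lm(v ~ q, data.frame(q = sf$q_bins[hi],
                                  v = sf$values[hi, 1])))[2]
  expect_lt(abs(sl * diff(range(sf$q_bins[hi]))) / mean(sf$values[hi, 1]),
            0.05)
  sf <- estimate_noise_and_amplitude(sf)
  # pure noise: A(q) ~ 0 everywhere (well under 5% of B)
  expect_lt(max(sf$amplitude_A, na.rm = TRUE), 0.05 * sf$noise_floor_B)
})

test_that("A and B are recovered from a constructed structure function", {
  A0 <- 400; B0 <- 20; tau0 <- 0.05
  lags <- exp(seq(log(5e-5), log(5), length.out = 25))
  nq <- 40
  sf <- structure(list(
    q_bins = seq(0.5, 20, length.out = nq), lags = lags,
    values = outer(rep(A0, nq), 1 - exp(-lags / tau0)) + B0,
    n_pairs = rep(100L, 25), amplitude_A = rep(NA_real_, nq),
    noise_floor_B = NA_real_, usable = rep(NA, nq),
    normalization = "forward DFT unscaled; power / n_pixels",
    pixel_size = 0.1, elapsed_time = 0, parseval = NULL),
    class = "structure_function")
  out <- estimate_noise_and_amplitude(sf)
  expect_lt(abs(out$noise_floor_B - B0) / B0, 0.02)
  expect_lt(max(abs(out$amplitude_A - A0)) / A0, 0.02)
  expect_true(all(out$usable))
})

test_that("the camera noise floor of a rendered movie matches 2 sigma^2", {
  # band-limited optics (sigma = 2 px): no sample signal at the top of the
  # q-range, so the high-q estimator sees pure read noise (+ quantization)
  mv <- fixture("bmpsf2", function() {
    D <- stokes_einstein_d(2, 0.57)
    tr <- simulate_trajectories(
      motion_model("brownian", diffusion_coefficient = D),
      300, 500, 0.02, box = 25.6, seed = 4)
    list(stack = render_movie(tr, optics_model(psf_sigma = 2), seed = 5),
         D = D)
  })
  sf <- estimate_noise_and_amplitude(
    structure_function(mv$stack, max_pairs = 60))
  expect_lt(abs(sf$noise_floor_B - 2 * 3^2) / (2 * 3^2), 0.1)
})

test_that("ISF limits: plateau maps to 0 and pure noise floor to 1", {
  A0 <- 400; B0 <- 20
  lags <- exp(seq(log(1e-4), log(5), length.out = 20))
  nq <- 40
  mkD <- function(fill) {
    structure(list(
      q_bins = seq(0.5, 20, length.out = nq), lags = lags,
      values = matrix(fill, nq, 20), n_pairs = rep(10L, 20),
      amplitude_A = rep(A0, nq), noise_floor_B = B0,
      usable = rep(TRUE, nq),
      normalization = "forward DFT unscaled; power / n_pixels",
      pixel_size = 0.1, elapsed_time = 0, parseval = NULL),
      class = "structure_function")
  }
  expect_equal(extract_isf(mkD(A0 + B0), 10)$f_values, rep(0, 20))
  expect_equal(extract_isf(mkD(B0), 10)$f_values, rep(1, 20))
})

test_that("ISF of a Brownian movie decays at rate D q^2", {
  mv <- brownian_movie(eta = 2, seed = 101)
  sf <- movie_sf(mv, "eta2")
  isf <- extract_isf(sf, 2 * pi / 0.57)
  keep <- isf$f_values > 0.05 & isf$f_values < 0.95
  rate <- coef(lm(y ~ x + 0,
                  data.frame(x = isf$lags[keep],
                             y = -log(isf$f_values[keep]))))[1]
  expect_lt(abs(rate / (mv$D * isf$q^2) - 1), 0.1)
})

test_that("relaxation times scale as q^-2 across usable wavevectors", {
  mv <- brownian_movie(eta = 2, seed = 101)
  sf <- movie_sf(mv, "eta2")
  qs <- c(6, 8, 10, 12, 14)
  taus <- vapply(qs, function(q) {
    isf <- extract_isf(sf, q)
    fit_stretched_exponential(isf$lags, isf$f_values)$tau
  }, 0)
  expect_lt(abs(loglog_slope(qs, taus) - (-2)), 0.15)
})

test_that("isf_to_msd inverts the Brownian closed form exactly", {
  q <- 11; D <- 0.3
  lags <- exp(seq(log(0.01), log(1), length.out = 15))
  isf <- structure(list(q = q, q_requested = q, lags = lags,
                        f_values = exp(-D * q^2 * lags), n_clipped = 0L,
                        amplitude_A = 100, noise_floor_B = 1,
                        elapsed_time = 0), class = "isf_curve")
  msd <- isf_to_msd(isf, beta = 1, f_range = c(1e-12, 1 - 1e-12))
  expect_equal(msd$msd, 4 * D * msd$lags, tolerance = 1e-12)
  expect_equal(msd$exponent, 1, tolerance = 1e-10)
  # general beta: the stretched form round-trips to a linear MSD
  isf$f_values <- exp(-(D * q^2 * lags)^0.5)
  msd2 <- isf_to_msd(isf, beta = 0.5, f_range = c(1e-12, 1 - 1e-12))
  expect_equal(msd2$msd, 4 * D * msd2$lags, tolerance = 1e-10)
})

test_that("MSD magnitude falls with viscosity while the slope stays 1", {
  expo <- c(); mag <- c()
  for (eta in c(2, 4)) {
    mv <- brownian_movie(eta = eta, seed = if (eta == 2) 101 else 104)
    isf <- extract_isf(movie_sf(mv, paste0("eta", eta)), 2 * pi / 0.57)
    m <- isf_to_msd(isf)
    expo <- c(expo, m$exponent)
    mag <- c(mag, stats::approx(log(m$lags), log(m$msd),
                                xout = log(0.04))$y)
  }
  expect_lt(max(abs(expo - 1)), 0.05)
  expect_lt(mag[2], mag[1])
})

test_that("shape and usability errors are explicit", {
  st <- texture_pair()
  rect <- crop_roi(st, c(1, 1), c(64, 128))
  expect_error(structure_function(rect), "square")
  mv <- brownian_movie(eta = 2, seed = 101)
  sf <- movie_sf(mv, "eta2")
  # q = 2 um^-1 relaxes too slowly for this movie: plateau unaccepted
  expect_error(extract_isf(sf, 2), "plateau acceptance")
})
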