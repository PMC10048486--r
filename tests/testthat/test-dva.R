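test_that("a static noiseless movie has zero differential variance", {
  set.seed(1)
  base <- matrix(runif(32 * 32, 0, 200), 32, 32)
  fr <- array(0, c(6, 32, 32))
  for (t in 1:6) fr[t, , ] <- base
  st <- image_stack(fr, 0.1, 0.02)
  dc <- differential_variance_curve(st, lags = c(0.02, 0.04))
  expect_equal(dc$variance, c(0, 0))
})

test_that("static movie plus i.i.d. noise gives variance 2 sigma^2", {
  set.seed(2)
  sigma <- 5
  base <- matrix(100, 128, 128)
  fr <- array(0, c(40, 128, 128))
  for (t in 1:40) fr[t, , ] <- round(base + rnorm(128 * 128, sd = sigma))
  st <- image_stack(fr, 0.1, 0.02)
  dc <- differential_variance_curve(st, lags = c(0.02, 0.1, 0.2))
  # rounding adds ~2/12 of quantization variance on top of 2 sigma^2
  expect_lt(max(abs(dc$variance - 2 * sigma^2) / (2 * sigma^2)), 0.05)
  expect_true(all(dc$n_pairs >= c(39, 35, 30)))
})

test_that("a hand-computed 4x4 two-frame stack matches exactly", {
  f1 <- matrix(c(1, 2, 3, 4,
                 5, 6, 7, 8,
                 9, 10, 11, 12,
                 13, 14, 15, 16), 4, 4, byrow = TRUE)
  f2 <- matrix(c(2, 2, 4, 4,
                 5, 7, 7, 9,
                 8, 10, 12, 12,
                 13, 15, 15, 17), 4, 4, byrow = TRUE)
  fr <- array(0, c(2, 4, 4)); fr[1, , ] <- f1; fr[2, , ] <- f2
  st <- image_stack(fr, 0.1, 0.02)
  dc <- differential_variance_curve(st, lags = 0.02)
  # oracle: var of dI = f2 - f1 computed by hand
  di <- as.vector(f2 - f1)
  expect_equal(dc$variance, sum((di - mean(di))^2) / (length(di) - 1))
})

test_that("order parameter algebra round-trips exactly", {
  tau0 <- 0.2; plateau <- 123.4
  lags <- exp(seq(log(0.01), log(10), length.out = 30))
  curve <- list(lags = lags,
                variance = plateau * (1 - exp(-lags / tau0)),
                n_pairs = rep(100L, 30), elapsed_time = 0)
  out <- order_parameter(curve, plateau = plateau)
  expect_equal(out$q_values, exp(-lags / tau0))
  # variance equal to the plateau at all lags: Q identically 0
  flat <- order_parameter(list(lags = lags,
                               variance = rep(plateau, 30)),
                          plateau = plateau)
  expect_equal(flat$q_values, rep(0, 30))
})

test_that("an unrelaxed variance curve raises a plateau diagnostic", {
  lags <- exp(seq(log(0.02), log(2), length.out = 15))
  st_curve <- structure(list(lags = lags, variance = 50 * lags^0.5,
                             n_pairs = rep(50L, 15),
                             plateau = NA_real_, plateau_slope = 0.5,
                             q_values = rep(NA_real_, 15),
                             elapsed_time = 0), class = "dva_curve")
  expect_error(order_parameter(st_curve), "plateau not estimable")
})

test_that("DVA plateau is accepted on a relaxed Brownian movie and Q decays", {
  mv <- brownian_movie(eta = 2, seed = 101)
  dc <- differential_variance_curve(mv$stack, max_pairs = 60)
  expect_true(is.finite(dc$plateau) && dc$plateau > 0)
  dc <- order_parameter(dc)
  expect_true(all(dc$q_values > -0.05 & dc$q_values < 1.05))
  # decays from near 1 toward 0, monotone within noise
  expect_gt(dc$q_values[1], 0.5)
  expect_lt(dc$q_values[length(dc$q_values)], 0.1)
  sm <- diff(dc$q_values)
  expect_true(all(sm < 0.05))
})

test_that("DVA and DDM relaxation times agree at the probe wavevector", {
  mv <- brownian_movie(eta = 2, seed = 101)
  dc <- order_parameter(differential_variance_curve(mv$stack,
                                                    max_pairs = 60))
  dva_fit <- fit_stretched_exponential(dc$lags, dc$q_values)
  sf <- movie_sf(mv, "eta2")
  isf <- extract_isf(sf, 2 * pi / 0.57)
  ddm_fit <- fit_stretched_exponential(isf$lags, isf$f_values)
  expect_lt(abs(dva_fit$tau / ddm_fit$tau - 1), 0.25)
})

test_that("halving the diffusion doubles the fitted relaxation times", {
  tau_for <- function(eta, seed) {
    mv <- brownian_movie(eta = eta, seed = seed)
    dc <- order_parameter(differential_variance_curve(mv$stack,
                                                      max_pairs = 60))
    dva <- fit_stretched_exponential(dc$lags, dc$q_values)$tau
    isf <- extract_isf(movie_sf(mv, paste0("eta", eta)), 2 * pi / 0.57)
    ddm <- fit_stretched_exponential(isf$lags, isf$f_values)$tau
    c(dva = dva, ddm = ddm)
  }
  t2 <- tau_for(2, 101); t4 <- tau_for(4, 104)
  expect_lt(abs(t4[["dva"]] / t2[["dva"]] - 2) / 2, 0.1)
  expect_lt(abs(t4[["ddm"]] / t2[["ddm"]] - 2) / 2, 0.1)
  # and the microscopic viscosities inherit the factor of two
  e2 <- microscopic_viscosity(t2[["ddm"]], 0.57, method = "ddm")$eta
  e4 <- microscopic_viscosity(t4[["ddm"]], 0.57, method = "ddm")$eta
  expect_lt(abs(e4 / e2 - 2) / 2, 0.1)
})

test_that("lag validation rejects bad grids", {
  st <- texture_pair()
  expect_error(differential_variance_curve(st, lags = numeric(0)), "empty")
  expect_error(differential_variance_curve(st, lags = 0.05),
               "integer multiple")
  expect_error(differential_variance_curve(st, lags = 10), "duration")
})
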