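test_that("absorbance-to-rate conversion", {
  expect_equal(absorbance_to_rate(0), 0)
  # hydrolysis rate is positive while absorbance decreases
  expect_equal(absorbance_to_rate(-3.76e-4, epsilon = 376, path_length = 1),
               1e-6)
  expect_equal(EPSILON_225, 376)
  expect_error(absorbance_to_rate(1, epsilon = 0), "epsilon")
  expect_error(absorbance_to_rate(1, path_length = -1), "path_length")
})

test_that("Michaelis-Menten fit inverts exact data and derives kcat", {
  s <- c(0.25, 0.5, 1, 2, 4) * 1e-4
  v <- 1e-6 * s / (1e-4 + s)
  fit <- fit_michaelis_menten(s, v)
  expect_equal(fit$Vmax, 1e-6, tolerance = 1e-6)
  expect_equal(fit$KM, 1e-4, tolerance = 1e-6)
  fit2 <- fit_michaelis_menten(s, v, enzyme_conc = 1e-8)
  expect_equal(fit2$kcat, 100, tolerance = 1e-5)
  expect_equal(fit2$kcat * 1e-8, fit2$Vmax, tolerance = 1e-12)
  expect_error(fit_michaelis_menten(s[1:3], v[1:3]), ">= 4 distinct")
})

test_that("noisy MM fit agrees with a dense grid-search oracle", {
  world <- list(Vmax = 1e-6, KM = 1e-4)
  s <- c(0.25, 0.5, 1, 2, 4, 8, 16) * 1e-4 # 7 concentrations
  sim <- simulate_initial_rates(world, s, rel_noise = 0.02, seed = 17)
  fit <- fit_michaelis_menten(sim$substrate_M, sim$rate_M_s)
  oracle <- mm_grid_oracle(sim$substrate_M, sim$rate_M_s,
                           vmax_range = c(0.5e-6, 2e-6),
                           km_range = c(0.3e-4, 3e-4))
  expect_equal(fit$Vmax, oracle$Vmax, tolerance = 1e-3)
  expect_equal(fit$KM, oracle$KM, tolerance = 1e-3)
})

test_that("saturating-only designs flag an ill-conditioned KM", {
  world <- list(Vmax = 1e-6, KM = 1e-6)
  s <- c(1, 2, 4, 8) * 1e-3 # everything >> KM
  sim <- simulate_initial_rates(world, s, rel_noise = 0.01, seed = 4)
  expect_warning(fit <- fit_michaelis_menten(sim$substrate_M, sim$rate_M_s),
                 "ill-conditioned")
  expect_true(fit$ill_conditioned_km)
})

test_that("closed-form progress matches limits and the ODE oracle", {
  expect_identical(closed_form_progress(1e-4, 1e-6, 1e-4, 0), 1e-4)
  # first-order limit KM' >> s0
  s0 <- 1e-5; KM <- 1e-3; Vmax <- 1e-6
  t <- seq(0, 5, length.out = 20) # < 50% conversion at these settings
  s <- closed_form_progress(s0, Vmax, KM, t)
  expect_equal(s, s0 * exp(-Vmax * t / KM), tolerance = 0.01)
  # adaptive ODE integration, 50-point grid, 1e-8 relative
  for (scale in c(1, 2.5)) {
    tg <- seq(0, time_to_conversion(1e-4, 1e-6, 1e-4, 0.95, scale),
              length.out = 50)
    s_cf <- closed_form_progress(1e-4, 1e-6, 1e-4, tg, KM_scale = scale)
    s_ode <- ode_progress(1e-4, 1e-6, 1e-4, tg, KM_scale = scale)
    expect_equal(s_cf, s_ode, tolerance = 1e-8)
  }
  expect_true(all(diff(s) < 0)) # monotone decreasing
  expect_error(closed_form_progress(1e-4, 1e-6, 1e-4, -1), "non-negative")
  expect_error(closed_form_progress(-1, 1e-6, 1e-4, 0), "positive")
})

test_that("linearization recovers the generating line exactly", {
  s0 <- 1e-4; Vmax <- 1e-6; KM <- 1e-4 # KM/Vmax = 100 s, 1/Vmax = 1e6 s/M
  t90 <- time_to_conversion(s0, Vmax, KM, 0.9)
  times <- seq(t90 / 40, t90, length.out = 40)
  cv <- progress_curve(times, closed_form_progress(s0, Vmax, KM, times), s0)
  lin <- linearize_and_fit(cv)
  expect_equal(lin$km_over_vmax, 100, tolerance = 1e-6)
  expect_equal(lin$inv_vmax, 1e6, tolerance = 1e-6)
  expect_gt(lin$r_squared, 1 - 1e-10)
  # doubling all times doubles both intercept and slope
  cv2 <- progress_curve(2 * times, cv$substrate, s0)
  lin2 <- linearize_and_fit(cv2)
  expect_equal(lin2$km_over_vmax, 2 * lin$km_over_vmax, tolerance = 1e-9)
  expect_equal(lin2$inv_vmax, 2 * lin$inv_vmax, tolerance = 1e-9)
})

test_that("conversion filter excludes s = s0 points instead of erroring", {
  s0 <- 1e-4
  times <- c(1e-6, seq(10, 400, length.out = 39))
  s <- closed_form_progress(s0, 1e-6, 1e-4, times)
  s[1] <- s0 # conversion 0: must be filtered, not fatal
  cv <- progress_curve(times, s, s0)
  lin <- linearize_and_fit(cv)
  expect_lt(lin$n_points, length(times))
  expect_equal(lin$km_over_vmax, 100, tolerance = 1e-6)
  # too few usable points is a defined error
  cv5 <- progress_curve(times[1:5], s[1:5], s0)
  expect_error(linearize_and_fit(cv5), "fewer than 5 usable")
})

test_that("inhibition fit is exact on constructed apparent values", {
  K_I <- 3.4e-4 # SArg-like scenario
  I <- c(0, 1e-4, 3e-4, 1e-3)
  app <- 50 * (1 + I / K_I)
  fit <- fit_inhibition(data.frame(I = I, km_over_vmax = app))
  expect_true(fit$determinable)
  expect_equal(fit$K_I, 3.4e-4, tolerance = 1e-12)
  expect_equal(fit$km_over_vmax_0, 50, tolerance = 1e-12)
  # flat response -> no measurable inhibition, not a number
  flat <- fit_inhibition(data.frame(I = I, km_over_vmax = rep(50, 4)))
  expect_false(flat$determinable)
  expect_true(is.na(flat$K_I))
  expect_error(fit_inhibition(data.frame(I = 0:1, km_over_vmax = c(1, 2))),
               ">= 3")
})

test_that("noiseless end-to-end pipeline returns the generating K_I", {
  fit <- run_ki_pipeline(noise_sd = 0, seed = 1)
  expect_equal(fit$K_I, kin_world()$K_I, tolerance = 1e-6)
  expect_equal(fit$km_over_vmax_0, 100, tolerance = 1e-6)
})

test_that("competitive signature: I = K_I doubles the intercept, slope invariant", {
  w <- kin_world()
  lin0 <- local({
    t90 <- time_to_conversion(w$s0, w$params$Vmax, w$params$KM, 0.9)
    times <- seq(t90 / 40, t90, length.out = 40)
    linearize_and_fit(simulate_progress_curve(w$params, w$K_I, 0, w$s0, times))
  })
  linK <- local({
    t90 <- time_to_conversion(w$s0, w$params$Vmax, w$params$KM, 0.9, 2)
    times <- seq(t90 / 40, t90, length.out = 40)
    linearize_and_fit(simulate_progress_curve(w$params, w$K_I, w$K_I, w$s0,
                                              times))
  })
  expect_equal(linK$km_over_vmax, 2 * lin0$km_over_vmax, tolerance = 0.01)
  expect_equal(linK$inv_vmax, lin0$inv_vmax, tolerance = 0.01)
})

test_that("curve files round-trip, absorbance traces convert", {
  w <- kin_world()
  times <- seq(5, 300, by = 5)
  cv <- simulate_progress_curve(w$params, w$K_I, w$K_I, w$s0, times,
                                noise_sd = 1e-6, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_progress_curve(cv, f)
  cv2 <- read_progress_curve(f)
  expect_equal(cv2$substrate, cv$substrate, tolerance = 1e-9)
  expect_equal(cv2$I, w$K_I)
  # absorbance variant: A = A0 - eps * L * (s0 - s), trace starting at t = 0
  ta <- seq(0, 300, by = 5)
  sa <- closed_form_progress(w$s0, w$params$Vmax, w$params$KM, ta)
  A <- 0.5 - 376 * 1 * (w$s0 - sa)
  fa <- tempfile(fileext = ".tsv")
  writeLines(c(sprintf("#s0=%g", w$s0), "#I=0", "#epsilon=376", "#path_cm=1",
               "time_s\tabsorbance_AU",
               sprintf("%g\t%.10g", ta, A)), fa)
  cva <- read_progress_curve(fa)
  expect_equal(cva$substrate, sa, tolerance = 1e-6)
})
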