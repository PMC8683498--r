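test_that("viability normalization divides by the control mean", {
  expect_equal(normalize_viability(5, c(5, 5, 5)), 1)
  expect_equal(normalize_viability(0, c(4, 6)), 0)
  ## triplicate controls around c: raw c normalizes to 1
  expect_equal(normalize_viability(100, c(90, 100, 110)), 1)
  expect_error(normalize_viability(1, c(0, 0)), "control mean")
})

test_that("relative AUC is exact for constant viability and linear in it", {
  conc <- 1000 / 2^(0:8)
  expect_equal(relative_auc(conc, rep(1, 9)), 100)
  expect_equal(relative_auc(conc, rep(0.5, 9)), 50)
  expect_equal(relative_auc(conc, rep(0, 9)), 0)
  ## linearity: auc(alpha * v) = alpha * auc(v)
  set.seed(1)
  v <- runif(9, 0.2, 1)
  for (alpha in c(0.25, 0.5, 0.9))
    expect_equal(relative_auc(conc, alpha * v),
                 alpha * relative_auc(conc, v), tolerance = 1e-12)
  ## zero-dose point is excluded from the log axis, not an error
  expect_equal(relative_auc(c(0, conc), c(1, rep(0.5, 9))), 50)
  expect_error(relative_auc(c(0, 10), c(1, 1)), ">= 2 nonzero")
})

test_that("log-logistic fit recovers noiseless parameters", {
  x <- 10^seq(-1, 3, length.out = 9)
  truth <- list(lower = 0, upper = 1, ec50 = 10, slope = 1)
  y <- truth$lower + (truth$upper - truth$lower) /
    (1 + (truth$ec50 / x)^truth$slope)
  f <- fit_loglogistic(x, y)
  expect_equal(f$lower, 0, tolerance = 1e-6)
  expect_equal(f$upper, 1, tolerance = 1e-6)
  expect_equal(f$ec50, 10, tolerance = 1e-5)
  expect_equal(f$slope, 1, tolerance = 1e-6)
  ## steeper curve with shifted asymptotes
  y2 <- 0.1 + 0.75 / (1 + (50 / x)^2.5)
  f2 <- fit_loglogistic(x, y2)
  expect_equal(f2$ec50, 50, tolerance = 1e-3)
  expect_equal(f2$slope, 2.5, tolerance = 1e-3)
})

test_that("degenerate and flipped responses are handled explicitly", {
  x <- c(1, 3, 10, 30, 100)
  f0 <- fit_loglogistic(x, rep(0, 5))
  expect_true(f0$degenerate)
  expect_equal(f0$lower, 0)
  expect_equal(f0$upper, 0)
  ## viability handed in instead of inhibition: flipped with warning
  v <- 1 - 1 / (1 + (10 / x))
  expect_warning(ff <- fit_loglogistic(x, v), "flipping")
  expect_true(ff$flipped)
  expect_equal(ff$ec50, 10, tolerance = 1e-4)
})

test_that("ZIP delta vanishes on an exactly Bliss-independent matrix", {
  m <- simulate_dose_response(delta_true = 0, noise_sd = 0, seed = 1)
  z <- zip_delta(m)
  expect_lt(max(abs(z$delta)), 1e-6)
  expect_lt(abs(z$summary), 1e-6)
})

test_that("an inert partner drug gives zero ZIP delta", {
  m <- simulate_dose_response(ec50_b = 1e12, delta_true = 0, noise_sd = 0,
                              seed = 2)
  z <- zip_delta(m)
  expect_lt(max(abs(z$delta)), 1e-4)
})

test_that("ZIP null summaries center at zero and shrink with noise", {
  s_lo <- vapply(1:10, function(s) zip_delta(
    simulate_dose_response(delta_true = 0, noise_sd = 0.005, seed = s)
  )$summary, 0)
  s_hi <- vapply(1:10, function(s) zip_delta(
    simulate_dose_response(delta_true = 0, noise_sd = 0.04, seed = s)
  )$summary, 0)
  expect_lt(abs(mean(s_lo)), 0.01)
  expect_lt(mean(abs(s_lo)), mean(abs(s_hi)))
})

test_that("injected synergy is recovered by the delta surface", {
  ## the full-grid mean is the unbiased estimator of a uniform offset
  z <- zip_delta(simulate_dose_response(delta_true = 0.2, noise_sd = 0,
                                        seed = 1))
  expect_equal(mean(z$delta), 0.2, tolerance = 0.03)
  ## the top-9 summary reports the most synergistic region, which sits
  ## above the injected offset by the refit's structural overshoot
  expect_gt(z$summary, 0.2)
  expect_lt(z$summary, 0.28)
  ## antagonism pushes the surface clearly negative (low-dose cells clip at
  ## zero inhibition, so the full offset is not recoverable by construction)
  za <- zip_delta(simulate_dose_response(delta_true = -0.2, noise_sd = 0,
                                         seed = 1))
  expect_lt(mean(za$delta), -0.08)
})

test_that("summary equals the full-matrix mean with exactly 9 nonzero cells", {
  conc_a <- c(0, 1, 10, 100)
  conc_b <- c(0, 1, 10, 100)
  ya <- loglog <- function(x, e) ifelse(x > 0, 1 / (1 + e / x), 0)
  inh <- outer(loglog(conc_b, 10), loglog(conc_a, 10),
               function(b, a) a + b - a * b) + 0.05
  inh[1, 1] <- 0
  m <- dose_matrix(1 - inh, conc_a, conc_b)
  z <- zip_delta(m, n_top = 9)
  expect_equal(z$summary, mean(z$delta), tolerance = 1e-12)
  ## contiguous-window option agrees when the window is the whole grid
  z2 <- zip_delta(m, top_mode = "window")
  expect_equal(z2$summary, mean(z$delta), tolerance = 1e-12)
})

test_that("3-D ZIP reduces to 2-D with an inert third drug", {
  base <- simulate_dose_response(delta_true = 0.1, noise_sd = 0, seed = 5)
  stack <- list(base, base)  # both layers at zero third-drug effect
  res <- zip_delta_3d(stack, conc_c = c(0, 0))
  z2d <- zip_delta(base)
  for (k in 1:2)
    expect_equal(res$layers[[k]]$delta, z2d$delta, tolerance = 1e-6)
  expect_equal(res$y_c, c(0, 0))
})

test_that("triple-Bliss cubes give near-zero deviations, all-inert gives zero", {
  ca <- c(0, 300 / 3^(4:0)); cb <- c(0, 100 / 3^(4:0))
  ya <- loglogistic <- function(x, e) ifelse(x > 0, 1 / (1 + e / x), 0)
  stack <- lapply(c(0, 0.2, 0.4), function(yc) {
    inh <- outer(loglogistic(cb, 100), loglogistic(ca, 300),
                 function(b, a) 1 - (1 - a) * (1 - b) * (1 - yc))
    dose_matrix(1 - inh, ca, cb)
  })
  res <- zip_delta_3d(stack, conc_c = c(0, 1, 2))
  expect_equal(res$y_c, c(0, 0.2, 0.4), tolerance = 1e-9)
  expect_lt(max(abs(res$cube)), 1e-5)
  ## all three inert: zero cube
  inert <- dose_matrix(matrix(1, 6, 6), ca, cb)
  res0 <- zip_delta_3d(list(inert, inert), conc_c = c(0, 1))
  expect_equal(max(abs(res0$cube)), 0)
  ## inconsistent axes rejected
  other <- dose_matrix(matrix(1, 6, 6), ca * 2, cb)
  expect_error(zip_delta_3d(list(inert, other)), "inconsistent")
})
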