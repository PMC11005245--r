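cal <- plim_calibration()

test_that("total photons is additive and rejects empty input", {
  p <- plim_protocol(collection_us = 3, bin_width_us = 1)
  d <- decay_histogram(0:2, c(3, 2, 5), protocol = p)
  expect_equal(total_photons(d), 10)
  expect_equal(total_photons(rep(0, 50)), 0)
  expect_equal(total_photons(c(d$counts, d$counts)), 2 * total_photons(d))
  expect_error(total_photons(numeric(0)), "empty")
})

test_that("decay averaging is a per-bin mean, idempotent, grid-checked", {
  p <- plim_protocol(collection_us = 2, bin_width_us = 1)
  d1 <- decay_histogram(0:1, c(0, 2), protocol = p)
  d2 <- decay_histogram(0:1, c(2, 0), protocol = p)
  expect_equal(average_decays(list(d1, d2))$counts, c(1, 1))
  expect_equal(average_decays(list(d1))$counts, d1$counts)
  expect_equal(average_decays(rep(list(d1), 7))$counts, d1$counts)
  p2 <- plim_protocol(collection_us = 2, bin_width_us = 1, excitation_us = 20)
  d3 <- decay_histogram(0:1 + 0.5, c(1, 1), protocol = p)
  expect_error(average_decays(list(d1, d3)), "grid")
})

test_that("Grubbs critical values agree with the t-distribution closed form", {
  for (n in 3:30) {
    tc <- qt(1 - 0.05 / (2 * n), n - 2)
    expect_equal(grubbs_critical(n, 0.05),
                 (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2)))
  }
})

test_that("outlier decay rejection flags the known outlier and keeps clean sets", {
  p <- plim_protocol(collection_us = 1, bin_width_us = 1)
  mk <- function(tot) matrix(tot, ncol = 1)
  # 20 identical totals: zero variance, nothing rejected
  r <- reject_outlier_decays(mk(rep(100, 20)))
  expect_true(all(r$kept))
  # frozen oracle: totals [100, 101, 99, 500] give G = 1.49999 > G_crit(4) = 1.48125
  r <- reject_outlier_decays(mk(c(100, 101, 99, 500)), alpha = 0.05)
  expect_equal(which(!r$kept), 4)
  expect_equal(r$rejections$G, 1.49998750016, tolerance = 1e-9)
  expect_equal(r$rejections$G_crit, 1.48125, tolerance = 1e-5)
  # order of kept entries preserved
  expect_equal(r$totals[r$kept], c(100, 101, 99))
  # fewer than 3 repetitions: pass-through with warning
  expect_warning(r <- reject_outlier_decays(mk(c(1, 1000))), "fewer than 3")
  expect_true(all(r$kept))
})

test_that("iterated rejection removes multiple outliers one at a time", {
  set.seed(42)
  totals <- c(rnorm(18, 1000, 5), 2000, 3000)
  r <- reject_outlier_decays(matrix(totals, ncol = 1))
  expect_setequal(which(!r$kept), c(19, 20))
  expect_equal(nrow(r$rejections), 2)
  # most extreme first
  expect_equal(r$rejections$index[1], 20)
})

test_that("noiseless mono-exponential fit recovers (A, tau, C) exactly", {
  t <- bin_times(plim_protocol())
  y <- 1000 * exp(-t / 20) + 5
  f <- fit_lifetime(y, t = t)
  expect_true(f$converged)
  expect_lt(abs(f$A - 1000) / 1000, 1e-6)
  expect_lt(abs(f$tau - 20) / 20, 1e-6)
  expect_lt(abs(f$C - 5) / 5, 1e-6)
  # window invariance when the model is exact
  f0 <- fit_lifetime(y, t = t, window_start_us = 0)
  expect_equal(f0$tau, f$tau, tolerance = 1e-8)
})

test_that("degenerate fits are flagged, not silently returned", {
  t <- bin_times(plim_protocol())
  expect_error(fit_lifetime(rep(7, length(t)), t = t), "dynamic range")
  expect_error(fit_lifetime(exp(-t / 20), t = t, window_start_us = 400),
               "no bins")
})

test_that("plim_fit pipeline: rejection before averaging, scaling equivariance", {
  set.seed(7)
  decays <- t(replicate(20, simulate_decay(60, cal, photon_budget = 5e4)$counts))
  # inject a motion-corrupted repetition with half the photons
  decays[3, ] <- round(decays[3, ] * 0.2)
  fit <- plim_fit(decays, cal)
  expect_false(fit$kept[3])
  expect_equal(fit$n_kept, 19)
  # scaling every repetition leaves tau and pO2 unchanged
  fit2 <- plim_fit(decays * 4, cal)
  expect_equal(coef(fit2)[["tau"]], coef(fit)[["tau"]], tolerance = 1e-6)
  expect_equal(fit2$po2, fit$po2, tolerance = 1e-4)
  expect_equal(fit2$n_kept, fit$n_kept)
})

test_that("plim_fit S3 methods are coherent", {
  set.seed(8)
  decays <- replicate(20, simulate_decay(40, cal, photon_budget = 5e4),
                      simplify = FALSE)
  fit <- plim_fit(decays, cal)
  expect_s3_class(fit, "plim_fit")
  expect_named(coef(fit), c("A", "tau", "C"))
  expect_equal(fit$so2, po2_to_so2(fit$po2, cal))
  expect_length(fitted(fit), 290)
  expect_equal(residuals(fit), fit$mean_decay$counts - fitted(fit))
  expect_equal(predict(fit, newdata = data.frame(t = 0))[1],
               sum(coef(fit)[c("A", "C")]), ignore_attr = TRUE)
  expect_output(print(fit), "pO2")
  expect_output(print(summary(fit)), "Coefficients")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "decay_histogram")
  # simulated repetitions refit close to the parent fit
  refit <- plim_fit(sims, cal, alpha = NULL)
  expect_equal(coef(refit)[["tau"]], coef(fit)[["tau"]], tolerance = 0.05)
})

test_that("Poisson-noise lifetime recovery tightens with photon budget", {
  set.seed(11)
  tau_true <- po2_to_lifetime(40, cal)
  med_err <- vapply(c(1e4, 1e5, 1e6), function(budget) {
    errs <- replicate(40, {
      d <- simulate_decay(40, cal, photon_budget = budget)
      abs(fit_lifetime(d)$tau - tau_true) / tau_true
    })
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 0.005)
})
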