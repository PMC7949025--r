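test_that("noiseless single-exponential decays are recovered exactly", {
  sch <- hx_schedule()
  d <- data.frame(time_s = sch$time_s,
                  intensity = 100 * exp(-1e-4 * sch$time_s))
  fit <- fit_decay(d)
  expect_equal(fit$status, "measured")
  expect_equal(fit$k_obs, 1e-4, tolerance = 1e-6)
  expect_equal(fit$I0, 100, tolerance = 1e-6)
})

test_that("constant series over the full window hit the slow limit", {
  sch <- hx_schedule()
  set.seed(5)
  d <- data.frame(time_s = sch$time_s,
                  intensity = 100 + rnorm(nrow(sch), 0, 2))
  expect_equal(fit_decay(d)$status, "slow_limit")
})

test_that("series with no signal above the noise floor hit the fast limit", {
  sch <- hx_schedule()
  set.seed(6)
  d <- data.frame(time_s = sch$time_s, intensity = rnorm(nrow(sch), 0, 2))
  expect_equal(fit_decay(d, noise_floor = 6)$status, "fast_limit")
})

test_that("noisy replicate fits are unbiased at the percent level", {
  sch <- hx_schedule()
  k_true <- 5e-5
  set.seed(7)
  ks <- replicate(500, {
    I <- 100 * exp(-k_true * sch$time_s) * (1 + rnorm(nrow(sch), 0, 0.02))
    fit_decay(data.frame(time_s = sch$time_s, intensity = I))$k_obs
  })
  expect_equal(mean(ks), k_true, tolerance = 0.01)
})

test_that("protection converts rate ratios to free energies", {
  sch <- hx_schedule()
  fit <- fit_decay(data.frame(time_s = sch$time_s,
                              intensity = 100 * exp(-2e-4 * sch$time_s)))
  rec <- protection(fit, k_pred = 2e-4, residue = 1)
  expect_equal(rec$logPF, 0, tolerance = 1e-5)
  expect_equal(rec$dG_kJmol, 0, tolerance = 1e-4)
  # linearity in log PF with slope 2.303 R T, checked at three temperatures
  for (T in c(283.15, 294.15, 298.15)) {
    r1 <- protection(fit, k_pred = 2e-3, temperature_K = T)
    r2 <- protection(fit, k_pred = 2e-2, temperature_K = T)
    expect_equal(r2$dG_kJmol - r1$dG_kJmol, 2.303 * 8.314 * T / 1000,
                 tolerance = 1e-6)
  }
})

test_that("the printed free-energy landmarks follow from the conversion", {
  dg <- function(logpf) 2.303 * 8.314 * 298.15 * logpf / 1000
  expect_gte(dg(8.5), 48)
  expect_equal(round(dg(7)), 40)
  expect_equal(dg(7), 39.96, tolerance = 1e-3)
})

test_that("censoring bounds follow the stated limit formulas", {
  s <- data.frame(time_s = c(300, 600, 900), intensity = c(0, 0, 0))
  b <- censor_limits(s, k_pred = 1, max_measured_logPF = 7.0)
  expect_equal(b$upper, log10(1 * 300 / log(20)), tolerance = 1e-12)
  expect_equal(b$upper, 2.0, tolerance = 0.01)
  expect_equal(b$lower, 7.0)
  expect_error(censor_limits(list(time_s = NULL), 1, 7), "first observation")
})

test_that("super-intrinsic exchange triggers a diagnostic warning", {
  sch <- hx_schedule()
  fit <- fit_decay(data.frame(time_s = sch$time_s,
                              intensity = 100 * exp(-1e-3 * sch$time_s)))
  expect_warning(protection(fit, k_pred = 1e-5, residue = 9),
                 "super-intrinsic")
})

test_that("full-profile recovery: statuses and log PF across the ladder", {
  model <- hx_model_default()
  lp <- default_logpf_profile(seed = 101)
  g <- gen_hx_dataset(lp, model, seed = 11)
  prot <- hx_protection(g$data, model)
  j <- match(prot$residue, g$truth$residue)
  truth_lp <- g$truth$logPF[j]
  # non-exchangers are censored slow with a lower bound
  expect_true(all(prot$status[is.infinite(truth_lp)] == "slow_limit"))
  expect_true(all(prot$bound_direction[is.infinite(truth_lp)] == "lower"))
  # unprotected residues (true log PF <= 2) are censored fast
  expect_true(all(prot$status[truth_lp <= 2] == "fast_limit"))
  # measured band recovers log PF closely
  band <- is.finite(truth_lp) & truth_lp >= 3 & truth_lp <= 6.5
  err <- abs(prot$logPF[band] - truth_lp[band])
  err[prot$status[band] != "measured"] <- Inf
  expect_lt(median(err), 0.05)
  # no record is simultaneously measured and bounded
  expect_true(all(is.na(prot$bound_direction[prot$status == "measured"])))
  expect_true(all(!is.na(prot$bound_direction[prot$status != "measured"])))
})

test_that("censoring bounds bracket the truth on the synthetic ladder", {
  model <- hx_model_default()
  lp <- default_logpf_profile(seed = 101)
  g <- gen_hx_dataset(lp, model, seed = 12)
  prot <- hx_protection(g$data, model)
  truth_lp <- g$truth$logPF[match(prot$residue, g$truth$residue)]
  up <- prot$status == "fast_limit"
  expect_true(all(truth_lp[up] <= prot$logPF[up] + 0.75))
  # the slow-exchange bound (largest measured log PF in the sample) must sit
  # below the never-exchanging residues and above the measured band
  lo <- prot$status == "slow_limit" & is.infinite(truth_lp)
  expect_true(any(lo))
  expect_true(all(prot$logPF[lo] >= max(truth_lp[prot$status == "measured"] - 0.5)))
})

test_that("scan-count scaling normalizes intensities across spectra", {
  s <- intensity_series(1, c(0, 10, 20), c(200, 100, 50),
                        n_scans = c(8, 4, 2))
  expect_equal(s$intensity, c(25, 25, 25))
})
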