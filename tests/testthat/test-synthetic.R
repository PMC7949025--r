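test_that("helix-bundle generator produces the annotated construct", {
  s <- gen_helix_bundle(seed = 1)
  expect_equal(nrow(residues(s)), 86L)
  expect_equal(range(residues(s)$resno), c(40L, 125L))
  # i,i+4 N...O distance inside a helix segment is ~3 A
  a <- s$atoms
  d <- function(r1, ety1, r2, ety2) {
    p <- as.numeric(a[a$resno == r1 & a$elety == ety1, c("x", "y", "z")])
    q <- as.numeric(a[a$resno == r2 & a$elety == ety2, c("x", "y", "z")])
    sqrt(sum((p - q)^2))
  }
  for (r in 66:72) expect_lt(d(r + 4, "N", r, "O"), 3.3)
  expect_error(gen_helix_bundle(helix_annotation("H", 10, 20)),
               "outside the construct")
})

test_that("generators are deterministic for a fixed seed", {
  g1 <- gen_shift_tables(c(77, 99), seed = 3)
  g2 <- gen_shift_tables(c(77, 99), seed = 3)
  expect_identical(g1, g2)
  m <- hx_model_default()
  h1 <- gen_hx_dataset(c("70" = 4), m, seed = 3)
  h2 <- gen_hx_dataset(c("70" = 4), m, seed = 3)
  expect_identical(h1, h2)
  t1 <- gen_trajectory(small_helix(), 0.3, 5, seed = 3)
  t2 <- gen_trajectory(small_helix(), 0.3, 5, seed = 3)
  expect_identical(t1$xyz, t2$xyz)
})

test_that("zero-noise trajectory generation returns identical frames", {
  s <- small_helix()
  tr <- gen_trajectory(s, 0, n_frames = 4, seed = 2)
  for (f in 2:4) expect_identical(tr$xyz[, , f], tr$xyz[, , 1])
})

test_that("uniform-sigma trajectories reproduce the sqrt(3) sigma RMSF", {
  tr <- gen_trajectory(small_helix(), 0.3, n_frames = 500, seed = 9)
  rp <- rmsf_profile(tr, align_range = c(5, 16))
  expect_equal(mean(rp$rmsf), sqrt(3) * 0.3, tolerance = 0.05)
})

test_that("exchange generator encodes the protection-factor definition", {
  m <- hx_model_default()
  kp <- predict_intrinsic_rates(m)
  g <- gen_hx_dataset(c("70" = 0, "71" = Inf), m, noise_frac = 0,
                      noise_add = 0, seed = 1)
  d70 <- g$data[g$data$residue == 70, ]
  k70 <- kp$k_pred[kp$resno == 70]
  expect_equal(d70$intensity / d70$n_scans,
               100 * exp(-k70 * d70$time_s), tolerance = 1e-10)
  d71 <- g$data[g$data$residue == 71, ]
  expect_equal(unique(d71$intensity / d71$n_scans), 100)
})

test_that("full synthetic ladder maps onto the expected statuses", {
  # closed-form expectation: an amide is measurable when at least three
  # scheduled spectra retain signal above the noise floor, and shows
  # significant decay when k_obs t_last exceeds the slow-decay minimum
  m <- hx_model_default()
  kp <- predict_intrinsic_rates(m)
  sch <- hx_schedule()
  lp <- c("69" = 2, "70" = 4, "74" = 6, "71" = 8)
  g <- gen_hx_dataset(lp, m, seed = 13)
  prot <- hx_protection(g$data, m)
  expected <- vapply(names(lp), function(r) {
    k <- kp$k_pred[kp$resno == as.integer(r)] / 10^lp[[r]]
    frac <- exp(-k * sch$time_s)
    if (sum(frac > 0.06) < 3) "fast_limit"
    else if (k * max(sch$time_s) < 0.2) "slow_limit"
    else "measured"
  }, character(1))
  expect_equal(setNames(prot$status[match(as.integer(names(lp)),
                                          prot$residue)], names(lp)),
               expected)
  expect_equal(unname(expected),
               c("fast_limit", "measured", "measured", "slow_limit"))
})

test_that("scan generator reproduces the hot-spot count of its truth table", {
  t1 <- etv6_scan_tables()$EH
  truth <- data.frame(mutation = t1$mutation, kon = t1$kon, koff = t1$koff)
  g <- gen_scan_dataset(truth, noise_sd = 0, seed = 1,
                        t_grid = seq(0, 900, by = 10))
  expect_equal(sum(g$truth$hotspot[-1]), 6L)
  expect_equal(nrow(g$sensorgrams) / length(seq(0, 900, by = 10)) / 5,
               nrow(t1))
  same <- data.frame(mutation = c("None", "m1", "m2"), kon = 2e5,
                     koff = 1.5e-3)
  g0 <- gen_scan_dataset(same, noise_sd = 0, seed = 1,
                         t_grid = seq(0, 900, by = 10))
  expect_equal(sum(g0$truth$hotspot[-1]), 0L)
})

test_that("default-range shift tables recover most interface residues", {
  truth <- etv6_interfaces()$EH$residues
  hits <- vapply(1:50, function(sd) {
    g <- gen_shift_tables(truth, seed = sd)
    flagged <- classify_interface(compute_csp(g$free, g$bound), 0.2)
    length(intersect(flagged, g$interface)) / length(g$interface)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
  # zero-magnitude, zero-noise tables are identical
  g0 <- gen_shift_tables(truth, dh_range = c(0, 0), dn_range = c(0, 0),
                         background_sd = 0, seed = 1)
  r0 <- compute_csp(g0$free, g0$bound)
  expect_true(all(r0$csp_ppm == 0))
  one <- gen_shift_tables(77, dh_range = c(0.3, 0.3),
                          dn_range = c(1, 1), background_sd = 0, seed = 1)
  expect_equal(classify_interface(compute_csp(one$free, one$bound)), 77L)
})
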