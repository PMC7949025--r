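test_that("superposition is exact for rigid transformations", {
  s <- small_helix()
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  fit0 <- superpose(X, X)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$R, diag(3), tolerance = 1e-8)
  Y <- sweep(X %*% rot_z(90), 2, c(5, -3, 2), "+")
  fit <- superpose(Y, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$coords, X, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("superposed RMSD matches an independent reference fit", {
  # displaced-vertex tetrahedron, cross-checked against bio3d
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  B <- A; B[4, ] <- B[4, ] + c(0, 0, 1)
  Brot <- sweep(B %*% rot_z(35), 2, c(2, 1, -1), "+")
  mine <- superpose(Brot, A)$rmsd
  oracle <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(Brot)),
                        fit = TRUE)
  expect_equal(mine, oracle, tolerance = 1e-3)
  expect_error(superpose(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 0))),
               "degenerate")
})

test_that("RMSD series vanish for static and rigidly rotating trajectories", {
  s <- small_helix()
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  tr <- static_traj(s, 5)
  expect_equal(rmsd_series(tr, c(1, 20))$rmsd, rep(0, 5), tolerance = 1e-10)
  xyz <- array(NA_real_, c(nrow(X), 3, 6))
  for (f in 1:6) xyz[, , f] <- sweep(X %*% rot_z(30 * (f - 1)), 2,
                                     c(f, 0, -f), "+")
  rot <- pnt_trajectory(s, xyz, 100)
  expect_equal(rmsd_series(rot, c(1, 20))$rmsd, rep(0, 6), tolerance = 1e-8)
  expect_equal(rmsd_series(rot, c(1, 20))$time_ns, 0.1 * (0:5))
  expect_error(rmsd_series(tr, c(500, 600)), "empty selection")
})

test_that("Gaussian displacement RMSD matches the analytic expectation", {
  s <- gen_helix_bundle()
  tr <- gen_trajectory(s, 0.5, n_frames = 200, seed = 3)
  rs <- rmsd_series(tr, c(40, 125), atom_class = "all")
  # both frames carry sigma = 0.5 noise: E[rmsd] ~ sqrt(6) * sigma
  expect_equal(mean(rs$rmsd[-1]), sqrt(6) * 0.5, tolerance = 0.1)
})

test_that("RMSF recovers the isotropic closed form and profile shape", {
  s <- small_helix()
  tr <- gen_trajectory(s, 0.3, n_frames = 500, seed = 4)
  rp <- rmsf_profile(tr, align_range = c(5, 16))
  expect_equal(mean(rp$rmsf), sqrt(3) * 0.3, tolerance = 0.05)
  expect_error(rmsf_profile(static_traj(s, 1)), "at least 2 frames")
  expect_equal(rmsf_profile(static_traj(s, 3))$rmsf, rep(0, 20),
               tolerance = 1e-10)
  # terminal residues at 3x the core sigma stand out in the profile
  sig <- setNames(rep(0.2, 20), 1:20)
  sig[c("1", "2", "19", "20")] <- 0.6
  tr2 <- gen_trajectory(s, sig, n_frames = 300, seed = 5)
  rp2 <- rmsf_profile(tr2, align_range = c(5, 16))
  expect_gt(min(rp2$rmsf[rp2$resno %in% c(1, 2, 19, 20)]),
            2 * median(rp2$rmsf[rp2$resno %in% 5:16]))
})

test_that("RMSF is invariant under global rigid motion of all frames", {
  s <- small_helix()
  tr <- gen_trajectory(s, 0.3, n_frames = 60, seed = 6)
  moved <- tr
  for (f in seq_len(n_frames(tr))) {
    moved$xyz[, , f] <- sweep(tr$xyz[, , f] %*% rot_z(77), 2,
                              c(10, -4, 3), "+")
  }
  expect_equal(rmsf_profile(moved, align_range = c(5, 16))$rmsf,
               rmsf_profile(tr, align_range = c(5, 16))$rmsf,
               tolerance = 1e-8)
  # duplicating the trajectory leaves the RMSF unchanged
  dup <- pnt_trajectory(s, array(c(tr$xyz, tr$xyz),
                                 c(dim(tr$xyz)[1], 3, 2 * n_frames(tr))),
                        100)
  expect_equal(rmsf_profile(dup, align_range = c(5, 16))$rmsf,
               rmsf_profile(tr, align_range = c(5, 16))$rmsf,
               tolerance = 1e-10)
})

test_that("delta-RMSF classifies at the symmetric 0.3 A threshold", {
  a <- data.frame(chain = "A", resno = 1:5, rmsf = c(1, 1, 1, 1, 1))
  same <- delta_rmsf(a, a)
  expect_true(all(same$class == "neutral"))
  b <- a; b$rmsf <- a$rmsf + 0.5
  expect_true(all(delta_rmsf(a, b)$class == "reduced_in_a"))
  c3 <- a; c3$rmsf <- a$rmsf - c(0, 0.29, 0.299, 0.31, 0.8)
  expect_equal(delta_rmsf(a, c3)$class,
               c("neutral", "neutral", "neutral", "reduced_in_b",
                 "reduced_in_b"))
  expect_error(delta_rmsf(a, a[1:3, ]), "different residues")
})

test_that("damped-interface heterodimer chains are flagged by delta-RMSF", {
  s <- gen_heterodimer()
  damped <- etv6_interfaces()$EH$residues
  sig <- expand.grid(chain = c("A", "B"), resno = 40:125,
                     stringsAsFactors = FALSE)
  sig$sigma <- 0.45
  sig$sigma[sig$chain == "B" & sig$resno %in% damped] <- 0.05
  tr <- gen_trajectory(s, sig, n_frames = 150, seed = 8)
  rp <- rmsf_profile(tr, align_range = c(57, 120))
  dr <- delta_rmsf(rp[rp$chain == "A", ], rp[rp$chain == "B", ])
  expect_equal(sort(dr$resno[dr$class == "reduced_in_b"]), sort(damped))
})

test_that("PCA variance fractions behave analytically on mode fixtures", {
  s <- small_helix()
  nf <- 40
  ph <- 2 * pi * (1:nf) / nf
  xyz <- array(rep(as.matrix(s$atoms[, c("x", "y", "z")]), nf),
               c(nrow(s$atoms), 3, nf))
  # two orthogonal oscillation modes with amplitude ratio 2:1
  xyz[1, 1, ] <- xyz[1, 1, ] + 2 * sin(ph)
  xyz[5, 2, ] <- xyz[5, 2, ] + 1 * sin(ph + pi / 2)
  tr <- pnt_trajectory(s, xyz, 100)
  pc <- traj_pca(tr, c(1, 20), atom_class = "all", align = FALSE)
  expect_equal(sum(pc$variance_fractions), 1)
  expect_equal(pc$variance_fractions[1:2], c(0.8, 0.2), tolerance = 1e-8)
  # single-mode fixture: all variance on the first component
  xyz1 <- array(rep(as.matrix(s$atoms[, c("x", "y", "z")]), nf),
                c(nrow(s$atoms), 3, nf))
  xyz1[1, 1, ] <- xyz1[1, 1, ] + sin(ph)
  pc1 <- traj_pca(pnt_trajectory(s, xyz1, 100), c(1, 20),
                  atom_class = "all", align = FALSE)
  expect_equal(pc1$variance_fractions[1], 1, tolerance = 1e-10)
  # reconstruction from all components reproduces the centered data
  Xc <- t(vapply(seq_len(nf), function(f) as.numeric(xyz[, , f]),
                 numeric(3 * nrow(s$atoms)))) |> scale(scale = FALSE)
  back <- pc$projections %*% t(pc$rotation[, seq_len(ncol(pc$projections))])
  full <- traj_pca(tr, c(1, 20), atom_class = "all", align = FALSE,
                   k = length(pc$eigenvalues))
  back_full <- full$projections %*% t(full$rotation)
  expect_equal(back_full, unclass(Xc), ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(pc$eigenvalues >= -1e-12))
})

test_that("ideal helix amides hydrogen bond to the i-4 carbonyl", {
  s <- small_helix()
  hb <- hbond_persistence(static_traj(s))
  mid <- hb[hb$resno %in% 10:14, ]
  expect_true(all(mid$bonded))
  expect_equal(mid$partner1, paste0("A", mid$resno - 4))
  expect_true(all(mid$dist1 < 3.2))
  # static trajectory equals the single-frame calculation
  hb3 <- hbond_persistence(static_traj(s, 3))
  expect_equal(hb3, hb)
})

test_that("extended chains have no backbone hydrogen bonds", {
  seqv <- setNames(rep("A", 20), 1:20)
  ext <- gen_helix_bundle(helix_annotation(character(0), integer(0),
                                           integer(0)), sequence = seqv)
  hb <- hbond_persistence(static_traj(ext))
  expect_false(any(hb$bonded))
})

test_that("the 3.5 A hydrogen-bond rule is inclusive at the boundary", {
  atoms <- data.frame(
    chain = "A", resno = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 5L, 5L, 5L, 5L),
    resid = "ALA",
    elety = rep(c("N", "CA", "C", "O"), 3),
    x = c(0, 1.4, 2, 1.3,   20, 21.4, 22, 21.3,   0, 1.4, 2, 1.3),
    y = c(0, 0, 1.4, 2.4,   0, 0, 1.4, 2.4,       3.5, 4.5, 5.5, 0),
    z = 0, o = 1, b = 0)
  # residue 2 amide N sits exactly 3.5 A from residue 5's carbonyl? build
  # directly: N(2) at (20,0,0); place O(5) at (20, 3.5, 0)
  atoms$x[12] <- 20; atoms$y[12] <- 3.5; atoms$z[12] <- 0
  s <- pnt_structure(atoms)
  hb <- hbond_persistence(static_traj(s))
  r2 <- hb[hb$resno == 2, ]
  expect_equal(r2$dist1, 3.5)
  expect_true(r2$bonded)
})

test_that("prolines and chain-initial residues carry no amide", {
  seqv <- setNames(c("A", "A", "P", "A", "A"), 1:5)
  s <- gen_helix_bundle(helix_annotation("H", 1, 5), sequence = seqv)
  hb <- hbond_persistence(static_traj(s))
  expect_false(1 %in% hb$resno)
  expect_false(3 %in% hb$resno)
})

test_that("hydrogen bonding and HX protection cross-tabulate correctly", {
  hb <- data.frame(chain = "A", resno = 1:6,
                   bonded = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  prot <- data.frame(residue = 1:6,
                     logPF = c(5, 6, 7, 1.2, 2.0, 2.5),
                     status = c("measured", "measured", "slow_limit",
                                "fast_limit", "fast_limit", "measured"))
  ct <- compare_hbond_pf(hb, prot, logpf_floor = 3)
  expect_equal(as.numeric(ct$table), c(3, 0, 1, 2))
  # all-bonded, all-protected: off-diagonal zeros
  ct2 <- compare_hbond_pf(hb[1:3, ], prot[1:3, ])
  expect_equal(as.numeric(ct2$table), c(3, 0, 0, 0))
  expect_error(compare_hbond_pf(hb, prot[0, ]), "no shared residues")
})
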