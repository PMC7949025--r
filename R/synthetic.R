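# Synthetic fixture generators: ideal-geometry helix bundles, Gaussian
# fluctuation trajectories, exchange-decay datasets, sensorgram scan sets,
# and perturbed shift tables. Each generator is deterministic for a fixed
# seed and returns the ground truth alongside the data.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Place atom D from A-B-C with given bond length C-D, angle B-C-D (deg) and
# torsion A-B-C-D (deg). Natural extension reference frame construction.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  c + bond * (-bc * cos(th) + m * sin(th) * cos(chi) + n * sin(th) * sin(chi))
}

# Ideal backbone internal coordinates (Angstrom / degrees)
.BB_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                 b_c_o = 1.231, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                 a_c_n_ca = 121.7, a_ca_c_o = 120.8, omega = 180)

#' Generate an ideal-geometry helix-bundle backbone
#'
#' Builds an N-CA-C-O backbone with ideal alpha-helical dihedrals
#' (phi = -57, psi = -47) inside the annotated segments and extended
#' dihedrals elsewhere. With an empty segment list the chain is fully
#' extended. The construction is deterministic.
#'
#' @param segments a [helix_annotation()] (default [etv6_helices()]); pass a
#'   zero-row annotation for a fully extended chain.
#' @param sequence named one-letter sequence (names = residue numbers);
#'   default [etv6_construct()].
#' @param chain chain identifier.
#' @param phi_psi_helix,phi_psi_extended dihedral pairs (degrees).
#' @param seed accepted for generator-interface uniformity; the geometry is
#'   deterministic and does not consume randomness.
#' @return A [pnt_structure()].
#' @export
gen_helix_bundle <- function(segments = etv6_helices(),
                             sequence = etv6_construct(), chain = "A",
                             phi_psi_helix = c(-57, -47),
                             phi_psi_extended = c(-135, 135),
                             seed = NULL) {
  resno <- as.integer(names(sequence))
  if (nrow(segments)) {
    if (min(segments$start) < min(resno) || max(segments$end) > max(resno)) {
      stop("helix segments outside the construct range")
    }
  }
  in_helix <- resno %in% (if (nrow(segments)) helix_residues(segments) else integer(0))
  phi <- ifelse(in_helix, phi_psi_helix[1], phi_psi_extended[1])
  psi <- ifelse(in_helix, phi_psi_helix[2], phi_psi_extended[2])
  g <- .BB_GEOM
  n <- length(resno)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  a1 <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(a1), sin(a1), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                             g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          g$b_c_o, g$a_ca_c_o, psi[i] - 180)
  }
  resid3 <- bio3d::aa123(unname(sequence))
  atoms <- data.frame(
    chain = chain,
    resno = rep(resno, each = 4L),
    resid = rep(resid3, each = 4L),
    elety = rep(c("N", "CA", "C", "O"), n),
    x = as.numeric(t(cbind(N[, 1], CA[, 1], C[, 1], O[, 1]))),
    y = as.numeric(t(cbind(N[, 2], CA[, 2], C[, 2], O[, 2]))),
    z = as.numeric(t(cbind(N[, 3], CA[, 3], C[, 3], O[, 3]))),
    o = 1, b = 0, stringsAsFactors = FALSE)
  pnt_structure(atoms)
}

#' Generate a two-chain heterodimer model
#'
#' Two ideal helix bundles side by side (chains `A` and `B`, the second
#' translated by `offset`), standing in for a monomer/monomer heterodimer.
#'
#' @inheritParams gen_helix_bundle
#' @param offset translation (Angstrom) applied to chain B.
#' @return A [pnt_structure()] with two chains.
#' @export
gen_heterodimer <- function(segments = etv6_helices(),
                            sequence = etv6_construct(),
                            offset = c(40, 0, 0), seed = NULL) {
  a <- gen_helix_bundle(segments, sequence, chain = "A")
  b <- gen_helix_bundle(segments, sequence, chain = "B")
  b$atoms$x <- b$atoms$x + offset[1]
  b$atoms$y <- b$atoms$y + offset[2]
  b$atoms$z <- b$atoms$z + offset[3]
  pnt_structure(rbind(a$atoms, b$atoms))
}

# Resolve a per-atom sigma vector from a scalar, a named per-residue vector,
# or a data frame (chain, resno, sigma).
.atom_sigma <- function(ref, sigma) {
  a <- ref$atoms
  if (is.data.frame(sigma)) {
    key <- paste(a$chain, a$resno)
    s <- sigma$sigma[match(key, paste(sigma$chain, sigma$resno))]
  } else if (!is.null(names(sigma))) {
    s <- sigma[as.character(a$resno)]
  } else {
    s <- rep(sigma[1], nrow(a))
  }
  if (anyNA(s)) stop("sigma profile does not cover every residue")
  if (any(s < 0)) stop("negative sigma")
  as.numeric(s)
}

#' Generate a Gaussian-fluctuation trajectory about a reference structure
#'
#' Every frame is the reference plus independent per-atom Gaussian
#' displacements whose per-component standard deviation is the residue's
#' sigma; an optional rigid-body jitter (random small rotation and
#' translation per frame) can be superimposed to emulate imperfectly removed
#' global motion.
#'
#' @param ref a [pnt_structure()] reference.
#' @param sigma scalar, named per-residue vector, or data frame with
#'   `chain`, `resno`, `sigma` (Angstrom per component).
#' @param n_frames number of frames.
#' @param interval_ps frame spacing (ps; 100 ps mirrors a typical recording
#'   stride).
#' @param seed integer seed.
#' @param rigid_sd optional rigid-body jitter: translation sd (Angstrom) and
#'   rotation sd (degrees) as `c(trans, rot)`; `NULL` for none.
#' @return A [pnt_trajectory()].
#' @export
gen_trajectory <- function(ref, sigma, n_frames, interval_ps = 100,
                           seed = 1, rigid_sd = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .atom_sigma(ref, sigma)
  nat <- nrow(ref$atoms)
  base <- as.matrix(ref$atoms[, c("x", "y", "z")])
  xyz <- array(NA_real_, c(nat, 3, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- base + matrix(rnorm(nat * 3, 0, s), nat, 3)
    if (!is.null(rigid_sd)) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- rnorm(1, 0, rigid_sd[2]) * pi / 180
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      ctr <- colMeans(fr)
      fr <- sweep(sweep(fr, 2, ctr) %*% t(R), 2,
                  ctr + rnorm(3, 0, rigid_sd[1]), "+")
    }
    xyz[, , f] <- fr
  }
  pnt_trajectory(ref, xyz, interval_ps)
}

#' Generate a serial-spectra exchange dataset with known protection factors
#'
#' For each residue with a finite true log PF, the observed rate is
#' \eqn{k_{obs} = k_{pred}/10^{\log PF}} with the intrinsic rate predicted
#' from the model's sequence and conditions; residues with `log_pf = Inf`
#' never exchange. Raw intensities follow
#' \eqn{I_0 e^{-k_{obs} t}(1+\epsilon) + \delta} scaled by the spectrum's
#' acquisition count, with multiplicative noise `noise_frac` and an additive
#' baseline-noise term `noise_add` (fraction of I0) emulating spectral
#' thermal noise.
#'
#' @param log_pf named numeric vector of true log10 protection factors
#'   (names = residue numbers; `Inf` for non-exchangers).
#' @param model an [intrinsic_rate_model()] covering those residues.
#' @param schedule data frame with `time_s`, `n_scans` (default
#'   [hx_schedule()]).
#' @param noise_frac multiplicative intensity noise (fraction).
#' @param noise_add additive baseline noise (fraction of I0).
#' @param I0 per-scan reference intensity at t = 0.
#' @param seed integer seed.
#' @return List with `data` (columns `residue`, `time_s`, `intensity`,
#'   `n_scans`) and `truth` (columns `residue`, `logPF`, `k_pred`, `k_obs`).
#' @export
gen_hx_dataset <- function(log_pf, model, schedule = hx_schedule(),
                           noise_frac = 0.02, noise_add = 0.02, I0 = 100,
                           seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  rates <- predict_intrinsic_rates(model)
  resno <- as.integer(names(log_pf))
  k_pred <- rates$k_pred[match(resno, rates$resno)]
  if (anyNA(k_pred)) {
    stop("no intrinsic-rate prediction for residue(s): ",
         paste(resno[is.na(k_pred)], collapse = ", "))
  }
  k_obs <- ifelse(is.infinite(log_pf), 0, k_pred / 10^log_pf)
  rows <- vector("list", length(resno))
  for (j in seq_along(resno)) {
    clean <- I0 * exp(-k_obs[j] * schedule$time_s)
    eps <- rnorm(nrow(schedule), 0, noise_frac)
    delta <- rnorm(nrow(schedule), 0, noise_add * I0)
    rows[[j]] <- data.frame(residue = resno[j], time_s = schedule$time_s,
                            intensity = (clean * (1 + eps) + delta) *
                              schedule$n_scans,
                            n_scans = schedule$n_scans)
  }
  list(data = do.call(rbind, rows),
       truth = data.frame(residue = resno, logPF = unname(log_pf),
                          k_pred = k_pred, k_obs = k_obs))
}

#' Generate an alanine-scan sensorgram dataset with known kinetics
#'
#' Simulates a full concentration series for every mutant with shared
#' surface capacity and Gaussian noise, and tabulates the derived truth
#' (K_D, ddG versus the first row, hot-spot flag).
#'
#' @param truth data frame with columns `mutation`, `kon`, `koff`; the first
#'   row is the unmutated-interface reference.
#' @param concentrations analyte concentrations (M); default the standard
#'   high-affinity series 0.2, 2, 20, 40, 60 nM.
#' @param R_max surface capacity (RU).
#' @param t_grid,t_a sampling grid and association end time (s).
#' @param noise_sd Gaussian noise (RU).
#' @param seed integer seed.
#' @param temperature_K temperature for the truth ddG values.
#' @param hotspot_threshold kJ/mol.
#' @return List with `sensorgrams` (stacked data frame with a `mutation`
#'   column) and `truth` (input plus `kd`, `ddG`, `hotspot`).
#' @export
gen_scan_dataset <- function(truth,
                             concentrations = c(0.2, 2, 20, 40, 60) * 1e-9,
                             R_max = 100, t_grid = seq(0, 900, by = 2),
                             t_a = 300, noise_sd = 1, seed = 1,
                             temperature_K = 298.15, hotspot_threshold = 6) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(truth) * length(concentrations))
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    for (C in concentrations) {
      k <- k + 1L
      sg <- simulate_sensorgram(truth$kon[i], truth$koff[i], R_max, C,
                                t_grid, t_a, noise_sd = noise_sd,
                                seed = NULL)
      sg$mutation <- truth$mutation[i]
      out[[k]] <- sg
    }
  }
  truth$kd <- truth$koff / truth$kon
  truth$ddG <- vapply(truth$kd, function(kd) {
    ddg(kd, truth$kd[1], temperature_K = temperature_K)$ddG
  }, numeric(1))
  truth$hotspot <- truth$ddG > hotspot_threshold
  sens <- do.call(rbind, out)
  attr(sens, "t_a") <- t_a
  list(sensorgrams = sens, truth = truth)
}

#' Generate free/bound shift tables with a localized interface perturbation
#'
#' The bound state adds interface perturbations (uniform magnitudes with
#' random signs) on top of small Gaussian background changes, emulating a
#' slow-exchange complex-formation experiment.
#'
#' @param interface residue numbers carrying true perturbations.
#' @param residues all residue numbers of the construct (default the
#'   non-proline residues of [etv6_construct()]).
#' @param dh_range,dn_range uniform magnitude ranges (ppm) for the 1H and
#'   15N perturbations of interface residues.
#' @param background_sd Gaussian background change (ppm, both dimensions).
#' @param seed integer seed.
#' @return List with `free`, `bound` ([shift_table()]s) and `interface`.
#' @export
gen_shift_tables <- function(interface, residues = NULL,
                             dh_range = c(0.1, 0.4), dn_range = c(0.5, 2.0),
                             background_sd = 0.01, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(residues)) {
    sq <- etv6_construct()
    residues <- as.integer(names(sq)[sq != "P"])
  }
  # prolines (and other residues without an observable amide) cannot carry a
  # perturbation; restrict the truth set to the observable residues
  interface <- intersect(interface, residues)
  if (length(interface) == 0L) {
    stop("no interface residue is observable in the construct")
  }
  n <- length(residues)
  base_H <- rnorm(n, 8.3, 0.35)
  base_N <- rnorm(n, 118, 4)
  free <- shift_table(residues, base_H, base_N, state = "free")
  dH <- rnorm(n, 0, background_sd)
  dN <- rnorm(n, 0, background_sd)
  ii <- match(interface, residues)
  dH[ii] <- runif(length(ii), dh_range[1], dh_range[2]) *
    sample(c(-1, 1), length(ii), replace = TRUE)
  dN[ii] <- runif(length(ii), dn_range[1], dn_range[2]) *
    sample(c(-1, 1), length(ii), replace = TRUE)
  bound <- shift_table(residues, base_H + dH, base_N + dN, state = "bound")
  list(free = free, bound = bound, interface = sort(as.integer(interface)))
}
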