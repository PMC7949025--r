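# SPR 1:1 Langmuir kinetics: simulation, global fitting, K_D and
# alanine-scan delta-delta-G with hot-spot classification.

.RT_kJ <- function(temperature_K) .RGAS * temperature_K / 1000

#' Closed-form 1:1 Langmuir sensorgram
#'
#' Association phase: \eqn{R(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})} with
#' \eqn{R_{eq} = R_{max} C / (C + K_D)}; dissociation phase from `t_a`:
#' \eqn{R(t) = R(t_a) e^{-k_{off}(t - t_a)}}.
#'
#' @param t time grid (s).
#' @param C analyte concentration (M).
#' @param k_on,k_off,R_max kinetic parameters (M^-1 s^-1, s^-1, RU).
#' @param t_a association end time (s).
#' @return Numeric response vector (RU).
#' @export
langmuir_response <- function(t, C, k_on, k_off, R_max, t_a) {
  KD <- k_off / k_on
  Req <- R_max * C / (C + KD)
  kobs <- k_on * C + k_off
  Ra <- Req * (1 - exp(-kobs * pmin(t, t_a)))
  Rta <- Req * (1 - exp(-kobs * t_a))
  ifelse(t <= t_a, Ra, Rta * exp(-k_off * (t - t_a)))
}

#' Simulate a noisy sensorgram
#'
#' @inheritParams langmuir_response
#' @param t_grid sampling time grid (s).
#' @param noise_sd Gaussian noise standard deviation (RU).
#' @param seed integer seed; the simulation is reproducible for a fixed seed.
#' @return Data frame of class `sensorgram` with columns `time_s`,
#'   `response_RU`, `concentration_M`, `phase`.
#' @export
simulate_sensorgram <- function(k_on, k_off, R_max, C, t_grid, t_a,
                                noise_sd = 0, seed = NULL) {
  stopifnot(k_on > 0, k_off > 0, R_max > 0, C > 0, t_a <= max(t_grid))
  if (!is.null(seed)) set.seed(seed)
  r <- langmuir_response(t_grid, C, k_on, k_off, R_max, t_a)
  if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
  out <- data.frame(time_s = t_grid, response_RU = r, concentration_M = C,
                    phase = ifelse(t_grid <= t_a, "association", "dissociation"))
  attr(out, "t_a") <- t_a
  class(out) <- c("sensorgram", "data.frame")
  out
}

#' Global 1:1 fit across a concentration series
#'
#' Fits a single `(k_on, k_off, R_max)` triple jointly to all traces by
#' nonlinear least squares (R_max shared, single-surface assumption).
#' `K_D = k_off/k_on` identically, with relative standard errors combined in
#' quadrature.
#'
#' @param sensorgrams one data frame with columns `time_s`, `response_RU`,
#'   `concentration_M` (several concentrations stacked), or a list of
#'   [simulate_sensorgram()] outputs.
#' @param t_a association end time (s); taken from the first sensorgram
#'   attribute if absent.
#' @param start optional named list of starting values.
#' @return Object of class `spr_fit` with elements `k_on`, `k_off`, `R_max`,
#'   standard errors, `K_D`, `K_D_se`, `rms_residual`, `data`, `t_a`.
#' @export
fit_spr_global <- function(sensorgrams, t_a = NULL, start = NULL) {
  if (is.data.frame(sensorgrams)) {
    if (is.null(t_a)) t_a <- attr(sensorgrams, "t_a")
    d <- sensorgrams
  } else {
    if (is.null(t_a)) t_a <- attr(sensorgrams[[1]], "t_a")
    d <- do.call(rbind, lapply(sensorgrams, as.data.frame))
  }
  if (is.null(t_a)) stop("association end time t_a is required")
  concs <- sort(unique(d$concentration_M))
  if (length(concs) < 3L) stop("at least 3 analyte concentrations required")

  if (is.null(start)) {
    # koff from the tail of the highest-concentration dissociation phase
    hi <- d[d$concentration_M == max(concs) & d$time_s > t_a, , drop = FALSE]
    k_off0 <- 1e-3
    if (nrow(hi) > 5L) {
      sl <- tryCatch(-coef(stats::lm(log(pmax(hi$response_RU, 1e-3)) ~
                                       hi$time_s))[[2]],
                     error = function(e) NA_real_)
      if (is.finite(sl) && sl > 0) k_off0 <- sl
    }
    R_max0 <- max(d$response_RU)
    k_on0 <- max(k_off0 / max(concs), 1 / (max(concs) * t_a))
    start <- list(k_on = k_on0, k_off = k_off0, R_max = R_max0)
  }
  fit <- minpack.lm::nlsLM(
    response_RU ~ langmuir_response(time_s, concentration_M, k_on, k_off,
                                    R_max, t_a),
    data = d, start = start,
    lower = c(k_on = 1e-3, k_off = 1e-8, R_max = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  kd <- kd_from_rates(cf[["k_on"]], cf[["k_off"]],
                      se[["k_on"]], se[["k_off"]])
  if (kd$K_D > 100 * max(concs) || kd$K_D < min(concs) / 100) {
    warning("fitted K_D lies far outside the analyte concentration range")
  }
  out <- list(k_on = cf[["k_on"]], k_off = cf[["k_off"]],
              R_max = cf[["R_max"]],
              k_on_se = se[["k_on"]], k_off_se = se[["k_off"]],
              R_max_se = se[["R_max"]],
              K_D = kd$K_D, K_D_se = kd$K_D_se,
              rms_residual = sqrt(mean(residuals(fit)^2)),
              data = d, t_a = t_a, nls = fit)
  class(out) <- "spr_fit"
  out
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf(paste0("<spr_fit> 1:1 Langmuir global fit (%d concentrations)\n",
                     "  k_on  = %.3g +/- %.2g M^-1 s^-1\n",
                     "  k_off = %.3g +/- %.2g s^-1\n",
                     "  R_max = %.3g RU\n",
                     "  K_D   = %.3g +/- %.2g nM   (RMS residual %.2g RU)\n"),
              length(unique(x$data$concentration_M)),
              x$k_on, x$k_on_se, x$k_off, x$k_off_se, x$R_max,
              x$K_D * 1e9, x$K_D_se * 1e9, x$rms_residual))
  invisible(x)
}

#' @export
coef.spr_fit <- function(object, ...) {
  c(k_on = object$k_on, k_off = object$k_off, R_max = object$R_max)
}

#' @export
predict.spr_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  langmuir_response(d$time_s, d$concentration_M, object$k_on, object$k_off,
                    object$R_max, object$t_a)
}

#' @export
residuals.spr_fit <- function(object, ...) {
  object$data$response_RU - predict(object)
}

#' @export
summary.spr_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Equilibrium dissociation constant from rate constants
#'
#' \eqn{K_D = k_{off}/k_{on}} with relative errors combined in quadrature.
#'
#' @param k_on,k_off rate constants (M^-1 s^-1, s^-1).
#' @param k_on_se,k_off_se their standard errors.
#' @return List with `K_D` (M) and `K_D_se`.
#' @export
kd_from_rates <- function(k_on, k_off, k_on_se = 0, k_off_se = 0) {
  stopifnot(k_on > 0, k_off > 0)
  KD <- k_off / k_on
  list(K_D = KD,
       K_D_se = KD * sqrt((k_off_se / k_off)^2 + (k_on_se / k_on)^2))
}

#' Binding free-energy change of a mutant relative to a reference
#'
#' \eqn{\Delta\Delta G = RT \ln(K_{D,mut}/K_{D,ref})} in kJ/mol, with the
#' relative K_D errors combined in quadrature.
#'
#' @param kd_mut,kd_ref dissociation constants (any common unit).
#' @param kd_mut_se,kd_ref_se their standard errors.
#' @param temperature_K temperature (default 298.15 K, i.e. 25 C).
#' @return List with `ddG` and `ddG_se` (kJ/mol).
#' @export
ddg <- function(kd_mut, kd_ref, kd_mut_se = 0, kd_ref_se = 0,
                temperature_K = 298.15) {
  stopifnot(kd_mut > 0, kd_ref > 0)
  RT <- .RT_kJ(temperature_K)
  list(ddG = RT * log(kd_mut / kd_ref),
       ddG_se = RT * sqrt((kd_mut_se / kd_mut)^2 + (kd_ref_se / kd_ref)^2))
}

#' Annotate an alanine scan with ddG, hot-spot flags and fold categories
#'
#' Hot spots are mutations with ddG strictly greater than
#' `hotspot_threshold` (default 6 kJ/mol). The fold category is the nearest
#' decade of the K_D ratio on a log10 scale (`~1x`, `~10x`, `~100x`,
#' `~1000x`).
#'
#' @param records data frame with columns `mutation`, `kd` (and optionally
#'   `kd_se`), K_D in any common unit.
#' @param reference_kd reference (unmutated-interface) K_D in the same unit;
#'   defaults to the row whose `mutation` is `"None"`.
#' @param reference_kd_se its standard error.
#' @param hotspot_threshold kJ/mol.
#' @param temperature_K temperature for the ddG computation.
#' @return The records with added columns `ddG`, `ddG_se`, `hotspot`,
#'   `fold_category`; attribute `n_hotspots` counts hot spots among mutant
#'   rows.
#' @export
classify_scan <- function(records, reference_kd = NULL, reference_kd_se = 0,
                          hotspot_threshold = 6, temperature_K = 298.15) {
  if (is.null(reference_kd)) {
    i <- which(records$mutation == "None")
    if (length(i) != 1L) stop("no reference: supply reference_kd or a 'None' row")
    reference_kd <- records$kd[i]
    if (!is.null(records$kd_se)) reference_kd_se <- records$kd_se[i]
  }
  kd_se <- if (is.null(records$kd_se)) rep(0, nrow(records)) else records$kd_se
  dd <- Map(function(k, s) {
    ddg(k, reference_kd, s, reference_kd_se, temperature_K = temperature_K)
  }, records$kd, kd_se)
  records$ddG <- vapply(dd, `[[`, numeric(1), "ddG")
  records$ddG_se <- vapply(dd, `[[`, numeric(1), "ddG_se")
  records$hotspot <- records$ddG > hotspot_threshold
  dec <- pmin(pmax(round(log10(records$kd / reference_kd)), 0), 3)
  records$fold_category <- c("~1x", "~10x", "~100x", "~1000x")[dec + 1L]
  attr(records, "n_hotspots") <-
    sum(records$hotspot[records$mutation != "None"])
  records
}

#' Published-style alanine-scan kinetic tables for the ETV6 PNT interfaces
#'
#' Fitted 1:1 kinetic parameters for alanine substitutions within or around
#' the two self-association surfaces of the ETV6 PNT domain: 18 mutations on
#' the EH-surface (A93D-PNT analyte series, V112E-PNT ligand) and 14 on the
#' ML-surface (V112E-PNT analyte series, A93D-PNT ligand), each with an
#' unmutated-interface reference row (`"None"`). Columns: `mutation`, `kon`,
#' `kon_se` (M^-1 s^-1), `koff`, `koff_se` (s^-1), `kd_nM`, `kd_se_nM`,
#' `ddg_kJmol`, `ddg_se_kJmol` (as printed in the source tables).
#'
#' @return Named list of two data frames, `EH` and `ML`.
#' @export
etv6_scan_tables <- function() {
  EH <- data.frame(
    mutation = c("None", "S47A", "I48A", "E76A", "F77A", "S78A", "L79A",
                 "R80A", "K99A", "E100A", "R103A", "P107A", "H108A", "D111A",
                 "V112A", "Y114A", "E115A", "L116A", "H119A"),
    kon = c(2.0e5, 2.1e5, 3.4e5, 6.2e5, 3.4e4, 2.8e6, 8.1e3, 9.1e4, 2.4e3,
            3.1e5, 2.5e5, 2.6e5, 2.6e5, 3.3e3, 2.0e4, 3.5e4, 2.3e5, 2.3e5,
            2.7e5),
    kon_se = c(0.03e5, 0.02e5, 0.03e5, 0.10e5, 0.11e4, 0.58e6, 0.10e3,
               0.11e4, 0.02e3, 0.02e5, 0.27e5, 0.03e5, 0.02e5, 0.04e3,
               0.06e4, 0.04e4, 0.08e5, 0.004e5, 0.02e5),
    koff = c(1.5e-3, 1.4e-3, 4.0e-3, 6.2e-3, 1.5e-2, 9.3e-3, 1.6e-3, 2.9e-3,
             2.3e-3, 1.5e-3, 5.4e-3, 2.1e-3, 1.4e-3, 1.4e-3, 1.1e-2, 4.5e-3,
             2.5e-3, 7.6e-4, 3.4e-3),
    koff_se = c(0.01e-3, 0.01e-3, 0.03e-3, 0.08e-3, 0.04e-2, 1.8e-3,
                0.03e-3, 0.02e-3, 0.01e-3, 0.01e-3, 0.48e-3, 0.01e-3,
                0.005e-3, 0.02e-3, 0.02e-2, 0.03e-3, 0.06e-3, 0.02e-4,
                0.02e-3),
    kd_nM = c(7.5, 6.9, 12, 9.9, 450, 3.3, 200, 32, 930, 5, 21, 8.1, 5.4,
              420, 550, 130, 11, 3.3, 13),
    kd_se_nM = c(0.10, 0.09, 0.15, 0.20, 21, 0.96, 4, 0.4, 9, 0.04, 3, 0.10,
                 0.04, 8, 19, 2, 0.5, 0.01, 0.12),
    ddg_kJmol = c(NA, -0.2, 1.2, 0.7, 10.2, -2.0, 8.2, 3.6, 12.0, -1.0, 2.6,
                  0.2, -0.8, 9.9, 10.7, 7.1, 1.0, -2.0, 1.4),
    ddg_se_kJmol = c(NA, 0.05, 0.05, 0.06, 0.12, 0.71, 0.06, 0.05, 0.04,
                     0.04, 0.35, 0.05, 0.04, 0.06, 0.09, 0.05, 0.12, 0.04,
                     0.04))
  ML <- data.frame(
    mutation = c("None", "I59A", "R63A", "N85A", "E88A", "M89A", "N90A",
                 "K92A", "L96A", "L97A", "T98A", "E100A", "D101A", "Y104A",
                 "R105A"),
    kon = c(4.4e5, 4.3e5, 3.6e5, 3.5e5, 5.0e5, 9.7e4, 7.8e4, 3.5e5, 9.5e3,
            9.8e4, 6.2e5, 5.0e5, 6.3e3, 7.3e5, 2.3e3),
    kon_se = c(0.09e5, 0.03e5, 0.04e5, 0.04e5, 0.03e5, 0.16e4, 0.20e4,
               0.06e5, 1.3e3, 0.16e4, 0.05e5, 0.04e5, 0.12e3, 0.10e5,
               0.11e3),
    koff = c(2.3e-3, 2.5e-3, 5.4e-3, 3.4e-3, 4.0e-3, 3.3e-2, 3.7e-2, 2.2e-2,
             9.5e-3, 6.8e-2, 5.4e-3, 3.5e-3, 2.5e-3, 1.5e-2, 5.4e-3),
    koff_se = c(0.03e-3, 0.01e-3, 0.05e-3, 0.03e-3, 0.02e-3, 0.03e-2,
                0.10e-2, 0.04e-2, 1.1e-3, 0.06e-2, 0.04e-3, 0.02e-3,
                0.04e-3, 0.02e-2, 0.11e-3),
    kd_nM = c(5.1, 5.8, 15, 9.9, 8.1, 340, 480, 62, 1000, 700, 8.8, 7,
              400, 21, 2340),
    kd_se_nM = c(0.13, 0.05, 0.2, 0.13, 0.07, 6, 17, 1.6, 180, 13, 0.09,
                 0.07, 10, 0.37, 120),
    ddg_kJmol = c(NA, 0.3, 2.7, 1.6, 1.1, 10.4, 11.3, 6.2, 13.1, 12.2, 1.3,
                  0.8, 10.8, 3.5, 15.2),
    ddg_se_kJmol = c(NA, 0.06, 0.07, 0.07, 0.06, 0.08, 0.11, 0.09, 0.45,
                     0.08, 0.07, 0.07, 0.09, 0.08, 0.14))
  list(EH = EH, ML = ML)
}
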