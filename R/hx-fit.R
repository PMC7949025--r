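# Amide exchange decay fitting, protection factors, and censoring.

#' Per-residue intensity time course
#'
#' @param residue residue number.
#' @param time_s seconds since transfer into D2O (strictly increasing, >= 0).
#' @param intensity peak intensities. When `n_scans` is given, intensities
#'   are scaled by the number of acquisitions (linear detector assumption)
#'   before storage.
#' @param n_scans optional acquisitions per spectrum (recycled).
#' @param temperature_K,pH_star sample conditions (metadata).
#' @return Data frame of class `intensity_series`.
#' @export
intensity_series <- function(residue, time_s, intensity, n_scans = NULL,
                             temperature_K = NA_real_, pH_star = NA_real_) {
  if (is.unsorted(time_s, strictly = TRUE) || any(time_s < 0)) {
    stop("times must be strictly increasing and non-negative")
  }
  if (!all(is.finite(intensity))) stop("non-finite intensities")
  if (length(time_s) < 3L) stop("at least 3 samples required")
  if (!is.null(n_scans)) intensity <- intensity / n_scans
  out <- data.frame(residue = as.integer(residue), time_s = time_s,
                    intensity = intensity)
  attr(out, "temperature_K") <- temperature_K
  attr(out, "pH_star") <- pH_star
  class(out) <- c("intensity_series", "data.frame")
  out
}

#' Default serial-HSQC acquisition schedule
#'
#' Mimics a typical exchange-out schedule: twelve ~5-min spectra (2 scans) on
#' the minutes timescale starting ~5 min after transfer into D2O, ~20-min
#' spectra (8 scans) back-to-back for ~3 h, one per hour for ~24 h, then
#' intermittent spectra out to three months.
#'
#' @return Data frame with columns `time_s`, `n_scans`.
#' @export
hx_schedule <- function() {
  t5 <- 300 * (1:12)                                   # 5-min spectra
  t20 <- seq(4800, 14400, by = 1200)                   # back-to-back 20-min
  th <- seq(18000, 86400, by = 3600)                   # hourly for a day
  td <- seq(2, 7, by = 1) * 86400                      # daily for a week
  tw <- seq(14, 90, by = 7) * 86400                    # weekly to 3 months
  data.frame(time_s = c(t5, t20, th, td, tw),
             n_scans = c(rep(2L, length(t5)),
                         rep(8L, length(c(t20, th, td, tw)))))
}

# Noise floor: 3 x the robust noise scale of the late-time baseline points,
# estimated from successive differences so a residual slow decay through the
# tail does not inflate the estimate.
.noise_floor <- function(intensity, frac = 0.4, k = 3) {
  nlate <- max(4L, ceiling(frac * length(intensity)))
  late <- tail(intensity, nlate)
  k * mad(diff(late)) / sqrt(2)
}

#' Fit a single-exponential exchange decay
#'
#' Fits \eqn{I_t = I_0 e^{-k_{obs} t}} by unweighted nonlinear least squares.
#' Series with fewer than three samples above the noise floor are censored as
#' `fast_limit` (the amide exchanged before enough spectra were recorded);
#' series without significant decay over the observation window (fitted
#' `k_obs * t_last` below `slow_decay_min`) are censored as `slow_limit`.
#'
#' @param series an [intensity_series()] or data frame with `time_s`,
#'   `intensity`.
#' @param noise_floor absolute intensity below which a point is considered
#'   baseline; default 3x the median absolute deviation of the late-time
#'   baseline points.
#' @param slow_decay_min minimum total fractional decay (as `k * t_last`)
#'   required to report a measured rate.
#' @return Object of class `hx_decay_fit` with elements `k_obs`, `I0`,
#'   `k_obs_se`, `I0_se`, `status`, `residuals`, `data`, `noise_floor`.
#' @export
fit_decay <- function(series, noise_floor = NULL, slow_decay_min = 0.2) {
  t <- series$time_s
  I <- series$intensity
  if (length(t) < 3L) stop("at least 3 samples required for fitting")
  if (is.null(noise_floor)) noise_floor <- .noise_floor(I)
  out <- list(k_obs = NA_real_, I0 = NA_real_, k_obs_se = NA_real_,
              I0_se = NA_real_, status = "measured", residuals = NULL,
              data = data.frame(time_s = t, intensity = I),
              noise_floor = noise_floor)
  class(out) <- "hx_decay_fit"

  # an exponential decay is maximal at the first spectrum: if that point is
  # already at baseline, or fewer than 3 points carry signal, the amide
  # exchanged before enough spectra were recorded
  if (I[1] <= noise_floor || sum(I > noise_floor) < 3L) {
    out$status <- "fast_limit"
    return(out)
  }

  # starting values: log-linear regression on clearly positive points
  pos <- I > max(noise_floor, 0.05 * max(I))
  k0 <- if (sum(pos) >= 2L) {
    sl <- -coef(stats::lm(log(I[pos]) ~ t[pos]))[[2]]
    max(sl, 1e-3 / max(t))
  } else 1 / max(t)
  I0_0 <- max(I)
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ I0 * exp(-k * time_s),
                      data = out$data,
                      start = list(I0 = I0_0, k = k0),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # no convergence: decide by signal level relative to baseline noise
    out$status <- if (max(I) < 3 * noise_floor) "fast_limit" else "slow_limit"
    return(out)
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(I0 = NA_real_, k = NA_real_))
  # a fitted signal that is already indistinguishable from baseline noise at
  # the first recorded spectrum cannot be quantified
  if (cf[["I0"]] * exp(-cf[["k"]] * t[1]) <= 3 * noise_floor) {
    out$status <- "fast_limit"
    return(out)
  }
  if (cf[["k"]] * max(t) < slow_decay_min) {
    out$status <- "slow_limit"
    return(out)
  }
  out$k_obs <- cf[["k"]]
  out$I0 <- cf[["I0"]]
  out$k_obs_se <- unname(se[["k"]])
  out$I0_se <- unname(se[["I0"]])
  out$residuals <- I - predict(fit)
  out
}

#' @export
print.hx_decay_fit <- function(x, ...) {
  cat("<hx_decay_fit> status:", x$status)
  if (x$status == "measured") {
    cat(sprintf("  k_obs = %.3g +/- %.2g s^-1, I0 = %.3g", x$k_obs,
                x$k_obs_se, x$I0))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.hx_decay_fit <- function(object, ...) {
  c(I0 = object$I0, k_obs = object$k_obs)
}

#' @export
residuals.hx_decay_fit <- function(object, ...) object$residuals

#' Protection factor and exchange free energy for one amide
#'
#' For a measured decay, \eqn{PF = k_{pred}/k_{obs}} and
#' \eqn{\Delta G_{HX} = 2.303\,R\,T\,\log_{10}(PF)}. Censored fits carry an
#' inequality instead of a point estimate: fast exchangers get an upper bound
#' on log PF (see [censor_limits()]), and slow exchangers a lower bound equal
#' to `max_measured_logPF` for the sample.
#'
#' @param fit an [fit_decay()] result.
#' @param k_pred predicted intrinsic rate (s^-1) for the same amide.
#' @param temperature_K temperature for the free-energy conversion (default
#'   298.15 K).
#' @param residue optional residue number carried through.
#' @param max_measured_logPF bound assigned to slow-limit amides.
#' @param i0_over_noise detection ratio I0/I_noise used for fast-limit
#'   bounds when the series itself cannot supply it.
#' @return One-row data frame with columns `residue`, `k_pred`, `k_obs`,
#'   `k_obs_se`, `logPF`, `dG_kJmol`, `status`, `bound_direction`. For
#'   censored amides `logPF`/`dG_kJmol` hold the bound value.
#' @export
protection <- function(fit, k_pred, temperature_K = 298.15, residue = NA,
                       max_measured_logPF = NA_real_, i0_over_noise = 20) {
  stopifnot(k_pred > 0)
  status <- fit$status
  bound <- NA_character_
  if (status == "measured") {
    if (fit$k_obs > 10 * k_pred) {
      warning("observed rate exceeds 10x the intrinsic prediction ",
              "(super-intrinsic exchange; check assignment) for residue ",
              residue)
    }
    logPF <- log10(k_pred / fit$k_obs)
  } else if (status == "fast_limit") {
    t_first <- fit$data$time_s[1]
    logPF <- log10(k_pred * t_first / log(i0_over_noise))
    bound <- "upper"
  } else {
    logPF <- max_measured_logPF
    bound <- "lower"
  }
  dG <- 2.303 * .RGAS * temperature_K * logPF / 1000
  data.frame(residue = residue, k_pred = k_pred,
             k_obs = if (status == "measured") fit$k_obs else NA_real_,
             k_obs_se = if (status == "measured") fit$k_obs_se else NA_real_,
             logPF = logPF, dG_kJmol = dG, status = status,
             bound_direction = bound, stringsAsFactors = FALSE)
}

#' Censoring bounds for fast and slow exchangers
#'
#' Fast exchangers (gone before the first spectrum) get an upper bound on
#' log PF from the first observation time:
#' \deqn{\log PF < \log_{10}\!\big(k_{pred}\, t_{first} / \ln(I_0/I_{noise})\big)}
#' Slow exchangers (no significant decay over the window) get a lower bound
#' equal to the largest measured log PF of the sample.
#'
#' @param series an [intensity_series()] (its first time defines
#'   \eqn{t_{first}}).
#' @param k_pred predicted intrinsic rate (s^-1).
#' @param max_measured_logPF largest measured log PF in the same sample.
#' @param i0_over_noise detection ratio \eqn{I_0/I_{noise}}.
#' @return List with `upper` (fast-exchange bound on log PF) and `lower`
#'   (slow-exchange bound).
#' @export
censor_limits <- function(series, k_pred, max_measured_logPF,
                          i0_over_noise = 20) {
  t_first <- series$time_s[1]
  if (is.null(t_first) || is.na(t_first)) stop("undefined first observation time")
  list(upper = log10(k_pred * t_first / log(i0_over_noise)),
       lower = max_measured_logPF)
}

#' Protection-factor analysis of a full exchange dataset
#'
#' Fits every residue's decay, joins with intrinsic-rate predictions, and
#' applies the censoring rules: fast-limit amides receive an upper bound on
#' log PF from the first observation time, slow-limit amides a lower bound
#' equal to the largest measured log PF in the dataset.
#'
#' @param data data frame with columns `residue`, `time_s`, `intensity`
#'   (and optionally `n_scans`; intensities are then scaled by scan count).
#' @param model an [intrinsic_rate_model()] for the same construct.
#' @param temperature_K temperature for the free-energy conversion.
#' @param ... passed to [fit_decay()].
#' @return Data frame of class `hx_protection`, one row per residue with a
#'   predicted intrinsic rate.
#' @export
hx_protection <- function(data, model, temperature_K = 298.15, ...) {
  if (!is.null(data$n_scans)) data$intensity <- data$intensity / data$n_scans
  rates <- predict_intrinsic_rates(model)
  fits <- list()
  for (r in sort(unique(data$residue))) {
    kp <- rates$k_pred[match(r, rates$resno)]
    if (length(kp) != 1L || is.na(kp)) next
    d <- data[data$residue == r, , drop = FALSE]
    d <- d[order(d$time_s), , drop = FALSE]
    fits[[as.character(r)]] <-
      list(fit = fit_decay(d, ...), k_pred = kp, residue = r)
  }
  measured_logpf <- vapply(fits, function(f) {
    if (f$fit$status == "measured") log10(f$k_pred / f$fit$k_obs) else NA_real_
  }, numeric(1))
  max_logpf <- if (all(is.na(measured_logpf))) NA_real_
               else max(measured_logpf, na.rm = TRUE)
  rows <- lapply(fits, function(f) {
    protection(f$fit, f$k_pred, temperature_K = temperature_K,
               residue = f$residue, max_measured_logPF = max_logpf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hx_protection", "data.frame")
  out
}
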