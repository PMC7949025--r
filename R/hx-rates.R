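# Intrinsic (random-coil) amide exchange rate prediction.
#
# Reference chemistry: poly-DL-alanine acid-, base- and water-catalyzed rate
# constants with per-residue side-chain correction factors for the amide's own
# residue ("left") and the preceding residue ("right"), Arrhenius temperature
# corrections, and N-/C-terminal group factors (Bai/Connelly parameter set).
# Factors for ionizable side chains (Asp, Glu, His) are mixed between their
# protonated and deprotonated values by Henderson-Hasselbalch weighting at the
# sample pD.

# log10 side-chain correction factors: acid left/right, base left/right.
# "left" modifies the residue's own amide NH; "right" modifies the NH of the
# following residue. Proline has no amide NH (left factors undefined).
.HX_FACTORS <- local({
  m <- rbind(
    A  = c( 0.00,  0.00,  0.00,  0.00),
    R  = c(-0.59, -0.32,  0.08,  0.22),
    N  = c(-0.58, -0.13,  0.49,  0.32),
    D  = c( 0.90,  0.58, -0.30, -0.18),  # Asp, deprotonated
    Dp = c(-0.90, -0.12,  0.69,  0.60),  # Asp, protonated
    C  = c(-0.54, -0.46,  0.62,  0.55),
    Q  = c(-0.47, -0.27,  0.06,  0.20),
    E  = c(-0.90,  0.31, -0.51, -0.15),  # Glu, deprotonated
    Ep = c(-0.60, -0.27,  0.24,  0.39),  # Glu, protonated
    G  = c(-0.22,  0.22,  0.27,  0.17),
    H  = c( 0.00,  0.00, -0.10,  0.14),  # His, neutral
    Hp = c(-0.80, -0.51,  0.80,  0.83),  # His, protonated
    I  = c(-0.91, -0.59, -0.73, -0.23),
    L  = c(-0.57, -0.13, -0.58, -0.21),
    K  = c(-0.56, -0.29, -0.04,  0.12),
    M  = c(-0.64, -0.28, -0.01,  0.11),
    F  = c(-0.52, -0.43, -0.24,  0.06),
    P  = c(   NA, -0.19,    NA, -0.24),  # trans proline; right factors only
    S  = c(-0.44, -0.39,  0.37,  0.30),
    T  = c(-0.79, -0.47, -0.07,  0.20),
    W  = c(-0.40, -0.44, -0.41, -0.11),
    Y  = c(-0.41, -0.37, -0.27,  0.05),
    V  = c(-0.74, -0.30, -0.70, -0.14),
    X  = c( 0.00,  0.00,  0.00,  0.00),  # unknown residue: reference factors
    NT = c(   NA, -1.32,    NA,  1.62),  # N-terminal ammonium (right factor)
    CT = c( 0.96,    NA, -1.80,    NA)   # C-terminal carboxylate (left factor)
  )
  colnames(m) <- c("aL", "aR", "bL", "bR")
  m
})

# Side-chain pK values (pD scale) used for protonation-state mixing.
.HX_PK <- c(D = 4.48, E = 4.93, H = 7.42)

# Reference poly-DL-alanine rates at 293 K (log10; acid/base in M^-1 min^-1,
# water in min^-1), activation energies (kcal/mol), and solvent ion product.
.HX_REFERENCE <- list(
  HtoD = list(logkA = 1.62, logkB = 10.05, logkW = -1.5,
              EaA = 14, EaB = 17, EaW = 19, pKion = 15.05, Tref = 293),
  DtoH = list(logkA = 2.04, logkB = 10.36, logkW = -1.5,
              EaA = 14, EaB = 17, EaW = 19, pKion = 14.17, Tref = 293)
)

# Henderson-Hasselbalch mix of log-factors for an ionizable side chain.
.mix_log_factor <- function(log_deprot, log_prot, pK, pD) {
  f_prot <- 1 / (1 + 10^(pD - pK))
  log10(f_prot * 10^log_prot + (1 - f_prot) * 10^log_deprot)
}

# Resolve the four log-factors of one residue code at a given pD.
.residue_factors <- function(code, pD) {
  if (code %in% names(.HX_PK)) {
    dep <- .HX_FACTORS[code, ]
    pro <- .HX_FACTORS[paste0(code, "p"), ]
    vapply(seq_along(dep), function(j) {
      .mix_log_factor(dep[j], pro[j], .HX_PK[[code]], pD)
    }, numeric(1)) -> v
    names(v) <- names(dep)
    v
  } else {
    .HX_FACTORS[code, ]
  }
}

#' Intrinsic exchange rate model
#'
#' Bundles the construct sequence, solution conditions and reference
#' parameter set for random-coil amide exchange prediction.
#'
#' @param sequence named character vector of one-letter codes (names = author
#'   residue numbers), e.g. [etv6_construct()], or an unnamed vector/string
#'   together with `offset`.
#' @param pH_star pH-meter reading of the D2O sample, uncorrected for the
#'   deuterium isotope effect. An optional fixed correction can be applied
#'   via `pD_correction` (default 0; +0.4 is the conventional glass-electrode
#'   correction).
#' @param temperature_K sample temperature in kelvin.
#' @param offset author number of the first residue when `sequence` is
#'   unnamed.
#' @param isotope exchange regime: `"HtoD"` (protium out, into D2O; the
#'   NMR-detected experiment) or `"DtoH"`.
#' @param pD_correction value added to `pH_star` before use (default 0).
#' @return Object of class `intrinsic_rate_model`.
#' @export
intrinsic_rate_model <- function(sequence, pH_star, temperature_K,
                                 offset = NULL, isotope = c("HtoD", "DtoH"),
                                 pD_correction = 0) {
  isotope <- match.arg(isotope)
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (is.null(names(sequence))) {
    if (is.null(offset)) offset <- 1L
    names(sequence) <- seq(offset, length.out = length(sequence))
  }
  bad <- setdiff(unique(sequence), rownames(.HX_FACTORS))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  if (pH_star < 0 || pH_star > 14) stop("pH* outside 0-14")
  if (length(sequence) < 2L) stop("sequence must have at least 2 residues")
  structure(list(sequence = sequence, pH_star = pH_star,
                 temperature_K = temperature_K, isotope = isotope,
                 pD_correction = pD_correction),
            class = "intrinsic_rate_model")
}

#' Predict intrinsic (random-coil) amide exchange rates
#'
#' For the amide of residue i the predicted rate is
#' \deqn{k_{pred} = k_A 10^{-pD} F_A + k_B 10^{pD - pK_{ion}} F_B + k_W F_B'}
#' where the acid factor combines the left factor of residue i with the right
#' factor of residue i-1 (base and water terms analogously, with the water
#' term using the base factors), the N-terminal ammonium contributes an extra
#' right factor to the second residue, the C-terminal carboxylate an extra
#' left factor to the last residue, and each catalytic term carries its own
#' Arrhenius correction from the 293 K reference. The first residue has no
#' predicted value (free alpha-amine), nor do prolines (no amide NH).
#'
#' @param model an [intrinsic_rate_model()].
#' @return Data frame with columns `resno`, `code`, `k_pred` (s^-1; `NA` for
#'   the first residue and prolines).
#' @export
predict_intrinsic_rates <- function(model) {
  stopifnot(inherits(model, "intrinsic_rate_model"))
  seqv <- model$sequence
  n <- length(seqv)
  ref <- .HX_REFERENCE[[model$isotope]]
  pD <- model$pH_star + model$pD_correction
  T <- model$temperature_K
  Rcal <- 1.987204e-3  # kcal mol^-1 K^-1
  arr <- function(Ea) exp(-Ea / Rcal * (1 / T - 1 / ref$Tref))
  kA <- 10^ref$logkA * 10^(-pD) * arr(ref$EaA)
  kB <- 10^ref$logkB * 10^(pD - ref$pKion) * arr(ref$EaB)
  kW <- 10^ref$logkW * arr(ref$EaW)

  fac <- lapply(seqv, .residue_factors, pD = pD)
  k <- rep(NA_real_, n)
  for (i in 2:n) {
    if (seqv[i] == "P") next
    fL <- fac[[i]]
    fR <- fac[[i - 1]]
    la <- fL[["aL"]] + fR[["aR"]]
    lb <- fL[["bL"]] + fR[["bR"]]
    if (i == 2L) {
      la <- la + .HX_FACTORS["NT", "aR"]
      lb <- lb + .HX_FACTORS["NT", "bR"]
    }
    if (i == n) {
      la <- la + .HX_FACTORS["CT", "aL"]
      lb <- lb + .HX_FACTORS["CT", "bL"]
    }
    # per-minute -> per-second
    k[i] <- (kA * 10^la + kB * 10^lb + kW * 10^lb) / 60
  }
  data.frame(resno = as.integer(names(seqv)), code = unname(seqv), k_pred = k)
}
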