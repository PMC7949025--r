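# Combined amide chemical shift perturbation (CSP) analysis.

#' Amide shift table
#'
#' One row per residue of backbone amide 1H and 15N chemical shifts for a
#' single protein state.
#'
#' @param residue integer residue numbers (author numbering).
#' @param delta_H_ppm,delta_N_ppm amide 1H and 15N chemical shifts (ppm).
#' @param state free-text state label (e.g. `"free"`, `"bound"`).
#' @param pH sample pH of the measurement (recorded as metadata; no
#'   correction between states is applied).
#' @return Data frame of class `shift_table` with attributes `state`, `pH`.
#' @export
shift_table <- function(residue, delta_H_ppm, delta_N_ppm,
                        state = "unknown", pH = NA_real_) {
  if (anyDuplicated(residue)) stop("one row per residue required")
  if (!all(is.finite(delta_H_ppm)) || !all(is.finite(delta_N_ppm))) {
    stop("non-finite chemical shifts")
  }
  if (any(delta_H_ppm < 5 | delta_H_ppm > 12) ||
      any(delta_N_ppm < 100 | delta_N_ppm > 135)) {
    warning("shifts outside typical amide ranges (1H 5-12 ppm, 15N 100-135 ppm)")
  }
  out <- data.frame(residue = as.integer(residue),
                    delta_H_ppm = delta_H_ppm, delta_N_ppm = delta_N_ppm)
  out <- out[order(out$residue), , drop = FALSE]
  attr(out, "state") <- state
  attr(out, "pH") <- pH
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Read a shift table from TSV
#' @param file TSV with columns `residue`, `delta_H_ppm`, `delta_N_ppm`.
#' @inheritParams shift_table
#' @export
read_shift_table <- function(file, state = "unknown", pH = NA_real_) {
  d <- read.delim(file)
  shift_table(d$residue, d$delta_H_ppm, d$delta_N_ppm, state = state, pH = pH)
}

#' Combined chemical shift perturbations between two states
#'
#' For each residue assigned in both states, the combined amide CSP is
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (w\,\Delta\delta_N)^2}}
#' with nitrogen weight \eqn{w = 0.14} by default. Differences are taken
#' bound - free; the sign is irrelevant to the combined value but the signed
#' components are kept for diagnostics. Residues assigned in only one state
#' are returned with `missing = TRUE` and no combined value rather than being
#' dropped.
#'
#' @param free,bound [shift_table()] objects for the two states.
#' @param nitrogen_weight dimensionless weight applied to the 15N component.
#' @return Data frame with columns `residue`, `dH_ppm`, `dN_ppm`, `csp_ppm`,
#'   `missing`.
#' @export
compute_csp <- function(free, bound, nitrogen_weight = 0.14) {
  shared <- intersect(free$residue, bound$residue)
  if (length(shared) == 0L) {
    stop("no residues shared between the two shift tables")
  }
  all_res <- sort(union(free$residue, bound$residue))
  i_f <- match(all_res, free$residue)
  i_b <- match(all_res, bound$residue)
  dH <- bound$delta_H_ppm[i_b] - free$delta_H_ppm[i_f]
  dN <- bound$delta_N_ppm[i_b] - free$delta_N_ppm[i_f]
  csp <- sqrt(dH^2 + (nitrogen_weight * dN)^2)
  out <- data.frame(residue = all_res, dH_ppm = dH, dN_ppm = dN,
                    csp_ppm = csp, missing = !(all_res %in% shared))
  attr(out, "nitrogen_weight") <- nitrogen_weight
  attr(out, "pH_free") <- attr(free, "pH")
  attr(out, "pH_bound") <- attr(bound, "pH")
  out
}

#' Classify interface residues from CSPs
#'
#' Residues with a combined CSP strictly greater than `threshold` (default
#' 0.2 ppm) are flagged as interface candidates.
#'
#' @param records output of [compute_csp()].
#' @param threshold ppm cutoff; the comparison is strict (`>`).
#' @return Sorted integer vector of flagged residue numbers.
#' @export
classify_interface <- function(records, threshold = 0.2) {
  keep <- !records$missing & !is.na(records$csp_ppm) &
    records$csp_ppm > threshold
  sort(records$residue[keep])
}

#' Overlap of CSP-flagged residues with an interface annotation
#'
#' @param flagged integer vector of flagged residue numbers.
#' @param annotation an [interface_annotation()].
#' @param universe optional residue numbers of the whole construct, for the
#'   2x2 contingency counts (defaults to the union of both sets).
#' @return List with `fraction` (|flagged annotated| / |flagged|; `NA` when
#'   nothing is flagged) and a 2x2 `table` of flagged/unflagged by
#'   annotated/unannotated.
#' @export
interface_overlap <- function(flagged, annotation, universe = NULL) {
  ann <- annotation$residues
  if (length(ann) == 0L) stop("empty interface annotation")
  if (is.null(universe)) universe <- sort(union(flagged, ann))
  fl <- universe %in% flagged
  an <- universe %in% ann
  tab <- table(flagged = factor(fl, c(TRUE, FALSE)),
               annotated = factor(an, c(TRUE, FALSE)))
  frac <- if (length(flagged)) length(intersect(flagged, ann)) / length(flagged)
          else NA_real_
  list(fraction = frac, table = tab)
}
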