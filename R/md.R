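# Trajectory statistics: superposition, RMSD series, per-residue RMSF,
# delta-RMSF classification, PCA, and backbone hydrogen-bond persistence.

#' Trajectory container
#'
#' @param topology a [pnt_structure()] describing every frame's atoms.
#' @param xyz numeric array `c(n_atoms, 3, n_frames)`.
#' @param interval_ps time between recorded frames (ps).
#' @return Object of class `pnt_trajectory`.
#' @export
pnt_trajectory <- function(topology, xyz, interval_ps = 100) {
  stopifnot(inherits(topology, "pnt_structure"),
            length(dim(xyz)) == 3L, dim(xyz)[2] == 3L,
            interval_ps > 0)
  if (dim(xyz)[1] != nrow(topology$atoms)) {
    stop("frame atom count does not match topology")
  }
  structure(list(topology = topology, xyz = xyz, interval_ps = interval_ps),
            class = "pnt_trajectory")
}

#' @export
print.pnt_trajectory <- function(x, ...) {
  cat("<pnt_trajectory> ", dim(x$xyz)[3], " frames x ", dim(x$xyz)[1],
      " atoms, ", x$interval_ps, " ps/frame\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [pnt_trajectory()].
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL becomes one frame; the first model defines the topology.
#'
#' @inheritParams read_structure
#' @param interval_ps frame spacing in ps (not stored in PDB files).
#' @return A [pnt_trajectory()].
#' @export
read_trajectory <- function(x, interval_ps = 100) {
  file <- .as_pdb_file(x)
  .check_pdb_lines(readLines(file, warn = FALSE))
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  topo <- pnt_structure(.atoms_from_bio3d(pdb))
  nat <- nrow(topo$atoms)
  xyz2 <- pdb$xyz
  if (is.null(dim(xyz2))) xyz2 <- matrix(xyz2, nrow = 1)
  nf <- nrow(xyz2)
  arr <- array(NA_real_, c(nat, 3, nf))
  for (f in seq_len(nf)) {
    arr[, , f] <- matrix(xyz2[f, seq_len(3 * nat)], ncol = 3, byrow = TRUE)
  }
  pnt_trajectory(topo, arr, interval_ps)
}

#' Write a trajectory as multi-model PDB text
#' @param traj a [pnt_trajectory()].
#' @return Character vector of PDB lines (MODEL/ENDMDL blocks).
#' @export
write_trajectory <- function(traj) {
  a <- traj$topology$atoms
  out <- character(0)
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$xyz[, , f]
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)),
      ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
      a$resid, a$chain, a$resno, xyz[, 1], xyz[, 2], xyz[, 3], a$o, a$b)
    out <- c(out, sprintf("MODEL %8d", f), lines, "ENDMDL")
  }
  c(out, "END")
}

# Row indices of topology atoms matching a selection.
.sel_idx <- function(s, residue_range = NULL, atom_class = "all",
                     chain = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residue_range)) {
    keep <- keep & a$resno >= residue_range[1] & a$resno <= residue_range[2]
  }
  if (atom_class == "backbone") keep <- keep & a$elety %in% .BACKBONE
  which(keep)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets.
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3, non-collinear).
#' @return List with `R` (3x3 rotation applied as `coords \%*\% R`),
#'   `center_mobile`, `center_reference`, `rmsd`, and `coords` (the
#'   transformed mobile set).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || nrow(mobile) < 3L) {
    stop("superposition needs equal coordinate counts of at least 3")
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- tryCatch(svd(H), error = function(e) stop("degenerate geometry"))
  if (sv$d[2] < 1e-10) stop("degenerate geometry: collinear coordinates")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(R = R, center_mobile = cm, center_reference = cr, rmsd = rmsd,
       coords = sweep(fitted, 2, cr, "+"))
}

# Apply a superposition transform (fit on a subset) to a full frame.
.apply_transform <- function(X, fit) {
  sweep(sweep(X, 2, fit$center_mobile) %*% fit$R, 2,
        fit$center_reference, "+")
}

#' RMSD time series relative to the first frame
#'
#' Each frame is superposed on frame 1 over the selection; the RMSD is
#' computed on the same selection. Default selection: backbone atoms of core
#' residues 57-120 (the terminal segments 47-56 and 121-123 are dominated by
#' flexible-end motions).
#'
#' @param traj a [pnt_trajectory()].
#' @param residue_range inclusive residue interval, e.g. `c(47, 123)` or the
#'   core `c(57, 120)`.
#' @param atom_class `"backbone"` or `"all"`.
#' @param chain optional chain restriction.
#' @return Data frame of class `rmsd_series` with `time_ns`, `rmsd`.
#' @export
rmsd_series <- function(traj, residue_range = c(57, 120),
                        atom_class = "backbone", chain = NULL) {
  idx <- .sel_idx(traj$topology, residue_range, atom_class, chain)
  if (length(idx) == 0L) stop("empty selection")
  ref <- traj$xyz[idx, , 1]
  nf <- n_frames(traj)
  rmsd <- vapply(seq_len(nf), function(f) {
    superpose(traj$xyz[idx, , f], ref)$rmsd
  }, numeric(1))
  out <- data.frame(time_ns = (seq_len(nf) - 1) * traj$interval_ps / 1000,
                    rmsd = rmsd)
  attr(out, "selection") <- list(residue_range = residue_range,
                                 atom_class = atom_class, chain = chain)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

# Align all frames onto a reference coordinate set using alignment indices.
.align_frames <- function(traj, idx_align, ref_align) {
  nf <- n_frames(traj)
  out <- traj$xyz
  for (f in seq_len(nf)) {
    fit <- superpose(out[idx_align, , f], ref_align)
    out[, , f] <- .apply_transform(out[, , f], fit)
  }
  out
}

#' Per-residue all-atom RMSF profile
#'
#' Frames are aligned on the backbone of the core residues to the
#' time-averaged structure (two alignment passes: first to frame 1, then to
#' the resulting mean). The per-atom RMSF is
#' \eqn{\sqrt{\langle |r - \langle r\rangle|^2 \rangle}} and the per-residue
#' value averages all atoms of the residue (no mass weighting).
#'
#' @param traj a [pnt_trajectory()].
#' @param chain optional chain to report (alignment always uses all chains).
#' @param align_range residue interval used for alignment (default core
#'   57-120).
#' @return Data frame of class `rmsf_profile` with `chain`, `resno`, `rmsf`.
#' @export
rmsf_profile <- function(traj, chain = NULL, align_range = c(57, 120)) {
  if (n_frames(traj) < 2L) stop("RMSF requires at least 2 frames")
  idx_al <- .sel_idx(traj$topology, align_range, "backbone")
  if (length(idx_al) < 3L) idx_al <- seq_len(dim(traj$xyz)[1])
  aligned <- .align_frames(traj, idx_al, traj$xyz[idx_al, , 1])
  mean_xyz <- apply(aligned, c(1, 2), mean)
  traj2 <- traj; traj2$xyz <- aligned
  aligned <- .align_frames(traj2, idx_al, mean_xyz[idx_al, ])
  mean_xyz <- apply(aligned, c(1, 2), mean)
  dev2 <- (aligned - array(mean_xyz, dim(aligned)))^2
  atom_rmsf <- sqrt(apply(dev2, 1, mean) * 3)  # mean over frames of |dr|^2
  # apply(dev2, 1, mean) averages over both xyz and frames; restore the
  # sum over components with the factor 3
  a <- traj$topology$atoms
  keep <- if (is.null(chain)) rep(TRUE, nrow(a)) else a$chain %in% chain
  agg <- stats::aggregate(atom_rmsf[keep],
                          by = list(chain = a$chain[keep],
                                    resno = a$resno[keep]),
                          FUN = mean)
  out <- data.frame(chain = agg$chain, resno = agg$resno, rmsf = agg$x)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Delta-RMSF between paired chains with interface classification
#'
#' Computes `a - b` per residue and classifies at `+/- threshold` (default
#' 0.3 Angstrom): values above `+threshold` mean the residue fluctuates less
#' in profile `b` (`"reduced_in_b"`), values below `-threshold` less in
#' profile `a` (`"reduced_in_a"`). For a heterodimer with `a` the V112R-like
#' chain and `b` the A93D-like chain, positive classifications correspond to
#' rigidification of the A93D-like subunit.
#'
#' @param a,b [rmsf_profile()] data frames covering the same residues.
#' @param threshold classification threshold (Angstrom).
#' @return Data frame with `resno`, `rmsf_a`, `rmsf_b`, `delta`, `class`.
#' @export
delta_rmsf <- function(a, b, threshold = 0.3) {
  if (!setequal(a$resno, b$resno)) {
    stop("profiles cover different residues; cannot join")
  }
  b <- b[match(a$resno, b$resno), , drop = FALSE]
  delta <- a$rmsf - b$rmsf
  cls <- ifelse(delta > threshold, "reduced_in_b",
                ifelse(delta < -threshold, "reduced_in_a", "neutral"))
  data.frame(resno = a$resno, rmsf_a = a$rmsf, rmsf_b = b$rmsf,
             delta = delta, class = cls, stringsAsFactors = FALSE)
}

#' Principal component analysis of trajectory fluctuations
#'
#' Frames are aligned over the selection, the selected coordinates are
#' flattened to one row per frame, and the covariance matrix of the centered
#' coordinates is eigen-decomposed (via [stats::prcomp()]).
#'
#' @param traj a [pnt_trajectory()].
#' @param residue_range,atom_class,chain selection (default backbone of core
#'   residues 57-120).
#' @param k number of components for which to return per-frame projections.
#' @param align superpose every frame on frame 1 over the selection before
#'   the decomposition (default `TRUE`; disable for pre-aligned input).
#' @return List of class `traj_pca`: `eigenvalues`, `variance_fractions`
#'   (sorted descending, summing to 1), `projections` (frames x k).
#' @export
traj_pca <- function(traj, residue_range = c(57, 120),
                     atom_class = "backbone", chain = NULL, k = 5,
                     align = TRUE) {
  if (n_frames(traj) < 10L) stop("PCA requires at least 10 frames")
  idx <- .sel_idx(traj$topology, residue_range, atom_class, chain)
  if (length(idx) == 0L) stop("empty selection")
  aligned <- if (align) .align_frames(traj, idx, traj$xyz[idx, , 1]) else traj$xyz
  nf <- n_frames(traj)
  X <- t(vapply(seq_len(nf), function(f) as.numeric(aligned[idx, , f]),
                numeric(3 * length(idx))))
  if (sum(apply(X, 2, stats::var)) < 1e-12) stop("zero variance in selection")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(k, ncol(pc$x))
  structure(list(eigenvalues = ev, variance_fractions = ev / sum(ev),
                 projections = pc$x[, seq_len(k), drop = FALSE],
                 rotation = pc$rotation, center = pc$center),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  vf <- x$variance_fractions
  cat("<traj_pca> ", length(vf), " components; leading variance fractions: ",
      paste(sprintf("%.3f", head(vf, 5)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Backbone hydrogen-bond persistence
#'
#' For every amide nitrogen (prolines and chain-initial residues excluded)
#' the two backbone carbonyl oxygens with the smallest trajectory-mean N...O
#' distance are selected as hydrogen-bond candidates, excluding the carbonyls
#' of the residue itself and of the preceding residue (covalently adjacent).
#' An amide is assigned as hydrogen bonded when the smallest mean distance is
#' within `cutoff` (inclusive; default 3.5 Angstrom).
#'
#' @param traj a [pnt_trajectory()].
#' @param cutoff distance criterion (Angstrom), compared inclusively.
#' @param exclude_adjacent exclude carbonyls of residues i and i-1 (default
#'   TRUE).
#' @param per_frame if `TRUE`, average the per-frame minimum distance instead
#'   of ranking by trajectory-mean distance.
#' @return Data frame of class `hbond_profile` with `chain`, `resno`,
#'   `partner1`, `dist1`, `partner2`, `dist2`, `bonded`.
#' @export
hbond_persistence <- function(traj, cutoff = 3.5, exclude_adjacent = TRUE,
                              per_frame = FALSE) {
  a <- traj$topology$atoms
  iN <- which(a$elety == "N" & a$resid != "PRO")
  # drop chain-initial amides (free alpha-amine)
  first_res <- tapply(a$resno, a$chain, min)
  iN <- iN[a$resno[iN] != first_res[a$chain[iN]]]
  iO <- which(a$elety == "O")
  if (length(iN) == 0L || length(iO) == 0L) {
    stop("topology lacks backbone N or O atoms")
  }
  nf <- n_frames(traj)
  nN <- length(iN); nO <- length(iO)
  dsum <- matrix(0, nN, nO)
  dmin_sum <- rep(0, nN)
  excl <- matrix(FALSE, nN, nO)
  if (exclude_adjacent) {
    for (j in seq_len(nO)) {
      excl[, j] <- a$chain[iO[j]] == a$chain[iN] &
        (a$resno[iO[j]] == a$resno[iN] | a$resno[iO[j]] == a$resno[iN] - 1L)
    }
  }
  for (f in seq_len(nf)) {
    N <- traj$xyz[iN, , f, drop = FALSE]
    O <- traj$xyz[iO, , f, drop = FALSE]
    d <- sqrt(outer(N[, , 1][, 1], O[, , 1][, 1], "-")^2 +
              outer(N[, , 1][, 2], O[, , 1][, 2], "-")^2 +
              outer(N[, , 1][, 3], O[, , 1][, 3], "-")^2)
    dsum <- dsum + d
    if (per_frame) {
      df <- d; df[excl] <- Inf
      dmin_sum <- dmin_sum + apply(df, 1, min)
    }
  }
  dmean <- dsum / nf
  dmean[excl] <- Inf
  olab <- paste0(a$chain[iO], a$resno[iO])
  out <- data.frame(chain = a$chain[iN], resno = a$resno[iN],
                    partner1 = NA_character_, dist1 = NA_real_,
                    partner2 = NA_character_, dist2 = NA_real_,
                    bonded = NA, stringsAsFactors = FALSE)
  for (i in seq_len(nN)) {
    ord <- order(dmean[i, ])[1:2]
    out$partner1[i] <- olab[ord[1]]; out$dist1[i] <- dmean[i, ord[1]]
    out$partner2[i] <- olab[ord[2]]; out$dist2[i] <- dmean[i, ord[2]]
  }
  out$bonded <- if (per_frame) (dmin_sum / nf) <= cutoff else
    out$dist1 <= cutoff
  class(out) <- c("hbond_profile", "data.frame")
  out
}

#' Cross-tabulate hydrogen bonding against HX protection
#'
#' Protected means a measured log PF above `logpf_floor` or a slow-exchange
#' lower bound; unprotected means fast-limit censoring or a measured log PF
#' at or below the floor.
#'
#' @param hbonds a [hbond_persistence()] result.
#' @param prot an [hx_protection()] table.
#' @param logpf_floor measurable-protection floor on log PF (default 3).
#' @return List with the 2x2 `table` (bonded x protected) and the joined
#'   per-residue data frame.
#' @export
compare_hbond_pf <- function(hbonds, prot, logpf_floor = 3) {
  shared <- intersect(hbonds$resno, prot$residue)
  if (length(shared) == 0L) stop("no shared residues")
  h <- hbonds[match(shared, hbonds$resno), , drop = FALSE]
  p <- prot[match(shared, prot$residue), , drop = FALSE]
  protected <- p$status == "slow_limit" |
    (p$status == "measured" & p$logPF > logpf_floor)
  tab <- table(bonded = factor(h$bonded, c(TRUE, FALSE)),
               protected = factor(protected, c(TRUE, FALSE)))
  list(table = tab,
       data = data.frame(resno = shared, bonded = h$bonded,
                         protected = protected, logPF = p$logPF,
                         status = p$status))
}
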