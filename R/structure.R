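# Residue-resolved structure model: PDB I/O (via bio3d), atom selection,
# helix/interface annotation, and per-residue value maps.

.BACKBONE <- c("N", "CA", "C", "O")

#' Residue-resolved structure object
#'
#' A light container for one model of a protein structure: a data frame of
#' atom records keyed by author residue numbering. All downstream stages join
#' on `(chain, resno)`.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`
#'   (three-letter residue name), `elety` (atom name), `x`, `y`, `z` (.ANGSTROM),
#'   `o` (occupancy) and `b` (B-factor).
#' @return An object of class `pnt_structure`.
#' @export
pnt_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z", "o", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  atoms <- atoms[need]
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms), class = "pnt_structure")
}

#' @export
print.pnt_structure <- function(x, ...) {
  res <- residues(x)
  cat("<pnt_structure> ", nrow(x$atoms), " atoms, ", nrow(res),
      " residues, chains: ", paste(unique(res$chain), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Residue table of a structure
#'
#' @param s a [pnt_structure()].
#' @return Data frame with columns `chain`, `resno` and one-letter `code`.
#' @export
residues <- function(s) {
  a <- s$atoms
  key <- !duplicated(paste(a$chain, a$resno))
  out <- data.frame(chain = a$chain[key], resno = a$resno[key],
                    code = bio3d::aa321(a$resid[key]),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE]
}

# Validate raw PDB coordinate lines so parse failures carry a line number.
.check_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom) ) stop("empty structure: input contains no ATOM records")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed ATOM record at line ", i, ": fewer than 54 columns")
    }
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (is.na(resno) || anyNA(xyz)) {
      stop("malformed ATOM record at line ", i,
           ": non-numeric residue number or coordinates")
    }
    icode <- substr(ln, 27, 27)
    if (icode != " ") {
      stop("insertion code '", icode, "' at line ", i,
           " is not supported; renumber the input")
    }
  }
  invisible(TRUE)
}

.as_pdb_file <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) return(x)
  lines <- if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]] else x
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

.atoms_from_bio3d <- function(pdb) {
  a <- pdb$atom
  keep <- a$type %in% c("ATOM", "HETATM") & a$resid != "HOH"
  a <- a[keep, , drop = FALSE]
  # first altloc kept (read.pdb already drops later altlocs; dedup is a guard)
  a <- a[!duplicated(paste(a$chain, a$resno, a$elety)), , drop = FALSE]
  chain <- a$chain
  chain[is.na(chain)] <- "A"
  data.frame(chain = chain, resno = as.integer(a$resno), resid = a$resid,
             elety = a$elety, x = a$x, y = a$y, z = a$z,
             o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
             stringsAsFactors = FALSE)
}

#' Read a structure from PDB text
#'
#' Parses ATOM records of a PDB file (multi-model files return the first
#' model). Author residue numbering and chain identifiers are preserved; the
#' first alternate location is kept and insertion codes are rejected.
#'
#' @param x a file path, a single string of PDB text, or a character vector
#'   of PDB lines.
#' @return A [pnt_structure()].
#' @export
read_structure <- function(x) {
  file <- .as_pdb_file(x)
  .check_pdb_lines(readLines(file, warn = FALSE))
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  pnt_structure(.atoms_from_bio3d(pdb))
}

#' Select atoms from a structure
#'
#' @param s a [pnt_structure()].
#' @param residue_range inclusive integer range `c(first, last)` of author
#'   residue numbers, or `NULL` for all residues.
#' @param atom_class `"backbone"` (N, CA, C, O) or `"all"`.
#' @param chain optional chain identifier(s) to restrict to.
#' @return Atom-record data frame ordered by chain, residue, then canonical
#'   atom order (N, CA, C, O, side chain alphabetical).
#' @export
select_atoms <- function(s, residue_range = NULL,
                         atom_class = c("all", "backbone"), chain = NULL) {
  atom_class <- match.arg(atom_class)
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!is.null(residue_range)) {
    a <- a[a$resno >= residue_range[1] & a$resno <= residue_range[2], ,
           drop = FALSE]
  }
  if (atom_class == "backbone") a <- a[a$elety %in% .BACKBONE, , drop = FALSE]
  if (nrow(a) == 0L) stop("empty selection: no atoms match the given range")
  rank <- match(a$elety, .BACKBONE)
  rank[is.na(rank)] <- length(.BACKBONE) + 1L
  a[order(a$chain, a$resno, rank, a$elety), , drop = FALSE]
}

#' Write per-residue values into the B-factor column of a PDB file
#'
#' Every atom of a residue carries the residue's value formatted to two
#' decimals; residues without a supplied value receive `default`. Useful for
#' surface coloring of CSP, protection-factor or delta-RMSF maps in external
#' viewers.
#'
#' @param s a [pnt_structure()].
#' @param values named numeric vector (names = residue numbers), or a data
#'   frame with columns `residue` and `value` (optionally `chain`).
#' @param default sentinel for residues without a value.
#' @return Character vector of PDB lines.
#' @export
write_residue_map <- function(s, values, default = 0) {
  a <- s$atoms
  if (is.data.frame(values)) {
    v <- values$value
    names(v) <- values$residue
    values <- v
  }
  b <- values[as.character(a$resno)]
  b[is.na(b)] <- default
  if (any(b > 999.99 | b < -99.99)) {
    stop("value not representable in the 6-column PDB B-factor field")
  }
  tf <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tf, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, o = a$o, b = as.numeric(b))
  lines <- readLines(tf, warn = FALSE)
  unlink(tf)
  lines
}

#' Helix annotation
#'
#' @param label,start,end parallel vectors describing helical segments in
#'   author residue numbering.
#' @return Data frame of class `helix_annotation`.
#' @export
helix_annotation <- function(label, start, end) {
  seg <- data.frame(label = label, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (any(seg$end < seg$start)) stop("segment end precedes start")
  seg <- seg[order(seg$start), , drop = FALSE]
  if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
    stop("overlapping helix segments")
  }
  class(seg) <- c("helix_annotation", "data.frame")
  seg
}

#' Default ETV6 PNT domain helix boundaries
#'
#' The four alpha-helices of the PNT helical bundle in ETV6 numbering:
#' H1 63-76, H2 91-94, H3 99-105, H4 110-122.
#'
#' @return A [helix_annotation()].
#' @export
etv6_helices <- function() {
  helix_annotation(c("H1", "H2", "H3", "H4"),
                   c(63, 91, 99, 110),
                   c(76, 94, 105, 122))
}

#' Expand a helix annotation to its residue numbers
#' @param h a [helix_annotation()].
#' @return Integer vector of residue numbers covered by the segments.
#' @export
helix_residues <- function(h) {
  unlist(Map(seq.int, h$start, h$end), use.names = FALSE)
}

#' Interface annotation
#'
#' @param surface label of the self-association surface (`"ML"` mid-loop or
#'   `"EH"` end-helix for the PNT domain).
#' @param residues integer vector of residue numbers on the surface.
#' @export
interface_annotation <- function(surface, residues) {
  structure(list(surface = surface, residues = sort(unique(as.integer(residues)))),
            class = "interface_annotation")
}

#' Default ETV6 PNT interface annotations
#'
#' The residue sets probed by alanine scanning: 18 residues within or around
#' the EH-surface and 14 within or around the ML-surface.
#'
#' @return Named list of two [interface_annotation()] objects (`EH`, `ML`).
#' @export
etv6_interfaces <- function() {
  list(
    EH = interface_annotation("EH", c(47, 48, 76, 77, 78, 79, 80, 99, 100,
                                      103, 107, 108, 111, 112, 114, 115, 116, 119)),
    ML = interface_annotation("ML", c(59, 63, 85, 88, 89, 90, 92, 96, 97, 98,
                                      100, 101, 104, 105))
  )
}

#' Synthetic stand-in sequence for the ETV6 PNT construct (residues 40-125)
#'
#' One-letter codes for an 86-residue construct in ETV6 author numbering.
#' Residue identities that are fixed by the domain's described mutation sites,
#' helix boundaries and interface residues are pinned; the remaining positions
#' carry a fixed generic filler pattern. This is a synthetic stand-in, not the
#' database ETV6 sequence, and is used only to give the intrinsic-rate and
#' structure generators a concrete sequence context.
#'
#' @param variant optional point substitutions as a named character vector,
#'   e.g. `c("93" = "D")` for the ML-surface monomerizing mutation.
#' @return Named character vector of one-letter codes, names 40..125.
#' @export
etv6_construct <- function(variant = NULL) {
  resno <- 40:125
  seqv <- rep(c("S", "E", "K", "A", "T", "L", "Q", "N", "V", "D"),
              length.out = length(resno))
  names(seqv) <- resno
  pinned <- c(
    "40" = "A", "43" = "M", "47" = "S", "48" = "I", "52" = "A", "54" = "L",
    "58" = "P", "59" = "I", "60" = "Y", "63" = "R", "69" = "W", "70" = "L",
    "76" = "E", "77" = "F", "78" = "S", "79" = "L", "80" = "R", "84" = "S",
    "85" = "N", "86" = "T", "88" = "E", "89" = "M", "90" = "N", "91" = "G",
    "92" = "K", "93" = "A", "94" = "L", "96" = "L", "97" = "L", "98" = "T",
    "99" = "K", "100" = "E", "101" = "D", "102" = "F", "103" = "R",
    "104" = "Y", "105" = "R", "107" = "P", "108" = "H", "110" = "G",
    "111" = "D", "112" = "V", "113" = "L", "114" = "Y", "115" = "E",
    "116" = "L", "117" = "L", "119" = "H", "122" = "K", "123" = "Q"
  )
  seqv[names(pinned)] <- pinned
  if (!is.null(variant)) seqv[names(variant)] <- variant
  seqv
}
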