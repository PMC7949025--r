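# Shared fixtures, all built in code.

# Format a minimal PDB ATOM line.
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          o = 1, b = 0) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, ifelse(nchar(elety) < 4, paste0(" ", elety), elety),
          resid, chain, resno, x, y, z, o, b)
}

# A hand-built two-chain heterodimer toy file: chain A has two alanines
# (resno 40, 41), chain B one glycine (resno 7).
two_chain_pdb <- function() {
  c(pdb_atom_line(1, "N",  "ALA", "A", 40, 0.000, 0.000, 0.000),
    pdb_atom_line(2, "CA", "ALA", "A", 40, 1.458, 0.000, 0.000),
    pdb_atom_line(3, "C",  "ALA", "A", 40, 2.009, 1.421, 0.000),
    pdb_atom_line(4, "O",  "ALA", "A", 40, 1.251, 2.390, 0.000),
    pdb_atom_line(5, "N",  "ALA", "A", 41, 3.332, 1.536, 0.000),
    pdb_atom_line(6, "CA", "ALA", "A", 41, 4.031, 2.803, 0.000),
    pdb_atom_line(7, "C",  "ALA", "A", 41, 5.540, 2.617, 0.000),
    pdb_atom_line(8, "O",  "ALA", "A", 41, 6.040, 1.495, 0.000),
    "TER",
    pdb_atom_line(9,  "N",  "GLY", "B", 7, 10.000, 0.000, 0.000),
    pdb_atom_line(10, "CA", "GLY", "B", 7, 11.458, 0.000, 0.000),
    pdb_atom_line(11, "C",  "GLY", "B", 7, 12.009, 1.421, 0.000),
    pdb_atom_line(12, "O",  "GLY", "B", 7, 11.251, 2.390, 0.000),
    "END")
}

# Static single-frame trajectory from a structure.
static_traj <- function(s, n_frames = 1, interval_ps = 100) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  pnt_trajectory(s, array(rep(xyz, n_frames),
                          c(nrow(xyz), 3, n_frames)), interval_ps)
}

# Short synthetic sequence/annotation for fast trajectory tests:
# a 20-residue chain with one 12-residue helix.
small_helix <- function() {
  seqv <- rep("A", 20)
  names(seqv) <- 1:20
  gen_helix_bundle(helix_annotation("H1", 5, 16), sequence = seqv)
}

# Rotation matrix about the z axis.
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# Standard conditions of the monomeric-sample exchange experiment.
hx_model_default <- function() {
  intrinsic_rate_model(etv6_construct(), pH_star = 7.3,
                       temperature_K = 294.15)
}
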