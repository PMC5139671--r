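# Amino-acid constants: codes, radii, hydrophobicity, covalent topology.
# All side-chain geometry is heavy-atom only; hydrogens are ignored throughout.

#' The twenty standard amino acids
#'
#' One-letter codes in the fixed alphabetical order used for mutation
#' enumeration and for the columns of the mutation matrix.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

AA3 <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR"
)
AA1 <- stats::setNames(names(AA3), AA3)

# Kyte-Doolittle hydropathy (dimensionless, -4.5..4.5)
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
  H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
  P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
  W = -0.9, Y = -1.3
)

# van der Waals radii by element (Angstrom, heavy atoms only)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Backbone atoms required for a site to be scannable
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Side-chain internal-coordinate topology.
# Each atom is placed by NeRF from three previously placed atoms:
#   torsion a1-a2-a3-atom, bond angle a2-a3-atom, bond length a3-atom.
# tor_chi = k (>0) means torsion = chi_k + tor_off; tor_chi = 0 means the
# torsion is the fixed value tor_off (ring / branch geometry).
# CB is implicit: every non-Gly residue gets CB from (N, C, CA) with an
# improper torsion (see .place_cb).
sc_row <- function(atom, a1, a2, a3, bond, angle, tor_chi, tor_off, element) {
  list(atom = atom, a1 = a1, a2 = a2, a3 = a3, bond = bond, angle = angle,
       tor_chi = tor_chi, tor_off = tor_off, element = element)
}

SIDECHAIN_TOPOLOGY <- list(
  A = list(),
  G = list(),
  S = list(sc_row("OG",  "N",  "CA", "CB", 1.417, 110.8, 1, 0, "O")),
  C = list(sc_row("SG",  "N",  "CA", "CB", 1.808, 113.8, 1, 0, "S")),
  T = list(sc_row("OG1", "N",  "CA", "CB", 1.433, 109.5, 1, 0, "O"),
           sc_row("CG2", "N",  "CA", "CB", 1.521, 110.5, 1, -120, "C")),
  V = list(sc_row("CG1", "N",  "CA", "CB", 1.527, 110.5, 1, 0, "C"),
           sc_row("CG2", "N",  "CA", "CB", 1.527, 110.5, 1, -122.3, "C")),
  L = list(sc_row("CG",  "N",  "CA", "CB", 1.530, 116.3, 1, 0, "C"),
           sc_row("CD1", "CA", "CB", "CG", 1.524, 110.7, 2, 0, "C"),
           sc_row("CD2", "CA", "CB", "CG", 1.525, 110.4, 2, 122.5, "C")),
  I = list(sc_row("CG1", "N",  "CA", "CB", 1.530, 110.4, 1, 0, "C"),
           sc_row("CG2", "N",  "CA", "CB", 1.521, 110.5, 1, -122.3, "C"),
           sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2, 0, "C")),
  M = list(sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1, 0, "C"),
           sc_row("SD",  "CA", "CB", "CG", 1.803, 112.7, 2, 0, "S"),
           sc_row("CE",  "CB", "CG", "SD", 1.791, 100.9, 3, 0, "C")),
  P = list(sc_row("CG",  "N",  "CA", "CB", 1.492, 104.5, 1, 0, "C"),
           sc_row("CD",  "CA", "CB", "CG", 1.503, 106.1, 2, 0, "C")),
  D = list(sc_row("CG",  "N",  "CA", "CB", 1.516, 112.6, 1, 0, "C"),
           sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 2, 0, "O"),
           sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 2, 180, "O")),
  N = list(sc_row("CG",  "N",  "CA", "CB", 1.516, 112.6, 1, 0, "C"),
           sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 2, 0, "O"),
           sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 2, 180, "N")),
  E = list(sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1, 0, "C"),
           sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 2, 0, "C"),
           sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 3, 0, "O"),
           sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 3, 180, "O")),
  Q = list(sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1, 0, "C"),
           sc_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 2, 0, "C"),
           sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 3, 0, "O"),
           sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 3, 180, "N")),
  K = list(sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1, 0, "C"),
           sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, 2, 0, "C"),
           sc_row("CE",  "CB", "CG", "CD", 1.520, 111.3, 3, 0, "C"),
           sc_row("NZ",  "CG", "CD", "CE", 1.489, 111.9, 4, 0, "N")),
  R = list(sc_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1, 0, "C"),
           sc_row("CD",  "CA", "CB", "CG", 1.520, 111.3, 2, 0, "C"),
           sc_row("NE",  "CB", "CG", "CD", 1.461, 112.0, 3, 0, "N"),
           sc_row("CZ",  "CG", "CD", "NE", 1.329, 124.2, 4, 0, "C"),
           sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0, 0, "N"),
           sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 0, 180, "N")),
  H = list(sc_row("CG",  "N",  "CA", "CB", 1.497, 113.8, 1, 0, "C"),
           sc_row("ND1", "CA", "CB", "CG", 1.378, 122.7, 2, 0, "N"),
           sc_row("CD2", "CA", "CB", "CG", 1.356, 131.0, 2, 180, "C"),
           sc_row("CE1", "CB", "CG", "ND1", 1.320, 109.3, 0, 180, "C"),
           sc_row("NE2", "CG", "ND1", "CE1", 1.320, 111.7, 0, 0, "N")),
  F = list(sc_row("CG",  "N",  "CA", "CB", 1.502, 113.8, 1, 0, "C"),
           sc_row("CD1", "CA", "CB", "CG", 1.384, 120.8, 2, 0, "C"),
           sc_row("CD2", "CA", "CB", "CG", 1.384, 120.8, 2, 180, "C"),
           sc_row("CE1", "CB", "CG", "CD1", 1.382, 120.8, 0, 180, "C"),
           sc_row("CE2", "CB", "CG", "CD2", 1.382, 120.8, 0, 180, "C"),
           sc_row("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, 0, 0, "C")),
  Y = list(sc_row("CG",  "N",  "CA", "CB", 1.502, 113.8, 1, 0, "C"),
           sc_row("CD1", "CA", "CB", "CG", 1.384, 120.8, 2, 0, "C"),
           sc_row("CD2", "CA", "CB", "CG", 1.384, 120.8, 2, 180, "C"),
           sc_row("CE1", "CB", "CG", "CD1", 1.382, 120.8, 0, 180, "C"),
           sc_row("CE2", "CB", "CG", "CD2", 1.382, 120.8, 0, 180, "C"),
           sc_row("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, 0, 0, "C"),
           sc_row("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, 0, 180, "O")),
  W = list(sc_row("CG",  "N",  "CA", "CB", 1.498, 113.6, 1, 0, "C"),
           sc_row("CD1", "CA", "CB", "CG", 1.365, 126.9, 2, 0, "C"),
           sc_row("CD2", "CA", "CB", "CG", 1.433, 126.6, 2, 180, "C"),
           sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, 0, 180, "N"),
           sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, 0, 180, "C"),
           sc_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0, 0, "C"),
           sc_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 0, 180, "C"),
           sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.8, 0, 180, "C"),
           sc_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0, 0, "C"))
)

# Number of chi angles per amino acid, derived from the topology
N_CHI <- vapply(SIDECHAIN_TOPOLOGY, function(top) {
  if (!length(top)) return(0L)
  max(vapply(top, function(r) as.numeric(r$tor_chi), numeric(1)))
}, numeric(1))

# Atom quadruples defining chi_k: (a1, a2, a3, atom) of the first topology
# row with tor_chi == k and tor_off == 0. Used both to build and to measure.
chi_definitions <- function(aa) {
  top <- SIDECHAIN_TOPOLOGY[[aa]]
  if (!length(top)) return(list())
  out <- list()
  for (k in seq_len(N_CHI[[aa]])) {
    row <- Filter(function(r) r$tor_chi == k && r$tor_off == 0, top)[[1]]
    out[[k]] <- c(row$a1, row$a2, row$a3, row$atom)
  }
  out
}

# Covalent bonds within a residue (heavy atoms): backbone + CB + topology
# parent bonds. Used for 1-2/1-3 exclusion in the clash term.
residue_bonds <- function(aa) {
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (aa != "G") bonds <- c(bonds, list(c("CA", "CB")))
  for (r in SIDECHAIN_TOPOLOGY[[aa]]) bonds <- c(bonds, list(c(r$a3, r$atom)))
  # ring closures (not part of the build tree but covalently bonded)
  extra <- switch(aa,
    P = list(c("CD", "N")),
    H = list(c("CD2", "NE2")),
    F = list(c("CD2", "CE2"), c("CE2", "CZ")),
    Y = list(c("CD2", "CE2"), c("CE2", "CZ")),
    W = list(c("NE1", "CE2"), c("CE3", "CZ3"), c("CZ2", "CH2")),
    list())
  c(bonds, extra)
}
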