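# Per-site energy: the documented, pluggable scorer behind the ddG scan.
#
#   E(site) = w_clash   * sum_pairs max(0, 0.85*(r_i + r_j) - d_ij)^2
#           + w_contact * sum_residues e(aa_site, aa_j)   [rep-atom <= 6.5 A]
#           + w_rotamer * (-ln p_rotamer)
#           + w_burial  * (-h(aa)/4.5) * burial_fraction
#
# Clash runs over heavy-atom pairs involving the site within 6 A, excluding
# 1-2/1-3 covalently bonded pairs. The contact potential is a rank-1
# hydrophobicity-factorized approximation to a statistical (Miyazawa-
# Jernigan-style) potential: e(a, b) = -(h_a * h_b)/4.5^2 with h the
# Kyte-Doolittle hydropathy; representative atom CB (CA for Gly). Burial is
# the capped count of foreign heavy atoms within 8 A of the representative
# atom. Every term and weight is configurable; the propensity transform
# downstream is agnostic to the scorer.

#' Energy-term weights for the site scorer
#'
#' @param clash,contact,rotamer,burial Non-negative term weights
#'   (kcal/mol-scaled). Defaults (10, 1, 0.6, 0.5).
#' @return A named list of class `foldscan_weights`.
#' @export
energy_weights <- function(clash = 10, contact = 1, rotamer = 0.6,
                           burial = 0.5) {
  w <- list(clash = clash, contact = contact, rotamer = rotamer,
            burial = burial)
  if (any(unlist(w) < 0)) rlang::abort("energy weights must be >= 0")
  structure(w, class = "foldscan_weights")
}

CLASH_CUTOFF <- 6.0
CLASH_SOFTNESS <- 0.85
CONTACT_CUTOFF <- 6.5
BURIAL_CUTOFF <- 8.0
BURIAL_SATURATION <- 40

# intra-residue atom pairs at graph distance <= 2 (1-2 and 1-3)
.bonded_pairs_cache <- new.env(parent = emptyenv())
intra_excluded_pairs <- function(aa) {
  if (!is.null(.bonded_pairs_cache[[aa]])) return(.bonded_pairs_cache[[aa]])
  bonds <- residue_bonds(aa)
  atoms <- unique(unlist(bonds))
  adj <- stats::setNames(vector("list", length(atoms)), atoms)
  for (b in bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  excl <- character(0)
  for (a in atoms) {
    one <- unique(adj[[a]])
    two <- unique(unlist(adj[one]))
    near <- setdiff(unique(c(one, two)), a)
    excl <- c(excl, paste(pmin(a, near), pmax(a, near), sep = "|"))
  }
  res <- unique(excl)
  .bonded_pairs_cache[[aa]] <- res
  res
}

# cross-peptide 1-2/1-3 exclusions, keyed "siteAtom|otherAtom" with `next`
# meaning the residue after the site and `prev` before it
PEPTIDE_EXCL_NEXT <- c("C|N", "CA|N", "O|N", "C|CA")
PEPTIDE_EXCL_PREV <- c("N|C", "N|CA", "N|O", "CA|C")

#' Score one residue site
#'
#' Computes the site's energy terms against the rest of the structure
#' (neighbors fixed). Deterministic; the clash term is non-negative.
#'
#' @param model A `foldscan_structure`.
#' @param chain,seq_number,icode Site identity.
#' @param library Rotamer library (for the rotamer self-energy of the
#'   site's current conformation, assigned by nearest library rotamer).
#' @param weights `energy_weights()`.
#' @return A list of class `foldscan_energy` with elements `clash`,
#'   `contact`, `rotamer_self`, `burial`, `total` (kcal/mol).
#' @export
score_site <- function(model, chain, seq_number, icode = "",
                       library = default_rotamer_library(),
                       weights = energy_weights()) {
  in_site <- model$chain == chain & model$seq_number == seq_number &
    model$icode == icode
  if (!any(in_site)) rlang::abort("site not found in structure")
  s <- which(in_site)
  o <- which(!in_site)
  aa <- model$aa[s[1]]

  sx <- model$x[s]; sy <- model$y[s]; sz <- model$z[s]
  sa <- model$atom[s]
  se <- model$element[s]

  # ---- clash: cross pairs (site x rest) ----
  clash <- 0
  if (length(o)) {
    dx <- outer(sx, model$x[o], "-")
    dy <- outer(sy, model$y[o], "-")
    dz <- outer(sz, model$z[o], "-")
    d <- sqrt(dx^2 + dy^2 + dz^2)
    thr <- CLASH_SOFTNESS *
      outer(VDW_RADII[se], VDW_RADII[model$element[o]], "+")
    over <- thr - d
    over[d > CLASH_CUTOFF] <- 0
    # exclude covalent neighbors across the peptide bond
    nbr_next <- model$chain[o] == chain & model$seq_number[o] == seq_number + 1
    nbr_prev <- model$chain[o] == chain & model$seq_number[o] == seq_number - 1
    for (side in c("next", "prev")) {
      cols <- which(if (side == "next") nbr_next else nbr_prev)
      if (!length(cols)) next
      excl <- if (side == "next") PEPTIDE_EXCL_NEXT else PEPTIDE_EXCL_PREV
      keys <- outer(sa, model$atom[o][cols], paste, sep = "|")
      sub <- over[, cols, drop = FALSE]
      sub[keys %in% excl] <- 0
      over[, cols] <- sub
    }
    clash <- sum(pmax(0, over)^2)
  }
  # ---- clash: intra-site pairs beyond 1-3 ----
  if (length(s) > 1) {
    excl <- intra_excluded_pairs(aa)
    ns <- length(s)
    for (i in seq_len(ns - 1)) {
      for (j in (i + 1):ns) {
        key <- paste(min(sa[i], sa[j]), max(sa[i], sa[j]), sep = "|")
        if (key %in% excl) next
        d <- sqrt((sx[i] - sx[j])^2 + (sy[i] - sy[j])^2 + (sz[i] - sz[j])^2)
        if (d > CLASH_CUTOFF) next
        ov <- CLASH_SOFTNESS * (VDW_RADII[[se[i]]] + VDW_RADII[[se[j]]]) - d
        if (ov > 0) clash <- clash + ov^2
      }
    }
  }

  # ---- representative atom (CB, CA for Gly) ----
  rep_i <- match("CB", sa)
  if (is.na(rep_i)) rep_i <- match("CA", sa)
  rep_xyz <- c(sx[rep_i], sy[rep_i], sz[rep_i])

  contact <- 0
  burial_n <- 0
  if (length(o)) {
    # other residues' representative atoms
    others <- model[o, c("chain", "seq_number", "icode", "aa", "atom",
                         "x", "y", "z")]
    reps <- others[others$atom == "CB" |
                     (others$atom == "CA" & others$aa == "G"), , drop = FALSE]
    if (nrow(reps)) {
      dr <- sqrt((reps$x - rep_xyz[1])^2 + (reps$y - rep_xyz[2])^2 +
                   (reps$z - rep_xyz[3])^2)
      inc <- dr <= CONTACT_CUTOFF
      if (any(inc)) {
        contact <- sum(-(KD_HYDROPATHY[[aa]] * KD_HYDROPATHY[reps$aa[inc]]) /
                         4.5^2)
      }
    }
    do <- sqrt((model$x[o] - rep_xyz[1])^2 + (model$y[o] - rep_xyz[2])^2 +
                 (model$z[o] - rep_xyz[3])^2)
    burial_n <- sum(do <= BURIAL_CUTOFF)
  }
  burial_fraction <- min(1, burial_n / BURIAL_SATURATION)
  burial <- -(KD_HYDROPATHY[[aa]] / 4.5) * burial_fraction

  # ---- rotamer self-energy ----
  rot_self <- 0
  if (N_CHI[[aa]] > 0) {
    chis <- measure_chis(model[s, , drop = FALSE], aa)
    if (!anyNA(chis)) {
      k <- nearest_rotamer(library, aa, chis)
      rot_self <- -log(rotamer_probability(library, aa, k))
    }
  }

  terms <- list(
    clash = weights$clash * clash,
    contact = weights$contact * contact,
    rotamer_self = weights$rotamer * rot_self,
    burial = weights$burial * burial)
  terms$total <- terms$clash + terms$contact + terms$rotamer_self +
    terms$burial
  structure(terms, class = "foldscan_energy")
}

#' @export
print.foldscan_energy <- function(x, ...) {
  cat(sprintf(
    "<foldscan_energy> total %.4f (clash %.4f, contact %.4f, rotamer %.4f, burial %.4f)\n",
    x$total, x$clash, x$contact, x$rotamer_self, x$burial))
  invisible(x)
}
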