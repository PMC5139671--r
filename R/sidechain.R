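# Side-chain construction from internal coordinates. Backbone atoms are
# never touched; a side chain is fully determined by (backbone frame, amino
# acid, chi angles), so rebuilding the same rotamer on the same backbone is
# bit-reproducible.

# CB placement: improper torsion N-C-CA-CB = +122.6 deg (L-chirality),
# ideal tetrahedral frame.
.place_cb <- function(n, c_, ca) {
  nerf_place(n, c_, ca, bond = 1.530, angle = 110.5, torsion = 122.6)
}

# Build all side-chain atoms (CB onward) for amino acid `aa` at chi angles
# `chis` on the backbone frame (N, CA, C given as 3-vectors). Returns a
# tibble with atom, element, x, y, z (possibly 0 rows for Gly).
build_side_chain <- function(aa, chis, n, ca, c_) {
  out <- list()
  coords <- list(N = n, CA = ca, C = c_)
  if (aa != "G") {
    coords$CB <- .place_cb(n, c_, ca)
    out[[1]] <- list(atom = "CB", element = "C", xyz = coords$CB)
  }
  top <- SIDECHAIN_TOPOLOGY[[aa]]
  for (r in top) {
    torsion <- if (r$tor_chi > 0) chis[r$tor_chi] + r$tor_off else r$tor_off
    xyz <- nerf_place(coords[[r$a1]], coords[[r$a2]], coords[[r$a3]],
                      bond = r$bond, angle = r$angle, torsion = torsion)
    coords[[r$atom]] <- xyz
    out[[length(out) + 1]] <- list(atom = r$atom, element = r$element,
                                   xyz = xyz)
  }
  if (!length(out)) {
    return(tibble::tibble(atom = character(), element = character(),
                          x = numeric(), y = numeric(), z = numeric()))
  }
  tibble::tibble(
    atom = vapply(out, `[[`, character(1), "atom"),
    element = vapply(out, `[[`, character(1), "element"),
    x = vapply(out, function(o) o$xyz[1], numeric(1)),
    y = vapply(out, function(o) o$xyz[2], numeric(1)),
    z = vapply(out, function(o) o$xyz[3], numeric(1)))
}

# Measure the chi angles of a site from its coordinates. Returns numeric(0)
# for Gly/Ala, NA entries where atoms are missing.
measure_chis <- function(site_atoms, aa) {
  defs <- chi_definitions(aa)
  if (!length(defs)) return(numeric(0))
  coord_of <- function(name) {
    i <- match(name, site_atoms$atom)
    if (is.na(i)) return(NULL)
    c(site_atoms$x[i], site_atoms$y[i], site_atoms$z[i])
  }
  vapply(defs, function(d) {
    ps <- lapply(d, coord_of)
    if (any(vapply(ps, is.null, logical(1)))) return(NA_real_)
    dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
  }, numeric(1))
}

#' Place a mutant side chain at a rotamer-library conformation
#'
#' Replaces the side chain of one site by the target amino acid built from
#' ideal bond lengths/angles at the chi angles of the requested library
#' rotamer. Backbone atoms (and every other residue) are untouched. The
#' construction is deterministic: identical inputs give bit-identical
#' coordinates.
#'
#' @param model A `foldscan_structure`.
#' @param chain,seq_number,icode Site identity (author numbering).
#' @param target_aa One-letter code of the replacement amino acid.
#' @param rotamer_index 1-based index into the library's rotamers for
#'   `target_aa`.
#' @param library A rotamer library (default: packaged library).
#' @return A new `foldscan_structure` with the single-site variant.
#' @export
place_side_chain <- function(model, chain, seq_number, icode = "",
                             target_aa, rotamer_index = 1L,
                             library = default_rotamer_library()) {
  if (!target_aa %in% amino_acids()) {
    rlang::abort(paste0("not a standard amino acid: ", target_aa))
  }
  if (rotamer_index < 1 || rotamer_index > n_rotamers(library, target_aa)) {
    rlang::abort(paste0("invalid rotamer index ", rotamer_index, " for ",
                        target_aa))
  }
  in_site <- model$chain == chain & model$seq_number == seq_number &
    model$icode == icode
  if (!any(in_site)) rlang::abort("site not found in structure")
  site <- model[in_site, , drop = FALSE]
  bb <- lapply(c("N", "CA", "C"), function(a) {
    i <- match(a, site$atom)
    if (is.na(i)) rlang::abort(paste0("site lacks backbone atom ", a))
    c(site$x[i], site$y[i], site$z[i])
  })
  chis <- rotamer_chis(library, target_aa, rotamer_index)
  sc <- build_side_chain(target_aa, chis, bb[[1]], bb[[2]], bb[[3]])

  keep_bb <- site[site$atom %in% c(BACKBONE_ATOMS, "OXT"), , drop = FALSE]
  keep_bb$aa <- target_aa
  new_rows <- if (nrow(sc)) {
    tibble::tibble(
      chain = chain, seq_number = seq_number, icode = icode,
      aa = target_aa, atom = sc$atom, element = sc$element,
      x = sc$x, y = sc$y, z = sc$z, occupancy = 1, is_sidechain = TRUE)
  } else NULL
  replaced <- dplyr::bind_rows(keep_bb, new_rows)

  idx <- which(in_site)
  before <- if (idx[1] > 1) model[seq_len(idx[1] - 1), , drop = FALSE] else NULL
  after_start <- idx[length(idx)] + 1
  after <- if (after_start <= nrow(model)) {
    model[after_start:nrow(model), , drop = FALSE]
  } else NULL
  out <- dplyr::bind_rows(before, replaced, after)
  new_structure(out, id = attr(model, "id"), source = attr(model, "source"),
                parse_report = attr(model, "parse_report"))
}
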