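# Structure model: a tidy atom table with one row per heavy atom.
#
# Columns: chain, seq_number, icode, aa (one-letter), atom, element,
# x, y, z (Angstrom), occupancy, is_sidechain. Attributes: id, source,
# parse_report. Author numbering (chain, seq_number, icode) is preserved
# for every report; internal site indices are ordinal.

new_structure <- function(atoms, id = "structure", source = "memory",
                          parse_report = list()) {
  atoms <- tibble::as_tibble(atoms)
  structure(atoms,
            id = id, source = source, parse_report = parse_report,
            class = c("foldscan_structure", class(tibble::tibble())))
}

#' @export
print.foldscan_structure <- function(x, ...) {
  sites <- structure_sites(x)
  cat("<foldscan_structure> ", attr(x, "id"), "\n",
      "  ", nrow(sites), " residue site(s), ", nrow(x), " heavy atoms, ",
      sum(sites$scannable), " scannable\n", sep = "")
  NextMethod()
}

#' Residue sites of a structure
#'
#' One row per residue site, in structure order. A site is scannable when
#' all four backbone atoms (N, CA, C, O) are present; unscannable sites are
#' flagged, never silently mutated.
#'
#' @param model A `foldscan_structure`.
#' @return Tibble with columns `site` (ordinal), `chain`, `seq_number`,
#'   `icode`, `aa`, `scannable`.
#' @export
structure_sites <- function(model) {
  model |>
    dplyr::group_by(.data$chain, .data$seq_number, .data$icode, .data$aa) |>
    dplyr::summarise(
      scannable = all(BACKBONE_ATOMS %in% .data$atom), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$seq_number, .data$icode) |>
    dplyr::mutate(site = dplyr::row_number(), .before = 1)
}

# Author-numbering label used in all reports, e.g. "M1" or "M1A" (icode),
# prefixed with the chain when the structure has several chains.
site_labels <- function(sites, multi_chain = length(unique(sites$chain)) > 1) {
  lab <- paste0(sites$aa, sites$seq_number, trimws(sites$icode))
  if (multi_chain) lab <- paste0(sites$chain, ":", lab)
  lab
}

# Atom rows of one site
site_atoms <- function(model, chain, seq_number, icode) {
  model[model$chain == chain & model$seq_number == seq_number &
          model$icode == icode, , drop = FALSE]
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of the first MODEL, keeping heavy atoms of standard
#' residues (selenomethionine MSE is mapped to Met). Waters, other
#' heteroatoms and non-standard residues are excluded but tallied in the
#' parse report (`attr(x, "parse_report")`). Alternate locations are
#' resolved by highest occupancy, ties by altloc label order.
#'
#' @param path Path to a PDB file.
#' @param chain_filter Optional character vector of chain identifiers to
#'   keep. An absent chain is an error naming the available chains.
#' @return A `foldscan_structure` tibble of atoms.
#' @export
parse_pdb <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)

  # first MODEL only
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    lines <- lines[seq(model_starts[1], ends[1])]
  }

  rec <- substr(lines, 1, 6)
  is_atom <- grepl("^ATOM", rec) | grepl("^HETATM", rec)
  atom_lines <- lines[is_atom]
  if (!length(atom_lines)) rlang::abort("no ATOM records in file")

  resname <- trimws(substr(atom_lines, 18, 20))
  hetero <- grepl("^HETATM", substr(atom_lines, 1, 6))
  # MSE (selenomethionine) is treated as Met, selenium as sulfur
  is_mse <- resname == "MSE"
  resname[is_mse] <- "MET"

  keep_std <- resname %in% names(AA1)
  n_water <- sum(resname %in% c("HOH", "WAT", "DOD"))
  n_hetero_excl <- sum(hetero & !keep_std & !(resname %in% c("HOH", "WAT", "DOD")))
  nonstd <- unique(resname[!keep_std & !(resname %in% c("HOH", "WAT", "DOD"))])
  if (length(nonstd)) {
    rlang::warn(paste0("excluding non-standard residue(s): ",
                       paste(nonstd, collapse = ", ")))
  }

  al <- atom_lines[keep_std]
  if (!length(al)) rlang::abort("no standard-residue ATOM records in file")
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resn <- trimws(substr(al, 18, 20))
  resn[resn == "MSE"] <- "MET"
  chain <- substr(al, 22, 22)
  seqn <- as.integer(substr(al, 23, 26))
  icode <- trimws(substr(al, 27, 27))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  occ <- suppressWarnings(as.numeric(substr(al, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- trimws(substr(al, 77, 78))
  elem[elem == "SE"] <- "S"
  elem[elem == ""] <- substr(gsub("[0-9']", "", name[elem == ""]), 1, 1)

  atoms <- tibble::tibble(
    chain = chain, seq_number = seqn, icode = icode,
    aa = unname(AA1[resn]), atom = name, element = elem,
    x = x, y = y, z = z, occupancy = occ, altloc = altloc)

  # drop hydrogens/deuterium; heavy atoms only
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]

  if (!is.null(chain_filter)) {
    avail <- unique(atoms$chain)
    missing <- setdiff(chain_filter, avail)
    if (length(missing)) {
      rlang::abort(paste0("chain(s) not in structure: ",
                          paste(missing, collapse = ","),
                          "; available: ", paste(avail, collapse = ",")))
    }
    atoms <- atoms[atoms$chain %in% chain_filter, , drop = FALSE]
  }

  # altloc resolution: highest occupancy, ties by altloc label order
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$seq_number, .data$icode, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$seq_number, .data$icode)
  atoms$altloc <- NULL
  atoms$is_sidechain <- !(atoms$atom %in% c(BACKBONE_ATOMS, "OXT"))

  report <- list(n_atoms = nrow(atoms), n_water = n_water,
                 n_hetero_excluded = n_hetero_excl,
                 nonstandard_residues = nonstd, mse_mapped = any(is_mse))
  new_structure(atoms, id = tools::file_path_sans_ext(basename(path)),
                source = path, parse_report = report)
}

#' Write a structure model to a PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals), so a
#' parse/write round trip preserves site identities and coordinates to
#' 0.001 Angstrom.
#'
#' @param model A `foldscan_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  if (!nrow(model)) rlang::abort("cannot write an empty structure")
  name_field <- ifelse(nchar(model$atom) < 4,
                       sprintf(" %-3s", model$atom),
                       sprintf("%-4s", model$atom))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(model)), name_field, AA3[model$aa], model$chain,
    model$seq_number, ifelse(model$icode == "", " ", model$icode),
    model$x, model$y, model$z, model$occupancy, 0, model$element)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
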