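# The saturation scan: every scannable position x all 20 amino acids
# (19 missense + 1 identity), mutant side chains from the rotamer library,
# ddG = best mutant site energy minus wild-type site energy. Positive ddG
# is destabilizing. The scan is a pure function of (structure, library,
# weights): no randomness anywhere.

#' Scan settings
#'
#' @param library Rotamer library (`read_rotamer_library()` /
#'   `default_rotamer_library()`).
#' @param weights Energy-term weights (`energy_weights()`).
#' @param params Thermodynamic transform parameters
#'   (`transform_params()`), used to fill the propensity column.
#' @return A list of class `foldscan_config`.
#' @export
scan_config <- function(library = default_rotamer_library(),
                        weights = energy_weights(),
                        params = transform_params()) {
  structure(list(library = library, weights = weights, params = params),
            class = "foldscan_config")
}

#' Enumerate all substitutions of a structure
#'
#' Twenty targets per scannable site (19 missense plus the identity
#' substitution), targets in fixed alphabetical one-letter order.
#' Unscannable sites (incomplete backbone) are skipped with a warning.
#'
#' @param model A `foldscan_structure`.
#' @return Tibble with columns `site`, `chain`, `seq_number`, `icode`,
#'   `wt_aa`, `mut_aa`; exactly `20 * n_scannable_sites` rows.
#' @export
enumerate_mutations <- function(model) {
  sites <- structure_sites(model)
  if (!any(sites$scannable)) rlang::abort("no scannable sites in structure")
  skipped <- sum(!sites$scannable)
  if (skipped) {
    rlang::warn(paste0(skipped, " site(s) lack a complete backbone and are skipped"))
  }
  sites <- sites[sites$scannable, , drop = FALSE]
  tidyr::crossing(sites[c("site", "chain", "seq_number", "icode", "aa")],
                  mut_aa = amino_acids()) |>
    dplyr::rename(wt_aa = "aa") |>
    dplyr::arrange(.data$site, .data$mut_aa)
}

# ddG of mutating one site to mut_aa, given a precomputed wild-type site
# energy. Returns list(ddg, chosen_rotamer); chosen_rotamer 0 means the
# native conformation was kept (identity substitution at its optimum).
.site_ddg <- function(model, chain, seq_number, icode, wt_aa, mut_aa,
                      wt_total, library, weights) {
  best_e <- Inf
  best_k <- 1L
  for (k in seq_len(n_rotamers(library, mut_aa))) {
    variant <- place_side_chain(model, chain, seq_number, icode,
                                mut_aa, k, library)
    e <- score_site(variant, chain, seq_number, icode, library,
                    weights)$total
    if (e < best_e) {
      best_e <- e
      best_k <- k
    }
  }
  if (mut_aa == wt_aa && best_e >= wt_total) {
    # native conformation is among the candidates and is optimal:
    # identity ddG is exactly zero
    list(ddg = 0, chosen_rotamer = 0L)
  } else {
    list(ddg = best_e - wt_total, chosen_rotamer = best_k)
  }
}

#' Folding free-energy change of one substitution
#'
#' Builds every library rotamer of the target amino acid at the site
#' (surrounding residues held fixed), scores each variant and returns the
#' best. For an identity substitution the native conformation is included
#' among the candidates, so identity ddG is never positive and is exactly
#' zero whenever the native conformation is the site optimum — the
#' expectation the internal control tests on well-refined models.
#'
#' @inheritParams place_side_chain
#' @param mut_aa Target amino acid (one-letter).
#' @param weights Energy-term weights.
#' @return One-row tibble: `chain`, `seq_number`, `icode`, `wt_aa`,
#'   `mut_aa`, `ddg` (kcal/mol), `chosen_rotamer` (0 = native kept).
#' @export
compute_ddg <- function(model, chain, seq_number, icode = "", mut_aa,
                        library = default_rotamer_library(),
                        weights = energy_weights()) {
  sites <- structure_sites(model)
  row <- sites[sites$chain == chain & sites$seq_number == seq_number &
                 sites$icode == icode, , drop = FALSE]
  if (!nrow(row)) rlang::abort("site not found in structure")
  if (!row$scannable) rlang::abort("site lacks a complete backbone")
  wt_total <- score_site(model, chain, seq_number, icode, library,
                         weights)$total
  res <- .site_ddg(model, chain, seq_number, icode, row$aa, mut_aa,
                   wt_total, library, weights)
  tibble::tibble(chain = chain, seq_number = seq_number, icode = icode,
                 wt_aa = row$aa, mut_aa = mut_aa, ddg = res$ddg,
                 chosen_rotamer = res$chosen_rotamer)
}

#' Run the full saturation scan
#'
#' One record per (scannable site, target amino acid) pair in enumeration
#' order. Deterministic: re-running with the same inputs gives identical
#' records.
#'
#' @param model A `foldscan_structure`.
#' @param config A `scan_config()`.
#' @return Tibble of class `foldscan_scan`: `site`, `chain`, `seq_number`,
#'   `icode`, `wt_aa`, `mut_aa`, `ddg`, `chosen_rotamer`, `propensity`.
#' @export
#' @examples
#' fx <- make_fixture("helix", 3, sequence = "AAA", seed = 1)
#' scan <- run_scan(fx)
#' nrow(scan)  # 60
run_scan <- function(model, config = scan_config()) {
  pairs <- enumerate_mutations(model)
  per_site <- split(pairs, pairs$site)
  rows <- purrr::map(per_site, function(ps) {
    ch <- ps$chain[1]; sn <- ps$seq_number[1]; ic <- ps$icode[1]
    wt <- ps$wt_aa[1]
    wt_total <- score_site(model, ch, sn, ic, config$library,
                           config$weights)$total
    res <- purrr::map(ps$mut_aa, function(m) {
      .site_ddg(model, ch, sn, ic, wt, m, wt_total, config$library,
                config$weights)
    })
    ps$ddg <- vapply(res, `[[`, numeric(1), "ddg")
    ps$chosen_rotamer <- vapply(res, `[[`, integer(1), "chosen_rotamer")
    ps
  })
  out <- dplyr::bind_rows(rows)
  out$propensity <- propensity(out$ddg, config$params)
  structure(out,
            structure_id = attr(model, "id"), params = config$params,
            class = c("foldscan_scan", class(tibble::tibble())))
}
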