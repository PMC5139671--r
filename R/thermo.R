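# Two-state thermodynamics: ddG -> unfolding propensity on the universal
# 0-1 scale. The mutant folding free energy under the linear extrapolation
# model (LEM) is
#     dG_mut = dG_wt - m*[D] - ddG
# and the equilibrium unfolded population of a two-state folder is the
# Boltzmann fraction
#     P_u = 1 / (1 + exp(dG_mut / RT)).
# Anchors: dG_mut = 0 gives exactly 0.5 (folding-unfolding equilibrium);
# strongly stabilized mutants approach 0, strongly destabilized approach 1.
# Because the transform depends only on (ddG, parameters), propensities
# from different proteins are directly comparable.

#' Thermodynamic transform parameters
#'
#' @param dg_wt Wild-type folding stability dG_wt in kcal/mol (> 0 for a
#'   folded protein). Default 5.0 — a typical globular-protein stability;
#'   this is a calibration choice of the package, not a measured value. It
#'   puts the wild type near fully folded (propensity ~2e-4) and the 0.5
#'   equilibrium point at ddG = 5 kcal/mol.
#' @param rt R*T in kcal/mol; default 0.593 (298 K).
#' @param m_value LEM slope m in kcal/mol/M (>= 0); default 1.0.
#' @param denaturant Denaturant concentration in M at which the propensity
#'   is evaluated; default 0 (water).
#' @return A list of class `foldscan_params`.
#' @export
transform_params <- function(dg_wt = 5.0, rt = 0.593, m_value = 1.0,
                             denaturant = 0.0) {
  if (rt <= 0) rlang::abort("rt must be > 0")
  if (m_value < 0) rlang::abort("m_value must be >= 0")
  if (denaturant < 0) rlang::abort("denaturant must be >= 0")
  if (!is.finite(dg_wt)) rlang::abort("dg_wt must be finite")
  structure(list(dg_wt = dg_wt, rt = rt, m_value = m_value,
                 denaturant = denaturant), class = "foldscan_params")
}

#' Unfolding propensity of a mutant
#'
#' Maps ddG values onto the universal 0-1 unfolding propensity scale:
#' 0 = maximally stabilized, 0.5 = folding-unfolding equilibrium,
#' 1 = completely unfolded. Strictly increasing in ddG; overflow is
#' guarded, so extreme ddG saturates at 0 or 1 without NaN.
#'
#' @param ddg Numeric vector of folding free-energy changes (kcal/mol,
#'   positive = destabilizing).
#' @param params `transform_params()`.
#' @return Numeric vector of propensities in `[0, 1]`.
#' @export
#' @examples
#' propensity(c(0, 5, 10))  # wild-type-like, equilibrium, unfolded
propensity <- function(ddg, params = transform_params()) {
  dg_mut <- params$dg_wt - params$m_value * params$denaturant - ddg
  stats::plogis(-dg_mut / params$rt)
}

#' Assemble the mutation matrix
#'
#' The N x 20 matrix of unfolding propensities: one row per structure
#' position (author numbering, structure order), one column per target
#' amino acid in alphabetical order.
#'
#' @param records A scan-record tibble from [run_scan()] (or any tibble
#'   with the same columns; ddG is re-transformed with `params`). Input
#'   row order is irrelevant.
#' @param params `transform_params()`.
#' @return Tibble of class `foldscan_matrix`: `chain`, `seq_number`,
#'   `icode`, `wt_aa`, then the 20 amino-acid columns.
#' @export
build_matrix <- function(records, params = transform_params()) {
  aas <- amino_acids()
  need <- c("chain", "seq_number", "icode", "wt_aa", "mut_aa", "ddg")
  if (!all(need %in% names(records))) {
    rlang::abort("records must carry chain, seq_number, icode, wt_aa, mut_aa, ddg")
  }
  counts <- records |>
    dplyr::count(.data$chain, .data$seq_number, .data$icode)
  bad <- counts[counts$n != 20, , drop = FALSE]
  if (nrow(bad)) {
    rlang::abort(paste0("incomplete records (need 20 per site) at: ",
                        paste0(bad$chain, bad$seq_number, bad$icode,
                               collapse = ", ")))
  }
  wide <- records |>
    dplyr::mutate(propensity = propensity(.data$ddg, params)) |>
    dplyr::select("chain", "seq_number", "icode", "wt_aa", "mut_aa",
                  "propensity") |>
    tidyr::pivot_wider(names_from = "mut_aa", values_from = "propensity") |>
    dplyr::arrange(.data$chain, .data$seq_number, .data$icode) |>
    dplyr::select(dplyr::all_of(c("chain", "seq_number", "icode", "wt_aa",
                                  aas)))
  structure(wide, params = params,
            class = c("foldscan_matrix", class(tibble::tibble())))
}

# numeric matrix of propensities with report row labels
matrix_values <- function(matrix) {
  m <- as.matrix(matrix[amino_acids()])
  rownames(m) <- site_labels(
    data.frame(aa = matrix$wt_aa, seq_number = matrix$seq_number,
               icode = matrix$icode, chain = matrix$chain),
    multi_chain = length(unique(matrix$chain)) > 1)
  m
}
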