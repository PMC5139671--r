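# Quality control: (1) the rotamer-based internal control for structure-
# model acceptance — every residue "mutated to itself" across the
# alternative library rotamers of its own amino acid, whose ddG
# distribution should center on 0 with a tight confidence interval for a
# well-refined model; (2) the validation harness that scores predicted
# propensities against experimentally derived ones (percent matching and
# fit-score).

#' Self-rotamer ddG values of a structure
#'
#' For every scannable non-Gly/non-Ala site, the ddG of replacing the
#' native side chain by each *alternative* library rotamer of the same
#' amino acid. The native conformation (nearest library rotamer) is
#' excluded: the statistic probes the conformational spread of the model,
#' not the identity optimum.
#'
#' @param model A `foldscan_structure`.
#' @param library Rotamer library.
#' @param weights Energy-term weights.
#' @return Tibble: `chain`, `seq_number`, `icode`, `aa`, `rotamer`, `ddg`.
#' @export
self_rotamer_ddgs <- function(model, library = default_rotamer_library(),
                              weights = energy_weights()) {
  sites <- structure_sites(model)
  sites <- sites[sites$scannable, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    aa <- sites$aa[i]
    if (aa %in% c("G", "A") || n_rotamers(library, aa) < 2) next
    ch <- sites$chain[i]; sn <- sites$seq_number[i]; ic <- sites$icode[i]
    s_atoms <- site_atoms(model, ch, sn, ic)
    chis <- measure_chis(s_atoms, aa)
    native_k <- if (anyNA(chis)) NA_integer_ else {
      nearest_rotamer(library, aa, chis)
    }
    wt_e <- score_site(model, ch, sn, ic, library, weights)$total
    for (k in seq_len(n_rotamers(library, aa))) {
      if (!is.na(native_k) && k == native_k) next
      variant <- place_side_chain(model, ch, sn, ic, aa, k, library)
      e <- score_site(variant, ch, sn, ic, library, weights)$total
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain = ch, seq_number = sn, icode = ic, aa = aa,
        rotamer = k, ddg = e - wt_e)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(chain = character(), seq_number = integer(),
                          icode = character(), aa = character(),
                          rotamer = integer(), ddg = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Internal-control statistics
#'
#' One-sample summary of self-rotamer ddG values against the expectation
#' of 0: mean, sample SD, two-sided one-sample t-test p-value, and the
#' `1 - alpha` confidence interval `mean +/- t * SD / sqrt(n)`.
#'
#' The acceptance flag follows the configured rule. `"tolerance"`
#' (default): accept iff `|mean| <= mean_tolerance` and the CI half-width
#' is `<= width_tolerance` — the coherent reading of "average close to 0
#' with a small confidence interval". `"pvalue"`: accept iff p < alpha
#' (the literal significance criterion; note a significant test against 0
#' argues *against* mean ~ 0, so this reading is offered but not the
#' default). The raw p-value is always reported.
#'
#' @param ddgs Numeric vector of self-rotamer ddG values (or the tibble
#'   from [self_rotamer_ddgs()]).
#' @param alpha Significance level; default 0.05.
#' @param mean_tolerance,width_tolerance Acceptance tolerances (kcal/mol);
#'   defaults 0.5 and 1.0.
#' @param rule `"tolerance"` or `"pvalue"`.
#' @param structure_id Label carried into the result.
#' @return A list of class `foldscan_control`: `structure_id`, `n`,
#'   `mean_ddg`, `sd_ddg`, `p_value`, `ci_low`, `ci_high`, `accepted`.
#' @export
control_statistics <- function(ddgs, alpha = 0.05, mean_tolerance = 0.5,
                               width_tolerance = 1.0,
                               rule = c("tolerance", "pvalue"),
                               structure_id = "structure") {
  rule <- match.arg(rule)
  if (is.data.frame(ddgs)) ddgs <- ddgs$ddg
  n <- length(ddgs)
  if (n < 2) {
    rlang::warn("fewer than 2 self-rotamer ddG values; statistics undefined")
    res <- list(structure_id = structure_id, n = n, mean_ddg = NA_real_,
                sd_ddg = NA_real_, p_value = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, accepted = FALSE)
    return(structure(res, class = "foldscan_control"))
  }
  m <- mean(ddgs)
  s <- stats::sd(ddgs)
  if (s == 0) {
    # zero-variance convention: p = 1 when the mean is exactly 0 (no
    # evidence of deviation), p = 0 otherwise (certain deviation)
    p <- if (m == 0) 1 else 0
    half <- 0
  } else {
    tstat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    half <- stats::qt(1 - alpha / 2, df = n - 1) * s / sqrt(n)
  }
  accepted <- if (rule == "tolerance") {
    abs(m) <= mean_tolerance && half <= width_tolerance
  } else {
    p < alpha
  }
  res <- list(structure_id = structure_id, n = n, mean_ddg = m, sd_ddg = s,
              p_value = p, ci_low = m - half, ci_high = m + half,
              accepted = accepted)
  structure(res, class = "foldscan_control")
}

#' @export
print.foldscan_control <- function(x, ...) {
  cat("<foldscan_control> ", x$structure_id, "\n", sep = "")
  cat(sprintf("  n = %d, mean ddG = %.4f, SD = %.4f kcal/mol\n",
              x$n, x$mean_ddg, x$sd_ddg))
  cat(sprintf("  p = %.4g, 95%% CI [%.4f, %.4f], %s\n", x$p_value,
              x$ci_low, x$ci_high,
              if (isTRUE(x$accepted)) "ACCEPTED" else "not accepted"))
  invisible(x)
}

#' Run the internal control on a structure
#'
#' Convenience wrapper: [self_rotamer_ddgs()] followed by
#' [control_statistics()].
#'
#' @inheritParams self_rotamer_ddgs
#' @param ... Passed to [control_statistics()].
#' @return A `foldscan_control`.
#' @export
internal_control <- function(model, library = default_rotamer_library(),
                             weights = energy_weights(), ...) {
  ddgs <- self_rotamer_ddgs(model, library, weights)
  control_statistics(ddgs$ddg, structure_id = attr(model, "id"), ...)
}

.classify_propensity <- function(p, neutral_band) {
  cut(p, breaks = c(-Inf, 0.5 - neutral_band, 0.5 + neutral_band, Inf),
      labels = c("stabilized", "neutral", "destabilized"))
}

#' Percent matching of predicted vs experimental propensities
#'
#' Each propensity is classified stabilized (< 0.5 - band), neutral, or
#' destabilized (> 0.5 + band); the score is the percentage of positions
#' whose predicted and experimental classes agree.
#'
#' @param pred,exp Equal-length propensity vectors in `[0, 1]`.
#' @param neutral_band Half-width of the neutral class around 0.5;
#'   default 0.1.
#' @return Percentage in `[0, 100]`.
#' @export
percent_matching <- function(pred, exp, neutral_band = 0.1) {
  if (length(pred) != length(exp)) rlang::abort("length mismatch")
  if (!length(pred)) rlang::abort("need at least one pair")
  100 * mean(.classify_propensity(pred, neutral_band) ==
               .classify_propensity(exp, neutral_band))
}

#' Fit-score of predicted vs experimental propensities
#'
#' `1 - mean(|pred - exp|)` on the shared universal 0-1 scale; 1 is a
#' perfect fit. This closed form is the package's documented
#' reconstruction of a score whose original definition is not published in
#' the source data descriptor.
#'
#' @inheritParams percent_matching
#' @return Score in `[0, 1]`.
#' @export
fit_score <- function(pred, exp) {
  if (length(pred) != length(exp)) rlang::abort("length mismatch")
  if (!length(pred)) rlang::abort("need at least one pair")
  1 - mean(abs(pred - exp))
}

#' Read an experimental ddG table
#'
#' Tab-delimited with columns `position`, `wt_aa`, `mut_aa`, `ddg_exp`
#' (kcal/mol, positive = destabilizing).
#'
#' @param path File path.
#' @return Tibble with those columns.
#' @export
read_experimental_ddg <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "wt_aa", "mut_aa", "ddg_exp")
  if (!all(need %in% names(raw))) {
    rlang::abort(paste0("experimental table needs columns: ",
                        paste(need, collapse = ", ")))
  }
  ok <- raw$wt_aa %in% amino_acids() & raw$mut_aa %in% amino_acids() &
    is.finite(raw$ddg_exp)
  if (!all(ok)) rlang::abort("non-standard amino acid or non-finite ddG in table")
  tibble::as_tibble(raw[need])
}

#' Score scan predictions against an experimental ddG table
#'
#' Experimental ddG values are converted to propensities with the same
#' transform as the predictions, then matched to scan records by
#' (position, wild-type, mutant).
#'
#' @param records Scan records from [run_scan()].
#' @param experimental Tibble from [read_experimental_ddg()].
#' @param params `transform_params()` applied to both sides.
#' @param neutral_band Passed to [percent_matching()].
#' @return A list: `n` pairs used, `percent_matching`, `fit_score`, and
#'   the paired tibble `pairs`.
#' @export
validate_predictions <- function(records, experimental,
                                 params = transform_params(),
                                 neutral_band = 0.1) {
  exp2 <- experimental
  exp2$prop_exp <- propensity(exp2$ddg_exp, params)
  pairs <- dplyr::inner_join(
    dplyr::mutate(records, prop_pred = propensity(.data$ddg, params)),
    exp2,
    by = c("seq_number" = "position", "wt_aa", "mut_aa"))
  if (!nrow(pairs)) rlang::abort("no overlapping mutations to score")
  list(n = nrow(pairs),
       percent_matching = percent_matching(pairs$prop_pred, pairs$prop_exp,
                                           neutral_band),
       fit_score = fit_score(pairs$prop_pred, pairs$prop_exp),
       pairs = tibble::as_tibble(pairs))
}
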