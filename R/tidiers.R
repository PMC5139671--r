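# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an internal-control result
#'
#' @param x A `foldscan_control`.
#' @param ... Unused.
#' @return One-row tibble: `structure_id`, `n`, `mean_ddg`, `sd_ddg`,
#'   `p_value`, `ci_low`, `ci_high`, `accepted`.
#' @method tidy foldscan_control
#' @export
tidy.foldscan_control <- function(x, ...) {
  tibble::tibble(structure_id = x$structure_id, n = x$n,
                 mean_ddg = x$mean_ddg, sd_ddg = x$sd_ddg,
                 p_value = x$p_value, ci_low = x$ci_low,
                 ci_high = x$ci_high, accepted = x$accepted)
}

#' @rdname tidy.foldscan_control
#' @method glance foldscan_control
#' @export
glance.foldscan_control <- function(x, ...) tidy(x)

#' Tidy a pipeline run
#'
#' @param x A `foldscan_run`.
#' @param ... Unused.
#' @return The artifact manifest (file, md5).
#' @method tidy foldscan_run
#' @export
tidy.foldscan_run <- function(x, ...) x$manifest

#' @rdname tidy.foldscan_run
#' @method glance foldscan_run
#' @export
glance.foldscan_run <- function(x, ...) {
  tibble::tibble(n_scannable = x$counts$n_scannable,
                 n_mutations = x$counts$n_mutations,
                 control_n = x$counts$control_n,
                 control_mean_ddg = x$control$mean_ddg,
                 accepted = x$counts$accepted)
}

#' Heat map of a mutation matrix
#'
#' ggplot2 rendering of the N x 20 propensity matrix with the standard
#' blue-white-red scale anchored at 0/0.5/1.
#'
#' @param object A `foldscan_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot foldscan_matrix
#' @export
autoplot.foldscan_matrix <- function(object, ...) {
  labels <- site_labels(
    data.frame(aa = object$wt_aa, seq_number = object$seq_number,
               icode = object$icode, chain = object$chain),
    multi_chain = length(unique(object$chain)) > 1)
  long <- object |>
    dplyr::mutate(residue = factor(labels, levels = rev(labels))) |>
    tidyr::pivot_longer(dplyr::all_of(amino_acids()),
                        names_to = "mutation", values_to = "propensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mutation, y = .data$residue,
                                     fill = .data$propensity)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "mutation", y = "wild-type residue",
                  fill = "unfolding\npropensity") +
    ggplot2::theme_minimal()
}

#' Descriptor profiles along the sequence
#'
#' @param object A `foldscan_descriptors`.
#' @param ... Unused.
#' @return A ggplot faceted by descriptor.
#' @method autoplot foldscan_descriptors
#' @export
autoplot.foldscan_descriptors <- function(object, ...) {
  long <- object |>
    dplyr::mutate(position = .data$seq_number) |>
    tidyr::pivot_longer(c("avg_propensity", "foldability", "entropy",
                          "depth"),
                        names_to = "descriptor", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~descriptor, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "residue position", y = NULL) +
    ggplot2::theme_minimal()
}
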