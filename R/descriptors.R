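# Per-residue descriptors derived from the mutation matrix and the 3D
# structure: average missense propensity, foldability (count-based severe-
# mutation tally), Shannon entropy of the discretized propensity profile,
# and residue depth below the solvent accessible surface.

#' Average unfolding propensity at a position
#'
#' Arithmetic mean over the 19 missense entries; the identity entry is
#' excluded (configurable).
#'
#' @param row Numeric vector of 20 propensities in matrix column order
#'   (alphabetical amino acids).
#' @param wt_aa Wild-type amino acid of the row (identifies the identity
#'   column to drop). If `NA`, all 20 entries are averaged.
#' @return Mean propensity in `[0, 1]`.
#' @export
average_propensity <- function(row, wt_aa = NA) {
  if (length(row) != 20) rlang::abort("row must have 20 propensities")
  if (!is.na(wt_aa)) row <- row[amino_acids() != wt_aa]
  mean(row)
}

#' Foldability of a position
#'
#' Tallies severe mutations without being influenced by less severe ones:
#' `1 - n_severe / 19`, where a missense entry is severe when its
#' propensity is at or above `severity_threshold`. Low foldability flags
#' critical residues essential to proper folding. This count-based form is
#' a documented reconstruction of a descriptor the source data format
#' defines only qualitatively.
#'
#' @inheritParams average_propensity
#' @param severity_threshold Severity cutoff in (0.5, 1]; default 0.9.
#' @return Foldability in `[0, 1]`.
#' @export
foldability <- function(row, wt_aa = NA, severity_threshold = 0.9) {
  if (length(row) != 20) rlang::abort("row must have 20 propensities")
  if (severity_threshold <= 0.5 || severity_threshold > 1) {
    rlang::abort("severity_threshold must be in (0.5, 1]")
  }
  if (!is.na(wt_aa)) row <- row[amino_acids() != wt_aa]
  1 - sum(row >= severity_threshold) / length(row)
}

#' Shannon entropy of a position's mutational profile
#'
#' Propensities are discretized to bins of width `bin_width` (by rounding,
#' so 0.1 gives 11 bins centered at 0, 0.1, ..., 1); P(x) is the empirical
#' bin frequency among all 20 entries (identity included: the profile has
#' 20 outcomes) and the entropy is `sum P(x) * log2(1/P(x))` in bits, with
#' `0 * log(1/0)` taken as 0. A position where every substitution lands in
#' one bin has 0 bits; a position split between the 0 and 1 bins has 1 bit
#' even though its average matches a uniformly-0.5 position.
#'
#' @param row Numeric vector of 20 propensities.
#' @param bin_width Bin width dividing 1 evenly; default 0.1.
#' @return Entropy in bits, in `[0, log2(20)]`.
#' @export
informational_entropy <- function(row, bin_width = 0.1) {
  if (length(row) != 20) rlang::abort("row must have 20 propensities")
  n_bins <- 1 / bin_width
  if (bin_width <= 0 || abs(n_bins - round(n_bins)) > 1e-9) {
    rlang::abort("bin_width must divide 1 evenly")
  }
  bins <- round(row / bin_width)
  p <- table(bins) / length(row)
  -sum(p * log2(p))
}

#' Residue depth below the solvent accessible surface
#'
#' The solvent accessible surface is sampled as a point cloud: each atom's
#' sphere of radius `r_vdw + probe_radius` is covered with
#' `n_sphere_points` deterministic (Fibonacci-lattice) directions and
#' points falling inside any other atom's expanded sphere are discarded.
#' An atom's depth is its minimum distance to the surviving surface
#' points; a residue's depth is the mean over its heavy atoms. Sampling
#' directions live in a PCA-canonicalized frame of the atom cloud, so
#' depths are invariant (to ~1e-9 A) under rigid motion of the input.
#'
#' @param model A `foldscan_structure`.
#' @param probe_radius Solvent probe radius in Angstrom; default 1.4
#'   (water).
#' @param n_sphere_points Sampling directions per atom; default 960.
#' @return Tibble: `chain`, `seq_number`, `icode`, `aa`, `depth` (Angstrom).
#' @export
residue_depth <- function(model, probe_radius = 1.4, n_sphere_points = 960) {
  if (!nrow(model)) rlang::abort("structure has no atoms")
  coords <- cbind(model$x, model$y, model$z)
  radii <- unname(VDW_RADII[model$element]) + probe_radius

  # canonical frame: centered, principal axes, deterministic signs
  center <- colMeans(coords)
  cc <- sweep(coords, 2, center)
  if (nrow(cc) > 3) {
    ev <- eigen(stats::cov(cc), symmetric = TRUE)$vectors
    proj <- cc %*% ev
    # sign convention intrinsic to the data (third moment of projections),
    # so any rigid motion of the input yields the same canonical coordinates
    for (j in 1:3) {
      if (sum(proj[, j]^3) < 0) proj[, j] <- -proj[, j]
    }
    cc <- proj
  }

  dirs <- fibonacci_sphere(n_sphere_points)
  atom_depth <- surface_min_distances(cc, radii, dirs)

  out <- model |>
    dplyr::mutate(.depth = atom_depth) |>
    dplyr::group_by(.data$chain, .data$seq_number, .data$icode, .data$aa) |>
    dplyr::summarise(depth = mean(.data$.depth), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$seq_number, .data$icode)
  out
}

# deterministic quasi-uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# build the accessible-surface point cloud and return the per-atom minimum
# distance from atom center to the cloud
surface_min_distances <- function(coords, radii, dirs) {
  n_atoms <- nrow(coords)
  pts <- list()
  for (i in seq_len(n_atoms)) {
    p <- dirs * radii[i]
    p <- sweep(p, 2, coords[i, ], "+")
    keep <- rep(TRUE, nrow(p))
    for (j in seq_len(n_atoms)) {
      if (j == i) next
      d2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      keep <- keep & d2 >= (radii[j] - 1e-9)^2
      if (!any(keep)) break
    }
    if (any(keep)) pts[[length(pts) + 1]] <- p[keep, , drop = FALSE]
  }
  if (!length(pts)) rlang::abort("no accessible surface found")
  surf <- do.call(rbind, pts)
  vapply(seq_len(n_atoms), function(i) {
    sqrt(min((surf[, 1] - coords[i, 1])^2 + (surf[, 2] - coords[i, 2])^2 +
               (surf[, 3] - coords[i, 3])^2))
  }, numeric(1))
}

#' Assemble the per-residue descriptor table
#'
#' Joins the mutation matrix with residue depths by site key (not by
#' position in the input) and computes the four descriptors per position.
#'
#' @param matrix A `foldscan_matrix` from [build_matrix()].
#' @param depths Depth tibble from [residue_depth()] (any row order).
#' @param severity_threshold Passed to [foldability()].
#' @param bin_width Passed to [informational_entropy()].
#' @param exclude_identity Drop the identity column from the average and
#'   foldability (default TRUE, matching their "missense" reading);
#'   entropy always sees all 20 outcomes.
#' @return Tibble of class `foldscan_descriptors`: `chain`, `seq_number`,
#'   `icode`, `wt_aa`, `avg_propensity`, `foldability`, `entropy`,
#'   `depth`.
#' @export
build_descriptors <- function(matrix, depths, severity_threshold = 0.9,
                              bin_width = 0.1, exclude_identity = TRUE) {
  vals <- as.matrix(matrix[amino_acids()])
  key <- matrix[c("chain", "seq_number", "icode", "wt_aa")]
  joined <- dplyr::left_join(
    key, depths,
    by = c("chain", "seq_number", "icode", "wt_aa" = "aa"))
  if (anyNA(joined$depth)) {
    rlang::abort("depth table does not cover every matrix site")
  }
  wt_for_drop <- if (exclude_identity) matrix$wt_aa else rep(NA, nrow(matrix))
  out <- tibble::tibble(
    chain = matrix$chain, seq_number = matrix$seq_number,
    icode = matrix$icode, wt_aa = matrix$wt_aa,
    avg_propensity = vapply(seq_len(nrow(vals)), function(i) {
      average_propensity(vals[i, ], wt_for_drop[i])
    }, numeric(1)),
    foldability = vapply(seq_len(nrow(vals)), function(i) {
      foldability(vals[i, ], wt_for_drop[i], severity_threshold)
    }, numeric(1)),
    entropy = vapply(seq_len(nrow(vals)), function(i) {
      informational_entropy(vals[i, ], bin_width)
    }, numeric(1)),
    depth = joined$depth)
  structure(out, severity_threshold = severity_threshold,
            class = c("foldscan_descriptors", class(tibble::tibble())))
}
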