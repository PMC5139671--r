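# Synthetic structure fixtures. These are the offline test substrate for
# the whole pipeline: ideal-geometry backbones whose side chains sit
# exactly at rotamer-library conformations, then relaxed (discrete
# coordinate descent over library rotamers) so each native side chain is
# the single-site energy optimum. On such structures an identity
# substitution has ddG = 0 at machine precision, which is what the
# internal-control logic expects of a well-refined model.

# Build an ideal backbone (N, CA, C, O per residue) from phi/psi vectors,
# omega fixed at 180. Returns a list of per-residue named coordinate lists.
build_backbone <- function(phi, psi) {
  n_res <- length(phi)
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.8
  res <- vector("list", n_res)
  t0 <- a_n_ca_c * pi / 180
  res[[1]] <- list(N = c(0, 0, 0), CA = c(b_n_ca, 0, 0),
                   C = c(b_n_ca, 0, 0) +
                     b_ca_c * c(-cos(t0), sin(t0), 0))
  for (i in seq_len(n_res)) {
    r <- res[[i]]
    if (i < n_res) {
      n_next <- nerf_place(r$N, r$CA, r$C, b_c_n, a_ca_c_n, psi[i])
      ca_next <- nerf_place(r$CA, r$C, n_next, b_n_ca, a_c_n_ca, 180)
      c_next <- nerf_place(r$C, n_next, ca_next, b_ca_c, a_n_ca_c,
                           phi[i + 1])
      res[[i + 1]] <- list(N = n_next, CA = ca_next, C = c_next)
    }
    # carbonyl O anti to the next N
    res[[i]]$O <- nerf_place(r$N, r$CA, r$C, b_c_o, a_ca_c_o, psi[i] + 180)
  }
  res
}

backbone_to_structure <- function(res_coords, sequence, id) {
  n_res <- length(res_coords)
  rows <- purrr::imap(res_coords, function(r, i) {
    tibble::tibble(
      chain = "A", seq_number = i, icode = "", aa = sequence[i],
      atom = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = c(r$N[1], r$CA[1], r$C[1], r$O[1]),
      y = c(r$N[2], r$CA[2], r$C[2], r$O[2]),
      z = c(r$N[3], r$CA[3], r$C[3], r$O[3]),
      occupancy = 1, is_sidechain = FALSE)
  })
  new_structure(dplyr::bind_rows(rows), id = id, source = "fixture")
}

# Discrete relaxation: repeatedly set each side chain to its single-site
# energy-optimal library rotamer until no strict improvement remains.
# Deterministic; terminates because total energy strictly decreases.
relax_rotamers <- function(model, library = default_rotamer_library(),
                           weights = energy_weights(), max_passes = 25) {
  sites <- structure_sites(model)
  sites <- sites[sites$scannable, , drop = FALSE]
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (i in seq_len(nrow(sites))) {
      aa <- sites$aa[i]
      if (n_rotamers(library, aa) < 2) next
      best_e <- score_site(model, sites$chain[i], sites$seq_number[i],
                           sites$icode[i], library, weights)$total
      best_model <- NULL
      for (k in seq_len(n_rotamers(library, aa))) {
        cand <- place_side_chain(model, sites$chain[i], sites$seq_number[i],
                                 sites$icode[i], aa, k, library)
        e <- score_site(cand, sites$chain[i], sites$seq_number[i],
                        sites$icode[i], library, weights)$total
        if (e < best_e - 1e-12) {
          best_e <- e
          best_model <- cand
        }
      }
      if (!is.null(best_model)) {
        model <- best_model
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  model
}

#' Generate a synthetic structure fixture
#'
#' Deterministic synthetic structures for offline testing: an ideal alpha
#' helix (phi = -57, psi = -47), a two-strand hairpin-like fold, or a
#' compact ball of residues packed on a spherical lattice so that genuinely
#' buried residues exist. Side chains are built at rotamer-library
#' conformations and relaxed so that the native conformation of every site
#' is its single-site energy optimum.
#'
#' @param kind `"helix"`, `"hairpin"` or `"compact_ball"`.
#' @param n_residues Number of residues (>= 3).
#' @param sequence Optional one-letter amino-acid string of length
#'   `n_residues`; by default a seed-determined random sequence.
#' @param seed Integer seed; identical calls are bit-identical.
#' @param library Rotamer library used for side-chain placement.
#' @param relax If `TRUE` (default) run the rotamer relaxation pass.
#' @return A `foldscan_structure`.
#' @export
#' @examples
#' fx <- make_fixture("helix", 5, sequence = "AAAAA", seed = 1)
#' structure_sites(fx)
make_fixture <- function(kind = c("helix", "hairpin", "compact_ball"),
                         n_residues, sequence = NULL, seed = 1,
                         library = default_rotamer_library(),
                         relax = TRUE) {
  kind <- match.arg(kind)
  if (n_residues < 3) rlang::abort("n_residues must be >= 3")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(seed)
  if (is.null(sequence)) {
    sequence <- sample(amino_acids(), n_residues, replace = TRUE)
  } else {
    sequence <- strsplit(sequence, "")[[1]]
    if (length(sequence) != n_residues) {
      rlang::abort("sequence length must equal n_residues")
    }
    if (!all(sequence %in% amino_acids())) {
      rlang::abort("sequence contains non-standard letters")
    }
  }

  id <- paste0(kind, "_", n_residues, "_seed", seed)
  if (kind %in% c("helix", "hairpin")) {
    if (kind == "helix") {
      phi <- rep(-57, n_residues)
      psi <- rep(-47, n_residues)
    } else {
      phi <- rep(-139, n_residues)
      psi <- rep(135, n_residues)
      mid <- floor(n_residues / 2)
      phi[mid] <- -60; psi[mid] <- -30
      phi[mid + 1] <- -90; psi[mid + 1] <- 0
    }
    model <- backbone_to_structure(build_backbone(phi, psi), sequence, id)
  } else {
    # compact ball: residue frames on a 5 A lattice sorted by radius,
    # seed-determined rigid orientations
    grid <- expand.grid(gx = -3:3, gy = -3:3, gz = -3:3)
    grid$norm <- with(grid, sqrt(gx^2 + gy^2 + gz^2))
    grid <- grid[order(grid$norm, grid$gx, grid$gy, grid$gz), ]
    if (n_residues > nrow(grid)) rlang::abort("n_residues too large")
    centers <- as.matrix(grid[seq_len(n_residues), c("gx", "gy", "gz")]) * 5.0
    t0 <- 111.2 * pi / 180
    tmpl <- list(N = c(-1.458, 0, 0), CA = c(0, 0, 0),
                 C = 1.525 * c(-cos(t0), sin(t0), 0))
    tmpl$O <- nerf_place(tmpl$N, tmpl$CA, tmpl$C, 1.231, 120.8, 133)
    res_coords <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      rot <- .quat_rotation(stats::rnorm(4))
      res_coords[[i]] <- lapply(tmpl, function(p) {
        as.numeric(rot %*% p) + as.numeric(centers[i, ])
      })
    }
    model <- backbone_to_structure(res_coords, sequence, id)
  }

  for (i in seq_len(n_residues)) {
    if (sequence[i] == "G") next
    model <- place_side_chain(model, "A", i, "", sequence[i], 1L, library)
  }
  if (relax) model <- relax_rotamers(model, library)
  attr(model, "id") <- id
  attr(model, "source") <- "fixture"
  model
}
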