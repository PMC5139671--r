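# Rotamer library: discrete side-chain conformations with prior
# probabilities. The packaged default is a coarse backbone-independent
# library (<= 4 rotamers per amino acid, chi1 wells at the canonical
# gauche-/trans/gauche+ positions, probabilities from broad published
# rotamer frequencies rounded to sum to one).

#' Read a rotamer library
#'
#' A rotamer library lists, per amino acid, discrete side-chain
#' conformations (chi angles, degrees) with prior probabilities. The file is
#' tab-delimited with columns `aa`, `chi1`..`chi4` (NA where the amino acid
#' has fewer chi angles) and `probability`.
#'
#' @param path Path to a tab-delimited library file.
#' @return A tibble of class `foldscan_rotamers` with columns `aa`,
#'   `rotamer` (1-based index within amino acid), `chi1`..`chi4`,
#'   `probability`.
#' @export
#' @examples
#' lib <- default_rotamer_library()
#' dplyr::count(lib, aa)
read_rotamer_library <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA", check.names = FALSE)
  needed <- c("aa", "chi1", "chi2", "chi3", "chi4", "probability")
  if (!all(needed %in% names(raw))) {
    rlang::abort(paste0("rotamer library must have columns: ",
                        paste(needed, collapse = ", ")))
  }
  lib <- tibble::as_tibble(raw[needed]) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(rotamer = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::relocate("rotamer", .after = "aa")
  validate_rotamer_library(lib)
  class(lib) <- c("foldscan_rotamers", class(lib))
  lib
}

#' @rdname read_rotamer_library
#' @export
default_rotamer_library <- function() {
  path <- system.file("extdata", "rotamer_library.tsv", package = "foldscan")
  read_rotamer_library(path)
}

validate_rotamer_library <- function(lib) {
  bad_aa <- setdiff(unique(lib$aa), amino_acids())
  if (length(bad_aa)) {
    rlang::abort(paste0("unknown amino acid(s) in rotamer library: ",
                        paste(bad_aa, collapse = ", ")))
  }
  missing <- setdiff(amino_acids(), unique(lib$aa))
  if (length(missing)) {
    rlang::abort(paste0("rotamer library lacks entries for: ",
                        paste(missing, collapse = ", ")))
  }
  sums <- tapply(lib$probability, lib$aa, sum)
  off <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(off)) {
    rlang::abort(paste0("rotamer probabilities must sum to 1 for: ",
                        paste(off, collapse = ", ")))
  }
  for (aa in c("A", "G")) {
    rows <- lib[lib$aa == aa, ]
    if (nrow(rows) != 1 || !all(is.na(unlist(rows[paste0("chi", 1:4)])))) {
      rlang::abort(paste0(aa, " must have exactly one empty-chi rotamer"))
    }
  }
  invisible(lib)
}

# chi angles of rotamer k of amino acid `aa` as a numeric vector (possibly
# length 0), trimmed to the amino acid's chi count
rotamer_chis <- function(lib, aa, k) {
  row <- lib[lib$aa == aa & lib$rotamer == k, ]
  if (!nrow(row)) rlang::abort(paste0("no rotamer ", k, " for ", aa))
  n <- N_CHI[[aa]]
  if (n == 0) return(numeric(0))
  chis <- as.numeric(row[paste0("chi", seq_len(n))])
  if (anyNA(chis)) rlang::abort(paste0("rotamer ", k, " of ", aa,
                                       " lacks required chi angles"))
  chis
}

n_rotamers <- function(lib, aa) sum(lib$aa == aa)

rotamer_probability <- function(lib, aa, k) {
  lib$probability[lib$aa == aa & lib$rotamer == k]
}

# Index of the library rotamer nearest (minimum circular chi distance) to
# the given chi angles; 1 for Gly/Ala. Deterministic: ties to lowest index.
nearest_rotamer <- function(lib, aa, chis) {
  n <- N_CHI[[aa]]
  if (n == 0) return(1L)
  rows <- which(lib$aa == aa)
  best <- 1L
  best_d <- Inf
  for (i in seq_along(rows)) {
    ref <- as.numeric(lib[rows[i], paste0("chi", seq_len(n))])
    d <- (chis - ref) %% 360
    d <- pmin(d, 360 - d)
    total <- sum(d^2)
    if (total < best_d - 1e-12) {
      best_d <- total
      best <- i
    }
  }
  best
}
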