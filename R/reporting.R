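# Report artifacts: the mutation matrix and descriptor files (tab-
# delimited text, Excel-openable), standard and clustered HTML heat maps
# (self-contained, hover labels, blue-white-red anchored at 0/0.5/1), the
# structure-coloring script + attribute table, and the pipeline
# orchestrator. All writers are pure functions of their inputs: identical
# inputs give byte-identical files.

FMT <- "%.3f"  # printed precision of all text outputs

#' Write the mutation matrix file
#'
#' Tab-delimited text: header row of the 20 amino-acid one-letter codes,
#' one row per position labelled by wild-type residue and author numbering
#' (e.g. `A23`), propensities at 3 decimals.
#'
#' @param matrix A `foldscan_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path) {
  m <- matrix_values(matrix)
  header <- paste(c("residue", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf(FMT, m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a written mutation matrix file
#'
#' @param path Path written by [write_matrix()].
#' @return Tibble: `residue` label plus the 20 amino-acid columns.
#' @export
read_matrix_file <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  tibble::as_tibble(raw)
}

#' Write the per-residue descriptor file
#'
#' Tab-delimited, one row per position, exactly five data columns in fixed
#' order: wild-type sequence, average unfolding propensity, foldability,
#' informational entropy (bits), residue depth (Angstrom).
#'
#' @param descriptors A `foldscan_descriptors`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_descriptor_file <- function(descriptors, path) {
  if (!nrow(descriptors)) rlang::abort("no descriptors to write")
  header <- paste(c("sequence", "avg_propensity", "foldability", "entropy",
                    "depth"), collapse = "\t")
  rows <- sprintf(paste0("%s\t", FMT, "\t", FMT, "\t", FMT, "\t", FMT),
                  descriptors$wt_aa, descriptors$avg_propensity,
                  descriptors$foldability, descriptors$entropy,
                  descriptors$depth)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_descriptor_file
#' @export
read_descriptor_file <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

# blue (0) -> white (0.5) -> red (1)
propensity_color <- function(p) {
  p <- pmin(1, pmax(0, p))
  lo <- p <= 0.5
  t_ <- ifelse(lo, p / 0.5, (p - 0.5) / 0.5)
  r <- ifelse(lo, round(255 * t_), 255)
  g <- ifelse(lo, round(255 * t_), round(255 * (1 - t_)))
  b <- ifelse(lo, 255, round(255 * (1 - t_)))
  sprintf("#%02X%02X%02X", r, g, b)
}

.heatmap_html <- function(m, title, extra = character(0)) {
  head_cells <- paste0("<th>", c("", colnames(m)), "</th>", collapse = "")
  body <- vapply(seq_len(nrow(m)), function(i) {
    cells <- vapply(seq_len(ncol(m)), function(j) {
      v <- m[i, j]
      sprintf('<td style="background-color:%s" title="%s &rarr; %s: %s">%s</td>',
              propensity_color(v), rownames(m)[i], colnames(m)[j],
              sprintf(FMT, v), sprintf(FMT, v))
    }, character(1))
    paste0("<tr><th>", rownames(m)[i], "</th>", paste0(cells, collapse = ""),
           "</tr>")
  }, character(1))
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", title, "</title>"),
    "<style>",
    "table{border-collapse:collapse;font:11px sans-serif}",
    "td,th{border:1px solid #ccc;padding:2px 4px;text-align:center}",
    "caption{font:bold 13px sans-serif;padding:4px}",
    "</style></head><body>",
    paste0("<table><caption>", title,
           " &mdash; unfolding propensity: 0 blue (stabilized), 0.5 white",
           " (equilibrium), 1 red (unfolded)</caption>"),
    paste0("<tr>", head_cells, "</tr>"),
    body,
    "</table>",
    extra,
    "</body></html>")
}

#' Render the standard heat map
#'
#' Self-contained HTML: rows are structure positions (wild-type residues,
#' author numbering), columns the 20 target amino acids; cell color runs
#' blue (0) through white (0.5) to red (1) and each cell's hover label
#' reports position, mutation and propensity.
#'
#' @param matrix A `foldscan_matrix`.
#' @param path Output path (.html).
#' @return Invisibly, `path`.
#' @export
render_standard_heatmap <- function(matrix, path) {
  m <- matrix_values(matrix)
  writeLines(.heatmap_html(m, "Mutation matrix"), path)
  invisible(path)
}

#' Render the clustered heat map
#'
#' Rows and columns are reordered by agglomerative hierarchical clustering
#' of their propensity vectors (Euclidean distance); the dendrograms are
#' embedded as newick strings below the map. A 1-row matrix falls back to
#' the standard map with a warning.
#'
#' @param matrix A `foldscan_matrix`.
#' @param path Output path (.html).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return Invisibly, `path`.
#' @export
render_clustered_heatmap <- function(matrix, path,
                                     linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  m <- matrix_values(matrix)
  if (nrow(m) < 2) {
    rlang::warn("fewer than 2 rows; writing a standard map instead")
    writeLines(.heatmap_html(m, "Mutation matrix"), path)
    return(invisible(path))
  }
  hr <- stats::hclust(stats::dist(m), method = linkage)
  hc <- stats::hclust(stats::dist(t(m)), method = linkage)
  mo <- m[hr$order, hc$order, drop = FALSE]
  nwk_r <- ape::write.tree(ape::as.phylo(hr))
  nwk_c <- ape::write.tree(ape::as.phylo(hc))
  extra <- c("<h3>Row dendrogram (newick)</h3>",
             paste0("<pre>", nwk_r, "</pre>"),
             "<h3>Column dendrogram (newick)</h3>",
             paste0("<pre>", nwk_c, "</pre>"))
  writeLines(.heatmap_html(mo, "Clustered mutation matrix", extra), path)
  invisible(path)
}

#' Write the structure-coloring script and attribute table
#'
#' Writes (a) a UCSF-Chimera-compatible Python script that assigns each
#' residue its foldability as a residue attribute and applies a red (0,
#' critical) to blue (1) color ramp, and (b) a generic tab-delimited
#' attribute table (chain, residue number, foldability). Residues at or
#' below `critical_cutoff` are reported as critical.
#'
#' @param model The scanned `foldscan_structure` (for author numbering).
#' @param descriptors A `foldscan_descriptors` covering all sites.
#' @param path Output path of the Python script (.py).
#' @param attr_path Output path of the attribute table; default: `path`
#'   with extension replaced by `_foldability.attr`.
#' @param critical_cutoff Foldability at or below which a residue is
#'   flagged critical; default 0.5.
#' @return Invisibly, a list with `script`, `attributes`,
#'   `critical` (tibble of flagged residues).
#' @export
write_structure_coloring <- function(model, descriptors, path,
                                     attr_path = NULL,
                                     critical_cutoff = 0.5) {
  sites <- structure_sites(model)
  sites <- sites[sites$scannable, , drop = FALSE]
  key_d <- paste(descriptors$chain, descriptors$seq_number,
                 descriptors$icode)
  key_s <- paste(sites$chain, sites$seq_number, sites$icode)
  if (!all(key_s %in% key_d)) {
    rlang::abort("descriptors do not cover all scannable sites")
  }
  d <- descriptors[match(key_s, key_d), , drop = FALSE]
  spec <- sprintf(":%d%s.%s", d$seq_number, trimws(d$icode), d$chain)

  critical <- d[d$foldability <= critical_cutoff, , drop = FALSE]
  if (nrow(critical)) {
    message("critical residues (foldability <= ", critical_cutoff, "): ",
            paste0(critical$wt_aa, critical$seq_number, collapse = ", "))
  }

  py <- c(
    "# Foldability coloring script (UCSF Chimera).",
    "# Residue attribute 'foldability': 0 = critical for folding, 1 = tolerant.",
    "from chimera import runCommand",
    sprintf('runCommand("setattr r foldability %s %s")',
            sprintf(FMT, d$foldability), spec),
    'runCommand("rangecolor foldability,r 0 red 0.5 white 1 blue")',
    "# critical residues:",
    if (nrow(critical)) {
      sprintf("#   %s%d%s (foldability %s)", critical$wt_aa,
              critical$seq_number, trimws(critical$icode),
              sprintf(FMT, critical$foldability))
    } else "#   none")
  writeLines(py, path)

  if (is.null(attr_path)) {
    attr_path <- paste0(tools::file_path_sans_ext(path), "_foldability.attr")
  }
  attr_lines <- c(
    "attribute: foldability",
    "match mode: 1-to-1",
    "recipient: residues",
    sprintf("\t%s\t%s", spec, sprintf(FMT, d$foldability)))
  writeLines(attr_lines, attr_path)

  invisible(list(script = path, attributes = attr_path,
                 critical = tibble::as_tibble(critical)))
}

#' Write the internal-control report
#'
#' @param control A `foldscan_control`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_control_report <- function(control, path) {
  lines <- c(
    paste0("structure\t", control$structure_id),
    paste0("n\t", control$n),
    paste0("mean_ddg\t", sprintf("%.6f", control$mean_ddg)),
    paste0("sd_ddg\t", sprintf("%.6f", control$sd_ddg)),
    paste0("p_value\t", sprintf("%.6g", control$p_value)),
    paste0("ci95_low\t", sprintf("%.6f", control$ci_low)),
    paste0("ci95_high\t", sprintf("%.6f", control$ci_high)),
    paste0("accepted\t", tolower(as.character(control$accepted))))
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input Path to a PDB file, or a `foldscan_structure`.
#' @param chains Optional chain filter (character vector).
#' @param out_dir Output directory (created if absent).
#' @param basename Artifact basename; default: structure id.
#' @param params `transform_params()`.
#' @param weights `energy_weights()`.
#' @param library Rotamer library.
#' @param severity_threshold,bin_width Descriptor settings.
#' @param probe_radius,n_sphere_points Depth settings.
#' @param linkage Clustering linkage.
#' @param critical_cutoff Foldability cutoff for the critical-residue list.
#' @return A list of class `foldscan_run_config`.
#' @export
run_config <- function(input, chains = NULL, out_dir = ".",
                       basename = NULL, params = transform_params(),
                       weights = energy_weights(),
                       library = default_rotamer_library(),
                       severity_threshold = 0.9, bin_width = 0.1,
                       probe_radius = 1.4, n_sphere_points = 960,
                       linkage = "average", critical_cutoff = 0.5) {
  structure(list(input = input, chains = chains, out_dir = out_dir,
                 basename = basename, params = params, weights = weights,
                 library = library, severity_threshold = severity_threshold,
                 bin_width = bin_width, probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points, linkage = linkage,
                 critical_cutoff = critical_cutoff),
            class = "foldscan_run_config")
}

#' Run the full pipeline
#'
#' parse -> scan -> transform -> descriptors -> internal control -> all
#' writers. Any stage failure aborts with a stage-named error and removes
#' partial outputs. The manifest lists every artifact with its MD5
#' checksum, so a rerun with the same configuration is checksum-identical.
#'
#' @param config A [run_config()].
#' @return A list of class `foldscan_run`: `manifest` (tibble file/md5),
#'   `control`, `counts`, `matrix`, `descriptors`, `records`.
#' @export
run_pipeline <- function(config) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  created <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(created)
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }
  model <- stage("parse", {
    if (inherits(config$input, "foldscan_structure")) config$input
    else parse_pdb(config$input, chain_filter = config$chains)
  })
  base <- config$basename
  if (is.null(base)) base <- attr(model, "id")
  p <- function(suffix) file.path(config$out_dir, paste0(base, suffix))

  records <- stage("scan", run_scan(model, scan_config(
    library = config$library, weights = config$weights,
    params = config$params)))
  mat <- stage("transform", build_matrix(records, config$params))
  depths <- stage("descriptors", residue_depth(
    model, probe_radius = config$probe_radius,
    n_sphere_points = config$n_sphere_points))
  desc <- stage("descriptors", build_descriptors(
    mat, depths, severity_threshold = config$severity_threshold,
    bin_width = config$bin_width))
  control <- stage("internal_control", internal_control(
    model, config$library, config$weights))

  stage("write", {
    created <- c(created, write_matrix(mat, p("_matrix.txt")))
    created <- c(created, write_descriptor_file(desc, p("_descriptor.txt")))
    created <- c(created, render_standard_heatmap(mat, p("_standard.html")))
    created <- c(created, render_clustered_heatmap(mat, p("_cluster.html"),
                                                    linkage = config$linkage))
    col <- write_structure_coloring(model, desc, p("_coloring.py"),
                                    p("_foldability.attr"),
                                    critical_cutoff = config$critical_cutoff)
    created <- c(created, col$script, col$attributes)
    created <- c(created, write_control_report(control, p("_control.txt")))
  })

  manifest <- tibble::tibble(
    file = created,
    md5 = unname(tools::md5sum(created)))
  sites <- structure_sites(model)
  counts <- list(n_sites = nrow(sites),
                 n_scannable = sum(sites$scannable),
                 n_mutations = nrow(records),
                 control_n = control$n,
                 accepted = control$accepted)
  message("scanned ", counts$n_scannable, " site(s), ",
          counts$n_mutations, " mutations; internal control n = ",
          counts$control_n, ", accepted = ", counts$accepted)
  structure(list(manifest = manifest, control = control, counts = counts,
                 matrix = mat, descriptors = desc, records = records),
            class = "foldscan_run")
}
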