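# a small synthetic matrix built directly (no scan needed)
synthetic_matrix <- function(vals, wt = NULL) {
  n <- nrow(vals)
  if (is.null(wt)) wt <- rep("A", n)
  out <- tibble::tibble(chain = "A", seq_number = seq_len(n), icode = "",
                        wt_aa = wt)
  colnames(vals) <- amino_acids()
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  structure(out, params = transform_params(),
            class = c("foldscan_matrix", class(tibble::tibble())))
}

test_that("matrix file: layout, round trip, and cell-level agreement", {
  scan <- run_scan(helix_aga3())
  mat <- build_matrix(scan)
  path <- withr::local_tempfile(fileext = ".txt")
  write_matrix(mat, path)
  lines <- readLines(path)
  expect_length(lines, 4)  # header + 3 rows
  expect_identical(strsplit(lines[1], "\t")[[1]],
                   c("residue", amino_acids()))
  back <- read_matrix_file(path)
  expect_identical(back$residue, c("A1", "G2", "A3"))
  vals <- as.matrix(mat[amino_acids()])
  expect_equal(as.matrix(back[amino_acids()]), round(vals, 3),
               ignore_attr = TRUE, tolerance = 1e-9)
  # the written G2/W cell equals the scan record's propensity
  rec <- scan[scan$seq_number == 2 & scan$mut_aa == "W", ]
  expect_equal(back$W[back$residue == "G2"], round(rec$propensity, 3))
})

test_that("descriptor file has the five columns in canonical order", {
  mat <- build_matrix(scan10())
  depths <- residue_depth(helix10(), n_sphere_points = 240)
  desc <- build_descriptors(mat, depths)
  path <- withr::local_tempfile(fileext = ".txt")
  write_descriptor_file(desc, path)
  back <- read_descriptor_file(path)
  expect_identical(names(back), c("sequence", "avg_propensity",
                                  "foldability", "entropy", "depth"))
  expect_equal(nrow(back), 10)
  expect_identical(back$sequence, desc$wt_aa)
  expect_equal(back$avg_propensity, round(desc$avg_propensity, 3),
               tolerance = 1e-9)
  expect_equal(back$depth, round(desc$depth, 3), tolerance = 1e-9)
})

test_that("standard heat map: cells, color anchors, hover labels, determinism", {
  vals <- matrix(runif(3 * 20), 3)
  vals[1, 1] <- 1
  vals[2, 2] <- 0
  vals[3, 3] <- 0.5
  mat <- synthetic_matrix(vals)
  p1 <- withr::local_tempfile(fileext = ".html")
  p2 <- withr::local_tempfile(fileext = ".html")
  render_standard_heatmap(mat, p1)
  html <- paste(readLines(p1), collapse = "\n")
  expect_equal(lengths(regmatches(html, gregexpr("<td ", html))), 60)
  expect_match(html, "background-color:#FF0000")  # propensity 1 = full red
  expect_match(html, "background-color:#0000FF")  # propensity 0 = full blue
  expect_match(html, "background-color:#FFFFFF")  # equilibrium = white
  expect_match(html, 'title="A1 &rarr; A: 1.000"', fixed = TRUE)
  render_standard_heatmap(mat, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("clustered map groups identical rows and preserves the cell multiset", {
  base <- matrix(runif(8 * 20), 8)
  base[2, ] <- base[7, ]  # two identical rows, far apart in input order
  # four cysteine-like rows sharing an extreme pattern
  pat <- c(rep(0.95, 5), rep(0.05, 15))
  for (i in c(1, 4, 6, 8)) base[i, ] <- pat + (i %% 3) * 1e-3
  mat <- synthetic_matrix(base)
  path <- withr::local_tempfile(fileext = ".html")
  render_clustered_heatmap(mat, path)
  html <- paste(readLines(path), collapse = "\n")
  # identical rows 2 and 7 are adjacent dendrogram leaves
  hr <- stats::hclust(stats::dist(foldscan:::matrix_values(mat)), "average")
  pos <- match(c(2, 7), hr$order)
  expect_equal(abs(diff(pos)), 1)
  # the four patterned rows form one subtree: contiguous in leaf order
  pos4 <- sort(match(c(1, 4, 6, 8), hr$order))
  expect_equal(pos4, seq(pos4[1], length.out = 4))
  # cell multiset identical to the standard map's
  std <- withr::local_tempfile(fileext = ".html")
  render_standard_heatmap(mat, std)
  get_vals <- function(f) {
    h <- paste(readLines(f), collapse = "")
    sort(as.numeric(regmatches(h, gregexpr("(?<=: )[0-9.]+(?=\")", h,
                                           perl = TRUE))[[1]]))
  }
  expect_identical(get_vals(path), get_vals(std))
  expect_match(html, "newick")
  # cophenetic distances agree with an independent naive UPGMA
  m <- foldscan:::matrix_values(mat)
  expect_equal(as.matrix(stats::cophenetic(hr)),
               naive_upgma_cophenetic(as.matrix(stats::dist(m))),
               ignore_attr = TRUE, tolerance = 1e-9)
  # degenerate single-row matrix falls back with a warning
  one <- synthetic_matrix(matrix(runif(20), 1))
  expect_warning(render_clustered_heatmap(one, withr::local_tempfile()),
                 "standard map")
})

test_that("structure coloring script and attribute table round-trip", {
  scan <- run_scan(helix_aga3())
  mat <- build_matrix(scan)
  depths <- residue_depth(helix_aga3(), n_sphere_points = 240)
  desc <- build_descriptors(mat, depths)
  desc$foldability[2] <- 0  # force a critical residue
  py <- withr::local_tempfile(fileext = ".py")
  at <- withr::local_tempfile(fileext = ".attr")
  res <- suppressMessages(
    write_structure_coloring(helix_aga3(), desc, py, at))
  script <- readLines(py)
  expect_length(grep("setattr r foldability", script), 3)
  expect_true(any(grepl(":2\\.A", script)))
  expect_equal(res$critical$seq_number, 2)
  # attribute file re-parses to the descriptor values at printed precision
  attr_lines <- readLines(at)
  vals <- as.numeric(sub(".*\t", "", grep("^\t", attr_lines, value = TRUE)))
  expect_equal(vals, round(desc$foldability, 3))
})

test_that("pipeline writes all artifacts deterministically and cleans up on error", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- function(dir) run_config(helix10(), out_dir = dir,
                                  n_sphere_points = 240)
  r1 <- suppressMessages(run_pipeline(cfg(out1)))
  r2 <- suppressMessages(run_pipeline(cfg(out2)))
  expect_equal(nrow(r1$manifest), 7)
  expect_identical(sort(basename(r1$manifest$file)),
                   sort(paste0("helix_10_seed1",
                               c("_matrix.txt", "_descriptor.txt",
                                 "_standard.html", "_cluster.html",
                                 "_coloring.py", "_foldability.attr",
                                 "_control.txt"))))
  expect_equal(r1$counts$n_mutations, 200)
  expect_identical(r1$manifest$md5, r2$manifest$md5)  # rerun-identical
  expect_identical(tidy(r1), r1$manifest)
  expect_true(is.logical(glance(r1)$accepted))
  # a bad chain aborts in the parse stage and leaves no partial output
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(helix_aaa3(), pdb)
  bad_dir <- withr::local_tempdir()
  expect_error(
    suppressMessages(run_pipeline(run_config(pdb, chains = "Q",
                                             out_dir = bad_dir))),
    "stage 'parse'")
  expect_length(list.files(bad_dir), 0)
})

test_that("autoplot methods return ggplot objects", {
  mat <- build_matrix(scan10())
  expect_s3_class(ggplot2::autoplot(mat), "ggplot")
  depths <- residue_depth(helix10(), n_sphere_points = 240)
  desc <- build_descriptors(mat, depths)
  expect_s3_class(ggplot2::autoplot(desc), "ggplot")
  ic <- internal_control(helix10())
  expect_s3_class(tidy(ic), "tbl_df")
  expect_equal(tidy(ic)$n, nrow(self_rotamer_ddgs(helix10())))
})
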