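test_that("self-rotamer enumeration excludes the native conformation", {
  fx <- helix10()
  lib <- default_rotamer_library()
  sr <- self_rotamer_ddgs(fx)
  sites <- structure_sites(fx)
  # per-site counts: n_rotamers - 1 for every non-Gly/Ala site
  expected_n <- sum(vapply(sites$aa, function(a) {
    if (a %in% c("G", "A")) 0L else foldscan:::n_rotamers(lib, a) - 1L
  }, integer(1)))
  expect_equal(nrow(sr), expected_n)
  # native conformation never appears
  for (i in which(!sites$aa %in% c("G", "A"))) {
    chis <- foldscan:::measure_chis(
      foldscan:::site_atoms(fx, "A", sites$seq_number[i], ""), sites$aa[i])
    nk <- foldscan:::nearest_rotamer(lib, sites$aa[i], chis)
    expect_false(nk %in% sr$rotamer[sr$seq_number == sites$seq_number[i]])
  }
  # all-Ala structures yield an empty control
  sr0 <- self_rotamer_ddgs(helix_aaa3())
  expect_equal(nrow(sr0), 0)
  # one value cross-checked against a hand-driven place + score composition
  one <- sr[1, ]
  w <- energy_weights()
  wt_e <- score_site(fx, one$chain, one$seq_number, one$icode, lib, w)$total
  v <- place_side_chain(fx, one$chain, one$seq_number, one$icode, one$aa,
                        one$rotamer, lib)
  alt_e <- score_site(v, one$chain, one$seq_number, one$icode, lib, w)$total
  expect_equal(one$ddg, alt_e - wt_e, tolerance = 1e-12)
  # relaxed fixtures: no alternative rotamer beats native (up to the
  # relaxation's strict-improvement tolerance)
  expect_true(all(sr$ddg >= -1e-9))
})

test_that("control statistics: degenerate conventions and symmetry", {
  z <- control_statistics(c(0, 0, 0, 0))
  expect_equal(z$mean_ddg, 0)
  expect_equal(z$sd_ddg, 0)
  expect_equal(z$p_value, 1)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))
  nz <- control_statistics(c(1, 1, 1))
  expect_equal(nz$p_value, 0)
  sym <- control_statistics(c(1, -1))
  expect_equal(sym$mean_ddg, 0)
  expect_lte(sym$ci_low, 0)
  expect_gte(sym$ci_high, 0)
  expect_warning(u <- control_statistics(numeric(0)), "fewer than 2")
  expect_false(u$accepted)
  expect_true(is.na(u$mean_ddg))
})

test_that("control statistics equal the textbook t-test on random vectors", {
  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.1, 2))
    got <- control_statistics(x)
    ref <- t.test(x, mu = 0, conf.level = 0.95)
    expect_equal(got$mean_ddg, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("acceptance rules: tolerance-based default and literal p-value mode", {
  near_zero <- c(-0.1, 0.1, 0.05, -0.03, 0.02, -0.06)
  a <- control_statistics(near_zero)
  expect_true(a$accepted)
  shifted <- near_zero + 2
  b <- control_statistics(shifted)
  expect_false(b$accepted)
  # the literal reading accepts significant deviation instead
  expect_true(control_statistics(shifted, rule = "pvalue")$accepted)
  expect_false(control_statistics(near_zero, rule = "pvalue")$accepted)
  # CI half-width shrinks ~ 1/sqrt(n)
  set.seed(11)
  x <- rnorm(6400, 0, 0.5)
  h100 <- with(control_statistics(x[1:100]), (ci_high - ci_low) / 2)
  h6400 <- with(control_statistics(x), (ci_high - ci_low) / 2)
  expect_equal(h100 / h6400, 8, tolerance = 0.25)
})

test_that("percent matching classifies around the 0.5 equilibrium band", {
  p <- c(0.1, 0.5, 0.9, 0.45, 0.7)
  expect_equal(percent_matching(p, p), 100)
  expect_equal(percent_matching(rep(0.9, 5), rep(0.1, 5)), 0)
  pred <- c(0.1, 0.2, 0.9, 0.8, 0.5, 0.45, 0.55, 0.95, 0.05, 0.3)
  exp_ <- c(0.2, 0.9, 0.8, 0.1, 0.52, 0.48, 0.58, 0.3, 0.15, 0.35)
  # counting oracle, written out independently
  cls <- function(v) ifelse(v < 0.4, "s", ifelse(v > 0.6, "d", "n"))
  expect_equal(percent_matching(pred, exp_),
               100 * mean(cls(pred) == cls(exp_)))
  expect_equal(percent_matching(pred, exp_), 70)
  # permutation equivariance
  o <- sample(10)
  expect_equal(percent_matching(pred[o], exp_[o]),
               percent_matching(pred, exp_))
  expect_error(percent_matching(1, c(1, 0)), "mismatch")
})

test_that("fit-score is one minus the mean absolute deviation", {
  v <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(fit_score(v, v), 1)
  expect_equal(fit_score(v + 0.2, v), 0.8)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(15); b <- runif(15)
    expect_equal(fit_score(a, b), 1 - sum(abs(a - b)) / 15,
                 tolerance = 1e-12)
    o <- sample(15)
    expect_equal(fit_score(a[o], b[o]), fit_score(a, b))
  }
})

test_that("experimental tables round-trip and validate against scan records", {
  scan <- scan10()
  sites <- structure_sites(helix10())
  tab <- data.frame(
    position = c(2, 4, 6),
    wt_aa = sites$aa[c(2, 4, 6)],
    mut_aa = c("W", "F", "D"),
    ddg_exp = c(2.5, -0.5, 6.0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  got <- read_experimental_ddg(path)
  expect_equal(as.data.frame(got), tab)
  res <- validate_predictions(scan, got)
  expect_equal(res$n, 3)
  expect_true(res$fit_score >= 0 && res$fit_score <= 1)
  expect_true(res$percent_matching >= 0 && res$percent_matching <= 100)
  # malformed tables are rejected
  bad <- tab; bad$wt_aa[1] <- "X"
  write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_experimental_ddg(path), "non-standard")
})
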