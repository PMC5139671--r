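test_that("enumeration yields 20 targets per scannable site in fixed order", {
  pairs <- enumerate_mutations(helix_aaa3())
  expect_equal(nrow(pairs), 60)
  first <- pairs[pairs$site == 1, ]
  expect_identical(first$mut_aa, amino_acids())
  pairs10 <- enumerate_mutations(helix10())
  expect_equal(nrow(pairs10), 200)
  # dropping a backbone atom silently excludes nothing: warned, count -20
  broken <- helix10()[!(helix10()$seq_number == 5 &
                          helix10()$atom == "O"), ]
  expect_warning(p2 <- enumerate_mutations(broken), "skipped")
  expect_equal(nrow(p2), 180)
  expect_false(5 %in% p2$seq_number)
})

test_that("identity placement at the native rotamer is bit-exact", {
  fx <- helix10()
  sites <- structure_sites(fx)
  lib <- default_rotamer_library()
  s <- sites[sites$aa != "G" & sites$aa != "A", ][1, ]
  chis <- foldscan:::measure_chis(
    foldscan:::site_atoms(fx, s$chain, s$seq_number, s$icode), s$aa)
  k <- foldscan:::nearest_rotamer(lib, s$aa, chis)
  v <- place_side_chain(fx, s$chain, s$seq_number, s$icode, s$aa, k)
  a0 <- foldscan:::site_atoms(fx, s$chain, s$seq_number, s$icode)
  a1 <- foldscan:::site_atoms(v, s$chain, s$seq_number, s$icode)
  a0 <- a0[order(a0$atom), ]
  a1 <- a1[order(a1$atom), ]
  expect_identical(a1$atom, a0$atom)
  expect_identical(a1$x, a0$x)
  expect_identical(a1$y, a0$y)
  expect_identical(a1$z, a0$z)
})

test_that("mutating to Gly removes the side chain; built chis hit the library", {
  v <- place_side_chain(helix_aaa3(), "A", 2, "", "G", 1L)
  site <- foldscan:::site_atoms(v, "A", 2, "")
  expect_setequal(site$atom, c("N", "CA", "C", "O"))

  lib <- default_rotamer_library()
  for (aa in c("L", "K", "W", "D")) {
    for (k in seq_len(foldscan:::n_rotamers(lib, aa))) {
      v2 <- place_side_chain(helix_aaa3(), "A", 2, "", aa, k)
      got <- foldscan:::measure_chis(foldscan:::site_atoms(v2, "A", 2, ""),
                                     aa)
      want <- foldscan:::rotamer_chis(lib, aa, k)
      delta <- (got - want) %% 360
      expect_lt(max(pmin(delta, 360 - delta)), 1e-6)
    }
  }
  expect_error(place_side_chain(helix_aaa3(), "A", 2, "", "L", 99L),
               "invalid rotamer")
})

test_that("score_site terms behave and match a brute-force re-summation", {
  lib <- default_rotamer_library()
  w <- energy_weights()
  # an isolated residue has no clash and no contacts
  lone <- helix_aaa3()[helix_aaa3()$seq_number == 2, ]
  e <- score_site(lone, "A", 2, "")
  expect_equal(e$clash, 0)
  expect_equal(e$contact, 0)
  expect_equal(e$total, e$clash + e$contact + e$rotamer_self + e$burial,
               tolerance = 1e-9)
  # two atoms forced to 1 A apart clash
  crushed <- helix_aaa3()
  i <- which(crushed$seq_number == 3 & crushed$atom == "CB")
  j <- which(crushed$seq_number == 1 & crushed$atom == "CB")
  crushed$x[i] <- crushed$x[j] + 1
  crushed$y[i] <- crushed$y[j]
  crushed$z[i] <- crushed$z[j]
  expect_gt(score_site(crushed, "A", 3, "")$clash, 0)
  # oracle equivalence on fixture sites
  for (sn in c(2, 5, 9)) {
    e <- score_site(helix10(), "A", sn, "", lib, w)
    expect_equal(e$total,
                 brute_site_energy(helix10(), "A", sn, "", lib, w),
                 tolerance = 1e-9)
  }
  e_ball <- score_site(ball30(), "A", 1, "", lib, w)
  expect_equal(e_ball$total,
               brute_site_energy(ball30(), "A", 1, "", lib, w),
               tolerance = 1e-9)
})

test_that("identity ddG is exactly zero on relaxed fixtures; Gly trivially", {
  for (fx in list(helix20(), ball30())) {
    sites <- structure_sites(fx)
    for (i in seq_len(nrow(sites))) {
      r <- compute_ddg(fx, sites$chain[i], sites$seq_number[i],
                       sites$icode[i], sites$aa[i])
      expect_identical(r$ddg, 0)
      expect_identical(r$chosen_rotamer, 0L)
    }
  }
})

test_that("burying a tryptophan in the packed ball is destabilizing", {
  fx <- ball40()
  # site 1 sits at the lattice center
  r <- compute_ddg(fx, "A", 1, "", "W")
  expect_gt(r$ddg, 0)
})

test_that("run_scan satisfies the count law, identity floor and determinism", {
  scan <- scan10()
  expect_equal(nrow(scan), 200)
  expect_true(all(scan$ddg[scan$wt_aa == scan$mut_aa] <= 0))
  expect_true(all(scan$propensity >= 0 & scan$propensity <= 1))
  again <- run_scan(helix10())
  expect_identical(scan$ddg, again$ddg)
  expect_identical(scan$chosen_rotamer, again$chosen_rotamer)
  # spot check one record against a hand-driven place + score sequence
  lib <- default_rotamer_library()
  w <- energy_weights()
  rec <- scan[scan$seq_number == 4 & scan$mut_aa == "F", ]
  wt_e <- score_site(helix10(), "A", 4, "", lib, w)$total
  es <- vapply(seq_len(foldscan:::n_rotamers(lib, "F")), function(k) {
    v <- place_side_chain(helix10(), "A", 4, "", "F", k, lib)
    score_site(v, "A", 4, "", lib, w)$total
  }, numeric(1))
  expect_equal(rec$ddg, min(es) - wt_e, tolerance = 1e-12)
})

test_that("locality: mutating a site leaves distant sites' scores unchanged", {
  fx <- helix20()
  v <- place_side_chain(fx, "A", 1, "", "W", 1L)
  # site 20 is ~28 A from site 1: outside every interaction cutoff
  e0 <- score_site(fx, "A", 20, "")
  e1 <- score_site(v, "A", 20, "")
  expect_identical(e0$total, e1$total)
})
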