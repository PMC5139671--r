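# Shared fixtures, built once per run. Everything is generated in code;
# no binary data anywhere.

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

helix_aaa3 <- function() cached("aaa3", make_fixture("helix", 3, "AAA", seed = 1))
helix_aga3 <- function() cached("aga3", make_fixture("helix", 3, "AGA", seed = 1))
helix10 <- function() cached("h10", make_fixture("helix", 10, seed = 1))
helix20 <- function() cached("h20", make_fixture("helix", 20, seed = 1))
ball30 <- function() cached("b30", make_fixture("compact_ball", 30, seed = 7))
ball40 <- function() cached("b40", make_fixture("compact_ball", 40, seed = 7))
scan10 <- function() cached("scan10", run_scan(helix10()))

# a PDB line formatted by hand so altloc (col 17) and element (77-78) are
# placed exactly
pdb_line <- function(serial, name, altloc, res, chain, seq, x, y, z, occ,
                     element, record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), altloc, res, chain, seq, " ",
          x, y, z, occ, 0, element)
}

# two-altloc Ser plus an MSE residue and a water, for parser edge cases
write_altloc_pdb <- function(path) {
  lines <- c(
    pdb_line(1, "N",  " ", "SER", "A", 1, 0.0, 0.0, 0.0, 1.00, "N"),
    pdb_line(2, "CA", " ", "SER", "A", 1, 1.458, 0.0, 0.0, 1.00, "C"),
    pdb_line(3, "C",  " ", "SER", "A", 1, 2.0, 1.4, 0.0, 1.00, "C"),
    pdb_line(4, "O",  " ", "SER", "A", 1, 3.2, 1.4, 0.0, 1.00, "O"),
    pdb_line(5, "CB", "A", "SER", "A", 1, 1.9, -0.8, 1.1, 0.60, "C"),
    pdb_line(6, "CB", "B", "SER", "A", 1, 1.9, -0.8, -1.1, 0.40, "C"),
    pdb_line(7, "OG", "A", "SER", "A", 1, 1.5, -2.1, 1.2, 0.60, "O"),
    pdb_line(8, "OG", "B", "SER", "A", 1, 1.5, -2.1, -1.2, 0.40, "O"),
    pdb_line(9,  "N",  " ", "MSE", "A", 2, 3.0, 2.5, 0.0, 1.00, "N",
             record = "HETATM"),
    pdb_line(10, "CA", " ", "MSE", "A", 2, 4.4, 2.5, 0.2, 1.00, "C",
             record = "HETATM"),
    pdb_line(11, "C",  " ", "MSE", "A", 2, 5.0, 3.9, 0.2, 1.00, "C",
             record = "HETATM"),
    pdb_line(12, "O",  " ", "MSE", "A", 2, 6.2, 4.0, 0.3, 1.00, "O",
             record = "HETATM"),
    pdb_line(13, "O",  " ", "HOH", "A", 90, 9.0, 9.0, 9.0, 1.00, "O",
             record = "HETATM"),
    "END")
  writeLines(lines, path)
  path
}

# independent all-pairs re-summation of the site energy (test oracle)
brute_site_energy <- function(model, ch, sn, ic, library, weights) {
  s <- which(model$chain == ch & model$seq_number == sn & model$icode == ic)
  aa <- model$aa[s[1]]
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  excl_intra <- foldscan:::intra_excluded_pairs(aa)
  excl_next <- c("C|N", "CA|N", "O|N", "C|CA")
  excl_prev <- c("N|C", "N|CA", "N|O", "CA|C")
  clash <- 0
  for (i in s) {
    for (j in seq_len(nrow(model))) {
      if (j %in% s && j <= i) next
      d <- sqrt((model$x[i] - model$x[j])^2 + (model$y[i] - model$y[j])^2 +
                  (model$z[i] - model$z[j])^2)
      if (d > 6) next
      key <- paste(model$atom[i], model$atom[j], sep = "|")
      if (j %in% s) {
        k2 <- paste(min(model$atom[i], model$atom[j]),
                    max(model$atom[i], model$atom[j]), sep = "|")
        if (k2 %in% excl_intra) next
      } else if (model$chain[j] == ch && model$seq_number[j] == sn + 1) {
        if (key %in% excl_next) next
      } else if (model$chain[j] == ch && model$seq_number[j] == sn - 1) {
        if (key %in% excl_prev) next
      }
      ov <- 0.85 * (vdw[[model$element[i]]] + vdw[[model$element[j]]]) - d
      if (ov > 0) clash <- clash + ov^2
    }
  }
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
          H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
          W = -0.9, Y = -1.3)
  rep_of <- function(rows) {
    i <- rows[model$atom[rows] == "CB"]
    if (!length(i)) i <- rows[model$atom[rows] == "CA"]
    i[1]
  }
  ri <- rep_of(s)
  contact <- 0
  burial_n <- 0
  others <- setdiff(seq_len(nrow(model)), s)
  other_sites <- unique(paste(model$chain[others], model$seq_number[others],
                              model$icode[others]))
  for (os in other_sites) {
    parts <- strsplit(os, " ")[[1]]
    rows <- which(model$chain == parts[1] &
                    model$seq_number == as.integer(parts[2]) &
                    model$icode == ifelse(length(parts) > 2, parts[3], ""))
    rj <- rep_of(rows)
    d <- sqrt((model$x[ri] - model$x[rj])^2 + (model$y[ri] - model$y[rj])^2 +
                (model$z[ri] - model$z[rj])^2)
    if (d <= 6.5) contact <- contact - kd[[aa]] * kd[[model$aa[rj]]] / 4.5^2
  }
  for (j in others) {
    d <- sqrt((model$x[ri] - model$x[j])^2 + (model$y[ri] - model$y[j])^2 +
                (model$z[ri] - model$z[j])^2)
    if (d <= 8) burial_n <- burial_n + 1
  }
  burial <- -(kd[[aa]] / 4.5) * min(1, burial_n / 40)
  chis <- foldscan:::measure_chis(model[s, ], aa)
  rot <- if (length(chis) && !anyNA(chis)) {
    k <- foldscan:::nearest_rotamer(library, aa, chis)
    -log(foldscan:::rotamer_probability(library, aa, k))
  } else 0
  weights$clash * clash + weights$contact * contact +
    weights$rotamer * rot + weights$burial * burial
}

# naive UPGMA (average linkage) cophenetic matrix, agglomerating by direct
# search — independent oracle for the clustering used in the heat maps
naive_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  coph <- matrix(0, n, n)
  cd <- d
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (a in idx) for (b in idx) {
      if (a >= b) next
      if (cd[a, b] < best_d - 1e-15) {
        best_d <- cd[a, b]
        best <- c(a, b)
      }
    }
    ia <- clusters[[best[1]]]
    ib <- clusters[[best[2]]]
    for (x in ia) for (y in ib) coph[x, y] <- coph[y, x] <- best_d
    merged <- c(ia, ib)
    clusters[[best[1]]] <- merged
    active[best[2]] <- FALSE
    for (o in which(active)) {
      if (o == best[1]) next
      io <- clusters[[o]]
      cd[best[1], o] <- cd[o, best[1]] <-
        mean(d[merged, io, drop = FALSE])
    }
  }
  coph
}

# independent brute-force residue/atom depth: same surface definition,
# straightforward loops, no canonical frame
brute_atom_depths <- function(model, probe = 1.4, n_points = 960) {
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  co <- cbind(model$x, model$y, model$z)
  radii <- unname(vdw[model$element]) + probe
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  surf <- list()
  for (a in seq_len(nrow(co))) {
    pts <- sweep(dirs * radii[a], 2, co[a, ], "+")
    keep <- rep(TRUE, n_points)
    for (b in seq_len(nrow(co))) {
      if (b == a) next
      d2 <- rowSums(sweep(pts, 2, co[b, ])^2)
      keep <- keep & d2 >= (radii[b] - 1e-9)^2
    }
    if (any(keep)) surf[[length(surf) + 1]] <- pts[keep, , drop = FALSE]
  }
  surf <- do.call(rbind, surf)
  vapply(seq_len(nrow(co)), function(a) {
    sqrt(min(rowSums(sweep(surf, 2, co[a, ])^2)))
  }, numeric(1))
}
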