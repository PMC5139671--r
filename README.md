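# foldscan

Exhaustive in silico missense mutagenesis of protein structures, with
unfolding propensities on a universal 0–1 scale.

Clinicians and structural biologists who encounter a missense variant —
often a *de novo* one with no conservation signal — need a quick,
structure-based estimate of whether it destabilizes the fold. `foldscan`
answers that for **every possible substitution at every position** of a
structure: it mutates each residue to all 20 amino acids (19 missense plus
an identity control), places mutant side chains from a rotamer library,
scores each variant with a documented, pluggable energy function, and
reports the result as an *unfolding propensity*.

## The model

For a substitution with folding free-energy change ΔΔG (kcal/mol, positive
= destabilizing), the mutant stability under the linear extrapolation model
(LEM) is

    ΔG_mut = ΔG_wt − m·[D] − ΔΔG

and the equilibrium unfolded fraction of a two-state folder is the
Boltzmann population

    P_u = 1 / (1 + exp(ΔG_mut / RT))

so `P_u = 0` means fully stabilized, `P_u = 0.5` is the folding–unfolding
equilibrium (ΔG_mut = 0), and `P_u = 1` is completely unfolded. Because the
transform depends only on (ΔΔG, parameters), propensities from different
proteins are directly comparable. Defaults: ΔG_wt = 5.0 kcal/mol (a typical
globular-protein stability — a documented calibration choice), RT = 0.593
kcal/mol (298 K), [D] = 0.

From the N×20 propensity matrix the package derives per-residue
descriptors: the **average** missense propensity, the **foldability**
1 − n_severe/19 (count of substitutions with propensity ≥ 0.9; low
foldability flags residues critical for folding), the **Shannon entropy**
Σ P(x)·log2(1/P(x)) of the discretized propensity profile (bits), and the
**residue depth** below the solvent accessible surface (Å). A rotamer-based
**internal control** re-mutates every residue to itself across alternative
rotamer conformations; for a well-refined model the resulting ΔΔG
distribution should center on 0 with a tight 95% CI.

## Worked example

```r
library(foldscan)

fx   <- make_fixture("helix", 10, seed = 1)   # sequence EHACMQVWAL
scan <- run_scan(fx)                          # 200 records: 10 sites x 20
scan[scan$seq_number == 4 & scan$mut_aa %in% c("A", "F", "P", "W"),
     c("seq_number", "wt_aa", "mut_aa", "ddg", "propensity")]
#>   seq_number wt_aa mut_aa    ddg propensity
#> 1          4 C     A      -0.129   0.000175
#> 2          4 C     F       0.468   0.000479
#> 3          4 C     P       1.79    0.00447
#> 4          4 C     W      28.0     1
```

Cys4 tolerates small substitutions (propensity ≈ 2×10⁻⁴, the wild-type
baseline), while cramming a tryptophan against the helix clashes badly:
ΔΔG = 28 kcal/mol puts the mutant far past the 0.5 equilibrium point, so
its propensity saturates at 1 (predicted unfolded).

```r
mat  <- build_matrix(scan)                         # 10 x 20 propensities
desc <- build_descriptors(mat, residue_depth(fx))  # per-residue table
desc[4, ]
#>   chain seq_number wt_aa avg_propensity foldability entropy depth
#> 1 A              4 C             0.0564       0.947   0.286  3.06

tidy(internal_control(fx))
#>   structure_id       n mean_ddg sd_ddg p_value ci_low ci_high accepted
#> 1 helix_10_seed1    17     5.60   12.5  0.0832 -0.824    12.0 FALSE
```

Foldability 0.947 means exactly one of Cys4's 19 missense substitutions
(the tryptophan) is severe. The internal control is rejected here, as it
should be: alternative rotamers of several side chains clash in a bare
10-residue helix, so the self-substitution ΔΔGs do not center tightly on 0.

The full pipeline writes all report artifacts (matrix, descriptor table,
standard and clustered HTML heat maps, Chimera coloring script + attribute
file, control report) and returns a checksummed manifest:

```r
run <- run_pipeline(run_config(fx, out_dir = "out"))
tidy(run)    # file + md5 per artifact; reruns are checksum-identical
autoplot(mat)   # ggplot2 heat map, blue(0)-white(0.5)-red(1)
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/foldscan.R scan --pdb protein.pdb --out results/
Rscript inst/cli/foldscan.R control --pdb protein.pdb
```

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the analytic anchors of the method: the propensity at the
folding–unfolding equilibrium point, the identity-substitution ΔΔG across a
20-residue library-conformation fixture, and the supremum of the propensity
over a dense ±100 kcal/mol ΔΔG sweep. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

The energy function is a deterministic, desk-scale scorer (soft steric
clash, hydrophobicity-factorized contact potential, rotamer prior,
hydrophobic burial) — documented and replaceable, not a physics-grade force
field. Mutant optimization is exhaustive over library rotamers with
neighbors held fixed (no repacking, no backbone relaxation); backbone
strain of X→Pro is not modelled. Multi-model NMR inputs use MODEL 1 only;
mmCIF is not supported.
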