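---
title: "Methods: saturation mutagenesis, unfolding propensities and model quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturation mutagenesis, unfolding propensities and model quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscan)
```

## What the package computes

Given a protein structure, `foldscan` enumerates every possible
single-residue substitution (20 targets per position: 19 missense plus the
identity), builds each mutant side chain at discrete rotamer-library
conformations on the fixed backbone, scores wild type and mutant with a
per-site energy function, and reports the difference as a folding
free-energy change ΔΔG (kcal/mol, positive = destabilizing). ΔΔG values are
then mapped to a universal 0–1 *unfolding propensity*, from which a
per-residue descriptor set, two heat maps, a structure-coloring script and
a model-quality control are derived.

This vignette explains each model component, its assumptions, the tunable
parameters with their defaults, and the design decisions taken where the
method leaves genuine freedom. It states no empirical result that the test
suite does not itself compute.

## The thermodynamic transform

A two-state folder at equilibrium populates its unfolded state with the
Boltzmann fraction

$$P_u = \frac{1}{1 + \exp(\Delta G_{mut}/RT)}, \qquad
  \Delta G_{mut} = \Delta G_{wt} - m[D] - \Delta\Delta G .$$

The linear extrapolation model (LEM) term $-m[D]$ expresses how stability
falls with denaturant concentration; by default the transform is evaluated
in water ($[D] = 0$), with the $m$-value (1.0 kcal/mol/M) and $[D]$ exposed
as knobs. The transform reproduces the three defining anchors of the
propensity scale: $P_u \to 0$ for strongly stabilized mutants, exactly
$0.5$ at $\Delta G_{mut} = 0$ (folding–unfolding equilibrium), and
$P_u \to 1$ for strongly destabilized ones. It is strictly increasing in
ΔΔG and is computed with `stats::plogis`, so extreme arguments saturate at
0/1 without overflow.

**ΔG~wt~ = 5.0 kcal/mol is a calibration choice, not a measurement.** It is
a typical stability for a small globular protein; it places the wild type
near fully folded ($P_u \approx 2\times10^{-4}$) and the 0.5 crossing at
ΔΔG = 5 kcal/mol. Because the transform depends only on (ΔΔG, parameters),
matrices from different proteins computed with the same parameters are
directly comparable. RT defaults to 0.593 kcal/mol (298 K); no
temperature-dependent heat-capacity modelling is attempted.

## The energy function

The method's original energy machinery is not publicly specified, so the
package ships a *documented, deterministic, term-separable* scorer behind a
pluggable surface (`energy_weights()`), chosen so that every term can be
verified independently in tests:

$$E(\text{site}) =
  w_{clash}\sum_{pairs}\max\!\big(0,\,0.85(r_i+r_j)-d_{ij}\big)^2
+ w_{contact}\sum_{res\,j} e(aa, aa_j)
+ w_{rot}\,(-\ln p_{rot})
+ w_{burial}\,\big(-\tfrac{h(aa)}{4.5}\big)\,b$$

* **Soft steric clash** over heavy-atom pairs involving the site within
  6 Å, excluding 1-2/1-3 covalently bonded pairs (including across the
  peptide bond); van der Waals radii by element (C 1.70, N 1.55, O 1.52,
  S 1.80 Å). The 0.85 softness factor tolerates the mild overlaps of real
  packing while punishing genuine collisions quadratically.
* **Contact potential**: a statistical contact term over residue pairs
  whose representative atoms (CB; CA for Gly) lie within 6.5 Å. The full
  published 20×20 contact matrices are not reproducible from the package's
  sources, so a rank-1 hydrophobicity-factorized form
  $e(a,b) = -h_a h_b/4.5^2$ (Kyte–Doolittle $h$) is used — such rank-1
  forms are known to capture the dominant structure of
  Miyazawa–Jernigan-style matrices, and the propensity transform downstream
  is agnostic to the scorer.
* **Rotamer self-energy** $-\ln p$ of the site's conformation, assigned by
  nearest library rotamer (zero for Gly/Ala).
* **Hydrophobic burial**: burial fraction $b$ = capped count (≤ 40) of
  foreign heavy atoms within 8 Å of the representative atom, rewarded for
  hydrophobic and penalized for polar residues.

Default weights $w = (10, 1, 0.6, 0.5)$ put a single serious clash
(~0.5 Å overlap) on the same scale as the largest contact/burial swings —
clashes dominate, as they should for packing-driven destabilization.

ΔΔG of a substitution is the *best* (minimum-energy) mutant rotamer minus
the wild-type site energy, with all other residues held fixed. For an
identity substitution the native conformation is included among the
candidates, so identity ΔΔG is never positive and is exactly zero whenever
the native conformation is the site optimum. No repacking of neighbors, no
backbone relaxation, and no modelling of X→Pro backbone strain: these are
stated limitations, traded for bit-level determinism and desk-scale speed.

## The rotamer library

The packaged library (`inst/extdata/rotamer_library.tsv`) is a coarse
backbone-independent library: 2–4 rotamers per amino acid at the canonical
gauche−/trans/gauche+ chi wells, probabilities rounded from broad published
rotamer frequencies so that each amino acid sums to exactly 1. Gly and Ala
carry a single empty-chi rotamer of probability 1. Any library in the same
tab-delimited format can be substituted (`read_rotamer_library()`); a finer
library sharpens the scan at linear cost in rotamer count.

## Descriptors

For each position the N×20 propensity matrix yields:

* **Average propensity** — mean of the 19 missense entries (identity
  excluded; switchable via `exclude_identity`).
* **Foldability** — $1 - n_{severe}/19$, counting missense entries with
  propensity ≥ 0.9. The descriptor is defined only qualitatively by its
  originators — it should "tally severe mutations without being influenced
  by the less severe" — so this count-based reconstruction is deliberately
  insensitive to sub-threshold magnitudes (a property the tests assert);
  both the 0.9 severity threshold and the reading are configurable.
  Low foldability flags residues critical for folding.
* **Informational (Shannon) entropy** — propensities are discretized to
  bins of width 0.1 by rounding (11 bins anchored at 0, 0.1, …, 1);
  $H = \sum_x P(x)\log_2(1/P(x))$ bits over all 20 outcomes, with
  $0\log(1/0) := 0$. The bin structure is a package decision (the source
  describes the formula but not the binning); any width dividing 1 evenly
  reproduces the canonical examples, e.g. a uniformly-0.5 row has 0 bits
  while an equal-average row split between 0 and 1 has 1 bit. The identity
  entry is included here — the profile genuinely has 20 outcomes — while
  the two "missense" summaries above exclude it; this split reading is
  exposed as configuration.
* **Residue depth** — mean over the residue's heavy atoms of the atom's
  minimum distance to the solvent accessible surface. Rather than calling
  the external MSMS binary, the surface is sampled directly: each atom's
  sphere of radius $r_{vdw} + 1.4$ Å carries `n_sphere_points` (default
  960) Fibonacci-lattice directions, and points inside any other atom's
  expanded sphere are discarded. Accuracy scales with the point count; the
  suite holds the sampler to ≤ 0.25 Å against an all-pairs brute-force
  oracle. Sampling directions live in a PCA-canonicalized frame of the atom
  cloud with a third-moment sign convention, so rigid motions of the input
  reproduce depths to ~1e-9 Å (a global-frame sampler would be invariant
  only to the sampling resolution). Structures with exactly degenerate
  principal axes or vanishing third moments would weaken that guarantee;
  real and fixture structures are generic.

## The internal control

A well-refined structure should sit at an energy optimum, so "mutating each
residue to itself" should cost nothing. The control statistic probes the
conformational spread instead of the identity optimum: for every
non-Gly/Ala site, the native side chain is replaced by each *alternative*
library rotamer of the same amino acid (the nearest-native rotamer is
excluded) and the ΔΔG distribution is summarized by mean, SD, two-sided
one-sample t-test against 0, and the 95% CI
$\bar x \pm t_{0.975,n-1}\,s/\sqrt n$.

The published acceptance wording — significance ($p < 0.05$) combined with
a small CI centered near 0 — is statistically self-contradictory: a
*significant* one-sample test against 0 is evidence the mean is *not* 0.
The package therefore defaults to the coherent reading, accepting iff
$|\bar x| \le 0.5$ kcal/mol and CI half-width ≤ 1.0 kcal/mol, while always
reporting the raw p-value and offering the literal rule via
`rule = "pvalue"`. Zero-variance samples use the convention $p = 1$ when
the mean is exactly 0 and $p = 0$ otherwise. Note that with any scorer that
prices non-native rotamers (rotamer prior, clashes), alternative-rotamer
ΔΔGs are non-negative by construction on relaxed structures, so the
distribution is expected to be centered slightly above zero; "close to 0
with a tight CI" — not "CI covers 0" — is the meaningful criterion.

## Validation harness

Experimental ΔΔG tables (tab-delimited: position, wild-type, mutant, ΔΔG)
are mapped through the same propensity transform and compared to
predictions by **percent matching** — three classes around equilibrium
(stabilized < 0.4, neutral, destabilized > 0.6 with the default ±0.1 band)
— and a **fit-score** $1 - \overline{|p_{pred} - p_{exp}|}$, a documented
reconstruction (the original score's definition is not published in the
package's sources). No thermodynamic database is downloaded or bundled.

## Synthetic fixtures: what they do and do not establish

`make_fixture()` generates the offline test substrate: ideal α-helices
(φ = −57°, ψ = −47°), hairpin-like two-strand folds, and `compact_ball`
structures that pack residue frames on a 5 Å spherical lattice with
seed-determined orientations so genuinely buried residues exist (depth
> 3 Å). Side chains are built exactly at library conformations and then
relaxed by deterministic coordinate descent over library rotamers until
every site is its own single-site optimum. This realizes, for arbitrary
sequences, the defining fixture property: an identity substitution costs
exactly 0 at machine precision, because the native candidate is bit-identical
to a library rebuild and no alternative beats it.

The fixtures emulate ideal covalent geometry, realistic packing density and
library-conformation side chains. They do **not** emulate: experimental
coordinate error, non-ideal bond geometry, cofactors/heteroatoms, waters,
multi-chain interfaces, or evolutionary sequence composition. A green test
therefore establishes the *algorithmic contracts* (counts, determinism,
anchors, oracle equivalences, round trips) — not predictive accuracy
against experimental stability data, which requires the validation harness
and real measurements.

## Numerical choices

* Side chains are built by natural-extension (NeRF) internal-coordinate
  placement; rebuilt conformations are bit-reproducible, which the
  identity-ΔΔG guarantee relies on.
* Altloc resolution keeps the highest occupancy, ties broken by label
  order; MSE is read as Met (Se as S); other non-standard residues are
  excluded with a warning and tallied in the parse report; hydrogens are
  ignored (energies are heavy-atom based); multi-model files use MODEL 1.
* Rotamer relaxation switches conformations only on strict improvement
  (> 1e-12), guaranteeing termination and a stable fixed point.
* Clustered maps use Euclidean distance with average linkage (configurable
  to complete); `stats::hclust` tie-breaking is deterministic given the
  fixed input order. Dendrograms are embedded as newick strings.
* Text outputs print 3 decimals; full precision is kept internally; all
  writers are pure functions, so pipeline reruns are checksum-identical.
* Heat-map colors interpolate blue (0) → white (0.5) → red (1); exact
  breakpoints beyond these three anchors are a package choice.

## Known limitations

Single-point energies with fixed neighbors miss compensatory repacking, so
large-to-large substitutions in dense cores overestimate ΔΔG; X→Pro and
X→Gly backbone effects are not modelled; the contact potential is a rank-1
approximation; multimeric inputs are scanned per selected chain in the
context of all retained atoms (interface effects enter only through the
fixed environment). The scorer is exchangeable precisely so that a
stronger energy model can be dropped in without touching the transform,
descriptors, control or reports.
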