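---
title: "Methods: comparative structural analysis of capping-protein heterodimers"
author: "CPcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative structural analysis of capping-protein heterodimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CPcompare)
```

CPcompare packages the quantitative half of a two-structure comparison of
homologous heterodimeric capping proteins: residue correspondence, rigid
superposition with regional reporting, B-factor flexibility statistics,
disorder detection, crystal packing numbers, and family-level sequence
conservation. This vignette explains the models and conventions behind each
step, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical edge cases.

## Coordinate model and selections

Structures are flat atom tables carrying the chain → residue → atom
hierarchy with **author numbering** — the numbering used in published
residue ranges — as the only numbering exposed. All ranges in the package
are 1-based and inclusive at both ends, so "residues 2–272" selects 271
residues. Alternate conformations are resolved at read time to the
highest-occupancy conformer (ties: first in file); this can only remove
atoms, never add them. Waters (HOH/WAT) stay in the table but are excluded
from every statistic unless requested. Insertion codes sort after the bare
number in file order; the generators never emit them. Modified residues
keep their deposited 3-letter names; sequence extraction maps them to
parent one-letter codes (MSE→M, SEP→S, …) and unknown names to X. Only
model 1 of multi-model files is used, and no symmetry expansion or
anisotropic displacement handling is attempted.

Parsing and writing of PDB/mmCIF atom records is delegated to `bio3d`; the
package adds altloc resolution, the CRYST1/`_cell` crystal metadata, and
fixed-width output (coordinates overflowing the PDB field width are an
error rather than silently corrupted output).

## Residue correspondence

"Equivalent Cα atoms" are established by global end-to-end alignment of the
sequences extracted from the two models, then taking one residue pair per
alignment column with letters on both sides. Mismatched columns **are**
equivalences — superposition compares positions, not identities — and the
resulting map is collinear (author numbers strictly increase on both
sides).

Default scoring is BLOSUM62 with affine gap penalties (open 10, extend 0.5,
matrix units), appropriate for remote homologs like the CP subunit families
across eukaryotes; an identity scoring mode (match 1 / mismatch 0 / gap −1)
exists for enumerable toy cases. Correspondence here is sequence-based
rather than structure-based (interactive least-squares pairing in a
graphics program is the usual alternative); consequently published atom
counts are reproduced only to a tolerance, and every r.m.s.d. the package
reports carries its own atom count.

**Reliability boundary.** On star-evolved synthetic families the map
recovers ≥ 95% of true homologous positions at 40% identity without indels
and at 70% identity with sparse indels, and ≈ 90% at 50% identity with
indels. Below ~40% identity recovery degrades (≈ 84% at 30%, gap-free):
the uniform-substitution evolver gives mismatch columns no
conservative-substitution signal, so BLOSUM62 has less to work with than on
real homologs, where substitutions are strongly biased toward similar
residues. Passing tests therefore demonstrate correctness of the machinery
and honest behaviour at the remote end, not that sequence alignment is a
universal substitute for structural superposition below the twilight zone.

## Superposition

`kabsch()` computes the proper rotation and translation minimizing the sum
of squared paired-atom distances via SVD of the 3×3 cross-covariance of the
centered clouds. The reflection branch is corrected by the determinant
sign, so the result is always a proper rotation (det +1), including planar
clouds, where the correction lands on the axis of the smallest singular
value. Inputs with fewer than 3 points or (near-)collinear geometry — the
second singular value below 10⁻¹² of the first — are rejected as degenerate
rather than silently fitted.

Superposition is **unweighted**: no B-factor or occupancy weighting
(a weight vector is accepted for forward compatibility but defaults off),
and there is no iterative outlier trimming. Published exclusions ("the
flexible β-subunit C-termini were excluded") are expressed as explicit
selections instead, which keeps them reproducible and auditable.

`superposeMapped()` separates *fit* from *report*: the transform is
computed on the fit selection ∩ map, then applied once, and each report
selection's r.m.s.d. is measured in that global frame. Whether a published
regional r.m.s.d. was measured after a global or a region-local fit is
often unstated; the default here is the global-fit frame, and a
region-local number is obtained by passing the region as the fit selection.
Cα-only is the default atom set; widening `atomNames` gives all-atom fits.

Numerical guarantees enforced by the validity methods and tests: rotations
orthonormal to 1e-8 with det +1; r.m.s.d. = √(mean of squared per-pair
deviations) to 1e-10; invariance of the r.m.s.d. under a common rigid
pre-transform and under argument exchange to 1e-9; optimality verified
against a 10,000-random-rotation brute-force oracle on small clouds.

## Flexibility and disorder

B statistics default to Cα atoms; whether published region means are Cα or
all-atom averages is often ambiguous, so both modes are provided and
reported. The z-score of a region mean is computed against the whole-chain
per-atom B distribution (waters/heteroatoms always excluded); an all-equal
reference distribution is flagged and reported as z = 0 with a warning
rather than NaN. The single model-wide "mean B" quoted in crystallographic
tables is computed over all protein atoms of all chains, altloc-resolved
and occupancy-unweighted; because "averaged over chains" is a defensible
alternative reading, `modelMeanB(byChain = TRUE)` reports both.

Disordered segments are maximal runs of expected author numbers with no
Cα-bearing residue in the model — the deposited-model signature of
residues without interpretable electron density. The report always
satisfies n_modeled + n_missing = expected span.

## Crystal packing

Cell volume uses the triclinic closed form
V = abc·√(1 − cos²α − cos²β − cos²γ + 2cosα·cosβ·cosγ), tested against a
vector triple-product oracle on 1000 random valid cells. The Matthews
coefficient is V_M = V/(Z·n·M) with Z asymmetric units per cell (small
built-in table of common space groups, overridable — no full symmetry
engine), n molecules per AU and M the molecular mass in Da. Solvent content
is 1 − 1.660·v̄/V_M with v̄ = 0.74 cm³/g by default; 1.660 = 10²⁴/N_A folds
the Dalton-to-gram and Å³-to-cm³ conversions into one constant, so
v̄ = 0.74 gives the familiar 1.228. Non-physical inputs clamp to 0 with a
warning. The shipped `crystalFixture()` describes the tetragonal P4₁ CP
form (124.5 × 124.5 × 77.5 Å, two heterodimers per AU); its 66,000 Da
heterodimer mass is an inferred value (32 + 34 kDa subunits, the naming
masses) rather than a published one, and is flagged as such.

## Sequence conservation

Pairwise identity follows a specific convention: columns gapped in **both**
sequences are removed; identities are columns with equal non-gap letters
(case-insensitive; ambiguity codes B/Z/X never count); the denominator is
the **longer** of the two ungapped sequence lengths. Removing gap-gap
columns cannot change either ungapped length, so the score is invariant
under that cleanup — a property the tests assert directly. The matrix
implementation (per-letter indicator cross-products) is exactly equivalent
to the per-pair definition and handles hundreds of sequences in seconds.

Distribution summaries use the off-diagonal upper triangle only. Histogram
binning multiplies by 100 and rounds **half-up** to integer percent
(configurable to banker's rounding); bin masses are percentages of pairs —
the matrix's natural unit — and always sum to 100. The five-number summary
and the median (the statistic used to rank families by conservation) are
computed on unrounded values.

Block-selection tools for removing poorly aligned alignment regions have
their own parameters and are out of scope; the package's documented
stand-in is a simple gap-fraction column filter (default: keep columns with
≤ 50% gaps) that reports kept-column indices so logo positions remain
traceable to the original alignment numbering. Pre-filtered alignments are
accepted as-is.

Logo data per column: frequencies over the 20 standard letters scaled by
the column's non-gap fraction (gap mass excluded; non-standard letters are
treated as gaps), and information content IC = log₂20 − H of the
renormalized non-gap frequencies, in bits, with **no** small-sample
correction. An all-gap column reports IC 0 and empty frequencies.

## Synthetic data: what it emulates, and what it does not

The generators produce: Cα-only traces (ideal helix — 1.5 Å rise, 2.3 Å
radius, 100° twist; a β-strand-like zigzag; or a 3.8 Å fixed-step random
walk), perturbed copies (global rigid transform → per-region rigid
displacements → i.i.d. Gaussian coordinate noise → painted B profiles →
deleted ranges, in that order), and star-topology sequence families where
the per-site substitution probability q solves
(1 − 19q/20)² + 19(q/20)² = target identity in closed form, with deletion
runs of geometric length (mean 3) painted at a per-column rate. Every
output carries its ground truth, RNG streams are private per call (a
generator call neither disturbs nor depends on the caller's random state),
and noise is applied to only one member of a pair so the expected refitted
r.m.s.d. is exactly σ√3.

Not emulated: side chains and realistic packing, correlated (TLS-like)
B-factor structure, insertion codes and altlocs in generated data,
phylogenetic tree shape beyond the star, insertions (gaps are deletions
painted onto a fixed-length alignment, keeping it rectangular), and
BLOSUM-like substitution bias (see the correspondence reliability boundary
above). Green tests on these fixtures therefore validate the algorithms
and conventions — exact ground-truth recovery, analytic noise floors,
conserved accounting — but do not by themselves certify behaviour on real
coordinate files beyond what the deposited-structure checks cover when the
files are available.

## Problem sizes and defaults used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
modest sizes chosen to exercise every code path while staying quick on a
single CPU: chains of 100–1000 residues, 10,000-rotation brute-force
oracles on ≤ 6-point clouds, families of 50 sequences × 300 columns
(≈ 1200 pairs per matrix), and 20 seeded replicates for
ground-truth-recovery properties. The two checks against the deposited
CP/CapZ coordinate sets locate the files via a local cache directory
(`CPCOMPARE_PDB_DIR`) or a short-timeout download and fail plainly when
the files are unavailable, rather than being skipped silently.

## Known limitations

- Sequence-based correspondence below ~40% identity under-recovers
  equivalences relative to structure-based pairing (quantified above);
  published atom counts are matched to tolerance, not exactly, because the
  exact residue sets behind them are generally unpublished.
- The space-group multiplicity table covers common macromolecular groups
  only; anything else needs an explicit `auPerCell`.
- No TLS/ADP analysis, ensemble variance, or flexibility prediction —
  B-factor statistics are descriptive.
- mmCIF support covers the atom_site loop plus cell/symmetry items; exotic
  dictionary usage is out of scope.
- Chain naming in deposited heterodimer structures is not assumed; run
  configurations must name the chains (see
  `inst/extdata/capz-compare.yaml`).
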