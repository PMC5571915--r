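---
title: "Docking-based interface prediction and variant annotation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking-based interface prediction and variant annotation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dockvar` answers a practical question: when a missense variant falls in a
protein whose binding partners have no experimentally solved complex, can
we still say whether the variant sits at a protein–protein interface?
The package's answer is the docking route: sample rigid-body poses of the
two unbound subunits, keep the energetically best ones, and read off which
residues are repeatedly buried. This vignette explains each model in the
pipeline, the parameters that matter, the numerical choices, and what the
synthetic fixtures do and do not establish.

## Solvent accessibility and residue classes

Absolute accessible surface area is computed with the numerical
Shrake–Rupley method: each atom's van der Waals sphere is inflated by the
probe radius (default 1.4 Å, water) and sampled with a deterministic
golden-angle spiral of `n_sphere_points` (default 960) test points; points
falling inside any other inflated sphere are buried. Determinism matters
more here than quadrature elegance — identical inputs must give
byte-identical profiles — and at 960 points the method stays within 2% of
the closed-form two-sphere result, which the test suite checks against the
analytic spherical-cap formula.

Relative ASA divides by a residue-type maximum. We package the theoretical
Gly-X-Gly maxima of Tien et al. (2013) and record the table id in every
profile, because absolute ASA values differ between implementations and
radii sets; the *thresholded labels*, not the raw areas, are the stable
contract. van der Waals radii are a small element table (C 1.70, N 1.55,
O 1.52, S 1.80 Å); unknown elements fall back to 1.70 Å with a warning.

Residue classes follow two thresholds: core below rASA 0.1 on the unbound
subunit, interface for exposed residues with any atom within 10 Å of a
partner atom (all atoms, never Cα only), non-interacting surface
otherwise. When several structures cover one protein the rASA entering the
core decision is the mean over the structures containing the residue, so a
residue buried in one crystal form and exposed in another gets a single,
averaged verdict. Hydrogens, waters, `HETATM` records and alternate
locations other than blank/`A` are dropped at parse time; common
non-standard residues are mapped to their standard parent (e.g. MSE→MET),
and anything unmappable is dropped with a warning. Only the first `MODEL`
of multi-model files is read.

## Rigid-body docking

Pose generation is grid shape correlation in the Katchalski-Katzir style.
Cells whose center falls inside an atom are the molecular interior; on the
receptor grid the interior is penalized (−15) and the shell of thickness
`surface_thickness` (default 1.5 Å) immediately *outside* the envelope
scores 1, so a ligand in van der Waals contact overlaps the rewarded shell
while penetration overlaps the penalty. For every rotation in a
quasi-uniform set of unit quaternions (identity first, the rest uniform on
SO(3) under the run seed), the rotated ligand is gridded in the receptor
frame and the translational correlation is computed by FFT; the `n_keep`
best-scoring translations over all rotations become the candidate poses.
The grid spans the receptor extent plus the ligand diameter per axis, so
cyclic wrap-around cannot create spurious contacts, and the FFT pathway is
required (and tested) to agree exactly with direct-space correlation on
integer grids.

Rescoring uses three pairwise terms, truncated at 12 Å:

* electrostatics: `332 q_i q_j / (4 r²)` (distance-dependent dielectric
  ε(r) = 4r), capped at ±1 per pair so a single close salt bridge cannot
  dominate;
* van der Waals: 6–12 Lennard-Jones with well depth 0.1, capped at +1 per
  pair (a clash cap, not an error — rigid-body poses routinely clash);
* desolvation: per-element atomic solvation parameters (apolar positive,
  polar slightly negative) times an approximate pairwise buried area.

The total is a weighted sum (electrostatics 1.0, desolvation 1.0, van der
Waals 0.1). These constants cannot be recovered from the pose-ensemble
literature at this fidelity, so all of them live in `energy_params()` and
are recorded in the run manifest; the published composition (electrostatics
plus desolvation dominating, a lightly weighted van der Waals) fixed the
defaults. Charges default to coarse formal side-chain charges per residue
type; fixtures carry explicit charges in the PDB B-factor column.

Ranking is fully deterministic: poses sort by total energy ascending, ties
break by shape score descending, then by pose index. `select_lowest()`
keeps the `k = 100` lowest-energy poses, the ensemble that feeds NIP.

## From poses to interface predictions

For each residue, the averaged buried surface is the relative ASA loss
between the unbound subunit and the mean over the selected poses; a
residue with zero unbound ASA gets ABS 0 rather than a division error, and
residues absent from the unbound profile are excluded from all
normalization statistics. ABS is normalized per protein by the affine map
sending the mean to 0 and the maximum to 1; a perfectly flat ABS profile
maps to all zeros, which propagates to "no hot-spots at any positive
cutoff, empty patch" — the correct degenerate answer. The affine map was a
genuinely open choice (the normalization behind published NIP values is
not printed); we chose it because it is parameter-free, reproduces the
documented value range (negative values through 1, hot-spots above 0.2),
and makes the hot-spot rule scale-free with respect to overall burial.

Hot-spots are residues with NIP ≥ 0.2 (inclusive). The extended patch adds
every surface residue (rASA > 0.1) whose minimum inter-residue atomic
distance to a hot-spot is at most 10 Å — the same distance primitive as
the interface rule, deliberately shared. Buried residues never enter the
patch through extension, though a buried hot-spot keeps itself as a seed.
Per-pose ASA is recomputed exactly with the same Shrake–Rupley settings;
a faster contact-count proxy exists behind `burial = "contact"` for
screening, and the suite checks only that it ranks residues similarly —
exact ASA remains the reference everywhere that matters.

Proteins with several partners get one NIP profile per docking run and a
union merge: a residue is predicted interface (or hot-spot) if any partner
predicts it, mirroring how interface residues are defined from multiple
complexes.

## Variant mapping and statistics

The humsavar dialect is parsed permissively: lines without a `p.Xaa123Yaa`
token are skipped, silent substitutions are rejected, and the classic
three-category vocabulary (Disease / Polymorphism / Unclassified) is
canonical, with the newer LP/P-style tokens mapped onto it behind a flag.
Structure-to-sequence reconciliation is a global alignment of the
structure-derived sequence within the full sequence (match 1, mismatch −1,
gap open 5, extend 0.5, via Biostrings), mapping only aligned identical
positions and rejecting maps below 95% identity over the aligned span.
Wild-type mismatches at mapped positions mark the variant unmapped rather
than failing the run — real PDB entries carry engineered mutations — with
a strict mode for pipelines that prefer the error.

Annotation applies the union rule (interface in any structure or any
docking patch), falls back to averaged rASA for core versus surface, and
calls a variant a hot-spot only if some docking profile flags the residue
*and* the final location is interface. Evidence records which source
covered the residue (structure, docking, both, none), and `NONE` is
reserved for unmapped variants. The census excludes unmapped variants from
location counts and reports them separately, so denominators always refer
to placeable variants.

Enrichment uses two complementary statistics. The observed/expected ratio
compares a region's share of variants with its share of residues; it is
scale-invariant and undefined (flagged `NA`, never 0) when a denominator
vanishes. The odds ratio is the cross-product on per-residue variant
probabilities; zero cells trigger the Haldane–Anscombe +0.5 correction
with an explicit flag rather than a silent infinity. Two-tailed p-values
come from Fisher's exact test — exact, assumption-free, and verified in
the suite against exhaustive hypergeometric enumeration — and confidence
intervals are Woolf log-OR normal intervals, which the planted-OR recovery
study shows reach nominal coverage at the sample sizes involved. No
multiple-testing correction is applied, matching the survey design the
census reproduces.

## What the synthetic fixtures emulate

The toy complex is two pseudo-atom bodies (one backbone and one side-chain
sphere per residue): a ring of `interface_size` residues facing the
partner, continued by a helical stalk pointing away. A short three-residue
arc of each ring carries complementary ±1 charges — an energetic anchor —
while the remaining rim residues are uncharged. This shape gives the
docking problem the structure the method assumes: low-energy poses cluster
around the anchor, bury the rim variably, and leave the stalk mostly
alone, so raw NIP calls concentrate on a subset of the true interface and
patch extension recovers the rest. The designed interface is *verified*
against the package's own 10 Å rule at generation time (the generator
retries, then errors, if jitter breaks the design), bodies are checked
clash-free, and everything is a pure function of the seed, down to
byte-identical PDB output.

Variant fixtures plant a location bias by independent per-residue
Bernoulli draws whose per-residue odds ratio equals the target and whose
expected count matches the request, so the downstream estimator is applied
to data from exactly the model it assumes.

What the fixtures do **not** emulate: real fold geometry, side-chain
packing, conformational change on binding, partial structural coverage, or
the composition of real interfaces. Passing the toy benchmark shows the
pipeline is internally consistent and that extension beats a size-matched
random surface baseline under favorable, designed conditions; it does not
certify benchmark-scale precision/sensitivity on real complexes, which
require the full docking benchmark and network-scale inputs. The packaged
census, by contrast, is real survey data, and the statistics module
reproduces its printed summaries exactly.

## Problem sizes and runtime choices

The desk-scale study conditions used by the tests and the acceptance
script: 20 toy complexes of 30 residues per body with a 6-residue
interface, 150 rotations at 1.8 Å spacing keeping 6,000 candidates,
NIP from the 100 lowest-energy poses; planted-OR recovery at n = 500
variants over 27,000 labeled residues, 200 replicates per target. These
sizes keep a full run in minutes on one core while leaving every
statistical conclusion comfortably away from its threshold. The production
preset (10,000 kept poses, dense rotation sets, 1.2 Å grids) is a
configuration choice, not a code path change.

## Known limitations

* Rigid-body docking only: no flexibility, no clustering of poses, no
  template-based docking.
* The energy function is a configured composition, not a reproduction of
  any published scoring function's constants; absolute energies are not
  comparable across parameter sets (the manifest records them).
* Coarse residue-level charges limit electrostatic realism on real PDB
  input; users with better charge assignments can supply a `charge`
  column.
* Sequence reconciliation assumes a single chain maps to a single
  sequence; chimeric chains and large insertions fail the identity floor
  by design.
* Absolute ASA values are implementation-specific; compare labels and
  rASA-thresholded quantities across tools, not raw areas.
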