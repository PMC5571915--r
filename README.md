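# dockvar

Most disease-associated missense variants (nsSNPs) cannot be placed on a
protein–protein interface simply because no structure of the complex
exists: structural coverage of the human interactome is a few percent.
`dockvar` implements a docking-based workaround for structural
bioinformaticians and variant curators: it predicts interface and hot-spot
residues from rigid-body docking of the *unbound* subunits, maps missense
variants onto those predictions, and computes the enrichment statistics
used to characterize where disease variants sit in interaction networks.

## The method

**Residue classes.** On a complex structure, a residue is *core* if its
relative solvent accessibility rASA < 0.1 (rASA = ASA divided by a
residue-type reference maximum; Shrake–Rupley ASA with a 1.4 Å probe),
*interface* if it is exposed and any of its atoms lies within 10 Å of a
partner atom, and *non-interacting surface* otherwise. When several
structures cover a protein, the rASA used for the core decision is the
average over structures.

**Docking-based interface prediction.** When no complex exists, the two
subunits are docked: shape complementarity is scored by FFT correlation of
Katchalski-Katzir grids over a quasi-uniform rotation set, and poses are
rescored with an energy function of capped Coulomb electrostatics
(ε(r) = 4r), capped 6–12 van der Waals and an atomic-solvation
desolvation term. For each residue *i*, the averaged buried surface over
the 100 lowest-energy poses is

    ABS_i = (ASA_unbound,i − mean_poses(ASA_i)) / ASA_unbound,i

normalized per protein into the *normalized interface propensity*

    NIP_i = (ABS_i − mean(ABS)) / (max(ABS) − mean(ABS))

Residues with NIP ≥ 0.2 are predicted interface **hot-spots**; the
predicted patch is then **extended** by all surface residues (rASA > 0.1)
within 10 Å of a hot-spot, trading some precision for much higher
sensitivity.

**Variant statistics.** Variants from a humsavar-dialect table are mapped
onto structure numbering by global sequence alignment and annotated as
core / interface / non-interacting surface using structures, docking
predictions, or both. Regional preferences are quantified by
observed/expected ratios and odds ratios

    OR_ij = [P_i/(1−P_i)] / [P_j/(1−P_j)],   P_i = n_i / N_i

with Fisher exact two-tailed p-values and Woolf confidence intervals,
plus sensitivity/precision of predictions against size-matched random
surface baselines.

## Worked example

Dock a synthetic two-body complex with a designed 6-residue interface and
recover it from the pose ensemble:

```r
library(dockvar)
toy <- make_toy_complex(n_residues = 30, interface_size = 6, seed = 1)
run <- dock_pair(toy$receptor, toy$ligand, n_rotations = 150,
                 spacing = 1.8, n_keep = 6000, seed = 1)
prof <- nip_profile(run, side = "receptor", k = 100)
glance(prof)
#> # A tibble: 1 × 6
#>   n_residues n_hotspots n_extended cutoff radius n_poses_used
#>        <int>      <int>      <int>  <dbl>  <dbl>        <int>
#> 1         30         11         17    0.2     10          100

surface <- prof$res_key[prof$rasa > 0.1]
evaluate_prediction(prof$res_key[prof$extended_interface],
                    intersect(toy$truth_receptor, surface), prof$res_key)
#> # A tibble: 1 × 5
#>      tp    fp    fn sensitivity precision
#>   <int> <int> <int>       <dbl>     <dbl>
#> 1     6    11     0           1     0.353
```

All six designed interface residues are recovered (sensitivity 1) at the
cost of 11 false-positive neighbors (precision 0.35) — the intended
behavior of patch extension. `autoplot(prof)` draws the per-residue NIP
profile with the 0.2 cutoff.

The packaged interaction-network census reproduces the survey statistics
for disease variants in six disease networks (combined
structures-plus-docking context):

```r
st <- census_statistics(interaction_census("combined"), "DISEASE")
round(st$oe, 2)
#>              core         interface     non_interface hotspot_interface
#>              1.59              0.94              0.63              1.05
glance(st$or_interface)
#> # A tibble: 1 × 5
#>   odds_ratio ci_lo ci_hi       p_value corrected
#>        <dbl> <dbl> <dbl>         <dbl> <lgl>
#> 1       1.51  1.31  1.73 0.00000000779 FALSE
```

Disease variants avoid the non-interacting surface (O/E 0.63) and prefer
interfaces over it (OR 1.51); predicted hot-spot positions show the
strongest preference (OR 1.68).

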