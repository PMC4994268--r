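# sigmaqsar

QSAR and pharmacophore geometry for sigma-1 (σ1) receptor ligands of the
1,4-disubstituted piperidine class: 4-aroylpiperidines ("ketone" series),
4-(α-hydroxybenzyl)piperidines ("alcohol" series) and their
N-(3-bromobenzyl)amine analogues. The package is aimed at medicinal /
computational chemists who want to rerun, audit, or extend the computational
arm of this structure–activity study from its published tables and compound
structures alone.

## What it computes

**Censored affinity transform.** Radioligand competition assays report an
equilibrium inhibition constant Ki (nM), censored at the assay ceiling when
binding is too weak (`>434` for σ1, `>854` for σ2). The study's log-affinity
response is the pKi calibrated to its tables,

    value = -log10(Ki / 1 nM),

with censored entries resolved to their bound, plus σ2/σ1 selectivity ratios
rounded to integers. The literal thermodynamic form `-RT ln Ki` is exposed
separately (`thermoFreeEnergy()`).

**Multilinear QSAR.** Ordinary least squares with intercept of the
log-affinity on subsets of five molecular descriptors — density *d*, 3D van
der Waals surface area *S_vdW*, water-accessible surface area *S_wat*, 2D
van der Waals surface area *A_vdW*, dipole moment *μ_D* — with the study's
statistics conventions:

    R² = 1 − SSE/SST,   RMSE = √(SSE/N),   F = (R²/k) / ((1−R²)/(N−k−1)),

plus exhaustive subset search (`subsetSearch()`) and leave-one-out Q²
(`looCv()`).

**Descriptors from structure.** Seeded distance-geometry conformers
minimized with a classical force field (GAFF by default), Shrake–Rupley
dot-sampled surface areas (Bondi radii, deterministic golden-spiral points,
1.4 Å water probe for *S_wat*), grid-based union-of-spheres volumes behind
the density, a connection-table cap model for *A_vdW*, and point-charge
dipoles from electronegativity-equalization charges.

**Pharmacophore distances.** On a minimized conformer the package locates
the basic piperidine nitrogen, the secondary-site oxygen (carbonyl or
hydroxyl; the secondary amine nitrogen stands in for the amine series) and
the primary hydrophobic aryl centroid, measures the three Gund-style
distances (centroid–N, O–centroid, O–N) and classifies them against the
published ranges (6.30–7.14 Å, 3.68–3.71 Å, 4.17–4.97 Å).

## Worked example

```r
library(sigmaqsar)

binding <- loadBindingTable(fixturePath("binding"))
aff <- affinityTable(binding)
head(aff[, c("compound", "pki_sigma1", "ratio", "ratio_printed")], 3)
#>   compound pki_sigma1 ratio ratio_printed
#> 1       7a -0.4712917     7             5
#> 2       7b -2.6374897     2             2
#> 3       7c -0.7767012    93            93
```

`pki_sigma1` is the transformed σ1 affinity (−log10 of Ki in nM; 7a's
2.96 nM becomes −0.47, the weak censored 7b becomes −2.64). `ratio` is the
recomputed σ2/σ1 selectivity; every row matches the published integer except
7a, a documented misprint (21.64/2.96 rounds to 7, not 5).

```r
tab4 <- loadDescriptorTable(fixturePath("descriptors"))
m <- fitQsar(tab4, c("S_vdW", "A_vdW", "S_wat"))
m
#> QsarModel (paper-reproduction mode): dG_exp ~ S_vdW + A_vdW + S_wat
#>   dG = -5.54 - 0.07*S_vdW + 0.01*A_vdW + 0.05*S_wat
#>   N = 14, k = 3, R2 = 0.128, RMSE = 0.998, F = 0.49
```

This is the refit of the study's best three-descriptor model on its own
printed table. The R² of 0.128 — far below the published 0.77 — is not a
bug: the published prediction column is provably not a linear function of
the published descriptor columns, so no least-squares refit can reproduce
the published statistics (the vignette gives the two-line proof).

```r
measurePharmacophore("7e", seed = 1)
#>   compound d_centroid_N d_O_centroid   d_O_N secondary_site
#> 1       7e     4.936318     3.618966 4.68175         oxygen
```

`d_O_centroid` ≈ 3.62 Å (3.64 averaged over five seeds) is the through-bond-constrained distance from the
benzoyl oxygen to the fluorophenyl centroid of the most potent ligand,
against 3.71 Å reported for the reference geometry; `d_centroid_N` is
conformer-dependent and is reported per seed.

The full arc — affinities, descriptors, fits, subset search, pharmacophore
table, and a summary JSON comparing every recomputable published number with
its recomputed value — is one call:

```r
res <- runPipeline(pipelineConfig("paper-reproduction", output_dir = "run1"))
res$status   # 0 all checks pass, 2 reproduction tolerance exceeded
```

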