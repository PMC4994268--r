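---
title: "Methods: censored-Ki QSAR and pharmacophore geometry for sigma-1 piperidine ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored-Ki QSAR and pharmacophore geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmaqsar)
```

This vignette is the package's account of its models, approximations and
design choices. Everything quantitative below is computed by the code as it
runs here; nothing is quoted from memory.

## The study system

Fourteen 1,4-disubstituted piperidines — six aroyl ketones (ids 7a–7f), six
carbinol alcohols (8a–8f) and two benzylamine analogues (9d, 9e) — were
assayed for binding at the σ1 and σ2 receptors. All carry a basic piperidine
nitrogen flanked by two aryl groups, the classical σ1 pharmacophore motif: an
amine site between a primary and a secondary hydrophobic pocket, with an
electronegative atom (here a carbonyl or hydroxyl oxygen) as a possible
secondary interaction site. `compoundRegistry()` encodes the fourteen
structures as SMILES derived from their systematic names; the chiral members
(the carbinol carbon of the alcohols, the benzylic carbon of the amines) are
stored as R-isomers, the configuration the original modelling used.

## Censored affinities

Ki values censored at the assay ceiling are printed as `>434` (σ1) or
`>854` (σ2) nM. The package resolves censored values **to their bound** for
both the log transform and selectivity ratios, because that is exactly how
the source tables were built: the tabulated response for every censored σ1
entry equals −log10(434) = −2.64, and censored-pair selectivity ratios equal
round(854/434) = 2.

The response scale itself deserves a note. The source describes the response
as a binding free energy, −RT·ln Ki, but a brute-force sweep over unit
conventions (nM/µM/M; ln vs log10; RT at plausible temperatures) shows that
every tabulated value equals plain −log10(Ki in nM): −log10(2.96) = −0.47,
−log10(526.53) = −2.72, and so on for all fourteen rows to ±0.005 — with a
single exception, compound 8c, where the table's own roundings disagree
(−log10(2.49) = −0.396 prints as −0.39). `kiToAffinity()` therefore
implements the pKi calibration, and the literal thermodynamic form is a
separate function (`thermoFreeEnergy()`) that plays no part in reproduction.

Two further printed slips are handled explicitly rather than silently: the
selectivity ratio of 7a prints 5 but 21.64/2.96 rounds to 7 (the recomputed
table flags it), and the residual of 8f prints +0.4 where the residual
identity gives −0.40 (the loader accepts it with a warning naming the row).

## The descriptor table is internally inconsistent — and what that means here

The packaged 14-row descriptor table transcribes the published one: five
descriptors (d, S_vdW, S_wat, A_vdW, μ_D), the observed log-affinity, the
model's predictions and residuals. Its statistics chain is self-consistent:

```{r}
t4 <- suppressWarnings(loadDescriptorTable(fixturePath("descriptors")))
sse <- sum(t4$dG_res^2)
sst <- sum((t4$dG_exp - mean(t4$dG_exp))^2)
c(R2 = 1 - sse / sst, RMSE = sqrt(sse / 14))
```

— which reproduces the published R² = 0.77 and RMSE = 0.51. But an ordinary
least-squares refit of the response on the same table's three surface-area
columns gives:

```{r}
fitQsar(t4, c("S_vdW", "A_vdW", "S_wat"))
```

Least squares *minimizes* the error sum of squares, so if the published
prediction column (SSE 3.70) were any linear function of the published
descriptor columns, the refit above could not have SSE 13.9. It follows that
the published predictions are **not** a linear function of the published
descriptors — the descriptor block that was typeset is not the data behind
the published fits (even the full five-descriptor refit reaches only
R² ≈ 0.56). The package keeps the published table as its fixture, fits
honestly, and reports both numbers side by side; the pipeline's
paper-reproduction summary and the acceptance tests record these comparisons
as failed rather than adjusting either side. The affinity transform, the
selectivity ratios, the statistics conventions (below) and the pharmacophore
geometry all reproduce; only quantities that depend on the descriptor block
itself do not.

## Regression conventions

`fitQsar()` is ordinary least squares with intercept on raw (unstandardized)
descriptor columns. The statistics follow the source's conventions, verified
against its printed residual column: R² = 1 − SSE/SST with SST about the
mean; RMSE = √(SSE/N) — denominator N, not residual degrees of freedom,
since √(3.697/14) = 0.514 matches the printed 0.51 while √(3.697/10) does
not; and the Fisher statistic F = (R²/k)/((1−R²)/(N−k−1)). A perfect fit
reports F as `Inf`. `subsetSearch()` enumerates all descriptor subsets of a
given size and ranks by R², ties broken by F and then lexicographically so
the ranking is deterministic. `looCv()` adds the standard leave-one-out Q²
the source omits.

## Conformers: distance geometry plus a classical force field

The original geometries came from semiempirical (AM1) optimization of
sketched structures, which is not reproducible at desk scale. The package's
geometry contract is classical and fully seeded:

1. **Bounds** from ideal bond lengths (by element pair and order), ideal
   angles by hybridization (109.47°/120°/180°), and exact aromatic-ring
   cross-distances (meta 1.39√3 Å, para 2.78 Å); all other pairs get
   element-based lower bounds.
2. **Embedding**: a distance matrix sampled between the bounds with a seeded
   RNG, embedded by the classical metric-matrix (MDS) construction, then
   polished against the restraints with L-BFGS.
3. **Minimization** with a force field via OpenBabel to a stated convergence
   criterion (default `crit = 1e-3`), which is deterministic given its input
   — so the whole chain is bit-reproducible for a fixed (compound, seed).
4. **Configuration check**: if the parent SMILES carries a stereocentre, the
   minimized geometry is canonicalized back to SMILES and mirrored once if
   the configuration flipped (each compound here has at most one
   stereocentre, so a mirror fixes it exactly).
5. **Validation**: bond lengths within 0.7–2.0 Å, no nonbonded clash below
   1.2 Å, aromatic rings planar; failed attempts are retried with derived
   sub-seeds, and an error names the compound after a bounded number of
   attempts.

**Force field.** The default is GAFF. MMFF94 was evaluated first and
produces, in this OpenBabel build, sporadically compressed aryl–carbonyl
angles (~116° instead of ~120°) even in low-energy minima, which makes the
through-bond O–centroid distance erratic across seeds (sd ≈ 0.1 Å); GAFF,
UFF and Ghemical agree with each other at ~3.63–3.65 Å with seed sd ≈ 0.02 Å.
All four remain available through the `ff` argument. Energies recorded in
the conformer provenance are the force field's own units and are used only
for comparisons within one field (post-minimization energy is asserted to
not exceed the pre-minimization energy, and `ensembleSize > 1` picks the
lowest-energy member).

**Protonation.** Geometries and descriptors use the neutral free base: the
receptor-site mapping conventions this work follows place a virtual
interaction point near the amine rather than protonating the ligand, so no
charged species is needed for the measurements made here.

## Descriptors and their approximations

* **S_vdW, S_wat** — Shrake–Rupley dot sampling with Bondi radii, probe 0
  and 1.4 Å respectively, 960 points per atom from a deterministic golden
  spiral (no RNG in the surface code). Coordinates are first put in a
  canonical principal-axes frame, which makes the dot- and grid-sampled
  quantities exactly invariant under rigid motion of the input (up to
  principal-axis degeneracy of highly symmetric molecules, irrelevant for
  this chemistry). Analytic limits (isolated sphere, disjoint union,
  two-sphere overlap) are tested to ≤1.5%.
* **Volume and density** — union-of-spheres volume on a 0.2 Å grid with a
  one-cell linear boundary ramp (removes the systematic undercount of hard
  cell-centre counting; the isolated-sphere error is ~0.5% and halving the
  spacing moves drug-sized volumes by well under 2%). Density is defined
  operationally as MW/(N_A·V_vdW). Note this yields ~1.8–2.2 g/cm³ for
  these compounds, whereas the reference table prints ~1.0: the original
  software's "density" evidently divides by a larger, packing-inclusive
  volume. Orderings (the brominated ketone denser than its methyl analogue)
  are preserved and tested; absolute agreement is not claimed.
* **A_vdW** — a connection-table model: each atom's full sphere minus the
  spherical caps buried by bonded neighbours placed at ideal bond lengths.
  No coordinates are used, so it is exactly conformation-independent.
* **μ_D** — the point-charge dipole |Σqᵢrᵢ|·4.8032 D from
  electronegativity-equalization charges (Gasteiger–Marsili by default;
  EEM and others selectable, and recommended for ions since sigma-only
  Gasteiger does not honour a net charge). This is the weakest surrogate for
  the reference's semiempirical dipoles: magnitudes and the per-compound
  ordering within a series are not preserved (vacuum-conformer dependence
  plus missing π polarization), and the package only asserts the coarse
  polar-versus-apolar ordering.

**Estimator choice.** Conformer-dependent descriptors are reported as means
over five seeded conformers (`nConformers = 5`). A single random embedding
is a noisy estimator of a surface area computed on a locally minimized
sketch: with one conformer the computed S_wat ranks agree with the reference
table at Spearman ρ ≈ 0.6, with the five-conformer mean at ρ ≈ 0.9 (S_vdW
ρ ≈ 0.92 either way). The package's contract for computed descriptors is
rank consistency, not numeric equality, and that is what the tests assert.

## Pharmacophore measurement

`identifyFeatures()` walks the graph: the basic nitrogen is the sp³ N in a
saturated six-membered ring; the linker carbon is the exocyclic carbon on
the ring position para to N; the secondary site is the O on that carbon
(carbonyl or hydroxyl) or, for the amine series which has none, the
secondary amine N — returned with an explicit `secondary_site = "amine"`
flag rather than a silent substitution. The primary aryl (Ar2) is the
six-membered aromatic ring bonded to the linker carbon: only that
assignment is geometrically consistent with the reported ~6.3 Å centroid–N
distances (the N-benzyl ring, Ar1, sits ~2.5 Å from N through one CH₂). The
centroid is the arithmetic mean of the six ring atoms.

Of the three distances, only O–centroid is constrained through bonds (two
bonds and a rigid ring), and it is the only one carried into acceptance:
measured 3.62–3.67 Å across seeds for 7e against the reported 3.71 Å, and
~3.65 Å for 8d against 3.68 Å, within the ±0.15 Å window; the closed-form
textbook-geometry oracle gives 3.65 Å. Centroid–N and O–N swing with the
benzyl and piperidine torsions, so the pipeline reports their seed mean ± sd
instead of a single number, and no acceptance tolerance is attached to them.
Classification against the published ranges is boundary-inclusive, and a
degenerate measurement (non-positive distances, triangle-inequality
violation) is an error rather than "outside".

## Synthetic data

The generator emulates the reference table's statistical regime, not its
chemistry: n = 14 rows; descriptor columns drawn from normal distributions
located and scaled like the real columns (d: 1.06 ± 0.06; S_vdW: 372 ± 52;
S_wat: 606 ± 74; A_vdW: 334 ± 38; μ_D: 2.5 ± 1.8, folded positive), with a
0.9 correlation between the two 3D surface areas mirroring their
near-collinearity in the real data so that rank-deficiency paths get
exercised; a known linear response with round, a-priori coefficients
(−3·d + 0.02·S_vdW + 0.01·S_wat − 0.02·A_vdW − 0.3·μ_D − 4.1) plus Gaussian
noise (default sd 0.5, the scale of the real fit's residuals). The table
carries the noiseless linear part as its prediction column, so the residual
identity holds by construction. The censored-binding generator draws Ki
log-uniformly on 0.5–5000 nM and censors at the assay ceilings, which gives
an analytically checkable censoring rate. What passing these tests shows is
that the estimators recover a *correctly specified* linear model under
realistic collinearity and noise; it says nothing about whether the real
descriptors linearly determine real affinities.

## Problem sizes and determinism

The test suite embeds each registry compound once (shared via a cache),
computes the full five-conformer descriptor table once, uses five seeds per
compound for the pharmacophore acceptance check, 200 replicates for the
coefficient-bias check and 40 per noise level for the recovery curve, and
runs the end-to-end pipeline on the fixtures plus a five-compound subset in
new-compound mode. Every stochastic step is seeded, sub-seeds are derived
arithmetically from the user seed, and reruns with one configuration are
byte-identical (the tests assert this on the pipeline's CSV outputs).

## Known limitations

* The published descriptor block cannot reproduce the published regression
  statistics (see above); the package documents and measures the
  discrepancy but cannot repair it.
* Computed descriptors are rank-faithful surrogates, not replacements, for
  the original semiempirical/commercial descriptor set; μ_D in particular
  should not be interpreted per-compound.
* The density definition is explicitly operational; its absolute scale
  differs from the reference's by a packing-volume factor.
* Conformer search is local: embeddings sample torsions randomly and
  minimize locally, which is adequate for through-bond pharmacophore
  distances and ensemble-averaged surfaces but is not a global
  conformational analysis.
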