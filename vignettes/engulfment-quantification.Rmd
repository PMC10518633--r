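---
title: "Quantifying glial engulfment of synapses: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial engulfment of synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaEngulf)
```

## The scientific problem

In Alzheimer's disease, astrocytes and microglia contain more synaptic
protein than in control brain, and glial cells in culture phagocytose
disease-derived synaptic particles more avidly than control ones. The
standard histological readout for this is **object-based 3D
colocalization**: immunofluorescence stacks are segmented per channel
(a glial marker such as GFAP or CD68, a synaptic marker such as
synapsin 1 or synaptophysin, optionally a neurite marker such as MAP2
and an amyloid-plaque stain), 3D objects are extracted, and a synaptic
object counts as *ingested* when it overlaps a glial object by at
least 25% of its structure. Per-stack summaries — colocalized volume,
stain burden, colocalized volume normalized to stack or glial volume,
plaque-proximity strata — are then compared between donor cohorts with
mixed-effects models that treat the donor as a random effect.

`gliaEngulf` implements that quantification chain end to end, together
with the live-imaging side of the same biology (phagocytosis indices,
within-experiment control normalization, areas under uptake curves,
post-wash degradation metrics) and a synthetic-data generator that
plants known effects so the whole pipeline can be validated without
access to human tissue.

## Segmentation model

Each channel is binarized with an **adaptive local-mean threshold**: a
voxel is foreground iff its intensity exceeds the mean of a
`window_size` × `window_size` neighbourhood in its own z-slice minus an
offset `C`, with edge-replicate padding. The shipped per-marker
settings are used unchanged for every stack of an experiment:

| marker | window (px) | C | method | min size |
|---|---|---|---|---|
| CD68 | 70 | 0.20 | mean | none |
| Syn1 | 10 | 1.00 | mean | none |
| GFAP | 70 | 0.15 | mean | none |

`MAP2` and the plaque stain reuse the GFAP settings — a package choice
for the other extended, filamentous markers. Two conventions are pinned
and surfaced as options rather than guessed silently:

* **2D windows, 3D objects.** The local mean is computed per z-slice
  (window sizes are single numbers, as in the classic auto-local
  threshold implementations); connected components are then assembled
  in 3D. "Segmented in 3D" is read as 3D object assembly.
* **Raw intensity scale.** `C` applies to the image's native (8-bit)
  scale. The shipped C values (0.2 vs 1) are only mutually consistent
  on a raw-count scale; on a normalized scale C = 1 would exceed the
  whole dynamic range.

The threshold uses a strict inequality, and even window sizes span
`floor((w-1)/2)` pixels before and `ceil((w-1)/2)` after the centre.
A documented degenerate case follows directly from the rule: on a
perfectly flat slice every voxel equals its local mean, so a positive
`C` marks the entire slice foreground.

**Connectivity.** Components are extracted with 6-, 18- or
26-connectivity; the package default is 6. At the 0.18 µm lateral
sampling these data emulate, a corner- or edge-only voxel contact is
far below the optical resolution and carries no evidence that two
structures are one. Empirically, 26-connectivity lets single-voxel
chance contacts bridge the dense synaptic channel into one giant
component, which destroys object-level colocalization; face
connectivity keeps genuinely separate puncta separate. All three
settings are available and tested against a flood-fill oracle.

## Colocalization model

For every pair of overlapping objects from two channels the package
records the overlap volume and the overlap fraction of each object,
and flags the pair **colocalized when the overlap reaches 25% of the
smaller object** (`min_overlap_fraction = 0.25`,
`denominator_rule = "min_object"`). The smaller-object anchor is a
deliberate reading of "overlap at least 25% of their whole structure":
synaptic puncta are minute relative to a glial arbor, so anchoring on
the glial object would make colocalization vanish; the minimum makes
the rule symmetric and matches the engulfed-punctum interpretation.
Both single-object anchors remain selectable.

Triple colocalization (synaptic + neurite marker inside glia) is
computed at the voxel level — the volume of the three-way mask
intersection — not by re-applying the object rule, because the
scientific quantity is a volume, not an object count.

Per-stack metrics follow the field's normalizations: stained volume
fraction per channel (*burden*), colocalized volume in µm³, colocalized
volume per stack volume, and colocalized volume per glial stain volume
(flagged missing when the glial volume is zero). Objects can be
stratified by plaque proximity using an exact anisotropic Euclidean
distance transform on the plaque mask; an object is *near* when the
minimum voxel-centre distance to plaque is at most 10 µm (the distance
is configurable and recorded; no published convention pins this
distance). Stacks with an empty plaque mask are flagged plaque-free
and excluded from near/far contrasts.

## The synthetic-data generator

The generator is first-class, tested code: it emits multi-channel
stacks together with ground truth (per-channel label volumes, a
punctum table with planted engulfment flags, the parameter record), so
every downstream stage can be validated against a known plant. One
integer seed fully determines every voxel and table.

**Geometry.** Filamentous (GFAP-like) glia are dilated branching
persistent random walks with tapering radius (base 0.5 µm); blobby
(CD68-like) glia are unions of spaced ellipsoids (≈1–2 µm across,
minimum 3 µm centre spacing) plus abundant sub-micron specks —
phago-lysosomal staining is granular at every scale. Structures are
added until a target volume fraction of the *imaged* region is reached
(default 8% filamentous, 4% blobby). Synaptic puncta are point-like
Gaussian spots (σ = 0.05 µm, truncated at 2.5σ) at a realistic cortical
density of 1.2 /µm³. A planted fraction of puncta is *engulfed*:
centred on voxels inside the glial ground truth, spaced at least
0.55 µm apart (phago-lysosomal compartments are distributed along
processes by transport, not as a Poisson rain), and rendered brighter
(1.2–1.8×) than free neuropil puncta, as aggregated material in
lysosomes is. All other puncta keep a 0.35 µm clearance from the glial
volume — two structures cannot occupy the same space unless engulfment
is planted. Optional MAP2-like neurites are dense 3D tubes (60 per
stack) that avoid the glial volume by 0.45 µm; planted *co-engulfed*
neurite fragments are short stubs threaded through locally isolated
engulfed puncta, pointing out of the glia, mirroring a dendrite
segment caught at its synapse. Plaques are large ellipsoidal blobs.

**Rendering.** Signal → Gaussian PSF blur (σ = 0.8 voxel axial,
0.6 voxel lateral, i.e. 0.24/0.11 µm — a realistic confocal PSF at
0.18 × 0.18 × 0.3 µm voxels) → Poisson shot noise at 50 photons per
digital number → additive Gaussian read noise (0.15 DN) → clipping and
8-bit quantization. The detector model is shot-noise-limited with
essentially zero background; the mean-minus-C rule classifies any
voxel within C of its local window mean as foreground, so a background
with appreciable additive noise floor would (correctly, per the rule)
be segmented as foreground. Every stack is simulated inside a guard
margin (4 slices, 6 pixels) and cropped: the imaged volume sits inside
continuous tissue, and hard simulation edges would otherwise create
stain-free windows that the threshold rule marks entirely foreground.

**What the generator does not emulate.** Paraffin autofluorescence,
staining chemistry, spectral bleed-through, photobleaching, optical
aberrations, and non-rigid tissue deformation are all absent; glial
morphology is a caricature (random walks and ellipsoids, not
reconstructions). Passing recovery tests on these simulations
therefore shows that the *quantification chain* is correct and
unbiased under a controlled forward model — not that segmentation
settings transfer to any particular real data set.

**Cohort designs** plant group effects as multipliers on the engulfed
fraction and/or the glial volume fraction; each case additionally
draws one unit-mean lognormal multiplier (CV 0.2 by default) shared by
its stacks — the between-case variability that the random-intercept
model later absorbs. Named presets encode the effect sizes the
pipeline is expected to recover (engulfment ratios 2.1 and 2.7, a 1.9×
burden ratio, pair:triple volume ratios of 10 and 44), each at 12
cases per group and 4 stacks per case on 32 × 128 × 128 voxel stacks —
a scale chosen so a full preset runs in minutes on one CPU while the
planted ratio's sampling error stays well inside the recovery
tolerances. Cohorts are materialised lazily (`realize_stack()`), so
memory stays constant regardless of cohort size.

**Phagocytosis kinetics** follow a logistic uptake curve
`v(t) = plateau / (1 + exp(-rate (t - t½)))`; published uptake curves
are sigmoid-like but state no functional form, so the logistic is a
modelling choice, and every analysis is validated against its closed
form. Cytochalasin D forces a zero plateau (actin blockade abolishes
phagocytosis); after an optional wash the retained signal decays
exponentially unless cathepsins are blocked (K777). Well noise is
multiplicative lognormal; with zero CV the emitted tables equal the
closed form exactly, which the tests exploit. Cell counts are emitted
as per-field averages (fractional values are kept rather than rounded,
so the closed-form identity is exact).

## Statistics

The group-comparison harness mirrors nested-histology practice:

* **Tukey ladder of powers.** λ is selected from
  {−2, −1, −0.5, 0, 0.5, 1, 2} by the probability-plot correlation
  (correlation of the sorted sample with standard normal quantiles);
  nonpositive data are shifted by `1e-6 + |min|` first; λ < 0 uses
  `-(x^λ)` so the transform is always monotone increasing. The chosen
  λ and shift are recorded in every fit.
* **Random-intercept mixed model** fitted by REML (`lmerTest`), one
  random intercept for the case / culture-replicate grouping — no
  random slopes, matching how such data are analysed. Per-term F tests
  use the Satterthwaite denominator-df approximation and are documented
  as approximate. Singular fits (zero between-case variance) are
  flagged, not hidden; in that balanced limit the F statistic
  approaches the one-way fixed-effects ANOVA value, which is a tested
  contract.
* **Tukey-corrected pairwise contrasts** over a factor's levels
  (`emmeans`), with the family-of-one identity for two-level factors.
* **Fold changes** are ratios of group means of case-level means (so
  duplicating within-case observations changes nothing), with a seeded
  case-level bootstrap CI; case medians are available by option.
* **Correlations** default to rank-based (the coefficient type behind
  published correlation values is not stated); Pearson by option.

The suite checks the pipeline's operating characteristics directly:
CI coverage of a planted effect, family-wise error of the contrasts,
and the type-I error of the full transform + model + contrast chain on
null simulations with real case structure (asserted to stay within
[0.03, 0.07] at nominal 0.05 over 1000 replicates).

## Numerical and design choices worth knowing

* Axis order is (z, y, x) everywhere; physical units are µm and µm³;
  voxel (1,1,1) sits at the physical origin, and distances are
  voxel-centre to voxel-centre with anisotropy respected.
* The local-mean kernel uses per-slice integral images (exact, no
  approximation); connected components use union-find with
  deterministic first-voxel label ordering; the distance transform is
  the exact lower-envelope algorithm, one pass per axis.
* Object tables carry voxel counts, physical volumes, bounding boxes
  and centroids; `volume_um3` is always `voxel_count ×` voxel volume.
* Stacks are written as multi-plane TIFF with an OME companion-XML
  metadata file (`<base>.companion.ome`) carrying physical pixel sizes
  and channel names; a write/read round trip is bit-identical. A
  voxel-size override is honoured when metadata are absent.
* Pipeline outputs are CSVs that carry the config hash and seed on
  every row, plus a JSON run record; re-running a config reproduces
  every table byte for byte.

## Known limitations

* The mean-minus-C threshold is **burden-adaptive**: a brighter or
  denser field raises every local mean, which thins the foreground
  shell recovered around true structure. Between-group ratios of
  *stained volume* are therefore compressed toward 1 when the groups
  differ strongly in burden — a property of the published segmentation
  rule itself, reproduced faithfully here, and visible in the
  burden-preset recovery, which lands below its planted 1.9× ratio.
* The same rule marks any window devoid of stain entirely foreground,
  so object-level colocalization relies on every local window seeing
  some structure; the generator's densities were chosen to satisfy
  that, and sparse real channels would need the same scrutiny.
* Ratios of very small volumes (the triple-colocalization readouts)
  remain noisy at realistic punctum counts; the presets use elevated
  densities and per-case averaging to keep their sampling error inside
  stated tolerances, and recovered values still sit toward the low
  side of the planted ratio because residual foreground around
  co-engulfed stubs adds to the small denominator.
* Satterthwaite denominator df are an approximation; with very few
  cases the F tests are only as good as that approximation.

## A minimal worked run

```{r smoke, eval = FALSE}
out <- run_pipeline(list(seed = 1, cohort = list(preset = "smoke")),
                    out_dir = tempfile())
out$metrics[, c("stack_id", "group", "coloc_volume_um3",
                "coloc_per_glia_volume")]
```

The `smoke` preset (2 groups × 2 cases × 1 stack at 16 × 64 × 64
voxels) exercises simulate → segment → colocalize → metrics in a few
seconds; the full presets behind the recovery analyses are run by
`recover_preset_ratio()` and by `scripts/acceptance.R`.
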