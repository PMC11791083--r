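---
title: "Differential interactome analysis of AP-MS pull-downs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential interactome analysis of AP-MS pull-downs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmstools)
```

## The problem

Affinity purification followed by mass spectrometry (AP-MS) identifies
the proteins that co-purify with a tagged bait. Because beads, tags and
sticky proteins co-purify too, the interactome is defined
*differentially*: a protein is an interactor only if it is
significantly enriched in the bait pull-down relative to a control
purification (here, cells expressing the GFP tag alone). apmstools
implements this enrichment analysis for label-free iBAQ quantification
in the MaxQuant proteinGroups dialect, together with three companions
used in the same experimental programme: comparison of two baits'
interactomes, hit calling for an shRNA reporter screen used to triage
candidate interactors functionally, and proximity-ligation-assay (PLA)
scoring of confocal z-stacks used to validate interactions in situ.

## The AP-MS statistical model

The pipeline operates on a proteins × samples matrix of log2 iBAQ
intensities with explicit missingness, built from quadruplicate
pull-downs of each cell line.

**Artifact exclusion.** Protein groups flagged as known contaminants,
reverse (decoy) matches, or identified only by a modification site are
removed before any numeric step.

**Normalization.** Technical variation between runs shifts whole-sample
intensity distributions. For sample $j$ the sample median over its
quantified protein groups is
$\mathrm{median}_j = \mathrm{median}_i(\log_2 \mathrm{iBAQ}_{ij})$, and
the normalization factor is
$\mathrm{NF}_j = \mathrm{median}_j - \mathrm{median}_{j'}(\mathrm{median}_{j'})$,
subtracted from every value of sample $j$. After this, every sample
median equals the grand median, and within-sample differences — the
quantities the test consumes — are untouched. Medians are taken over
present values only; the equation's range over all $N$ protein groups
is not computable when some entries are missing, and present-value
medians are the only well-defined reading. Even-count medians are the
midpoint of the two central order statistics, so normalized medians
agree exactly on odd-count columns and to one representable step
otherwise.

**Valid-value filtering.** A protein must be quantified in at least
$k = 3$ replicates of at least one condition to be retained, and — per
contrast — in at least 3 replicates of the *bait* condition to be
tested against the control. The per-contrast rule deliberately places
no requirement on the control: a prey detected in all bait replicates
and never in the GFP control is the strongest interaction signal, not a
missing-data problem. (The alternative readings — requiring the count
in either group or in both — would discard exactly these proteins or
change nothing, respectively.)

**Imputation.** Missingness in label-free proteomics is left-censored:
low-abundance proteins fall below the detection limit (missing not at
random). Missing values are therefore imputed per replicate from a
down-shifted, width-shrunk normal distribution fit to that replicate's
observed values: with observed mean $\mu_j$ and standard deviation
$\sigma_j$ (sample, $n-1$ denominator), imputed values are drawn from
$\mathcal{N}(\mu_j - 1.8\,\sigma_j,\ (0.3\,\sigma_j)^2)$. The defaults
(width 0.3, downshift 1.8) are the field-standard Perseus-style
settings for this MNAR model. Draws are taken in a fixed column-major
order from one seeded generator, so a seed makes the imputation
bit-reproducible and independent of storage layout. Parameters are
estimated in a single pass from the present values; a whole-matrix
pooled option exists (`per_column = FALSE`) but per-replicate
estimation is the default because detection limits are per-run
properties.

**Testing.** Each protein is tested bait vs control with a two-sided
Welch (unequal-variance) $t$ test. Ranking and significance use the
S0-moderated statistic
$$d = \frac{\bar{x} - \bar{y}}{\sqrt{s_x^2/n_x + s_y^2/n_y} + S_0},
\qquad S_0 = 0.1,$$
the SAM-style construction: the fudge constant in the denominator
de-emphasizes proteins whose tiny standard error would otherwise make
negligible absolute differences look extreme. At $S_0 = 0$, $d$ is
exactly the Welch $t$. The reported p-value column is the unmoderated
Welch p; the significance decision never uses it directly.

**Permutation FDR.** The false-discovery rate is estimated by shuffling
the bait/control labels across the contrast's eight samples. For a
cutoff $c$ on $|d|$, $R(c)$ counts observed proteins with $|d| \ge c$
and each permutation $\pi$ contributes $V_\pi(c)$, its count of
permuted statistics exceeding $c$; the estimate is
$\widehat{\mathrm{FDR}}(c) = \overline{V_\pi(c)} / \max(R(c), 1)$. The
significant set is the largest $R(c)$ with
$\widehat{\mathrm{FDR}}(c) < 0.05$, searched over the observed $|d|$
order statistics (the estimate is piecewise constant between them),
with ties at the cutoff included. At quadruplicate scale a 4v4 contrast
admits $\binom{8}{4}/2 = 35$ distinct splits (a split and its
complement give the same $|d|$), so with the 250-randomization budget
the enumeration is exhaustive and the procedure is fully deterministic;
the identity split is excluded from the null set. When the number of
distinct splits exceeds the budget (larger designs), splits are sampled
without replacement under a seed. The mean of $V_\pi$ is the default
aggregate; a median option (`null_center = "median"`) is exposed. The
Perseus implementation that popularized these settings uses a
two-dimensional threshold curve in the ($t$, difference) plane whose
exact construction is not published; the one-dimensional $|d|$
threshold implemented here is the documented SAM construction and is
the package's own, stated approximation.

### Operating characteristics

The acceptance suite measures the procedure at the study's design
scale (4v4, $S_0 = 0.1$, FDR < 0.05, exhaustive splits). Under a
global null of 5000 proteins the fraction of simulation repeats with
any (necessarily false) call is ≈ 0.05–0.07 — the strict `< 0.05` rule
controls the error as intended. With 5% of 1000 proteins spiked at
+4 within-group standard deviations, the estimated-FDR curve crosses
0.05 before the weakest spiked proteins are reached: measured
sensitivity is ≈ 0.83–0.86 at an empirical FDR of ≈ 0.05. This is a
property of the statistic at quadruplicate scale, not an estimation
error — at cutoffs low enough to capture every spiked protein,
genuinely null proteins exceed the cutoff at a rate that pushes the
(and the true) FDR above 5%. Users should expect high precision and
moderate recall near the detection margin.

## Interactome comparison

An interactor set is the bait-enriched significant proteins of one
contrast: `significant & diff > 0`. Depleted significant proteins are
retained separately but never enter set comparisons. Identity is the
protein-group identifier (the first "Majority protein IDs" entry) —
gene names can be empty or duplicated. The overlap of two baits'
interactomes is exact set arithmetic; shared percentages are kept as
exact rationals internally and rounded to one decimal only for
display. Both sets come from their own bait-vs-control contrast (each
after its own pairwise filter); a protein is "shared" only when
independently significant in both.

## RNAi screen hit calling

Candidate interactors are triaged by depleting each with (at least)
two independent shRNAs and measuring an ISRE reporter under two
stimuli that activate the two upstream sensors (a RIG-I ligand,
5′ppp-dsRNA, and a cGAS ligand, plasmid DNA). Relative activity is the
ratio of replicate means, target shRNA over non-targeting control
shRNA, per stimulus. A gene is a hit when at least `min_shrnas = 2`
shRNAs show `rel ≤ 0.5` under *every* required stimulus — conjunctive
over shRNAs and stimuli, boundary inclusive ("at least 50%" reduction
includes exactly 50%). Means are taken per stimulus over replicates;
background (non-stimulated) subtraction is available
(`subtract_background = TRUE`) but off by default. The rule is monotone
by construction: lowering any relative activity can never un-call a
hit, and raising the threshold can only shrink the hit set.

## PLA scoring

A PLA punctum appears where two antibody epitopes are within ~40 nm,
so puncta counts proxy interaction events in situ. Scoring follows the
ImageJ particle-analysis workflow: binarize each z plane by an
inclusive intensity window (defaults 6–255 on the 8-bit scale; 10–255
for brighter backgrounds), label connected components (8-neighbor by
default, the ImageJ convention; 4-neighbor available), discard
components below `min_area` pixels (5 by default, 10 for the stringent
setting), and assign each particle to the cell under its centroid
pixel, discarding centroids on background. The PLA score of a cell is
its total particle count over all planes of the stack — per-plane 2-D
counting with no 3-D merging, so a punctum spanning planes counts once
per plane; this is the score definition, not an approximation of a 3-D
count. Thresholds and size windows are fixed per run and never
auto-tuned, matching the requirement that settings be constant within
an experimental group. Cell segmentation itself is out of scope: the
mask is an input.

## Synthetic data: what it emulates and what it does not

Every stage has a generator with known ground truth, so the pipeline
is exercisable and testable without any deposited raw data.

`simulate_apms()` emulates: a 12-sample design (two baits + GFP
control × quadruplicates, the study's shape); between-protein log2
abundance $\mathcal{N}(25.5, 3^2)$ and replicate noise of 0.5 — values
in the range typical of iBAQ pull-down data; per-sample technical
shifts (s.d. 0.3) to exercise normalization; bait-specific interactors
with log2 effects $\mathcal{N}(3, 1)$; interactor fractions (4% unique
to the first bait, 0.05% unique to the second, 0.75% shared) chosen to
mirror a large and a small interactome of ≈ 96 and ≈ 16 proteins with
≈ 15 shared — the scale of the motivating experiments; and logistic
MNAR missingness $P(\text{missing}) =
\mathrm{logit}^{-1}(0.8\,(22.5 - x))$, giving ≈ 20–25% missing values
concentrated in the low-intensity tail. It does **not** emulate:
peptide-level quantification and razor-peptide ambiguity,
correlated (batch) noise, compositional effects of bead saturation, or
interactors enriched by abundance change rather than binding. Passing
tests therefore certify the statistical machinery under the model's
assumptions, not robustness to every artifact of real acquisitions.

`simulate_screen()` plants hits at a configurable relative activity
with truncated-Gaussian replicate noise; it does not model
plate/batch effects or partial knockdowns differing between shRNAs.
`simulate_zstack()` plants super-threshold discs (radius 1.5 px,
area 9 px ≥ the default `min_area` 5) at non-overlapping positions
inside rectangular cells over sub-threshold uniform background; it
does not model a realistic PSF, photobleaching across z, or touching
cells.

## Numerical choices

- Zero and absent iBAQ cells are both missing (MaxQuant writes
  unquantified iBAQ as 0; log2 needs positivity).
- Welch statistics are computed by the direct formula; the permutation
  engine centres each protein's row first, which leaves means' and
  variances' differences unchanged but makes the identity permutation
  reproduce the observed $d$ bit-identically.
- Zero pooled variance: equal means give $t = 0, p = 1$; unequal means
  give the $\pm\infty$ limit with $p = 0$, flagged.
- The FDR cutoff search takes the deepest observed $|d|$ order
  statistic with estimate < 0.05, even when the estimate is
  non-monotone in between.
- TSV writers emit the shortest decimal representation that parses
  back to the identical double, so canonical files round-trip
  byte-identically.
- Component labelling is iterative minimum-label propagation to a
  fixed point — exact for any image, with cost proportional to the
  largest component's diameter (small for diffraction-limited spots).

## Problem sizes used by the test suite

The shipped checks run at reduced but statistically meaningful scale,
chosen as the smallest sizes at which the measured quantities are
stable: normalization and filtering oracles at 1000–2000 proteins;
imputation recovery at 10 000 imputed cells per sample; the null FDR
simulation at 5000 proteins × 200 repeats; spike-in operating
characteristics at 1000 proteins × 100 repeats; PLA recovery on
160×160 px stacks with 9 cells × 5 planes.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_apms(proteome_sim_config(seed = 1))
tab <- exclude_artifacts(sim$table)
m   <- normalize_median(to_log2_matrix(tab))$matrix
m   <- filter_min_valid(m, sim$design, k = 3)

res <- lapply(c("hnRNPM", "ELAVL1"), function(bait)
  run_contrast(m, sim$design, bait, "GFP",
               impute_seed = 1, s0 = 0.1, fdr_threshold = 0.05,
               n_permutations = 250, seed = 1))
sets <- lapply(res, extract_interactors)
overlap(sets[[1]], sets[[2]])
```

## Known limitations

- The permutation-FDR construction is the SAM-style 1-D threshold;
  numbers produced by Perseus's unpublished 2-D curve can differ,
  especially near the significance boundary.
- At quadruplicate scale only 35 distinct label splits exist; the FDR
  estimate is coarse (granularity 1/34 per permutation count) and
  conservative near the margin.
- Imputation assumes the observed distribution is approximately
  normal per replicate; heavy bimodality would misplace the imputed
  tail.
- PLA scoring trusts the provided cell mask; mis-segmentation moves
  particles between cells silently.
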