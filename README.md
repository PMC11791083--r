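# apmstools

Differential interactome analysis for affinity-purification mass
spectrometry (AP-MS), with companions for RNAi reporter-screen hit
calling and proximity-ligation-assay (PLA) scoring.

## What it does, and for whom

AP-MS identifies proteins co-purifying with a tagged bait, but beads
and tags pull down background too: the interactome must be defined by
*differential enrichment* against a control purification (e.g. GFP
alone). apmstools is for proteomics analysts working with label-free
iBAQ quantification in the MaxQuant `proteinGroups.txt` dialect who
want that analysis as tested, scriptable R instead of interactive
point-and-click.

The core statistical pipeline, per bait-vs-control contrast:

1. exclude contaminant / reverse / site-only protein groups;
2. log2-transform; subtract the per-sample normalization factor
   NF_j = median_j − median(median_1..M), so every sample median equals
   the grand median;
3. keep proteins quantified in ≥ 3 replicates of some condition, and
   (per contrast) in ≥ 3 replicates of the bait condition;
4. impute missing values per replicate from a down-shifted normal,
   N(μ_j − 1.8 σ_j, (0.3 σ_j)²) — the standard model for left-censored
   (MNAR) proteomics missingness;
5. test with the S0-moderated two-sided Welch statistic
   d = (x̄ − ȳ) / (√(s²ₓ/nₓ + s²ᵧ/nᵧ) + S0), S0 = 0.1, and control FDR
   < 0.05 by label permutation (exhaustive over the 35 distinct 4v4
   splits; up to 250 sampled splits for larger designs).

Downstream: interactor sets (significant and bait-enriched), exact
overlap decomposition of two baits' interactomes, dual-shRNA /
dual-stimulus ≥ 50%-reduction hit calling for ISRE reporter screens,
and per-cell PLA scores from thresholded, size-filtered particle
counting on confocal z-stacks. Synthetic-data generators with ground
truth (`simulate_apms()`, `simulate_screen()`, `simulate_zstack()`)
exercise every stage.

See `vignettes/differential-interactome.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(apmstools)

sim <- simulate_apms(proteome_sim_config(seed = 1))  # 2 baits + GFP, 4 reps
tab <- exclude_artifacts(sim$table)
m   <- normalize_median(to_log2_matrix(tab))$matrix
m   <- filter_min_valid(m, sim$design, k = 3)
m
#> intensity_matrix: 1720 proteins x 12 samples, 12.6% missing

res <- lapply(c("hnRNPM", "ELAVL1"), function(bait)
  run_contrast(m, sim$design, bait, "GFP", impute_seed = 1, seed = 1))
res[[1]]
#> differential_result: hnRNPM vs GFP, 1509 proteins, 80 significant
#>   s0 = 0.1, FDR < 0.05, 34 permutations (exhaustive), |d| cutoff = 3.02209

sets <- lapply(res, extract_interactors)
overlap(sets[[1]], sets[[2]])
#> overlap_summary: hnRNPM (n=74) vs ELAVL1 (n=10)
#>   shared: 6 (8.1% of hnRNPM, 60.0% of ELAVL1)
```

Reading the output: of 2000 simulated protein groups, 1720 survive the
min-valid filter; the hnRNPM contrast tests 1509 proteins (pairwise
filter) and calls 80 significant at permutation FDR < 0.05, of which
74 are enriched toward the bait — its interactor set. Six of those are
also independent interactors of ELAVL1, i.e. 60% of the small ELAVL1
interactome is shared with the large hnRNPM one. `plot_volcano(res[[1]])`
draws the enrichment-vs-significance view; `write_differential_result()`
writes the volcano table as TSV.

A thin command-line front end covers the common runs:

```sh
Rscript inst/scripts/apms.R read-check proteinGroups.txt
Rscript inst/scripts/apms.R test --input proteinGroups.txt --bait hnRNPM --control GFP
Rscript inst/scripts/apms.R screen --input screen.tsv --threshold 0.5
Rscript inst/scripts/apms.R pla --stack stack.tif --mask mask.tif --tlow 6 --min-area 5
```

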