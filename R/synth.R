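# Synthetic-data generators with known ground truth for every pipeline
# stage: AP-MS quantification tables with bait-specific spiked
# interactors and intensity-dependent (MNAR) missingness, reporter
# screen tables with planted knockdown effects, and z-stacks with
# planted diffraction-limited spots inside labelled cells.

#' Configuration of the AP-MS simulator
#'
#' Defaults mirror a GFP-tagged two-bait pull-down study at
#' quadruplicate scale: three cell lines (two baits plus the GFP-only
#' control) with four replicates each, ~2000 protein groups, log-normal
#' intensity noise, per-sample technical shifts, and left-censored
#' missingness that is logistic in the true log2 intensity.
#'
#' @param n_proteins number of protein groups (default 2000)
#' @param baits bait condition labels (default `c("hnRNPM", "ELAVL1")`;
#'   the first two are the designated pair for shared interactors)
#' @param control control condition label (default `"GFP"`)
#' @param n_replicates replicates per condition (default 4)
#' @param baseline_mean,baseline_sd between-protein distribution of
#'   true log2 iBAQ abundance (defaults 25.5 and 3)
#' @param noise_sd replicate-level log-normal noise, s.d. on the log2
#'   scale (default 0.5)
#' @param frac_unique named fractions of proteins that interact with
#'   exactly one bait (defaults 0.04 for the first bait and 0.0005 for
#'   the second, the scale of a large and a small interactome)
#' @param frac_shared fraction of proteins interacting with both
#'   designated baits (default 0.0075)
#' @param effect_mean,effect_sd log2 enrichment of an interactor in its
#'   bait's samples (defaults 3 and 1)
#' @param missing_midpoint,missing_slope missingness model:
#'   `P(missing) = plogis(missing_slope * (missing_midpoint - x))` for
#'   realized log2 intensity x (defaults 22.5 and 0.8). A slope of
#'   `Inf` gives a hard detection limit at the midpoint; a midpoint of
#'   `-Inf` disables missingness entirely.
#' @param sample_shift per-sample technical offsets (log2); either a
#'   vector of length samples, or a single s.d. from which shifts are
#'   drawn (default 0.3)
#' @param frac_contaminant,frac_reverse,frac_site_only fractions of
#'   additional decoy/artifact rows injected with the corresponding
#'   flag set (defaults 0: off)
#' @param seed integer seed (default 1)
#' @return an object of class `proteome_sim_config`
#' @export
proteome_sim_config <- function(n_proteins = 2000L,
                                baits = c("hnRNPM", "ELAVL1"),
                                control = "GFP",
                                n_replicates = 4L,
                                baseline_mean = 25.5, baseline_sd = 3,
                                noise_sd = 0.5,
                                frac_unique = c(0.04, 0.0005),
                                frac_shared = 0.0075,
                                effect_mean = 3, effect_sd = 1,
                                missing_midpoint = 22.5,
                                missing_slope = 0.8,
                                sample_shift = 0.3,
                                frac_contaminant = 0,
                                frac_reverse = 0,
                                frac_site_only = 0,
                                seed = 1L) {
  stopifnot(n_proteins >= 1L, length(baits) >= 1L, n_replicates >= 2L,
            baseline_sd > 0, noise_sd >= 0,
            all(frac_unique >= 0), all(frac_unique <= 1),
            frac_shared >= 0, frac_shared <= 1)
  if (length(frac_unique) != length(baits))
    frac_unique <- rep_len(frac_unique, length(baits))
  names(frac_unique) <- baits
  structure(as.list(environment()), class = "proteome_sim_config")
}

#' Simulate an AP-MS protein-groups table with ground truth
#'
#' True log2 intensity of protein i in sample j is
#' `baseline_i + effect_i[condition_j] + shift_j + noise_ij`; the
#' emitted iBAQ value is `2^x`, zeroed (missing) where the logistic
#' MNAR model fires on the realized intensity. Interactor effects act
#' only in the designated bait's samples. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [proteome_sim_config]
#' @return list with `table` (a [protein_groups]), `design` (the
#'   matching [experiment_design]) and `truth`: data.frame of
#'   per-protein interactor status and effect size per bait, plus
#'   `sample_shift` and the missingness matrix
#' @export
simulate_apms <- function(cfg = proteome_sim_config()) {
  stopifnot(inherits(cfg, "proteome_sim_config"))
  .with_seed(cfg$seed, {
    conds <- c(cfg$control, cfg$baits)
    cond_of <- rep(conds, each = cfg$n_replicates)
    samples <- paste(cond_of, rep(seq_len(cfg$n_replicates),
                                  times = length(conds)), sep = "_")
    names(cond_of) <- samples
    np <- cfg$n_proteins
    ids <- sprintf("P%05d", seq_len(np))

    # interactor status: shared pair first, then unique per bait
    status <- matrix(FALSE, np, length(cfg$baits),
                     dimnames = list(ids, cfg$baits))
    u <- stats::runif(np)
    lo <- 0
    if (length(cfg$baits) >= 2L) {
      shared <- u >= lo & u < lo + cfg$frac_shared
      status[shared, 1L] <- TRUE
      status[shared, 2L] <- TRUE
      lo <- lo + cfg$frac_shared
    }
    for (b in seq_along(cfg$baits)) {
      f <- cfg$frac_unique[[b]]
      sel <- u >= lo & u < lo + f
      status[sel, b] <- TRUE
      lo <- lo + f
    }
    effects <- matrix(0, np, length(cfg$baits),
                      dimnames = list(ids, cfg$baits))
    n_int <- sum(status)
    effects[status] <- stats::rnorm(n_int, cfg$effect_mean, cfg$effect_sd)

    shift <- if (length(cfg$sample_shift) == length(samples))
      as.numeric(cfg$sample_shift)
    else stats::rnorm(length(samples), 0, cfg$sample_shift)
    names(shift) <- samples

    baseline <- stats::rnorm(np, cfg$baseline_mean, cfg$baseline_sd)
    x <- matrix(baseline, np, length(samples),
                dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
      cj <- cond_of[j]
      if (cj %in% cfg$baits) x[, j] <- x[, j] + effects[, cj]
      x[, j] <- x[, j] + shift[j] +
        stats::rnorm(np, 0, cfg$noise_sd)
    }

    p_miss <- if (is.infinite(cfg$missing_slope))
      (x < cfg$missing_midpoint) * 1
    else stats::plogis(cfg$missing_slope * (cfg$missing_midpoint - x))
    miss <- matrix(stats::runif(length(x)) < p_miss, np,
                   dimnames = dimnames(x))

    ibaq <- 2^x
    ibaq[miss] <- NA_real_

    meta <- data.frame(group_id = ids,
                       gene_name = sprintf("GENE%05d", seq_len(np)),
                       contaminant = FALSE, reverse = FALSE,
                       site_only = FALSE, stringsAsFactors = FALSE)

    # optional decoy/artifact rows (flagged; excluded by preprocessing)
    n_decoy <- round(np * c(cfg$frac_contaminant, cfg$frac_reverse,
                            cfg$frac_site_only))
    if (sum(n_decoy) > 0L) {
      kinds <- rep(c("contaminant", "reverse", "site_only"), n_decoy)
      did <- sprintf("DECOY%04d", seq_along(kinds))
      dx <- matrix(2^stats::rnorm(length(kinds) * length(samples),
                                  cfg$baseline_mean, cfg$baseline_sd),
                   length(kinds), dimnames = list(did, samples))
      dmeta <- data.frame(group_id = did,
                          gene_name = "",
                          contaminant = kinds == "contaminant",
                          reverse = kinds == "reverse",
                          site_only = kinds == "site_only",
                          stringsAsFactors = FALSE)
      ibaq <- rbind(ibaq, dx)
      meta <- rbind(meta, dmeta)
    }

    truth <- data.frame(protein = ids, status, effects,
                        check.names = FALSE, stringsAsFactors = FALSE)
    names(truth) <- c("protein", paste0("interactor_", cfg$baits),
                      paste0("effect_", cfg$baits))
    list(table = protein_groups(ibaq, meta),
         design = experiment_design(cond_of, cfg$control),
         truth = list(proteins = truth, sample_shift = shift,
                      missing = miss))
  })
}

#' Simulate an RNAi reporter-screen table with planted hits
#'
#' The control shRNA reports activity ~1 (arbitrary reporter units)
#' under every stimulus; target shRNAs of planted hits report
#' `rel_hit`, all others `rel_null`, each with multiplicative-free
#' Gaussian noise of s.d. `noise_sd` truncated at 0.
#'
#' @param n_targets number of target genes (default 28, a typical
#'   follow-up screen size)
#' @param true_hits character vector of planted hit gene names; they
#'   are added to (or matched within) the target list
#' @param rel_hit relative activity of planted hits (default 0.3,
#'   i.e. a 70% knockdown of reporter activity)
#' @param rel_null relative activity of non-hits (default 1)
#' @param noise_sd replicate noise s.d. (default 0.05)
#' @param stimuli stimulus labels (default RIG-I and cGAS ligands)
#' @param n_shrnas shRNAs per target gene (default 2)
#' @param n_replicates replicates per (shRNA, stimulus) (default 3)
#' @param control_shrna control shRNA label (default `"shCtrl"`)
#' @param cell_line cell line label (default `"THP1"`)
#' @param seed integer seed (default 1)
#' @return a [screen_table]; planted hits are in attribute `true_hits`
#' @export
simulate_screen <- function(n_targets = 28L, true_hits = character(),
                            rel_hit = 0.3, rel_null = 1,
                            noise_sd = 0.05,
                            stimuli = c("5ppp-dsRNA", "pDNA"),
                            n_shrnas = 2L, n_replicates = 3L,
                            control_shrna = "shCtrl",
                            cell_line = "THP1", seed = 1L) {
  stopifnot(n_targets >= 1L, rel_hit >= 0, noise_sd >= 0)
  .with_seed(seed, {
    genes <- sprintf("TARGET%02d", seq_len(n_targets))
    extra <- setdiff(true_hits, genes)
    if (length(extra))
      genes[seq_along(extra)] <- extra
    rows <- list()
    add <- function(cl, sh, g, stim, level) {
      act <- pmax(0, level + stats::rnorm(n_replicates, 0, noise_sd))
      data.frame(cell_line = cl, shrna = sh, target_gene = g,
                 stimulus = stim, replicate = seq_len(n_replicates),
                 activity = act, stringsAsFactors = FALSE)
    }
    for (stim in stimuli)
      rows[[length(rows) + 1L]] <-
        add(cell_line, control_shrna, "none", stim, 1)
    for (g in genes) {
      level <- if (g %in% true_hits) rel_hit else rel_null
      for (k in seq_len(n_shrnas))
        for (stim in stimuli)
          rows[[length(rows) + 1L]] <-
            add(cell_line, sprintf("sh%s.%d", g, k), g, stim, level)
    }
    out <- screen_table(do.call(rbind, rows),
                        control_shrna = control_shrna)
    attr(out, "true_hits") <- intersect(genes, true_hits)
    out
  })
}

# rectangular tiling of n_cells labelled cells with background gaps
.grid_mask <- function(n_cells, dim, gap = 3L) {
  k <- ceiling(sqrt(n_cells))
  mask <- matrix(0L, dim[1L], dim[2L])
  ch <- dim[1L] %/% k; cw <- dim[2L] %/% k
  if (ch <= 2L * gap || cw <= 2L * gap)
    stop("image too small for the requested cell count", call. = FALSE)
  cell <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (cell >= n_cells) break
    cell <- cell + 1L
    r0 <- (i - 1L) * ch + gap; r1 <- i * ch - gap
    c0 <- (j - 1L) * cw + gap; c1 <- j * cw - gap
    mask[r0:r1, c0:c1] <- cell
  }
  mask
}

#' Simulate a z-stack with planted spots and a cell-label mask
#'
#' Cells are laid out as labelled rectangles separated by background.
#' In each plane, the requested number of diffraction-limited spots
#' (super-threshold discs of radius `spot_radius`, area >= 9 px at the
#' default radius) is planted at random non-overlapping positions well
#' inside the owning cell; the background carries uniform sub-threshold
#' noise in `[0, noise_amp]`.
#'
#' @param counts integer matrix `n_cells x n_planes`: planted spots per
#'   cell per plane
#' @param dim image dimensions in pixels (default `c(96, 96)`)
#' @param spot_radius disc radius in pixels (default 1.5)
#' @param spot_intensity intensity of spot pixels on the 8-bit scale
#'   (default 200)
#' @param noise_amp background noise amplitude; must stay below the
#'   detection threshold in use (default 4)
#' @param seed integer seed (default 1)
#' @param max_tries rejection-sampling attempts per spot before the
#'   layout is rejected with an error (default 200)
#' @return list with `stack` (list of plane matrices), `mask` (integer
#'   matrix) and `truth` (the `counts` matrix)
#' @export
simulate_zstack <- function(counts, dim = c(96L, 96L), spot_radius = 1.5,
                            spot_intensity = 200, noise_amp = 4,
                            seed = 1L, max_tries = 200L) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            spot_intensity <= 255, noise_amp >= 0)
  n_cells <- nrow(counts); n_planes <- ncol(counts)
  mask <- .grid_mask(n_cells, dim)
  rad <- ceiling(spot_radius)
  # minimum centre separation so discs never touch, even diagonally
  min_sep2 <- (2 * spot_radius + 2)^2
  .with_seed(seed, {
    stack <- vector("list", n_planes)
    for (pl in seq_len(n_planes)) {
      img <- matrix(stats::runif(prod(dim), 0, noise_amp),
                    dim[1L], dim[2L])
      img[] <- floor(img)
      centres <- matrix(numeric(0), 0L, 2L)
      for (cell in seq_len(n_cells)) {
        n_spots <- counts[cell, pl]
        if (n_spots == 0L) next
        inside <- which(mask == cell, arr.ind = TRUE)
        # candidate centres: far enough from the cell border that the
        # whole disc (and its centroid) stays inside the cell
        ok <- inside[, 1L] > min(inside[, 1L]) + rad &
          inside[, 1L] < max(inside[, 1L]) - rad &
          inside[, 2L] > min(inside[, 2L]) + rad &
          inside[, 2L] < max(inside[, 2L]) - rad
        cand <- inside[ok, , drop = FALSE]
        if (nrow(cand) == 0L)
          stop("rejected layout: cell too small for the spot radius",
               call. = FALSE)
        for (s in seq_len(n_spots)) {
          placed <- FALSE
          for (try in seq_len(max_tries)) {
            ctr <- cand[sample.int(nrow(cand), 1L), ]
            if (nrow(centres) == 0L ||
                all((centres[, 1L] - ctr[1L])^2 +
                    (centres[, 2L] - ctr[2L])^2 > min_sep2)) {
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stop("rejected layout: could not place non-overlapping spots",
                 call. = FALSE)
          centres <- rbind(centres, ctr)
          rr <- (ctr[1L] - rad):(ctr[1L] + rad)
          cc <- (ctr[2L] - rad):(ctr[2L] + rad)
          for (r in rr) for (cl2 in cc)
            if ((r - ctr[1L])^2 + (cl2 - ctr[2L])^2 <= spot_radius^2)
              img[r, cl2] <- spot_intensity
        }
      }
      stack[[pl]] <- img
    }
    list(stack = stack, mask = mask, truth = counts)
  })
}
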