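# S0-moderated two-sided Welch test with permutation-based FDR control.
#
# The ranking statistic is the SAM-style moderated d = diff / (se + s0):
# the fudge constant s0 in the denominator de-emphasizes proteins whose
# small standard error would otherwise produce large t values at
# negligible absolute enrichment. Significance is decided by a
# permutation FDR on |d|; the reported p-value column comes from the
# unmoderated Welch test.

#' Two-sided Welch t-test for one protein
#'
#' Unequal-variance t statistic
#' `t = (mean(x) - mean(y)) / sqrt(s_x^2/n_x + s_y^2/n_y)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' Student's t distribution.
#'
#' Degenerate variance is handled explicitly: if both groups have zero
#' variance and equal means, `t = 0, p = 1`; zero variance with unequal
#' means gives the limit `t = +/-Inf, p = 0` with attribute
#' `degenerate = TRUE`.
#'
#' @param x numeric vector of bait replicate values (length >= 2)
#' @param y numeric vector of control replicate values (length >= 2)
#' @return list with elements `t`, `df`, `p`
#' @export
welch_statistic <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  diff <- mean(x) - mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (diff == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    out <- list(t = sign(diff) * Inf, df = nx + ny - 2, p = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  t <- diff / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' S0-moderated test statistic
#'
#' `d = (mean(x) - mean(y)) / (sqrt(s_x^2/n_x + s_y^2/n_y) + s0)`.
#' At `s0 = 0` this is exactly the Welch t statistic; for fixed data
#' with a nonzero difference, `|d|` decreases strictly in `s0`.
#'
#' @inheritParams welch_statistic
#' @param s0 non-negative fudge constant (default 0.1)
#' @return the moderated statistic `d`
#' @export
s0_statistic <- function(x, y, s0 = 0.1) {
  stopifnot(length(x) >= 2L, length(y) >= 2L, s0 >= 0)
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  diff <- mean(x) - mean(y)
  if (se + s0 == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / (se + s0)
}

# Row-wise group means and variances for a column subset (n-1
# denominator). X should be row-centred by the caller for precision.
.row_group <- function(X, idx) {
  n <- length(idx)
  sub <- X[, idx, drop = FALSE]
  mu <- rowMeans(sub)
  v <- (rowSums(sub * sub) - n * mu * mu) / (n - 1)
  v[v < 0] <- 0
  list(mean = mu, var = v, n = n)
}

# moderated d for all rows given bait/control column indices
.row_d <- function(X, bait_idx, ctrl_idx, s0) {
  a <- .row_group(X, bait_idx)
  b <- .row_group(X, ctrl_idx)
  se <- sqrt(a$var / a$n + b$var / b$n)
  diff <- a$mean - b$mean
  d <- diff / (se + s0)
  if (s0 == 0) {
    zero <- se == 0
    d[zero & diff == 0] <- 0
    d[zero & diff != 0] <- sign(diff[zero & diff != 0]) * Inf
  }
  d
}

# All distinct bait/control label splits of n samples with nb in the
# bait group, as a list of bait index vectors. For balanced designs a
# split and its complement give the same |d|, so the half containing
# sample 1 in the bait group is kept. The first returned split is the
# identity assignment (observed labels).
.label_splits <- function(n, nb) {
  splits <- utils::combn(n, nb, simplify = FALSE)
  if (nb * 2L == n)
    splits <- Filter(function(s) s[1L] == 1L, splits)
  identity_first <- order(!vapply(splits, function(s)
    identical(s, seq_len(nb)), logical(1L)))
  splits[identity_first]
}

#' Differential enrichment test with permutation-based FDR
#'
#' Tests every protein of one bait-vs-control contrast with the
#' S0-moderated Welch statistic and controls the FDR by label
#' permutation: for a cutoff c on `|d|`, the observed positives are
#' `R(c) = #\{|d| >= c\}`, each permutation pi of the bait/control
#' labels contributes `V_pi(c) = #\{|d_pi| >= c\}`, and
#' `FDR(c) = mean_pi V_pi(c) / max(R(c), 1)`. The significant set is the
#' largest `R(c)` with `FDR(c)` below `fdr_threshold`, with c searched
#' over the observed `|d|` order statistics (FDR is piecewise constant
#' between them) and ties at the cutoff included.
#'
#' All distinct label reassignments are enumerated when their number
#' does not exceed `n_permutations` (at quadruplicate scale 4v4 there
#' are C(8,4)/2 = 35 distinct splits, so enumeration is exhaustive);
#' otherwise `n_permutations` splits are sampled without replacement
#' under `seed`. The identity split is excluded from the null set.
#'
#' @param m an [intensity_matrix] with no missing values in the tested
#'   rows (run [impute_downshifted()] first)
#' @param design an [experiment_design]
#' @param bait,control condition labels of the contrast
#' @param s0 fudge constant of the moderated statistic (default 0.1)
#' @param fdr_threshold FDR level (default 0.05; the significant set
#'   satisfies estimated FDR strictly below this)
#' @param n_permutations maximum number of label permutations
#'   (default 250)
#' @param seed integer seed for permutation sampling (only used when
#'   sampling is needed); caller's RNG state is restored
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; `NULL` (default) enumerates exhaustively whenever
#'   possible within `n_permutations`
#' @param null_center aggregate of the permutation exceedance counts:
#'   `"mean"` (default) or `"median"`
#' @param gene_names optional named character vector mapping protein
#'   ids to gene names for the output table
#' @return data.frame of class `differential_result` with columns
#'   `protein`, `gene`, `diff` (mean bait - mean control, log2 units),
#'   `t_welch`, `df`, `p_value`, `neg_log10_p`, `d_s0`, `significant`.
#'   Attributes: `bait`, `control`, `s0`, `fdr_threshold`, `cutoff`
#'   (threshold on `|d|`; `Inf` if nothing is significant),
#'   `n_permutations_used`, `exhaustive`, `fdr_curve`.
#' @export
permutation_fdr <- function(m, design, bait, control, s0 = 0.1,
                            fdr_threshold = 0.05, n_permutations = 250L,
                            seed = NULL, exhaustive = NULL,
                            null_center = c("mean", "median"),
                            gene_names = NULL) {
  stopifnot(inherits(m, "intensity_matrix"),
            inherits(design, "experiment_design"),
            s0 >= 0, fdr_threshold > 0, fdr_threshold < 1,
            n_permutations >= 1L)
  null_center <- match.arg(null_center)
  bs <- .cond_samples(design, m, bait)
  cs <- .cond_samples(design, m, control)
  if (length(bs) < 2L || length(cs) < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  X <- unclass(m)[, c(bs, cs), drop = FALSE]
  if (anyNA(X))
    stop("matrix has missing values in the contrast's samples; impute first",
         call. = FALSE)
  nb <- length(bs); n <- ncol(X)
  Xc <- X - rowMeans(X)  # row-centred for numerical stability

  splits <- .label_splits(n, nb)
  null_splits <- splits[-1L]  # identity excluded
  if (length(null_splits) < 2L)
    stop("fewer than 2 distinct label permutations available",
         call. = FALSE)
  use_exhaustive <- if (is.null(exhaustive))
    length(null_splits) <= n_permutations else isTRUE(exhaustive)
  if (!use_exhaustive && length(null_splits) > n_permutations) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      set.seed(seed)
    }
    null_splits <- null_splits[sample.int(length(null_splits),
                                          n_permutations)]
  }

  obs <- .contrast_table(Xc, nb, s0)
  d_obs <- obs$d_s0
  abs_obs <- abs(d_obs)

  # permutation exceedance counts, evaluated at the observed |d| order
  # statistics (descending)
  cutoffs <- sort(unique(abs_obs), decreasing = TRUE)
  perm_counts <- vapply(null_splits, function(sp) {
    d_pi <- .row_d(Xc, sp, setdiff(seq_len(n), sp), s0)
    .count_ge(cutoffs, abs(d_pi))
  }, numeric(length(cutoffs)))
  perm_counts <- matrix(perm_counts, nrow = length(cutoffs))
  V <- apply(perm_counts, 1L,
             if (null_center == "mean") mean else stats::median)
  R <- .count_ge(cutoffs, abs_obs)
  fdr <- V / pmax(R, 1)
  ok <- which(fdr < fdr_threshold)
  cutoff <- if (length(ok)) cutoffs[max(ok)] else Inf
  significant <- abs_obs >= cutoff

  gene <- if (is.null(gene_names)) rep(NA_character_, nrow(X))
          else unname(gene_names[rownames(X)])
  res <- data.frame(protein = rownames(X), gene = gene,
                    diff = obs$diff, t_welch = obs$t, df = obs$df,
                    p_value = obs$p,
                    neg_log10_p = -log10(obs$p),
                    d_s0 = d_obs, significant = significant,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res,
            class = c("differential_result", "data.frame"),
            bait = bait, control = control, s0 = s0,
            fdr_threshold = fdr_threshold, cutoff = cutoff,
            n_permutations_used = length(null_splits),
            exhaustive = use_exhaustive,
            fdr_curve = data.frame(cutoff = cutoffs, R = R, V = V,
                                   fdr = fdr))
}

# #{values >= each cutoff}; cutoffs may be in any order
.count_ge <- function(cutoffs, values) {
  sv <- sort(values)
  length(sv) - findInterval(cutoffs, sv, left.open = TRUE)
}

# full per-row Welch table for the observed labels (bait columns
# first); fed the row-centred matrix so the identity permutation
# reproduces the observed d bit-identically
.contrast_table <- function(X, nb, s0) {
  a <- .row_group(X, seq_len(nb))
  b <- .row_group(X, (nb + 1L):ncol(X))
  diff <- a$mean - b$mean
  se2 <- a$var / a$n + b$var / b$n
  se <- sqrt(se2)
  t <- diff / se
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  zero <- se == 0
  t[zero & diff == 0] <- 0
  t[zero & diff != 0] <- sign(diff[zero & diff != 0]) * Inf
  df[zero] <- a$n + b$n - 2
  p <- 2 * stats::pt(-abs(t), df)
  list(diff = diff, t = t, df = df, p = p, d_s0 = diff / (se + s0))
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("differential_result: %s vs %s, %d proteins, %d significant\n",
              attr(x, "bait"), attr(x, "control"), nrow(x),
              sum(x$significant)))
  cat(sprintf("  s0 = %g, FDR < %g, %d permutations%s, |d| cutoff = %g\n",
              attr(x, "s0"), attr(x, "fdr_threshold"),
              attr(x, "n_permutations_used"),
              if (attr(x, "exhaustive")) " (exhaustive)" else "",
              attr(x, "cutoff")))
  invisible(x)
}

#' Write a differential (volcano) result table as TSV
#'
#' Columns: protein, gene, diff, t_welch, d_s0, p, neg_log10_p,
#' significant — the axes of a volcano plot plus the decision flag.
#'
#' @param x a `differential_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_differential_result <- function(x, path) {
  stopifnot(inherits(x, "differential_result"))
  out <- data.frame(protein = x$protein, gene = x$gene, diff = x$diff,
                    t_welch = x$t_welch, d_s0 = x$d_s0, p = x$p_value,
                    neg_log10_p = x$neg_log10_p,
                    significant = x$significant)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Volcano plot of a differential result
#'
#' Enrichment difference (log2) against -log10 p, significant proteins
#' highlighted. Requires ggplot2.
#'
#' @param x a `differential_result`
#' @return a ggplot object
#' @export
plot_volcano <- function(x) {
  stopifnot(inherits(x, "differential_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plot_volcano()", call. = FALSE)
  df <- as.data.frame(x)
  df$significant <- factor(df$significant, levels = c(FALSE, TRUE))
  ggplot2::ggplot(df, ggplot2::aes(x = diff, y = neg_log10_p,
                                   colour = significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change enrichment"),
                  y = expression(-log[10] ~ italic(P)),
                  colour = "significant") +
    ggplot2::theme_classic()
}
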