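# Row exclusion, log2 transform, sample-median normalization and
# minimum-valid-value filtering for AP-MS intensity matrices.

#' Construct an intensity matrix
#'
#' Protein groups x samples matrix of log2 intensities; `NA` encodes
#' missing (unquantified) entries. Infinite values are rejected.
#'
#' @param values numeric matrix with rownames (protein ids) and
#'   colnames (sample ids)
#' @return numeric matrix of class `intensity_matrix`
#' @export
intensity_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("intensity matrix needs protein rownames and sample colnames",
         call. = FALSE)
  if (any(is.infinite(values)))
    stop("intensity matrix must not contain infinities", call. = FALSE)
  structure(values, class = c("intensity_matrix", "matrix", "array"))
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Define the sample-to-condition assignment of an experiment
#'
#' Maps each sample to exactly one condition (bait cell line or the
#' control purification) and designates the control condition.
#'
#' @param condition_of named character vector: names are sample ids,
#'   values condition labels. At least two conditions are required.
#' @param control label of the control condition (e.g. the GFP-only
#'   purification); must be one of the conditions.
#' @return an object of class `experiment_design`
#' @export
experiment_design <- function(condition_of, control) {
  stopifnot(is.character(condition_of), !is.null(names(condition_of)))
  if (anyDuplicated(names(condition_of)))
    stop("duplicate sample ids in design", call. = FALSE)
  if (length(unique(condition_of)) < 2L)
    stop("design needs at least two conditions", call. = FALSE)
  if (!control %in% condition_of)
    stop(sprintf("control condition '%s' has no samples", control),
         call. = FALSE)
  structure(list(condition_of = condition_of, control = control),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  tab <- table(x$condition_of)
  cat("experiment_design:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "),
      sprintf("; control = %s\n", x$control))
  invisible(x)
}

# samples of one condition, in matrix column order
.cond_samples <- function(design, m, condition) {
  s <- names(design$condition_of)[design$condition_of == condition]
  s <- intersect(colnames(m), s)
  if (length(s) == 0L)
    stop(sprintf("condition '%s' has no samples in the matrix", condition),
         call. = FALSE)
  s
}

#' Remove contaminant, reverse and site-only protein groups
#'
#' Drops every record flagged as a known contaminant, a reverse (decoy)
#' sequence match, or identified only by a modification site. The number
#' of removed records is attached as attribute `n_removed`.
#'
#' @param table a [protein_groups] object with flags populated
#' @return the filtered [protein_groups] object
#' @export
exclude_artifacts <- function(table) {
  stopifnot(inherits(table, "protein_groups"))
  bad <- table$meta$contaminant | table$meta$reverse | table$meta$site_only
  out <- protein_groups(table$ibaq[!bad, , drop = FALSE],
                        table$meta[!bad, , drop = FALSE])
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Log2-transform raw iBAQ intensities
#'
#' @param table a [protein_groups] object, normally after
#'   [exclude_artifacts()]
#' @return an [intensity_matrix] of log2 intensities; missing stays
#'   missing
#' @export
to_log2_matrix <- function(table) {
  stopifnot(inherits(table, "protein_groups"))
  v <- table$ibaq
  if (any(v < 0, na.rm = TRUE))
    stop("negative intensity cannot be log2-transformed", call. = FALSE)
  intensity_matrix(log2(v))
}

#' Sample-median normalization
#'
#' Corrects per-sample technical variation by subtracting a
#' sample-specific normalization factor: for sample j,
#' `median_j` is the median log2 intensity over that sample's quantified
#' protein groups, and `NF_j = median_j - median(median_1..median_M)`.
#' Each present entry becomes `value - NF_j`, so after normalization all
#' sample medians equal the grand median. Medians are computed over
#' present values only; the median of an even count is the midpoint of
#' the two central order statistics.
#'
#' @param m an [intensity_matrix]; every sample must have at least one
#'   present value
#' @return list with `matrix` (normalized [intensity_matrix]),
#'   `factors` (data.frame: sample, median, nf) and `grand_median`
#' @export
normalize_median <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  n_present <- colSums(!is.na(m))
  if (any(n_present == 0L))
    stop("sample(s) with zero present values: ",
         paste(colnames(m)[n_present == 0L], collapse = ", "),
         call. = FALSE)
  med <- apply(m, 2L, stats::median, na.rm = TRUE)
  grand <- stats::median(med)
  nf <- med - grand
  out <- intensity_matrix(sweep(unclass(m), 2L, nf, `-`))
  list(matrix = out,
       factors = data.frame(sample = colnames(m), median = unname(med),
                            nf = unname(nf), stringsAsFactors = FALSE),
       grand_median = grand)
}

# present counts per protein within each condition
.cond_counts <- function(m, design, conditions) {
  counts <- vapply(conditions, function(cc) {
    s <- .cond_samples(design, m, cc)
    rowSums(!is.na(m[, s, drop = FALSE]))
  }, numeric(nrow(m)))
  matrix(counts, nrow = nrow(m),
         dimnames = list(rownames(m), conditions))
}

#' Filter proteins by minimum valid values in any one condition
#'
#' Keeps the protein groups quantified in at least `k` replicates of at
#' least one condition; all others are removed. The removed ids are
#' attached as attribute `removed`.
#'
#' @param m an [intensity_matrix]
#' @param design an [experiment_design]
#' @param k minimum number of present replicate values (default 3)
#' @return the filtered [intensity_matrix]
#' @export
filter_min_valid <- function(m, design, k = 3L) {
  stopifnot(inherits(m, "intensity_matrix"),
            inherits(design, "experiment_design"), k >= 1L)
  conds <- unique(design$condition_of)
  counts <- .cond_counts(m, design, conds)
  keep <- apply(counts >= k, 1L, any)
  out <- intensity_matrix(unclass(m)[keep, , drop = FALSE])
  attr(out, "removed") <- rownames(m)[!keep]
  out
}

#' Filter proteins for one bait-vs-control contrast
#'
#' Before testing a bait against the control purification, keeps the
#' protein groups quantified in at least `k` replicates of the bait
#' condition. The control may be sparsely observed: absence in the
#' control purification is itself the interaction signal, so no control
#' count is required.
#'
#' @param m an [intensity_matrix]
#' @param design an [experiment_design]
#' @param bait bait condition label
#' @param control control condition label; must differ from `bait`
#' @param k minimum present values in the bait condition (default 3)
#' @return the filtered [intensity_matrix]
#' @export
filter_pairwise_valid <- function(m, design, bait, control, k = 3L) {
  stopifnot(inherits(m, "intensity_matrix"),
            inherits(design, "experiment_design"))
  if (identical(bait, control))
    stop("bait and control must differ", call. = FALSE)
  if (!all(c(bait, control) %in% design$condition_of))
    stop("unknown condition in contrast", call. = FALSE)
  bs <- .cond_samples(design, m, bait)
  keep <- rowSums(!is.na(m[, bs, drop = FALSE])) >= k
  out <- intensity_matrix(unclass(m)[keep, , drop = FALSE])
  attr(out, "removed") <- rownames(m)[!keep]
  out
}

#' Write normalization factors as TSV
#' @param nf the `factors` data.frame from [normalize_median()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_normalization_factors <- function(nf, path) {
  utils::write.table(nf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
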