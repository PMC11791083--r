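# Missing-value imputation from a down-shifted, width-shrunk normal
# distribution, fit to each replicate's observed values. This models the
# left-censored (MNAR) missingness of label-free proteomics: a protein
# missing from a replicate is most plausibly below that replicate's
# detection limit, so replacement values are drawn from the low tail of
# the observed distribution.

#' Impute missing values from a down-shifted normal distribution
#'
#' For each sample (replicate) j with observed mean `mu_j` and sample
#' standard deviation `sd_j` (n-1 denominator), every missing entry is
#' replaced by an independent draw from
#' `Normal(mu_j - downshift * sd_j, (width * sd_j)^2)`.
#' Present values are never changed. Draws are taken column by column in
#' a fixed column-major cell order from a single seeded generator, so
#' identical seed and input give bit-identical output regardless of
#' storage layout.
#'
#' @param m an [intensity_matrix]; every sample needs >= 2 present
#'   values so the standard deviation is defined
#' @param width width of the imputation distribution as a multiple of
#'   the observed s.d. (default 0.3)
#' @param downshift left shift of its centre in observed s.d. units
#'   (default 1.8, applied as `mu - 1.8 * sd`)
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   state. When a seed is given the caller's RNG state is restored on
#'   exit.
#' @param per_column estimate `mu` and `sd` per replicate (default,
#'   matching per-replicate imputation); `FALSE` pools all observed
#'   values of the matrix
#' @return list with `matrix` (complete [intensity_matrix]) and
#'   `record` (data.frame: protein, sample, imputed_value — one row per
#'   imputed cell, column-major order)
#' @export
impute_downshifted <- function(m, width = 0.3, downshift = 1.8,
                               seed = NULL, per_column = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"), width > 0, downshift >= 0)
  n_present <- colSums(!is.na(m))
  if (any(n_present < 2L))
    stop("sample(s) with fewer than 2 present values: ",
         paste(colnames(m)[n_present < 2L], collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  vals <- unclass(m)
  if (!per_column) {
    mu_all <- mean(vals, na.rm = TRUE)
    sd_all <- stats::sd(as.vector(vals), na.rm = TRUE)
  }
  rec <- vector("list", ncol(vals))
  for (j in seq_len(ncol(vals))) {
    miss <- which(is.na(vals[, j]))
    if (length(miss) == 0L) { rec[[j]] <- NULL; next }
    if (per_column) {
      mu <- mean(vals[, j], na.rm = TRUE)
      s <- stats::sd(vals[, j], na.rm = TRUE)
    } else {
      mu <- mu_all
      s <- sd_all
    }
    draws <- stats::rnorm(length(miss), mean = mu - downshift * s,
                          sd = width * s)
    vals[miss, j] <- draws
    rec[[j]] <- data.frame(protein = rownames(vals)[miss],
                           sample = colnames(vals)[j],
                           imputed_value = draws,
                           stringsAsFactors = FALSE)
  }
  record <- do.call(rbind, c(rec, list(
    data.frame(protein = character(), sample = character(),
               imputed_value = numeric(), stringsAsFactors = FALSE))))
  rownames(record) <- NULL
  list(matrix = intensity_matrix(vals), record = record)
}

#' Write an imputation record as TSV
#' @param record the `record` data.frame from [impute_downshifted()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_imputation_record <- function(record, path) {
  utils::write.table(record, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
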