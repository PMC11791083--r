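# Readers and writers for the MaxQuant proteinGroups dialect and for
# reporter-screen tables. All text I/O is UTF-8, tab-separated, decimal
# point only.

#' Construct a protein-groups table
#'
#' The central input container for AP-MS quantification: one row per
#' protein group with its identifier, gene name, artifact flags and raw
#' iBAQ intensities per sample. Zero and absent intensities are both
#' stored as `NA` (the MaxQuant convention writes unquantified iBAQ
#' cells as 0; downstream log2 transformation requires positivity).
#'
#' @param ibaq numeric matrix, protein groups x samples; raw (linear
#'   scale) intensities, `NA` for missing. Row order defines record
#'   order; column names are sample identifiers.
#' @param meta data.frame with columns `group_id` (unique, taken from
#'   "Majority protein IDs"), `gene_name`, and logical flags
#'   `contaminant`, `reverse`, `site_only`.
#' @return An object of class `protein_groups`.
#' @export
protein_groups <- function(ibaq, meta) {
  stopifnot(is.matrix(ibaq), is.data.frame(meta),
            nrow(ibaq) == nrow(meta),
            all(c("group_id", "gene_name", "contaminant", "reverse",
                  "site_only") %in% names(meta)))
  if (anyDuplicated(meta$group_id))
    stop("duplicate group_id in protein-groups table", call. = FALSE)
  if (is.null(colnames(ibaq)) || anyDuplicated(colnames(ibaq)))
    stop("ibaq matrix needs unique sample column names", call. = FALSE)
  if (any(ibaq < 0, na.rm = TRUE))
    stop("raw intensities must be >= 0", call. = FALSE)
  ibaq[!is.na(ibaq) & ibaq == 0] <- NA_real_
  rownames(ibaq) <- meta$group_id
  structure(list(ibaq = ibaq, meta = meta), class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("protein_groups: %d protein groups x %d samples\n",
              nrow(x$ibaq), ncol(x$ibaq)))
  cat(sprintf("  flagged: %d contaminant, %d reverse, %d site-only\n",
              sum(x$meta$contaminant), sum(x$meta$reverse),
              sum(x$meta$site_only)))
  cat(sprintf("  missing values: %.1f%%\n",
              100 * mean(is.na(x$ibaq))))
  invisible(x)
}

#' @export
dim.protein_groups <- function(x) dim(x$ibaq)

#' Sample identifiers of a protein-groups table
#' @param x a `protein_groups` object
#' @return character vector of sample ids
#' @export
sample_ids <- function(x) colnames(x$ibaq)

# MaxQuant encodes boolean columns as "+" (true) / "" (false); anything
# other than "+" is false.
.parse_flag <- function(v) {
  if (is.null(v)) return(rep(FALSE, 0L))
  trimws(as.character(v)) == "+"
}

#' Read a MaxQuant-dialect proteinGroups table
#'
#' Parses a tab-separated proteinGroups.txt-style file. Per-sample
#' quantification is taken from columns whose name starts with
#' `ibaq_prefix`; the sample identifier is the column name with the
#' prefix and surrounding whitespace stripped. Artifact flags are read
#' from the "Potential contaminant", "Reverse" and "Only identified by
#' site" columns ("+" convention). Intensities of 0 or empty cells are
#' recorded as missing.
#'
#' @param path path to a tab-separated file with a header row.
#' @param ibaq_prefix prefix identifying per-sample intensity columns
#'   (default `"iBAQ "`). The bare aggregate column `"iBAQ"` (no
#'   suffix) is never treated as a sample.
#' @return a [protein_groups] object.
#' @export
read_protein_groups <- function(path, ibaq_prefix = "iBAQ ") {
  raw <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           colClasses = "character",
                           blank.lines.skip = FALSE,
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2L || nrow(raw) == 0L)
    stop("not a proteinGroups table: need a header row and data rows",
         call. = FALSE)
  ib_cols <- names(raw)[startsWith(names(raw), ibaq_prefix) &
                          nchar(names(raw)) > nchar(ibaq_prefix)]
  if (length(ib_cols) == 0L)
    stop(sprintf("no columns start with ibaq_prefix '%s'", ibaq_prefix),
         call. = FALSE)
  samples <- trimws(substring(ib_cols, nchar(ibaq_prefix) + 1L))
  ibaq <- vapply(ib_cols, function(cn) {
    v <- raw[[cn]]
    v[trimws(v) == ""] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(nrow(raw)))
  ibaq <- matrix(ibaq, nrow = nrow(raw),
                 dimnames = list(NULL, samples))
  col_or_empty <- function(nm)
    if (nm %in% names(raw)) raw[[nm]] else rep("", nrow(raw))
  meta <- data.frame(
    group_id    = vapply(strsplit(col_or_empty("Majority protein IDs"),
                                  ";", fixed = TRUE),
                         function(p) trimws(p[1L]), character(1L)),
    gene_name   = trimws(col_or_empty("Gene names")),
    contaminant = .parse_flag(col_or_empty("Potential contaminant")),
    reverse     = .parse_flag(col_or_empty("Reverse")),
    site_only   = .parse_flag(col_or_empty("Only identified by site")),
    stringsAsFactors = FALSE
  )
  if (any(meta$group_id == "" | is.na(meta$group_id)))
    stop("empty 'Majority protein IDs' entry", call. = FALSE)
  if (anyDuplicated(meta$group_id))
    stop("duplicate group_id in proteinGroups file", call. = FALSE)
  protein_groups(ibaq, meta)
}

# doubles -> shortest decimal string that parses back to the identical
# double (15 digits when sufficient, else 16 or 17)
.num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("0")
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1L))
}

#' Write a protein-groups table in the canonical dialect
#'
#' Emits the column layout [read_protein_groups()] consumes; missing
#' intensities are written as 0. Reading the written file back yields an
#' identical object, and rewriting a file produced by this writer is
#' byte-identical.
#'
#' @param x a [protein_groups] object
#' @param path output path
#' @param ibaq_prefix prefix for the per-sample intensity columns
#' @return `path`, invisibly
#' @export
write_protein_groups <- function(x, path, ibaq_prefix = "iBAQ ") {
  stopifnot(inherits(x, "protein_groups"))
  flag <- function(b) ifelse(b, "+", "")
  df <- data.frame(
    `Majority protein IDs` = x$meta$group_id,
    `Gene names` = x$meta$gene_name,
    `Potential contaminant` = flag(x$meta$contaminant),
    Reverse = flag(x$meta$reverse),
    `Only identified by site` = flag(x$meta$site_only),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(x$ibaq)))
    df[[paste0(ibaq_prefix, colnames(x$ibaq)[j])]] <- .num_chr(x$ibaq[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a reporter-screen table
#'
#' Long-format reporter measurements from an RNAi screen: one row per
#' (cell line, shRNA, stimulus, replicate) with a non-negative activity
#' in reporter units.
#'
#' @param df data.frame with columns `cell_line`, `shrna`,
#'   `target_gene`, `stimulus`, `replicate`, `activity`.
#' @param control_shrna label of the non-targeting control shRNA;
#'   must appear in `df$shrna`.
#' @return data.frame of class `screen_table` with attribute
#'   `control_shrna`.
#' @export
screen_table <- function(df, control_shrna = "shCtrl") {
  need <- c("cell_line", "shrna", "target_gene", "stimulus",
            "replicate", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("screen table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$replicate <- as.integer(df$replicate)
  df$activity <- as.numeric(df$activity)
  if (any(is.na(df$activity)) || any(df$activity < 0))
    stop("activity must be non-negative and numeric", call. = FALSE)
  if (!control_shrna %in% df$shrna)
    stop(sprintf("control shRNA '%s' not present in table", control_shrna),
         call. = FALSE)
  structure(df[, need], class = c("screen_table", "data.frame"),
            control_shrna = control_shrna)
}

#' Read a reporter-screen table from TSV
#' @param path tab-separated file with columns `cell_line`, `shrna`,
#'   `target_gene`, `stimulus`, `replicate`, `activity`
#' @param control_shrna control shRNA label (default `"shCtrl"`)
#' @return a [screen_table]
#' @export
read_screen_table <- function(path, control_shrna = "shCtrl") {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  screen_table(df, control_shrna = control_shrna)
}

#' Write a reporter-screen table as TSV
#' @param x a [screen_table]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_screen_table <- function(x, path) {
  stopifnot(inherits(x, "screen_table"))
  df <- as.data.frame(x)
  df$activity <- .num_chr(df$activity)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
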