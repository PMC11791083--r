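# Interactor sets per bait and their overlap decomposition.
# Protein identity is the protein-group identifier (first entry of
# "Majority protein IDs"), never the gene name: gene names may be empty
# or duplicated across groups.

#' Extract the interactor set of a bait
#'
#' An interactor is a protein that is significant in the bait-vs-control
#' contrast AND enriched toward the bait (`diff > 0`). Significant
#' depleted proteins are reported separately in the `depleted` attribute
#' but never count as interactors.
#'
#' @param r a `differential_result` from [permutation_fdr()]
#' @return an object of class `interactor_set`: list with `bait` and
#'   `members` (character vector of protein-group ids)
#' @export
extract_interactors <- function(r) {
  stopifnot(inherits(r, "differential_result"))
  members <- r$protein[r$significant & r$diff > 0]
  structure(list(bait = attr(r, "bait"), members = members),
            class = "interactor_set",
            depleted = r$protein[r$significant & r$diff < 0])
}

#' @export
print.interactor_set <- function(x, ...) {
  cat(sprintf("interactor_set: %d interactors of %s\n",
              length(x$members), x$bait))
  invisible(x)
}

#' Overlap decomposition of two interactor sets
#'
#' Exact set arithmetic on protein-group identifiers: counts of each
#' set, their intersection, and the shared percentage from each side
#' (`pct_a_shared` = 100 * n_shared / n_a; 0 when `n_a` is 0).
#' Percentages are kept at full precision internally and rounded to one
#' decimal only when printed.
#'
#' @param a,b [interactor_set] objects
#' @return an object of class `overlap_summary`: list with `bait_a`,
#'   `bait_b`, `n_a`, `n_b`, `n_shared`, `pct_a_shared`,
#'   `pct_b_shared`, `shared`, `unique_a`, `unique_b`
#' @export
overlap <- function(a, b) {
  stopifnot(inherits(a, "interactor_set"), inherits(b, "interactor_set"))
  shared <- intersect(a$members, b$members)
  n_a <- length(a$members); n_b <- length(b$members)
  n_shared <- length(shared)
  structure(list(
    bait_a = a$bait, bait_b = b$bait,
    n_a = n_a, n_b = n_b, n_shared = n_shared,
    pct_a_shared = if (n_a == 0L) 0 else 100 * n_shared / n_a,
    pct_b_shared = if (n_b == 0L) 0 else 100 * n_shared / n_b,
    shared = shared,
    unique_a = setdiff(a$members, b$members),
    unique_b = setdiff(b$members, a$members)
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap_summary: %s (n=%d) vs %s (n=%d)\n",
              x$bait_a, x$n_a, x$bait_b, x$n_b))
  cat(sprintf("  shared: %d (%.1f%% of %s, %.1f%% of %s)\n",
              x$n_shared, x$pct_a_shared, x$bait_a,
              x$pct_b_shared, x$bait_b))
  invisible(x)
}

#' Write an interactor set as TSV
#' @param x an [interactor_set]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_interactor_set <- function(x, path) {
  stopifnot(inherits(x, "interactor_set"))
  utils::write.table(
    data.frame(bait = x$bait, protein = x$members),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an overlap summary as TSV
#' @param x an [overlap_summary]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_overlap_summary <- function(x, path) {
  stopifnot(inherits(x, "overlap_summary"))
  df <- data.frame(bait_a = x$bait_a, bait_b = x$bait_b,
                   n_a = x$n_a, n_b = x$n_b, n_shared = x$n_shared,
                   pct_a_shared = x$pct_a_shared,
                   pct_b_shared = x$pct_b_shared)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Bait-prey edge list from a differential result
#'
#' Three-column table (bait, prey, diff) restricted to the bait's
#' interactors, suitable for import into network tools.
#'
#' @param r a `differential_result`
#' @return data.frame with columns `bait`, `prey`, `diff`
#' @export
edge_list <- function(r) {
  stopifnot(inherits(r, "differential_result"))
  keep <- r$significant & r$diff > 0
  data.frame(bait = attr(r, "bait"), prey = r$protein[keep],
             diff = r$diff[keep], stringsAsFactors = FALSE)
}
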