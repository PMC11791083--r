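# RNAi reporter-screen hit calling. A target gene is a hit when enough
# of its shRNAs reduce the stimulated reporter activity, relative to the
# non-targeting control shRNA, by at least the configured fraction under
# EVERY required stimulus (conjunctive over shRNAs and stimuli).

#' Hit-calling configuration for an RNAi reporter screen
#'
#' @param reduction_threshold minimum fractional reduction of reporter
#'   activity relative to the control shRNA (default 0.5: "reduced by
#'   at least 50%", i.e. relative activity <= 0.5 passes — the boundary
#'   is inclusive)
#' @param required_stimuli stimuli that must all show the reduction
#'   (default the RIG-I ligand `"5ppp-dsRNA"` and the cGAS ligand
#'   `"pDNA"`)
#' @param min_shrnas number of independent shRNAs per gene that must
#'   pass (default 2)
#' @param control_shrna label of the non-targeting control shRNA
#' @return an object of class `hit_call_config`
#' @export
hit_call_config <- function(reduction_threshold = 0.5,
                            required_stimuli = c("5ppp-dsRNA", "pDNA"),
                            min_shrnas = 2L,
                            control_shrna = "shCtrl") {
  stopifnot(reduction_threshold > 0, reduction_threshold < 1,
            min_shrnas >= 1L, length(required_stimuli) >= 1L)
  structure(list(reduction_threshold = reduction_threshold,
                 required_stimuli = required_stimuli,
                 min_shrnas = as.integer(min_shrnas),
                 control_shrna = control_shrna),
            class = "hit_call_config")
}

#' Relative reporter activity per shRNA and stimulus
#'
#' For each target shRNA s and stimulus,
#' `rel = mean(activity of s) / mean(activity of control shRNA)`, means
#' over replicates. Optionally the mean non-stimulated background
#' activity of each shRNA is subtracted from both numerator and
#' denominator first.
#'
#' @param t a [screen_table]
#' @param cfg a [hit_call_config]; its `control_shrna` overrides the
#'   table's attribute
#' @param subtract_background subtract each shRNA's mean activity under
#'   `background_stimulus` before ratioing (default `FALSE`)
#' @param background_stimulus stimulus label of the non-stimulated
#'   condition (default `"ctrl"`)
#' @return data.frame of class `hit_table` with columns `target_gene`,
#'   `shrna`, `stimulus`, `rel`
#' @export
relative_activity <- function(t, cfg = hit_call_config(),
                              subtract_background = FALSE,
                              background_stimulus = "ctrl") {
  stopifnot(inherits(t, "screen_table"), inherits(cfg, "hit_call_config"))
  ctrl <- cfg$control_shrna
  if (!ctrl %in% t$shrna)
    stop(sprintf("control shRNA '%s' not in table", ctrl), call. = FALSE)
  df <- as.data.frame(t)
  bg <- function(sh) {
    if (!subtract_background) return(0)
    v <- df$activity[df$shrna == sh & df$stimulus == background_stimulus]
    if (length(v) == 0L) 0 else mean(v)
  }
  stimuli <- setdiff(unique(df$stimulus),
                     if (subtract_background) background_stimulus else NULL)
  targets <- df[df$shrna != ctrl, c("target_gene", "shrna")]
  targets <- unique(targets)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    sh <- targets$shrna[i]
    vapply(stimuli, function(stim) {
      num <- df$activity[df$shrna == sh & df$stimulus == stim]
      den <- df$activity[df$shrna == ctrl & df$stimulus == stim]
      if (length(num) == 0L || length(den) == 0L) return(NA_real_)
      den_m <- mean(den) - bg(ctrl)
      if (den_m <= 0)
        stop(sprintf("control mean activity is not positive for stimulus '%s'",
                     stim), call. = FALSE)
      (mean(num) - bg(sh)) / den_m
    }, numeric(1L))
  })
  out <- data.frame(
    target_gene = rep(targets$target_gene, each = length(stimuli)),
    shrna = rep(targets$shrna, each = length(stimuli)),
    stimulus = rep(stimuli, times = nrow(targets)),
    rel = unlist(rows),
    stringsAsFactors = FALSE)
  structure(out, class = c("hit_table", "data.frame"), config = cfg)
}

#' Call screen hits from relative activities
#'
#' A gene is a hit when at least `min_shrnas` of its shRNAs have
#' `rel <= 1 - reduction_threshold` for every required stimulus. Genes
#' with fewer than `min_shrnas` distinct shRNAs are not evaluable
#' (`hit = NA`).
#'
#' @param h a `hit_table` from [relative_activity()]
#' @param cfg a [hit_call_config]
#' @return data.frame of class `hit_calls`: `target_gene`, `n_shrnas`,
#'   `n_passing`, `evaluable`, `hit`
#' @export
call_hits <- function(h, cfg = hit_call_config()) {
  stopifnot(inherits(h, "hit_table"), inherits(cfg, "hit_call_config"))
  lim <- 1 - cfg$reduction_threshold
  need <- cfg$required_stimuli
  miss <- setdiff(need, unique(h$stimulus))
  if (length(miss))
    stop("required stimulus missing from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  genes <- unique(h$target_gene)
  res <- lapply(genes, function(g) {
    hg <- h[h$target_gene == g & h$stimulus %in% need, ]
    shrnas <- unique(hg$shrna)
    passes <- vapply(shrnas, function(sh) {
      r <- hg$rel[hg$shrna == sh]
      length(r) == length(need) && all(!is.na(r)) && all(r <= lim)
    }, logical(1L))
    evaluable <- length(shrnas) >= cfg$min_shrnas
    data.frame(target_gene = g, n_shrnas = length(shrnas),
               n_passing = sum(passes),
               evaluable = evaluable,
               hit = if (evaluable) sum(passes) >= cfg$min_shrnas else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("hit_calls", "data.frame"), config = cfg)
}

#' Screen hits as a character vector
#' @param calls a `hit_calls` table
#' @return target genes with `hit == TRUE`
#' @export
screen_hits <- function(calls) {
  stopifnot(inherits(calls, "hit_calls"))
  calls$target_gene[!is.na(calls$hit) & calls$hit]
}

#' Write a hit report as TSV
#'
#' Per-shRNA relative activities in wide form (one column per required
#' stimulus) joined with the per-gene hit flag.
#'
#' @param h a `hit_table`
#' @param calls the matching `hit_calls`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hit_report <- function(h, calls, path) {
  wide <- stats::reshape(as.data.frame(h), idvar = c("target_gene", "shrna"),
                         timevar = "stimulus", direction = "wide")
  names(wide) <- sub("^rel\\.", "rel_", names(wide))
  out <- merge(wide, as.data.frame(calls)[, c("target_gene", "hit")],
               by = "target_gene", sort = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
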