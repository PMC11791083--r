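# Proximity-ligation-assay (PLA) scoring on confocal z-stacks:
# fixed-threshold binarization, connected-component particle detection
# with a size filter, assignment of particles to segmented cells, and
# per-cell scores summed over planes. Counting is per 2-D plane (no 3-D
# merging): the score is the total particle count over all planes of
# the stack, so a punctum spanning planes contributes once per plane.

#' PLA particle-detection parameters
#'
#' Mirrors the ImageJ "Analyze Particles" workflow: binarize by an
#' intensity window, label connected components, and discard components
#' smaller than `min_area`.
#'
#' @param threshold_low,threshold_high inclusive intensity window on the
#'   8-bit scale (defaults 6 and 255; a more stringent 10-255 window is
#'   common for brighter backgrounds)
#' @param min_area minimum particle area in pixels, inclusive
#'   (default 5; 10 for the stringent setting)
#' @param connectivity pixel adjacency: 8 (default, the ImageJ
#'   "Analyze Particles" convention — diagonals connect) or 4
#' @return an object of class `pla_params`
#' @export
pla_params <- function(threshold_low = 6L, threshold_high = 255L,
                       min_area = 5L, connectivity = 8L) {
  stopifnot(threshold_low >= 0, threshold_low <= threshold_high,
            threshold_high <= 255, min_area >= 1,
            connectivity %in% c(4L, 8L))
  structure(list(threshold_low = as.integer(threshold_low),
                 threshold_high = as.integer(threshold_high),
                 min_area = as.integer(min_area),
                 connectivity = as.integer(connectivity)),
            class = "pla_params")
}

#' Label connected components of a binary image
#'
#' Iterative minimum-label propagation: every foreground pixel starts
#' with a unique label, and each sweep replaces a pixel's label by the
#' minimum over itself and its (4- or 8-) neighbours until a fixed
#' point; labels are then renumbered 1..n in raster order. Deterministic
#' and exact for any image.
#'
#' @param bw logical (or 0/1) matrix; `TRUE`/nonzero is foreground
#' @param connectivity 4 or 8
#' @return integer matrix of the same shape; 0 background, components
#'   numbered from 1
#' @export
label_components <- function(bw, connectivity = 8L) {
  stopifnot(is.matrix(bw), connectivity %in% c(4L, 8L))
  fg <- bw != 0
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  if (!any(fg)) return(lab)
  lab[fg] <- seq_len(sum(fg))
  # neighbour shifts (row offset, col offset)
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(.Machine$integer.max, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  big <- .Machine$integer.max
  cur <- lab
  cur[!fg] <- big
  repeat {
    nxt <- cur
    for (s in shifts) {
      nb <- shift_mat(cur, s[1L], s[2L])
      nxt <- pmin(nxt, nb)
    }
    nxt[!fg] <- big
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  labels <- cur
  labels[!fg] <- 0L
  # renumber components 1..n in raster (column-major) order of their
  # smallest original label
  ids <- sort(unique(labels[fg]))
  labels[fg] <- match(labels[fg], ids)
  matrix(as.integer(labels), nr, nc)
}

# binarize + label + size filter; returns list(labels, areas, keep_ids)
.detect_particles <- function(plane, p) {
  bw <- plane >= p$threshold_low & plane <= p$threshold_high
  labels <- label_components(bw, p$connectivity)
  if (max(labels) == 0L)
    return(list(labels = labels, ids = integer(0),
                centroids = matrix(numeric(0), 0L, 2L)))
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= p$min_area)
  if (length(keep) == 0L)
    return(list(labels = labels, ids = integer(0),
                centroids = matrix(numeric(0), 0L, 2L)))
  idx <- which(labels > 0L & matrix(labels %in% keep, nrow(labels)))
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  ll <- labels[idx]
  cen_r <- vapply(split(rr, ll), mean, numeric(1L))
  cen_c <- vapply(split(cc, ll), mean, numeric(1L))
  list(labels = labels, ids = as.integer(names(cen_r)),
       centroids = cbind(row = cen_r, col = cen_c))
}

#' Count size-filtered particles per cell in one image plane
#'
#' Binarizes the plane by the intensity window, labels connected
#' components, discards those below `min_area` pixels, and assigns each
#' remaining particle to the cell whose mask value lies under the
#' particle's centroid pixel (rounded to the nearest pixel); particles
#' whose centroid falls on background are discarded.
#'
#' @param plane numeric matrix, intensities on the 8-bit scale
#' @param mask integer matrix of the same shape: 0 background, k > 0 is
#'   cell k
#' @param p a [pla_params]
#' @return named integer vector of particle counts, one entry per cell
#'   id present in the mask (cells without particles count 0)
#' @export
count_particles_plane <- function(plane, mask, p = pla_params()) {
  stopifnot(is.matrix(plane), is.matrix(mask),
            all(dim(plane) == dim(mask)), inherits(p, "pla_params"))
  cells <- sort(unique(mask[mask > 0L]))
  counts <- stats::setNames(integer(length(cells)), cells)
  if (length(cells) == 0L) {
    warning("cell mask contains no cells", call. = FALSE)
    return(counts)
  }
  det <- .detect_particles(plane, p)
  if (length(det$ids) == 0L) return(counts)
  cr <- pmin(pmax(round(det$centroids[, "row"]), 1L), nrow(mask))
  cc <- pmin(pmax(round(det$centroids[, "col"]), 1L), ncol(mask))
  owner <- mask[cbind(cr, cc)]
  tab <- table(owner[owner > 0L])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' PLA score per cell over a z-stack
#'
#' Runs [count_particles_plane()] on every plane and sums counts per
#' cell: the total particle count over all z planes is the PLA score of
#' a cell, a proportional measure of in-situ interaction events.
#'
#' @param stack list of numeric matrices (the z planes), all of the
#'   same shape
#' @param mask integer cell-label matrix matching the plane shape
#' @param p a [pla_params]
#' @return data.frame of class `pla_score_table` with columns `cell`,
#'   `plane`, `count`; the per-cell totals (the PLA scores) are in
#'   attribute `scores` and via [pla_scores()]
#' @export
pla_score <- function(stack, mask, p = pla_params()) {
  stopifnot(is.list(stack), length(stack) >= 1L)
  dims <- lapply(stack, dim)
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]])))
    stop("all z planes must have the same shape", call. = FALSE)
  if (!identical(dims[[1L]], dim(mask)))
    stop("mask shape must match the planes", call. = FALSE)
  per_plane <- lapply(stack, count_particles_plane, mask = mask, p = p)
  cells <- names(per_plane[[1L]])
  tab <- data.frame(
    cell = rep(as.integer(cells), times = length(stack)),
    plane = rep(seq_along(stack), each = length(cells)),
    count = as.integer(unlist(per_plane)),
    stringsAsFactors = FALSE)
  scores <- stats::setNames(
    as.integer(tapply(tab$count, tab$cell, sum)[cells]), cells)
  structure(tab, class = c("pla_score_table", "data.frame"),
            scores = scores, params = p)
}

#' Per-cell PLA scores of a score table
#' @param x a `pla_score_table`
#' @return named integer vector: total particle count per cell
#' @export
pla_scores <- function(x) {
  stopifnot(inherits(x, "pla_score_table"))
  attr(x, "scores")
}

#' Write a PLA score table as TSV
#'
#' Long form (cell, plane, count, total), the per-cell `total` repeated
#' on each of its plane rows.
#'
#' @param x a `pla_score_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pla_scores <- function(x, path) {
  stopifnot(inherits(x, "pla_score_table"))
  sc <- pla_scores(x)
  out <- as.data.frame(x)
  out$total <- as.integer(sc[as.character(out$cell)])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
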