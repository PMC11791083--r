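# fixture builders and independent oracles shared across tests

# hand-write a MaxQuant-dialect TSV, independent of the package writer
write_raw_pg_tsv <- function(path, ids, genes, contaminant, reverse,
                             site_only, ibaq) {
  header <- c("Majority protein IDs", "Gene names",
              "Potential contaminant", "Reverse",
              "Only identified by site",
              paste0("iBAQ ", colnames(ibaq)))
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], genes[i], contaminant[i], reverse[i], site_only[i],
            ibaq[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
}

# small complete protein_groups object
toy_pg <- function(values, samples = paste0("S", seq_len(ncol(values))),
                   ids = sprintf("P%02d", seq_len(nrow(values)))) {
  colnames(values) <- samples
  protein_groups(values, data.frame(
    group_id = ids, gene_name = toupper(ids),
    contaminant = FALSE, reverse = FALSE, site_only = FALSE,
    stringsAsFactors = FALSE))
}

toy_matrix <- function(values,
                       samples = paste0("S", seq_len(ncol(values))),
                       ids = sprintf("P%02d", seq_len(nrow(values)))) {
  dimnames(values) <- list(ids, samples)
  intensity_matrix(values)
}

toy_design <- function(conditions, n_rep) {
  cond <- rep(conditions, each = n_rep)
  names(cond) <- paste(cond, rep(seq_len(n_rep), length(conditions)),
                       sep = "_")
  experiment_design(cond, conditions[length(conditions)])
}

# brute-force flood-fill connected-component labelling (queue-based),
# the independent oracle for label_components()
flood_fill_label <- function(bw, connectivity = 8L) {
  fg <- bw != 0
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4L)
    cbind(c(1L, -1L, 0L, 0L), c(0L, 0L, 1L, -1L))
  else
    cbind(c(1L, -1L, 0L, 0L, 1L, 1L, -1L, -1L),
          c(0L, 0L, 1L, -1L, 1L, -1L, 1L, -1L))
  nextlab <- 0L
  for (start in which(fg)) {
    if (lab[start] > 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      px <- queue[1L]; queue <- queue[-1L]
      r <- ((px - 1L) %% nr) + 1L
      cc <- ((px - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(nb))) {
        r2 <- r + nb[k, 1L]; c2 <- cc + nb[k, 2L]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            fg[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nextlab
          queue <- c(queue, (c2 - 1L) * nr + r2)
        }
      }
    }
  }
  lab
}

# number of size-filtered components per labelling (any labelling)
component_count <- function(lab, min_area = 1L) {
  if (max(lab) == 0L) return(0L)
  sum(tabulate(lab[lab > 0L]) >= min_area)
}
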