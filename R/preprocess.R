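# Feature-table preprocessing: low-count filtering, organelle removal,
# rarefaction to a common depth, relative abundance, rank aggregation.

#' Remove low-count features
#'
#' Drops features whose total count across samples is below `min_total`
#' ("less than ten counts" by default, so a total of exactly 10 is kept).
#'
#' @param table count matrix (samples x features).
#' @param min_total minimum feature total to keep (default 10).
#' @return filtered count matrix.
#' @export
filter_low_count <- function(table, min_total = 10) {
  validate_count_table(table)
  keep <- colSums(table) >= min_total
  if (!any(keep)) warning("all features removed by the low-count filter")
  table[, keep, drop = FALSE]
}

#' Remove mitochondrial and chloroplast features
#'
#' Features whose lineage contains "mitochondria" or "chloroplast" at any
#' rank (case-insensitive) are removed. Features without a lineage are
#' retained with a warning.
#'
#' @param table count matrix.
#' @param tax taxonomy data.frame ([read_taxonomy()] layout).
#' @return filtered count matrix.
#' @export
remove_organelles <- function(table, tax) {
  validate_count_table(table)
  idx <- match(colnames(table), tax$feature_id)
  if (any(is.na(idx)))
    warning("features without lineage retained: ",
            paste(colnames(table)[is.na(idx)], collapse = ", "))
  lin <- tax[idx, RANKS, drop = FALSE]
  hit <- apply(lin, 1, function(r)
    any(grepl("mitochondria|chloroplast", r, ignore.case = TRUE)))
  hit[is.na(hit)] <- FALSE
  table[, !hit, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (the classical ecological rarefaction). Samples whose total is below the
#' depth are dropped and listed in a warning, not padded.
#'
#' @param table count matrix.
#' @param depth target reads per sample (default 20000).
#' @param seed integer seed; subsampling is reproducible given it.
#' @return rarefied count matrix with every row summing to `depth`.
#' @export
rarefy <- function(table, depth = 20000, seed = 1) {
  validate_count_table(table)
  if (depth <= 0) stop("depth must be positive")
  totals <- rowSums(table)
  low <- totals < depth
  if (all(low)) stop("all samples have fewer than ", depth, " reads")
  if (any(low))
    warning("samples below depth dropped: ",
            paste(rownames(table)[low], collapse = ", "))
  kept <- table[!low, , drop = FALSE]
  set.seed(seed)
  # vegan warns about depth/count ratios we have already validated above
  out <- suppressWarnings(vegan::rrarefy(kept, depth))
  storage.mode(out) <- "integer"
  out
}

#' Convert counts to relative abundances
#'
#' @param table count matrix with positive sample totals.
#' @return row-stochastic matrix (each row sums to 1).
#' @export
to_relative <- function(table) {
  totals <- rowSums(table)
  zero <- totals == 0
  if (any(zero))
    stop("zero-total sample(s): ",
         paste(rownames(table)[zero], collapse = ", "))
  sweep(table, 1, totals, "/")
}

#' Aggregate features at a taxonomic rank
#'
#' Features sharing the named rank are summed; features with an empty label
#' at that rank are pooled under an explicit `unassigned` bucket so sample
#' totals are conserved. Works on counts or relative abundances.
#'
#' @param table matrix (samples x features).
#' @param tax taxonomy data.frame.
#' @param rank one of phylum, class, order, family, genus.
#' @return matrix with one column per taxon at that rank.
#' @export
aggregate_rank <- function(table, tax,
                           rank = c("genus", "family", "order", "class",
                                    "phylum")) {
  rank <- match.arg(rank)
  idx <- match(colnames(table), tax$feature_id)
  labels <- tax[[rank]][idx]
  labels[is.na(labels) | labels == ""] <-
    paste0(RANK_PREFIX[[rank]], "__unassigned")
  groups <- factor(labels, levels = unique(labels))
  out <- t(rowsum(t(table), groups))
  colnames(out) <- levels(groups)
  rownames(out) <- rownames(table)
  out
}
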