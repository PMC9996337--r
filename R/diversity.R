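# Alpha/beta diversity and their two-group tests. Indices are delegated to
# vegan / picante / phyloseq; the PERMANOVA pseudo-F and its permutation
# p-value are computed here directly from the distance matrix.

check_tree_tips <- function(table, tree) {
  if (is.null(tree)) stop("this metric requires a phylogenetic tree")
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("tree is missing tips: ", paste(missing, collapse = ", "))
}

#' Alpha diversity
#'
#' Shannon uses natural logarithms; Pielou's evenness is Shannon divided by
#' the log of the number of observed features (NA when a sample has a single
#' feature); observed counts nonzero features; Faith's PD is the total
#' branch length of the subtree spanning a sample's observed features and
#' the root.
#'
#' @param table count matrix (samples x features).
#' @param tree rooted `phylo` covering all features (faith_pd only).
#' @param metric one of `shannon`, `observed`, `pielou`, `faith_pd`.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, tree = NULL,
                            metric = c("shannon", "observed", "pielou",
                                       "faith_pd")) {
  metric <- match.arg(metric)
  switch(metric,
    shannon = vegan::diversity(table, index = "shannon"),
    observed = rowSums(table > 0),
    pielou = {
      s <- vegan::diversity(table, index = "shannon")
      obs <- rowSums(table > 0)
      ifelse(obs > 1, s / log(obs), NA_real_)
    },
    faith_pd = {
      check_tree_tips(table, tree)
      res <- picante::pd(table, tree, include.root = ape::is.rooted(tree))
      stats::setNames(res$PD, rownames(table))
    })
}

#' Beta diversity distance matrix
#'
#' Jaccard is computed on presence/absence, Bray-Curtis on counts, and the
#' UniFrac variants on the shared/unique branch lengths of the feature tree
#' (weighted UniFrac normalized).
#'
#' @param table count matrix.
#' @param tree rooted `phylo` (UniFrac metrics only).
#' @param metric one of `jaccard`, `braycurtis`, `unweighted_unifrac`,
#'   `weighted_unifrac`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
beta_diversity <- function(table, tree = NULL,
                           metric = c("jaccard", "braycurtis",
                                      "unweighted_unifrac",
                                      "weighted_unifrac")) {
  metric <- match.arg(metric)
  d <- switch(metric,
    jaccard = vegan::vegdist(table, method = "jaccard", binary = TRUE),
    braycurtis = vegan::vegdist(table, method = "bray"),
    {
      check_tree_tips(table, tree)
      ps <- phyloseq::phyloseq(
        phyloseq::otu_table(table, taxa_are_rows = FALSE),
        phyloseq::phy_tree(tree))
      phyloseq::UniFrac(ps, weighted = metric == "weighted_unifrac",
                        normalized = TRUE)
    })
  as.matrix(d)
}

format_median_iqr <- function(x, digits = 2) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7)
  sprintf("%.*f (%.*f, %.*f)", digits, q[1], digits, q[2], digits, q[3])
}

#' Two-group comparison of per-sample diversity values
#'
#' Two-sided Wilcoxon rank-sum test; exact enumeration for arms of up to 8
#' untied values, otherwise the normal approximation with tie and continuity
#' correction. Group medians and IQRs are reported in "median (Q1, Q3)"
#' form.
#'
#' @param values named numeric vector.
#' @param groups factor/character of the same length.
#' @return list with `method`, `statistic`, `p`, and a per-group `summary`.
#' @export
compare_alpha <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  split_vals <- split(values, groups)
  if (any(vapply(split_vals, length, 0L) == 0)) stop("empty group")
  exact <- max(vapply(split_vals, length, 0L)) <= 8 &&
    !anyDuplicated(values)
  ht <- stats::wilcox.test(split_vals[[1]], split_vals[[2]],
                           exact = exact, correct = TRUE)
  list(method = "wilcoxon", statistic = unname(ht$statistic),
       p = ht$p.value,
       summary = vapply(split_vals, format_median_iqr, ""))
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance. The pseudo-F
#' is formed from total and within-group sums of squared distances
#' (`SS_b/(k-1)` over `SS_w/(n-k)`); the p-value is
#' `(1 + #permuted F >= observed) / (1 + n_perm)` so the observed labeling
#' counts as one permutation.
#'
#' @param dm distance matrix (or `dist`).
#' @param groups group label per sample.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return list with `statistic` (pseudo-F), `p`, `n_perm`, `df`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  groups <- as.factor(as.character(groups))
  if (length(groups) != n) stop("groups must cover all samples")
  k <- nlevels(groups)
  if (k < 2) stop("PERMANOVA needs at least two groups")
  D2 <- dm^2
  ss_total <- sum(D2) / (2 * n)
  f_stat <- function(g) {
    ss_w <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      ss_w <- ss_w + sum(D2[i, i]) / (2 * length(i))
    }
    ((ss_total - ss_w) / (k - 1)) / (ss_w / (n - k))
  }
  f_obs <- f_stat(groups)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm))
    if (f_stat(groups[sample.int(n)]) >= f_obs) exceed <- exceed + 1L
  list(statistic = f_obs, p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, df = c(k - 1, n - k))
}
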