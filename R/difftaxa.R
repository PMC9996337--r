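# Differential-abundance screening: per-taxon Wilcoxon rank-sum tests and a
# two-class LEfSe-style Kruskal-Wallis + bootstrapped LDA effect size.

#' Per-taxon Wilcoxon screening
#'
#' Tests every taxon between two groups with a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie correction, no continuity correction,
#' so the p-value coincides with the two-group Kruskal-Wallis screen used by
#' the LEfSe procedure). Significance is called
#' on the raw p-value at `alpha`; a Benjamini-Hochberg adjusted column is
#' emitted alongside for transparency. Direction is the group with the
#' higher mean relative abundance.
#'
#' @param rel relative-abundance matrix (samples x taxa) at one rank.
#' @param groups two-level group label per sample.
#' @param alpha significance level on the raw p (default 0.05).
#' @param rank optional rank label copied into the result.
#' @return data.frame with taxon, per-group means, statistic, p, p_bh,
#'   significant, enriched_group.
#' @export
wilcoxon_screen <- function(rel, groups, alpha = 0.05, rank = NA_character_) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  res <- lapply(colnames(rel), function(tx) {
    x <- rel[groups == g1, tx]; y <- rel[groups == g2, tx]
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    p <- if (is.nan(ht$p.value)) 1 else ht$p.value   # all-tied taxon
    data.frame(taxon = tx, rank = rank,
               mean_1 = mean(x), mean_2 = mean(y),
               statistic = unname(ht$statistic), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", g1)
  names(out)[names(out) == "mean_2"] <- paste0("mean_", g2)
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < alpha
  out$enriched_group <- ifelse(out[[3]] >= out[[4]], g1, g2)
  out
}

#' LEfSe-style LDA effect-size screening (two classes)
#'
#' Stage 1 screens taxa with Kruskal-Wallis at `alpha` (for two groups this
#' is equivalent to the Wilcoxon rank-sum test). Stage 2 estimates an LDA
#' effect size for the survivors on samples rescaled to one million per
#' sample: over `n_boot` bootstrap rounds, a random two-thirds of each class
#' is drawn and a one-component LDA fitted; each taxon's round effect is the
#' mean of (i) its share of the class-separation along the discriminant
#' (|unit coefficient| times the projected class gap) and (ii) its raw class
#' mean difference. The reported score is log10 of the bootstrap-averaged
#' effect (floored at 1), and taxa with score >= `lda_threshold` are
#' flagged.
#'
#' @param rel relative-abundance matrix (samples x taxa).
#' @param groups two-level class label per sample, >= 3 samples per class.
#' @param alpha Kruskal-Wallis screening level.
#' @param lda_threshold log10 effect-size cutoff (default 2.0).
#' @param n_boot bootstrap rounds (default 30).
#' @param seed integer seed.
#' @return data.frame with taxon, p_kw, lda_score, enriched_group,
#'   significant (score above threshold); flagged set is always a subset of
#'   the Kruskal-Wallis survivors.
#' @export
lefse_screen <- function(rel, groups, alpha = 0.05, lda_threshold = 2.0,
                         n_boot = 30, seed = 1) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two classes required")
  if (any(table(groups) < 3)) stop("each class needs at least 3 samples")
  X <- rel * 1e6                       # counts-per-million convention
  p_kw <- apply(X, 2, function(x)
    suppressWarnings(stats::kruskal.test(x, groups)$p.value))
  p_kw[is.nan(p_kw)] <- 1
  keep <- which(p_kw < alpha)
  empty <- data.frame(taxon = character(), p_kw = numeric(),
                      lda_score = numeric(), enriched_group = character(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  Xs <- X[, keep, drop = FALSE]
  set.seed(seed)
  idx_by_class <- split(seq_len(nrow(Xs)), groups)
  n_sub <- vapply(idx_by_class, function(i) ceiling(2 / 3 * length(i)), 0)
  eff_sum <- numeric(ncol(Xs)); n_ok <- 0L
  for (b in seq_len(n_boot)) {
    sub <- unlist(mapply(sample, idx_by_class, n_sub, SIMPLIFY = FALSE))
    Xb <- Xs[sub, , drop = FALSE]
    # jitter breaks exact collinearity so lda() is well posed
    Xb <- Xb + matrix(stats::rnorm(length(Xb), 0, 1e-8 + 1e-6 * stats::sd(Xb)),
                      nrow(Xb))
    gb <- droplevels(groups[sub])
    fit <- tryCatch(suppressWarnings(MASS::lda(Xb, grouping = gb)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    w <- fit$scaling[, 1]
    w <- w / sqrt(sum(w^2))
    mu <- apply(Xb, 2, tapply, gb, mean)      # 2 x p class means
    gap <- abs(sum((mu[1, ] - mu[2, ]) * w))  # projected class separation
    eff_sum <- eff_sum + (abs(w) * gap + abs(mu[1, ] - mu[2, ])) / 2
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0) stop("LDA failed in every bootstrap round")
  score <- log10(pmax(eff_sum / n_ok, 1))
  mu_full <- apply(Xs, 2, tapply, groups, mean)
  out <- data.frame(taxon = colnames(Xs), p_kw = p_kw[keep],
                    lda_score = score,
                    enriched_group = levels(groups)[
                      apply(mu_full, 2, which.max)],
                    significant = score >= lda_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$significant, , drop = FALSE]
}
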