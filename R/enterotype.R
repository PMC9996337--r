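# Enterotyping: Jensen-Shannon distance on genus profiles, PAM clustering,
# Calinski-Harabasz model selection on the PCoA embedding, between-class
# analysis ordination, driver-genus labeling, group-prevalence tests.

#' Jensen-Shannon distance matrix
#'
#' `JSD(P, Q) = sqrt((KL(P, M) + KL(Q, M)) / 2)` with `M = (P + Q)/2` and
#' base-2 logarithms, so distances live in `[0, 1]` and satisfy the metric
#' axioms. Zeros are replaced by a pseudocount and rows renormalized first.
#'
#' @param rel row-stochastic matrix (samples x genera).
#' @param pseudocount small positive value replacing zeros (default 1e-6).
#' @return symmetric distance matrix.
#' @export
jsd_matrix <- function(rel, pseudocount = 1e-6) {
  if (any(rel < 0)) stop("negative abundances")
  P <- pmax(rel, pseudocount)
  P <- sweep(P, 1, rowSums(P), "/")
  n <- nrow(P)
  # KL against pairwise mixtures, vectorized over the second argument
  H <- function(x) -rowSums(x * log2(x))           # entropies, P > 0 here
  hP <- H(P)
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n)) {
    M <- sweep(P, 2, P[i, ], "+") / 2
    jsdiv <- H(M) - (hP + hP[i]) / 2
    d[i, ] <- sqrt(pmax(jsdiv, 0))
  }
  diag(d) <- 0
  (d + t(d)) / 2
}

#' PAM clustering on a distance matrix
#'
#' k-medoids minimizing the total distance of samples to their cluster
#' medoid. Small problems (at most 3000 candidate medoid sets) are solved
#' exactly by enumeration; larger ones by BUILD + SWAP ([cluster::pam()]).
#' Both paths are deterministic given the distance matrix, with ties broken
#' toward the lowest sample index (the `seed` argument is kept for
#' interface symmetry only).
#'
#' @param dm distance matrix.
#' @param k number of clusters, `2 <= k < n`.
#' @param seed unused (both solvers are deterministic).
#' @return list with `assignments` (named integer vector), `medoids`
#'   (sample ids, one per cluster) and `cost` (total within-cluster
#'   distance to medoid).
#' @export
pam_cluster <- function(dm, k, seed = 1) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (is.null(rownames(dm)))
    dimnames(dm) <- list(paste0("S", seq_len(n)), paste0("S", seq_len(n)))
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n")
  if (choose(n, k) <= 3000) {
    sets <- utils::combn(n, k)
    best_cost <- Inf
    best_med <- NULL
    for (j in seq_len(ncol(sets))) {
      cost <- sum(apply(dm[, sets[, j], drop = FALSE], 1, min))
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best_med <- sets[, j]
      }
    }
    nearest <- apply(dm[, best_med, drop = FALSE], 1, which.min)
    assignments <- stats::setNames(as.integer(nearest), rownames(dm))
    list(assignments = assignments, medoids = rownames(dm)[best_med],
         cost = best_cost)
  } else {
    fit <- cluster::pam(stats::as.dist(dm), k, diss = TRUE)
    list(assignments = fit$clustering, medoids = fit$medoids,
         cost = sum(dm[cbind(seq_len(n),
                             match(fit$medoids,
                                   rownames(dm))[fit$clustering])]))
  }
}

ch_index <- function(coords, assignments) {
  n <- nrow(coords)
  k <- length(unique(assignments))
  grand <- colMeans(coords)
  ss_total <- sum(sweep(coords, 2, grand)^2)
  ss_within <- 0
  for (g in unique(assignments)) {
    i <- which(assignments == g)
    ss_within <- ss_within + sum(sweep(coords[i, , drop = FALSE], 2,
                                       colMeans(coords[i, , drop = FALSE]))^2)
  }
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

#' Select the number of clusters by the Calinski-Harabasz index
#'
#' Embeds the distance matrix by principal-coordinate analysis (all axes
#' with positive eigenvalues), PAM-clusters at every k in `k_range`, and
#' scores each partition with `CH(k) = [B/(k-1)] / [W/(n-k)]` (between /
#' within sums of squares around centroids). Returns the argmax.
#'
#' @param dm distance matrix.
#' @param k_range candidate cluster numbers (default 2..10).
#' @param seed passed to [pam_cluster()].
#' @return list with `k` (best), `ch_by_k` (named vector), `assignments`
#'   at the best k, `medoids`.
#' @export
optimal_k <- function(dm, k_range = 2:10, seed = 1) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (all(dm == 0)) stop("degenerate distance matrix (all zeros)")
  k_range <- k_range[k_range > 1 & k_range < n]
  if (!length(k_range)) stop("k_range empty after clipping to (1, n)")
  # cmdscale warns when fewer than n-1 eigenvalues are positive; we keep
  # only the positive axes below anyway
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1,
                                          eig = TRUE))
  keep <- mds$eig > max(mds$eig) * 1e-8
  coords <- mds$points[, keep[seq_len(ncol(mds$points))], drop = FALSE]
  fits <- lapply(k_range, function(k) pam_cluster(dm, k, seed))
  ch <- vapply(fits, function(f) ch_index(coords, f$assignments), 0)
  names(ch) <- k_range
  best <- which.max(ch)
  list(k = k_range[best], ch_by_k = ch,
       assignments = fits[[best]]$assignments,
       medoids = fits[[best]]$medoids)
}

#' Between-class analysis ordination
#'
#' Centers the genus matrix, forms size-weighted class centroids,
#' eigen-decomposes the between-class covariance and projects all samples
#' onto the leading axes (k-1, capped at 2). The explained inertia is the
#' between-class eigenvalue share of the total variance.
#'
#' @param rel genus-level relative abundances (samples x genera).
#' @param assignments cluster label per sample.
#' @return list with `coords` (samples x axes), `axes` (loadings),
#'   `explained_inertia` (fraction per axis).
#' @export
bca <- function(rel, assignments) {
  f <- as.factor(assignments)
  if (nlevels(f) < 2) stop("between-class analysis needs >= 2 clusters")
  if (any(table(f) == 1)) warning("singleton class in between-class analysis")
  X <- scale(rel, center = TRUE, scale = FALSE)
  n <- nrow(X)
  cent <- apply(X, 2, tapply, f, mean)              # k x p centroids
  w <- as.numeric(table(f)) / n
  B <- crossprod(cent * sqrt(w))                    # between-class covariance
  eig <- eigen(B, symmetric = TRUE)
  n_axes <- min(nlevels(f) - 1, 2)
  axes <- eig$vectors[, seq_len(n_axes), drop = FALSE]
  rownames(axes) <- colnames(rel)
  total_inertia <- sum(X^2) / n
  list(coords = X %*% axes, axes = axes,
       explained_inertia = eig$values[seq_len(n_axes)] / total_inertia)
}

#' Label clusters by their driver genus
#'
#' For each genus in the candidate panel a Kruskal-Wallis test across
#' clusters is reported, and each cluster is labeled by the panel genus with
#' the highest median abundance inside it.
#'
#' @param rel genus-level relative abundances.
#' @param assignments cluster label per sample.
#' @param panel candidate driver genera (classical enterotype drivers by
#'   default).
#' @return list with `labels` (genus per cluster) and `kw` (data.frame of
#'   panel Kruskal-Wallis tests).
#' @export
representative_genus <- function(rel, assignments,
                                 panel = c("Bacteroides", "Prevotella",
                                           "Ruminococcus")) {
  missing <- setdiff(panel, colnames(rel))
  if (length(missing)) {
    warning("panel genera absent, skipped: ", paste(missing, collapse = ", "))
    panel <- setdiff(panel, missing)
  }
  if (!length(panel)) stop("no panel genus present in the table")
  f <- as.factor(assignments)
  kw <- do.call(rbind, lapply(panel, function(g) {
    ht <- suppressWarnings(stats::kruskal.test(rel[, g], f))
    data.frame(genus = g, statistic = unname(ht$statistic),
               p = ifelse(is.nan(ht$p.value), 1, ht$p.value),
               stringsAsFactors = FALSE)
  }))
  med <- vapply(levels(f), function(cl)
    apply(rel[f == cl, panel, drop = FALSE], 2, stats::median),
    numeric(length(panel)))
  labels <- panel[apply(matrix(med, nrow = length(panel)), 2, which.max)]
  names(labels) <- levels(f)
  list(labels = labels, kw = kw)
}

#' Per-enterotype group-prevalence test
#'
#' For each enterotype, membership is crossed with the group label in a 2x2
#' table and tested with the pooled two-proportion chi-square (no continuity
#' correction; identical to the pooled two-proportion z-test). Fisher's
#' exact test can be requested for small cells but is off by default.
#'
#' @param assignments enterotype label per sample.
#' @param groups two-level group label per sample.
#' @param fisher_small_cells use Fisher when any cell <= 5 (default FALSE).
#' @return data.frame, one row per enterotype, with per-group membership
#'   counts, proportions, statistic and p.
#' @export
prevalence_test <- function(assignments, groups, fisher_small_cells = FALSE) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  do.call(rbind, lapply(sort(unique(assignments)), function(e) {
    x1 <- sum(assignments == e & groups == g1)
    x2 <- sum(assignments == e & groups == g2)
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2)
    if (fisher_small_cells && any(tab <= 5)) {
      ht <- stats::fisher.test(tab)
      stat <- NA_real_; p <- ht$p.value; method <- "fisher_exact"
    } else {
      res <- compare_proportions(x1, n1, x2, n2)
      stat <- res$statistic; p <- res$p; method <- "z_pooled"
    }
    out <- data.frame(enterotype = e, x1 = x1, n1 = n1, prop1 = x1 / n1,
                      x2 = x2, n2 = n2, prop2 = x2 / n2,
                      statistic = stat, p = p, method = method,
                      stringsAsFactors = FALSE)
    names(out)[c(2, 4, 5, 7)] <- c(paste0("x_", g1), paste0("prop_", g1),
                                   paste0("x_", g2), paste0("prop_", g2))
    out
  }))
}

#' Full enterotyping pipeline
#'
#' JSD on genus profiles, PAM with Calinski-Harabasz selection of k (or a
#' fixed k), between-class analysis coordinates and driver-genus labels.
#'
#' @param rel genus-level relative abundances.
#' @param k `"auto"` (Calinski-Harabasz over `k_range`) or a fixed integer.
#' @param k_range candidate k for auto selection.
#' @param pseudocount passed to [jsd_matrix()].
#' @param panel passed to [representative_genus()].
#' @param seed passed to clustering.
#' @return an `enterotype_fit` list: `k`, `assignments`, `medoids`,
#'   `ch_by_k`, `bca_coords`, `explained_inertia`, `representative`.
#' @export
enterotype_fit <- function(rel, k = "auto", k_range = 2:10,
                           pseudocount = 1e-6,
                           panel = c("Bacteroides", "Prevotella",
                                     "Ruminococcus"),
                           seed = 1) {
  dm <- jsd_matrix(rel, pseudocount)
  if (identical(k, "auto")) {
    sel <- optimal_k(dm, k_range, seed)
  } else {
    fit <- pam_cluster(dm, k, seed)
    sel <- list(k = k, ch_by_k = NULL, assignments = fit$assignments,
                medoids = fit$medoids)
  }
  ord <- bca(rel, sel$assignments)
  rep_g <- tryCatch(
    suppressWarnings(representative_genus(rel, sel$assignments, panel)),
    error = function(e) NULL)
  structure(list(k = sel$k, assignments = sel$assignments,
                 medoids = sel$medoids, ch_by_k = sel$ch_by_k,
                 bca_coords = ord$coords,
                 explained_inertia = ord$explained_inertia,
                 representative = rep_g, jsd = dm),
            class = "enterotype_fit")
}

#' @export
print.enterotype_fit <- function(x, ...) {
  cat("Enterotype fit: k =", x$k, "\n")
  cat("Cluster sizes:", paste(table(x$assignments), collapse = ", "), "\n")
  if (!is.null(x$representative))
    cat("Driver genera:", paste(x$representative$labels, collapse = ", "),
        "\n")
  invisible(x)
}
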