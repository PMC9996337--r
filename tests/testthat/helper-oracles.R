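# Independent oracles used across tests. Each is deliberately brute-force
# and shares no code with the implementation it checks.

# exhaustive k-medoids: best total distance-to-medoid over all medoid sets
brute_pam_cost <- function(dm, k) {
  n <- nrow(dm)
  sets <- utils::combn(n, k)
  best <- Inf
  for (j in seq_len(ncol(sets))) {
    med <- sets[, j]
    cost <- sum(apply(dm[, med, drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

# betweenness by explicit enumeration of all shortest paths (BFS layers)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  count_paths <- function(s, t) {
    # number of shortest s-t paths through each vertex, plus sigma_st
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- rep(0, n); sigma[s] <- 1
    queue <- s
    order <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order <- c(order, v)
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    if (is.infinite(dist[t])) return(rep(0, n))
    # sigma_st(v): paths s->v times v->t of compatible length
    distT <- rep(Inf, n); distT[t] <- 0
    sigmaT <- rep(0, n); sigmaT[t] <- 1
    queue <- t
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(distT[w])) {
          distT[w] <- distT[v] + 1
          queue <- c(queue, w)
        }
        if (distT[w] == distT[v] + 1) sigmaT[w] <- sigmaT[w] + sigmaT[v]
      }
    }
    through <- ifelse(dist + distT == dist[t], sigma * sigmaT, 0)
    through / sigma[t]
  }
  bc <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (s == t) next
    frac <- count_paths(s, t)
    frac[c(s, t)] <- 0
    bc <- bc + frac
  }
  bc
}

# two-sided Fisher p by full hypergeometric enumeration with factorials
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  pt_prob <- function(x) {
    y <- c1 - x
    if (y < 0 || y > r2 || x > r1) return(0)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
          lfactorial(r1 - x) - lfactorial(y) - lfactorial(r2 - y))
  }
  p_obs <- pt_prob(a)
  xs <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(xs, pt_prob, 0)[vapply(xs, pt_prob, 0) <= p_obs * (1 + 1e-7)])
}

# unweighted UniFrac by explicit branch walk over an ape tree
brute_unweighted_unifrac <- function(tree, pres_a, pres_b) {
  tips_under <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  shared_len <- 0; union_len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_under(tree$edge[e, 2])
    in_a <- any(tips %in% pres_a); in_b <- any(tips %in% pres_b)
    len <- tree$edge.length[e]
    if (in_a || in_b) union_len <- union_len + len
    if (in_a && in_b) shared_len <- shared_len + len
  }
  (union_len - shared_len) / union_len
}

# permutation of 1:n whose Spearman rho against 1:n is exactly `target`
# (greedy swaps toward the required sum of squared rank differences)
perm_with_spearman <- function(n, target, extra_sd2 = 0) {
  target_sd2 <- round((1 - target) * n * (n^2 - 1) / 6) + extra_sd2
  p <- seq_len(n)
  sd2 <- 0
  set.seed(99)
  for (iter in 1:200000) {
    if (sd2 == target_sd2) break
    i <- sample.int(n, 2)
    q <- p; q[i] <- q[rev(i)]
    new_sd2 <- sum((q - seq_len(n))^2)
    if (abs(new_sd2 - target_sd2) < abs(sd2 - target_sd2)) {
      p <- q; sd2 <- new_sd2
    }
  }
  stopifnot(sd2 == target_sd2)
  p
}

rand_index_adjusted <- function(a, b) mclust::adjustedRandIndex(a, b)

# small genus-level relative-abundance fixture: two groups, optional fold
# changes planted on named columns
fixture_rel <- function(n_per_group = 21, n_taxa = 20, folds = NULL,
                        seed = 1) {
  set.seed(seed)
  shape <- rep(2, n_taxa)
  x <- matrix(stats::rgamma(2 * n_per_group * n_taxa, shape = 2),
              nrow = 2 * n_per_group)
  colnames(x) <- sprintf("T%02d", seq_len(n_taxa))
  groups <- rep(c("A", "B"), each = n_per_group)
  if (!is.null(folds))
    for (tx in names(folds))
      x[groups == "B", tx] <- x[groups == "B", tx] * folds[[tx]]
  rel <- x / rowSums(x)
  rownames(rel) <- sprintf("S%03d", seq_len(nrow(rel)))
  list(rel = rel, groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
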