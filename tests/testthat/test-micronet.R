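panel_fixture <- function(seed = 1, n = 42, associations = list()) {
  co <- simulate_cohort(n_per_group = n / 2, seed = seed,
                        associations = associations)
  rel <- to_relative(co$counts)
  fit <- enterotype_fit(rel, k = 3, seed = 1)
  list(panel = build_panel(rel, co$frame, fit), co = co, rel = rel)
}

test_that("panel keeps the top genera and drops constant columns", {
  fx <- panel_fixture(seed = 2)
  expect_equal(sum(fx$panel$type == "genus"), 50)
  expect_true(fx$panel$abundance_share > 0.5 &&
                fx$panel$abundance_share <= 1)
  expect_true("enterotype" %in% names(fx$panel$type))

  fr <- fx$co$frame
  fr$allyes <- rep(1L, nrow(fr))
  attr(fr, "kinds") <- c(clinical_kinds(fr), allyes = "binary")
  expect_warning(p2 <- build_panel(fx$rel, fr, top_n = 10), "allyes")
  expect_false("allyes" %in% colnames(p2$data))

  expect_error(build_panel(fx$rel[1:2, ], fx$co$frame), "3 shared")
})

test_that("edges require both FDR significance and the magnitude floor", {
  n <- 49
  y <- perm_with_spearman(n, 0.35)
  y2 <- perm_with_spearman(n, 0.35, extra_sd2 = 2)  # just below the floor
  panel <- list(data = cbind(a = seq_len(n), b = y, c = y2),
                type = c(a = "genus", b = "clinical", c = "clinical"))
  colnames(panel$data) <- names(panel$type)
  edges <- correlation_edges(panel, alpha = 0.5)
  ab <- edges[edges$u == "a" & edges$v == "b", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$rho, 0.35, tolerance = 1e-12)    # boundary kept
  expect_false(any(edges$u == "a" & edges$v == "c"))  # 0.3499 dropped
  all_pairs <- attr(edges, "all_pairs")
  expect_lt(all_pairs$rho[all_pairs$u == "a" & all_pairs$v == "c"], 0.35)
})

test_that("a perfectly monotone pair reaches rho 1 with p 0", {
  panel <- list(data = cbind(x = 1:10, y = (1:10)^3, z = rnorm(10)),
                type = c(x = "genus", y = "clinical", z = "clinical"))
  edges <- correlation_edges(panel)
  xy <- edges[edges$u == "x" & edges$v == "y", ]
  expect_equal(xy$rho, 1)
  expect_equal(xy$p_adj, 0)
})

test_that("BH adjustment is monotone and edges shrink as the floor rises", {
  fx <- panel_fixture(seed = 3)
  edges <- correlation_edges(fx$panel, alpha = 0.25, rho_min = 0.2)
  all_pairs <- attr(edges, "all_pairs")
  ord <- order(all_pairs$p)
  expect_true(all(diff(all_pairs$p_adj[ord]) >= -1e-12))
  e2 <- correlation_edges(fx$panel, alpha = 0.25, rho_min = 0.4)
  expect_lte(nrow(e2), nrow(edges))
  key <- function(e) paste(e$u, e$v)
  expect_true(all(key(e2) %in% key(edges)))
})

test_that("directed networks keep only genus-to-clinical edges", {
  edges <- data.frame(
    u = c("Dorea", "Dorea", "fatigue", "craving"),
    v = c("Devosia", "fatigue", "Halomonas", "drowsiness"),
    type_u = c("genus", "genus", "clinical", "clinical"),
    type_v = c("genus", "clinical", "genus", "clinical"),
    rho = c(0.9, 0.5, 0.4, 0.6), p = 1e-4, p_adj = 1e-3,
    sign = 1, stringsAsFactors = FALSE)
  un <- undirected_net(edges)
  di <- directed_net(edges)
  expect_equal(nrow(un$edges), 4)
  expect_equal(nrow(di$edges), 2)
  expect_true(all(di$edges$type_u == "genus" & di$edges$type_v == "clinical"))
  expect_equal(di$edges$u[di$edges$v == "Halomonas" |
                            di$edges$u == "Halomonas"], "Halomonas")
  expect_equal(un$nodes$degree[un$nodes$id == "Dorea"], 2)
})

test_that("betweenness matches hand counts and path enumeration", {
  path_edges <- data.frame(u = c("a", "b"), v = c("b", "c"),
                           type_u = "genus", type_v = "genus",
                           rho = 0.5, p = 0.01, p_adj = 0.01, sign = 1,
                           stringsAsFactors = FALSE)
  net <- betweenness_centrality(undirected_net(path_edges))
  expect_equal(net$nodes$betweenness[match(c("a", "b", "c"), net$nodes$id)],
               c(0, 1, 0))

  star <- data.frame(u = "hub", v = paste0("leaf", 1:4),
                     type_u = "genus", type_v = "clinical",
                     rho = 0.5, p = 0.01, p_adj = 0.01, sign = 1,
                     stringsAsFactors = FALSE)
  snet <- betweenness_centrality(undirected_net(star))
  expect_equal(snet$nodes$betweenness[snet$nodes$id == "hub"], 6)

  set.seed(6)
  for (i in 1:50) {
    adj <- matrix(0, 10, 10)
    up <- which(upper.tri(adj))
    adj[sample(up, 12)] <- 1
    adj <- adj + t(adj)
    ids <- paste0("n", 1:10)
    idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    e <- data.frame(u = ids[idx[, 1]], v = ids[idx[, 2]],
                    type_u = "genus", type_v = "genus", rho = 0.5,
                    p = 0.01, p_adj = 0.01, sign = 1,
                    stringsAsFactors = FALSE)
    net_i <- betweenness_centrality(undirected_net(e))
    used <- match(net_i$nodes$id, ids)
    expect_equal(net_i$nodes$betweenness,
                 brute_betweenness(adj)[used], tolerance = 1e-9)
  }
})

test_that("HITS matches its closed form and the eigenvector oracle", {
  e <- data.frame(u = c("A", "B"), v = c("C", "C"), type_u = "genus",
                  type_v = "clinical", rho = 0.5, p = 0.01, p_adj = 0.01,
                  sign = 1, stringsAsFactors = FALSE)
  net <- hits_scores(directed_net(e))
  hubs <- setNames(net$nodes$hub, net$nodes$id)
  auth <- setNames(net$nodes$authority, net$nodes$id)
  expect_equal(unname(hubs[c("A", "B")]), c(1, 1))
  expect_equal(unname(auth[["C"]]), 1)
  expect_equal(unname(hubs[["C"]]), 0)

  set.seed(7)
  for (i in 1:50) {
    n <- 8
    A <- matrix(rbinom(n^2, 1, 0.3), n)
    diag(A) <- 0
    if (sum(A) == 0) next
    ev <- eigen(A %*% t(A), only.values = TRUE)$values
    if (ev[2] / ev[1] > 1 - 1e-6) next   # degenerate top eigenspace
    ids_g <- paste0("g", 1:n); ids_c <- paste0("c", 1:n)
    idx <- which(A > 0, arr.ind = TRUE)
    e <- data.frame(u = ids_g[idx[, 1]], v = ids_c[idx[, 2]],
                    type_u = "genus", type_v = "clinical", rho = 0.5,
                    p = 0.01, p_adj = 0.01, sign = 1,
                    stringsAsFactors = FALSE)
    net_i <- hits_scores(directed_net(e), rescale = "l2")
    # oracle: principal eigenvector of the bipartite A %*% t(A)
    hub_oracle <- abs(eigen(A %*% t(A))$vectors[, 1])
    hub_oracle <- hub_oracle / sqrt(sum(hub_oracle^2))
    got <- setNames(net_i$nodes$hub, net_i$nodes$id)[ids_g]
    got[is.na(got)] <- 0   # isolated rows never enter the net
    expect_equal(unname(got), hub_oracle, tolerance = 1e-6)
  }

  empty <- directed_net(e[0, ])
  expect_error(hits_scores(empty), "no edges")
})

test_that("HITS is stable under relabeling and tolerance tightening", {
  set.seed(8)
  e <- data.frame(u = paste0("g", sample(1:5, 8, TRUE)),
                  v = paste0("c", sample(1:5, 8, TRUE)),
                  type_u = "genus", type_v = "clinical", rho = 0.5,
                  p = 0.01, p_adj = 0.01, sign = 1, stringsAsFactors = FALSE)
  e <- unique(e)
  n1 <- hits_scores(directed_net(e))
  relab <- e
  relab$u <- paste0("X", relab$u); relab$v <- paste0("X", relab$v)
  n2 <- hits_scores(directed_net(relab))
  expect_equal(sort(n1$nodes$hub), sort(n2$nodes$hub), tolerance = 1e-8)
  n3 <- hits_scores(directed_net(e), tol = 1e-13)
  expect_equal(n1$nodes$hub, n3$nodes$hub, tolerance = 1e-9)
  expect_true(all(n1$nodes$hub >= 0 & n1$nodes$authority >= 0))
})

test_that("hub report flags the most connected genus", {
  e <- data.frame(
    u = c(rep("Devosia", 8), "Dorea"),
    v = c(paste0("trait", 1:8), "trait1"),
    type_u = "genus", type_v = "clinical", rho = 0.5, p = 1e-4,
    p_adj = 1e-3, sign = 1, stringsAsFactors = FALSE)
  net <- hits_scores(directed_net(e))
  rep_tab <- hub_report(net)
  expect_equal(rep_tab$id[rep_tab$role == "hub_genus"], "Devosia")
  expect_true(all(rep_tab$score[rep_tab$type == "clinical"] >= 0))

  empty_rep <- hub_report(directed_net(e[0, ]))
  expect_equal(nrow(empty_rep), 0)
})

test_that("a genus planted against many traits becomes the hub", {
  # Devosia correlates with 8 continuous traits (copula, rho 0.6); the other
  # genera touch at most one trait by chance
  hits_top <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 42
    r <- 2 * sin(pi * 0.6 / 6)
    genera <- matrix(rgamma(n * 10, 1), n,
                     dimnames = list(sprintf("S%02d", 1:n),
                                     c("Devosia", paste0("G", 1:9))))
    u <- qnorm((rank(genera[, "Devosia"]) - 0.5) / n)
    traits <- vapply(1:8, function(j) r * u + sqrt(1 - r^2) * rnorm(n),
                     numeric(n))
    colnames(traits) <- paste0("trait", 1:8)
    panel <- list(data = cbind(genera, traits),
                  type = setNames(rep(c("genus", "clinical"), c(10, 8)),
                                  c(colnames(genera), colnames(traits))))
    edges <- correlation_edges(panel, alpha = 0.05, rho_min = 0.35)
    di <- directed_net(edges)
    if (nrow(di$edges) == 0) return(NA_character_)
    rep_tab <- hub_report(hits_scores(di))
    rep_tab$id[rep_tab$role == "hub_genus"]
  }, "")
  expect_gte(mean(hits_top == "Devosia", na.rm = TRUE), 0.95)
})
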