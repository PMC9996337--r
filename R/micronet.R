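# Clinical-microbial Spearman network: variable panel assembly, FDR-gated
# correlation edges, undirected/directed graphs, betweenness and HITS
# hub/authority centrality, hub reporting.

#' Assemble the correlation variable panel
#'
#' Genus block: the `top_n` genera by mean relative abundance. Clinical
#' block: binary facets and group status as 0/1, counts and continuous
#' variables as numbers (categorical variables are excluded). The
#' enterotype enters as its integer label; the ordinal-encoding caveat is
#' recorded in the panel metadata. Constant columns are dropped with a
#' warning, since their Spearman correlation is undefined.
#'
#' @param rel genus-level relative abundances.
#' @param frame clinical frame on the same samples.
#' @param fit optional `enterotype_fit` contributing the enterotype column.
#' @param top_n genera kept (default 50).
#' @return list with `data` (numeric matrix, samples x variables), `type`
#'   (named: genus/clinical/enterotype), `abundance_share` of kept genera.
#' @export
build_panel <- function(rel, frame, fit = NULL, top_n = 50) {
  shared <- intersect(rownames(rel), frame$sample_id)
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  rel <- rel[shared, , drop = FALSE]
  frame <- frame[match(shared, frame$sample_id), , drop = FALSE]
  top_n <- min(top_n, ncol(rel))
  ord <- order(colMeans(rel), decreasing = TRUE)[seq_len(top_n)]
  genus_block <- rel[, ord, drop = FALSE]
  share <- sum(colMeans(genus_block)) / sum(colMeans(rel))

  kinds <- clinical_kinds(frame)
  numeric_vars <- names(kinds)[kinds %in% c("binary", "count", "continuous")]
  clin_block <- vapply(numeric_vars, function(v) as.numeric(frame[[v]]),
                       numeric(length(shared)))
  clin_block <- cbind(clin_block,
                      group_status = as.numeric(as.factor(frame$group)) - 1)
  data <- cbind(genus_block, clin_block)
  type <- c(rep("genus", ncol(genus_block)),
            rep("clinical", ncol(clin_block)))
  if (!is.null(fit)) {
    data <- cbind(data, enterotype = as.numeric(
      fit$assignments[match(shared, names(fit$assignments))]))
    type <- c(type, "enterotype")
  }
  names(type) <- colnames(data)
  constant <- apply(data, 2, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                      all(is.na(x)))
  if (any(constant)) {
    warning("constant columns dropped: ",
            paste(colnames(data)[constant], collapse = ", "))
    data <- data[, !constant, drop = FALSE]
    type <- type[!constant]
  }
  list(data = data, type = type, abundance_share = share,
       note = "enterotype encoded as its integer label (ordinal caveat)")
}

spearman_matrix <- function(data) {
  n <- nrow(data)
  ranks <- apply(data, 2, rank, ties.method = "average")
  rho <- stats::cor(ranks, use = "pairwise.complete.obs")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  list(rho = rho, p = p)
}

#' Spearman correlation edges with joint FDR control
#'
#' Spearman's rho (average ranks for ties; t-approximation p-values) for
#' every unordered variable pair, Benjamini-Hochberg adjustment jointly
#' across all pairs, and an edge kept iff `p_adj < alpha` and
#' `|rho| >= rho_min` (the boundary value is kept).
#'
#' @param panel result of [build_panel()].
#' @param alpha FDR level (default 0.05).
#' @param rho_min minimum correlation magnitude (default 0.35).
#' @return data.frame of edges: u, v, type_u, type_v, rho, p, p_adj, sign.
#' @export
correlation_edges <- function(panel, alpha = 0.05, rho_min = 0.35) {
  data <- panel$data
  if (nrow(data) < 3) stop("need >= 3 samples")
  sm <- spearman_matrix(data)
  vars <- colnames(data)
  idx <- which(upper.tri(sm$rho), arr.ind = TRUE)
  edges <- data.frame(u = vars[idx[, 1]], v = vars[idx[, 2]],
                      type_u = unname(panel$type[idx[, 1]]),
                      type_v = unname(panel$type[idx[, 2]]),
                      rho = sm$rho[idx], p = sm$p[idx],
                      stringsAsFactors = FALSE)
  edges$p_adj <- stats::p.adjust(edges$p, "BH")
  edges$sign <- sign(edges$rho)
  keep <- edges$p_adj < alpha & abs(edges$rho) >= rho_min
  keep[is.na(keep)] <- FALSE
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_pairs") <- edges
  out
}

make_corr_net <- function(edges, nodes_type, directed) {
  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v", "rho", "p", "p_adj", "sign")],
    directed = directed,
    vertices = data.frame(name = names(nodes_type), type = unname(nodes_type),
                          stringsAsFactors = FALSE))
  nodes <- data.frame(id = names(nodes_type), type = unname(nodes_type),
                      degree = igraph::degree(g)[names(nodes_type)],
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, directed = directed,
                 graph = g), class = "corr_net")
}

#' Build the undirected / directed correlation network
#'
#' The undirected network keeps all edge types. The directed variant keeps
#' only genus-clinical edges, oriented microbiota -> trait, so it is
#' bipartite by construction. Only nodes incident to at least one retained
#' edge are included.
#'
#' @param edges edge data.frame from [correlation_edges()].
#' @return a `corr_net`: `nodes`, `edges`, `directed`, `graph` (igraph).
#' @export
undirected_net <- function(edges) {
  used <- unique(c(edges$u, edges$v))
  type <- stats::setNames(c(edges$type_u, edges$type_v), c(edges$u, edges$v))
  make_corr_net(edges, type[used], directed = FALSE)
}

#' @rdname undirected_net
#' @export
directed_net <- function(edges) {
  gc <- (edges$type_u == "genus" & edges$type_v == "clinical") |
        (edges$type_u == "clinical" & edges$type_v == "genus")
  e <- edges[gc, , drop = FALSE]
  flip <- e$type_u == "clinical"
  if (any(flip)) {
    tmp <- e$u[flip]; e$u[flip] <- e$v[flip]; e$v[flip] <- tmp
    e$type_u[flip] <- "genus"; e$type_v[flip] <- "clinical"
  }
  used <- unique(c(e$u, e$v))
  type <- stats::setNames(c(e$type_u, e$type_v), c(e$u, e$v))
  make_corr_net(e, type[used], directed = TRUE)
}

#' Betweenness centrality (BCI)
#'
#' `BCI(v) = sum over unordered pairs s,t (both != v) of sigma_st(v) /
#' sigma_st`, where sigma_st counts unweighted shortest s-t paths and
#' sigma_st(v) those passing through v; disconnected pairs contribute 0.
#' Computed by Brandes' accumulation, unnormalized.
#'
#' @param net an undirected `corr_net`.
#' @return the net with a `betweenness` column added to `nodes`.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "corr_net"))
  if (net$directed) stop("BCI is defined on the undirected network")
  b <- igraph::betweenness(net$graph, directed = FALSE, weights = NA,
                           normalized = FALSE)
  net$nodes$betweenness <- unname(b[net$nodes$id])
  net
}

#' HITS hub and authority scores
#'
#' Power iteration of the mutual-reinforcement updates: authority
#' `x_p <- sum of y_q over edges (q, p)` and hub `y_p <- sum of x_q over
#' edges (p, q)`, L2-normalizing each round, until the largest change drops
#' below `tol`. Scores are rescaled so the maximum hub and maximum
#' authority equal 1 (`rescale = "l2"` keeps the eigenvector normalization
#' instead).
#'
#' @param net a directed `corr_net` with at least one edge.
#' @param tol convergence tolerance (default 1e-10).
#' @param max_iter iteration cap; exceeding it is an error.
#' @param rescale `"max"` or `"l2"`.
#' @return the net with `hub` and `authority` columns added to `nodes`.
#' @export
hits_scores <- function(net, tol = 1e-10, max_iter = 1000,
                        rescale = c("max", "l2")) {
  stopifnot(inherits(net, "corr_net"))
  rescale <- match.arg(rescale)
  if (!net$directed) stop("HITS is defined on the directed network")
  if (nrow(net$edges) == 0) stop("directed network has no edges")
  ids <- net$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(match(net$edges$u, ids), match(net$edges$v, ids))] <- 1
  x <- rep(1 / sqrt(n), n)   # authority
  y <- rep(1 / sqrt(n), n)   # hub
  for (it in seq_len(max_iter)) {
    x_new <- drop(t(A) %*% y)
    x_new <- x_new / sqrt(sum(x_new^2))
    y_new <- drop(A %*% x_new)
    y_new <- y_new / sqrt(sum(y_new^2))
    delta <- max(abs(x_new - x), abs(y_new - y))
    x <- x_new; y <- y_new
    if (delta < tol) {
      if (rescale == "max") {
        x <- x / max(x); y <- y / max(y)
      }
      net$nodes$authority <- x
      net$nodes$hub <- y
      return(net)
    }
  }
  stop("HITS did not converge in ", max_iter,
       " iterations (residual ", format(delta), ")")
}

#' Rank network nodes and flag the hub genus
#'
#' On a directed network, genera are ranked by hub score (top one flagged
#' `hub_genus`) and clinical nodes by authority. On an undirected network,
#' all nodes are ranked by betweenness.
#'
#' @param net a `corr_net` with centralities computed.
#' @return data.frame of ranked nodes with a `role` column.
#' @export
hub_report <- function(net) {
  nodes <- net$nodes
  if (nrow(nodes) == 0)
    return(data.frame(id = character(), type = character(),
                      score = numeric(), role = character()))
  if (net$directed) {
    if (is.null(nodes$hub)) stop("run hits_scores() first")
    genera <- nodes[nodes$type == "genus", ]
    genera <- genera[order(-genera$hub), ]
    genera$score <- genera$hub
    genera$role <- ""
    if (nrow(genera)) genera$role[1] <- "hub_genus"
    clin <- nodes[nodes$type == "clinical", ]
    clin <- clin[order(-clin$authority), ]
    clin$score <- clin$authority
    clin$role <- ""
    out <- rbind(genera[, c("id", "type", "score", "role")],
                 clin[, c("id", "type", "score", "role")])
  } else {
    if (is.null(nodes$betweenness)) stop("run betweenness_centrality() first")
    out <- nodes[order(-nodes$betweenness),
                 c("id", "type", "betweenness")]
    names(out)[3] <- "score"
    out$role <- ""
    if (nrow(out)) out$role[1] <- "hub_node"
  }
  rownames(out) <- NULL
  out
}
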