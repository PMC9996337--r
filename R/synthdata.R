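# Synthetic cohort generator: Dirichlet-multinomial counts over a genus
# panel, typed clinical variables, and Gaussian-copula association planting.
# Emulates a two-group (MCU/MUD) 16S study with three enterotype-like
# community types; all names and abundances are synthetic stand-ins.

#' Community template for the count generator
#'
#' A template describes one community type: per-genus mean proportions with
#' one dominant ("driver") genus boosted, and a Dirichlet concentration
#' controlling sample-to-sample variability (larger = less variable).
#'
#' @param taxon_names character vector of genus labels.
#' @param base_mean_abundance proportions per genus (renormalized after the
#'   boost).
#' @param dominant_genus genus whose mean is multiplied by `boost_factor`.
#' @param boost_factor multiplier >= 1.
#' @param dirichlet_concentration positive scalar.
#' @return a `community_template` list.
#' @export
community_template <- function(taxon_names, base_mean_abundance,
                               dominant_genus, boost_factor = 8,
                               dirichlet_concentration = 50) {
  stopifnot(length(taxon_names) == length(base_mean_abundance))
  if (boost_factor < 1) stop("boost_factor must be >= 1")
  if (dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be > 0")
  if (!dominant_genus %in% taxon_names)
    stop("dominant_genus '", dominant_genus, "' not in taxon_names")
  p <- base_mean_abundance / sum(base_mean_abundance)
  p[taxon_names == dominant_genus] <- p[taxon_names == dominant_genus] *
    boost_factor
  p <- p / sum(p)
  structure(list(taxon_names = taxon_names, mean = stats::setNames(p, taxon_names),
                 dominant_genus = dominant_genus, boost_factor = boost_factor,
                 concentration = dirichlet_concentration),
            class = "community_template")
}

# Genus panel: 30 named gut genera with means echoing a typical Western gut
# profile (Faecalibacterium/Bacteroides/Roseburia ~14-15% each), plus
# uniform filler genera to reach `n_genera`.
#' Default genus panel
#'
#' @param n_genera total number of genera (default 94).
#' @return named numeric vector of mean proportions summing to 1.
#' @export
default_genus_panel <- function(n_genera = 94) {
  top <- c(Faecalibacterium = 15.0, Bacteroides = 14.9, Roseburia = 14.3,
           Ruminococcus = 8.6, Megamonas = 6.7, Prevotella = 4.1,
           Lachnospira = 3.2, Blautia = 1.8, Coprococcus = 1.7,
           Dialister = 1.65,
           Bifidobacterium = 1.5, Collinsella = 1.4, Streptococcus = 1.3,
           Oscillospira = 1.2, Sutterella = 1.1, Parabacteroides = 1.0,
           Phascolarctobacterium = 0.95, Akkermansia = 0.9,
           Clostridium = 0.85, Dorea = 0.8, Coprobacillus = 0.75,
           Veillonella = 0.7, Haemophilus = 0.65, Fusobacterium = 0.6,
           Lactobacillus = 0.55, Escherichia = 0.5, Klebsiella = 0.45,
           Halomonas = 0.42, Devosia = 0.40, Succinivibrio = 0.38)
  if (n_genera < length(top)) stop("n_genera must be >= ", length(top))
  n_fill <- n_genera - length(top)
  fill <- stats::setNames(rep((100 - sum(top)) / max(n_fill, 1), n_fill),
                          sprintf("Genus%03d", seq_len(n_fill)))
  p <- c(top, fill)
  p / sum(p)
}

#' Default three-community configuration
#'
#' Three templates over the default genus panel whose drivers are Prevotella,
#' Ruminococcus and Bacteroides — the classical enterotype drivers.
#'
#' @param boost_factor driver boost (default 8, calibrated so the
#'   JSD/PAM/Calinski-Harabasz pipeline recovers k = 3 reliably).
#' @param dirichlet_concentration Dirichlet concentration (default 50).
#' @param n_genera panel size.
#' @return list of three `community_template`s.
#' @export
default_templates <- function(boost_factor = 8, dirichlet_concentration = 50,
                              n_genera = 94) {
  panel <- default_genus_panel(n_genera)
  lapply(c("Prevotella", "Ruminococcus", "Bacteroides"), function(g)
    community_template(names(panel), unname(panel), g, boost_factor,
                       dirichlet_concentration))
}

# lineage lookup for the named genera; filler genera get a generic
# Clostridiales lineage. Entirely synthetic scaffolding for taxonomy-aware
# steps (organelle filtering, rank aggregation).
genus_lineages <- function(genera) {
  known <- list(
    Bacteroides = c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae"),
    Prevotella = c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae"),
    Parabacteroides = c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Porphyromonadaceae"),
    Faecalibacterium = c("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae"),
    Ruminococcus = c("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae"),
    Oscillospira = c("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae"),
    Roseburia = c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae"),
    Blautia = c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae"),
    Coprococcus = c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae"),
    Dorea = c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae"),
    Lachnospira = c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae"),
    Clostridium = c("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae"),
    Megamonas = c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae"),
    Dialister = c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae"),
    Veillonella = c("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae"),
    Phascolarctobacterium = c("Firmicutes", "Negativicutes", "Selenomonadales", "Acidaminococcaceae"),
    Lactobacillus = c("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae"),
    Streptococcus = c("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae"),
    Coprobacillus = c("Firmicutes", "Erysipelotrichia", "Erysipelotrichales", "Erysipelotrichaceae"),
    Bifidobacterium = c("Actinobacteria", "Actinobacteria", "Bifidobacteriales", "Bifidobacteriaceae"),
    Collinsella = c("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae"),
    Akkermansia = c("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales", "Verrucomicrobiaceae"),
    Fusobacterium = c("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Fusobacteriaceae"),
    Sutterella = c("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Alcaligenaceae"),
    Escherichia = c("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae"),
    Klebsiella = c("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae"),
    Haemophilus = c("Proteobacteria", "Gammaproteobacteria", "Pasteurellales", "Pasteurellaceae"),
    Halomonas = c("Proteobacteria", "Gammaproteobacteria", "Oceanospirillales", "Halomonadaceae"),
    Succinivibrio = c("Proteobacteria", "Gammaproteobacteria", "Aeromonadales", "Succinivibrionaceae"),
    Devosia = c("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Hyphomicrobiaceae"))
  out <- t(vapply(genera, function(g) {
    mid <- if (g %in% names(known)) known[[g]] else
      c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae")
    c("Bacteria", mid, g, "")
  }, character(7)))
  colnames(out) <- RANKS
  out
}

dirichlet_multinomial <- function(mean, concentration, depth) {
  g <- stats::rgamma(length(mean), shape = mean * concentration)
  if (sum(g) == 0) g[which.max(mean)] <- 1
  as.integer(stats::rmultinom(1, depth, g / sum(g)))
}

#' Generate a synthetic count table, taxonomy and tree
#'
#' Each sample is a Dirichlet-multinomial draw from its community template at
#' a depth drawn uniformly from `depth_range`. Optionally each genus is split
#' into several ASV-level features (fixed within-genus weights) so
#' aggregation and tree-based metrics can be exercised; the tree is a random
#' coalescent over the features.
#'
#' @param templates list of [community_template()]s (all over the same panel).
#' @param n_per_template integer vector, samples per template.
#' @param depth_range integer interval `c(min, max)` (or a single depth).
#' @param seed integer seed; generation is reproducible given it.
#' @param asv_per_genus features per genus (default 1: features are genera).
#' @return list with `counts` (matrix, samples x features), `taxonomy`
#'   (data.frame), `tree` (`phylo`), and `template_id` (truth labels).
#' @export
generate_counts <- function(templates, n_per_template, depth_range = c(25000, 30000),
                            seed = 1, asv_per_genus = 1) {
  if (!length(templates)) stop("need at least one template")
  if (length(n_per_template) != length(templates))
    stop("n_per_template must match templates in length")
  if (any(n_per_template <= 0)) stop("n_per_template must be positive")
  if (length(depth_range) == 1) depth_range <- rep(depth_range, 2)
  if (any(depth_range <= 0)) stop("depth_range must be positive")
  set.seed(seed)
  genera <- templates[[1]]$taxon_names
  assignment <- rep(seq_along(templates), n_per_template)
  n <- length(assignment)
  depths <- if (depth_range[1] == depth_range[2]) rep(depth_range[1], n) else
    sample(seq(depth_range[1], depth_range[2]), n, replace = TRUE)
  counts <- t(vapply(seq_len(n), function(i) {
    tpl <- templates[[assignment[i]]]
    dirichlet_multinomial(tpl$mean, tpl$concentration, depths[i])
  }, integer(length(genera))))
  rownames(counts) <- sprintf("S%03d", seq_len(n))
  colnames(counts) <- genera

  if (asv_per_genus > 1) {
    m <- asv_per_genus
    split_w <- lapply(genera, function(g) {
      w <- stats::rgamma(m, 1); w / sum(w)
    })
    feat <- as.vector(t(outer(genera, seq_len(m),
                              function(g, j) sprintf("%s_ASV%02d", g, j))))
    big <- matrix(0L, n, length(feat), dimnames = list(rownames(counts), feat))
    for (k in seq_along(genera)) {
      cols <- (k - 1) * m + seq_len(m)
      for (i in seq_len(n))
        big[i, cols] <- as.integer(stats::rmultinom(1, counts[i, k],
                                                    split_w[[k]]))
    }
    counts <- big
    genus_of <- rep(genera, each = m)
  } else {
    genus_of <- genera
  }

  lin <- genus_lineages(genus_of)
  taxonomy <- data.frame(feature_id = colnames(counts), lin,
                         stringsAsFactors = FALSE)
  rownames(taxonomy) <- NULL
  tree <- ape::rcoal(ncol(counts), tip.label = colnames(counts))
  validate_count_table(counts)
  list(counts = counts, taxonomy = taxonomy, tree = tree,
       template_id = assignment)
}

#' Clinical variable specification
#'
#' @param facet_name variable name.
#' @param variable_kind `"binary"` (Bernoulli prevalence per group),
#'   `"count"` (Poisson mean per group) or `"continuous"` (Normal mean/sd
#'   per group).
#' @param mcu,mud per-group parameters: a probability for binary, a mean for
#'   count, `c(mean, sd)` for continuous.
#' @return a `clinical_spec` list.
#' @export
clinical_spec <- function(facet_name,
                          variable_kind = c("binary", "count", "continuous"),
                          mcu, mud) {
  variable_kind <- match.arg(variable_kind)
  if (variable_kind == "binary" &&
      (any(c(mcu, mud) < 0) || any(c(mcu, mud) > 1)))
    stop("binary prevalences must lie in [0, 1]")
  structure(list(facet_name = facet_name, kind = variable_kind,
                 mcu = mcu, mud = mud), class = "clinical_spec")
}

#' Default clinical panel
#'
#' Binary facet prevalences, count means and continuous parameters emulating
#' a two-group stimulant-use cohort: MUD participants show high rates of
#' loss-of-control, craving/tolerance and withdrawal facets that are rare or
#' absent among casual users.
#'
#' @return named list of [clinical_spec()]s.
#' @export
default_clinical_specs <- function() {
  b <- function(name, mcu, mud) clinical_spec(name, "binary", mcu, mud)
  specs <- list(
    b("inability_to_stop",      0.000, 0.524),
    b("intention_to_use",       0.000, 0.571),
    b("increased_tolerance",    0.000, 0.476),
    b("paranoia",               0.000, 0.238),
    b("depression",             0.000, 0.238),
    b("fatigue",                0.143, 0.810),
    b("drowsiness",             0.143, 0.810),
    b("increased_appetite",     0.048, 0.667),
    b("risky_behaviors",        0.095, 0.571),
    b("neglect_responsibilities", 0.000, 0.571),
    b("reduced_social_activities", 0.000, 0.571),
    b("reduced_contact",        0.048, 0.571),
    b("problems_friends_family", 0.524, 0.857),
    b("craving",                0.095, 0.619),
    b("daily_use",              0.048, 0.524),
    clinical_spec("mud_criteria_count", "count", 0.3, 7),
    clinical_spec("withdrawal_episodes", "count", 0.1, 1),
    clinical_spec("years_of_use", "count", 0.3, 2),
    clinical_spec("age", "continuous", c(37, 5), c(36, 7)),
    clinical_spec("bmi", "continuous", c(23.5, 2.5), c(23.8, 2.8)))
  stats::setNames(specs, vapply(specs, `[[`, "", "facet_name"))
}

#' Generate a synthetic clinical frame
#'
#' @param specs list of [clinical_spec()]s.
#' @param n_per_group samples per group (exact group sizes).
#' @param seed integer seed.
#' @param sample_id optional ids (length `2 * n_per_group`, MCU block first).
#' @return a [clinical_frame()] with groups `MCU` and `MUD`.
#' @export
generate_clinical <- function(specs, n_per_group, seed = 1,
                              sample_id = NULL) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  set.seed(seed)
  n <- n_per_group
  group <- rep(c("MCU", "MUD"), each = n)
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_len(2 * n))
  vars <- list()
  kinds <- character()
  for (sp in specs) {
    draw <- function(par, kind) {
      switch(kind,
        binary = stats::rbinom(n, 1, par),
        count = stats::rpois(n, par[1]),
        continuous = stats::rnorm(n, par[1], par[2]))
    }
    if (!sp$kind %in% c("binary", "count", "continuous"))
      stop("unknown variable_kind '", sp$kind, "'")
    vars[[sp$facet_name]] <- c(draw(sp$mcu, sp$kind), draw(sp$mud, sp$kind))
    kinds[sp$facet_name] <- sp$kind
  }
  clinical_frame(sample_id, group, vars, kinds)
}

#' Planted genus-trait association
#'
#' @param genus genus label.
#' @param trait clinical variable name.
#' @param target_spearman desired population Spearman, |rho| < 1.
#' @return a `planted_association` list.
#' @export
planted_association <- function(genus, trait, target_spearman) {
  if (abs(target_spearman) >= 1)
    stop("|target_spearman| must be < 1")
  structure(list(genus = genus, trait = trait, target = target_spearman),
            class = "planted_association")
}

#' Plant a Spearman association between a genus and a clinical trait
#'
#' Regenerates the trait via a Gaussian copula against the genus's abundance
#' ranks: the latent Pearson parameter is `r = 2*sin(pi*rho/6)`, so the
#' population Spearman of the (latent-)continuous pair equals the target.
#' Continuous traits take the latent directly (rescaled to the old trait's
#' location/scale); count traits are discretized onto an ordinal scale of
#' `n_levels` equiprobable bins (default 12, a 0-11 score), which attenuates
#' the realized Spearman only slightly. Binary traits are refused: exact
#' planting is impossible after dichotomization (set `allow_binary = TRUE`
#' for the attenuated variant that thresholds the latent at the trait's
#' prevalence quantile).
#'
#' @param rel relative-abundance matrix (samples x genera).
#' @param frame clinical frame covering the same samples.
#' @param assoc a [planted_association()].
#' @param seed integer seed.
#' @param n_levels ordinal levels used for count traits.
#' @param allow_binary allow the attenuated binary procedure.
#' @return the modified clinical frame.
#' @export
plant_association <- function(rel, frame, assoc, seed = 1, n_levels = 12,
                              allow_binary = FALSE) {
  stopifnot(inherits(assoc, "planted_association"))
  if (!assoc$genus %in% colnames(rel))
    stop("genus '", assoc$genus, "' not in abundance table")
  kinds <- clinical_kinds(frame)
  if (!assoc$trait %in% names(kinds))
    stop("trait '", assoc$trait, "' not in clinical frame")
  kind <- kinds[[assoc$trait]]
  if (kind == "binary" && !allow_binary)
    stop("binary trait '", assoc$trait, "': exact-target planting needs a ",
         "trait with >= 5 levels; use allow_binary = TRUE for the ",
         "attenuated (dichotomized-latent) procedure")
  if (kind == "count" && n_levels < 5)
    stop("ordinal planting needs >= 5 levels")
  idx <- match(frame$sample_id, rownames(rel))
  if (any(is.na(idx))) stop("clinical frame samples missing from table")
  a <- rel[idx, assoc$genus]
  set.seed(seed)
  n <- length(a)
  r <- 2 * sin(pi * assoc$target / 6)
  u <- stats::qnorm((rank(a, ties.method = "average") - 0.5) / n)
  latent <- r * u + sqrt(1 - r^2) * stats::rnorm(n)
  old <- frame[[assoc$trait]]
  new_val <- switch(kind,
    continuous = {
      s <- stats::sd(old)
      m <- mean(old)
      if (is.na(s) || s == 0) { s <- 1; m <- 0 }
      m + s * latent
    },
    count = pmin(n_levels - 1L, floor(stats::pnorm(latent) * n_levels)),
    binary = as.integer(latent > stats::quantile(latent, 1 - mean(old))))
  frame[[assoc$trait]] <- new_val
  frame
}

#' Simulate a full two-group cohort
#'
#' Convenience wrapper tying the pieces together: community-type membership
#' is drawn per sample with group-conditional probabilities (community type 2
#' over-represented in the MUD group by default), counts come from
#' [generate_counts()], clinical variables from [generate_clinical()], and
#' any requested associations are planted on the relative abundances.
#'
#' @param n_per_group samples per group.
#' @param seed integer seed (substreams for counts/clinical/planting are
#'   derived from it).
#' @param templates community templates (default [default_templates()]).
#' @param specs clinical specs (default [default_clinical_specs()]).
#' @param enterotype_prob 2 x k matrix of group-conditional community-type
#'   probabilities, rows MCU/MUD.
#' @param associations list of [planted_association()]s.
#' @param depth_range,asv_per_genus passed to [generate_counts()].
#' @return list with `counts`, `taxonomy`, `tree`, `frame`,
#'   `enterotype_truth` (named integer vector).
#' @export
simulate_cohort <- function(n_per_group = 21, seed = 1,
                            templates = default_templates(),
                            specs = default_clinical_specs(),
                            enterotype_prob = rbind(
                              MCU = c(0.333, 0.286, 0.381),
                              MUD = c(0.190, 0.619, 0.190)),
                            associations = list(),
                            depth_range = c(25000, 30000),
                            asv_per_genus = 1) {
  set.seed(seed)
  k <- length(templates)
  group <- rep(c("MCU", "MUD"), each = n_per_group)
  et <- vapply(group, function(g)
    sample.int(k, 1, prob = enterotype_prob[g, ]), integer(1))
  # generate per-template blocks, then reorder to the per-sample assignment
  ord <- order(et)
  n_per_template <- tabulate(et, k)
  keep <- n_per_template > 0
  gen <- generate_counts(templates[keep], n_per_template[keep], depth_range,
                         seed = (seed * 7 + 1) %% .Machine$integer.max,
                         asv_per_genus = asv_per_genus)
  counts <- gen$counts
  counts[ord, ] <- counts        # row i of block order -> sample ord[i]
  rownames(counts) <- sprintf("S%03d", seq_along(group))
  frame <- generate_clinical(specs, n_per_group,
                             seed = (seed * 7 + 2) %% .Machine$integer.max,
                             sample_id = rownames(counts))
  rel <- sweep(counts, 1, rowSums(counts), "/")
  for (i in seq_along(associations))
    frame <- plant_association(rel, frame, associations[[i]],
                               seed = (seed * 7 + 2 + i) %% .Machine$integer.max)
  list(counts = counts, taxonomy = gen$taxonomy, tree = gen$tree,
       frame = frame,
       enterotype_truth = stats::setNames(et, rownames(counts)))
}

#' Monte-Carlo recovery of a planted Spearman association
#'
#' Draws `n` genus-abundance values per replicate from the continuous layer
#' of the Dirichlet model (the gamma-distributed proportions underlying the
#' counts, which are tie-free), plants the trait with [plant_association()],
#' and estimates Spearman's rho with the network module's estimator. The
#' mean over replicates recovers the target up to finite-n bias for
#' continuous traits, and up to a small additional discretization
#' attenuation for ordinal traits. Note that planting against *realized
#' counts* of a rare genus instead attenuates the coefficient further,
#' because tied zero counts compress the ranks.
#'
#' @param target target Spearman coefficient.
#' @param n pairs per replicate (default 42).
#' @param n_reps replicates (default 200).
#' @param trait_kind `"continuous"` or `"count"` (ordinal `n_levels` scale).
#' @param n_levels ordinal levels for count traits (default 12, a 0-11
#'   score).
#' @param genus genus whose abundance model is used (default Devosia).
#' @param template community template supplying the genus's gamma shape.
#' @param seed integer seed.
#' @return list with `mean_rho`, `rho` (per-replicate), `n`, `n_reps`.
#' @export
planted_recovery <- function(target, n = 42, n_reps = 200,
                             trait_kind = c("continuous", "count"),
                             n_levels = 12, genus = "Devosia",
                             template = default_templates()[[1]],
                             seed = 1) {
  trait_kind <- match.arg(trait_kind)
  shape <- template$concentration * template$mean
  rho <- vapply(seq_len(n_reps), function(rep) {
    set.seed((seed * 1000 + rep) %% .Machine$integer.max)
    g <- matrix(stats::rgamma(n * length(shape), shape = rep(shape, each = n)),
                nrow = n)
    rel <- g / rowSums(g)
    colnames(rel) <- names(shape)
    rownames(rel) <- sprintf("S%03d", seq_len(n))
    trait0 <- if (trait_kind == "continuous") stats::rnorm(n) else
      stats::rpois(n, 3)
    frame <- clinical_frame(rownames(rel), rep(c("MCU", "MUD"), length.out = n),
                            variables = list(trait = trait0),
                            kinds = c(trait = trait_kind))
    planted <- plant_association(rel, frame,
                                 planted_association(genus, "trait", target),
                                 seed = (seed * 1000 + rep + 1) %%
                                   .Machine$integer.max,
                                 n_levels = n_levels)
    sm <- spearman_matrix(cbind(abund = rel[, genus],
                                trait = as.numeric(planted$trait)))
    sm$rho["abund", "trait"]
  }, 0)
  list(mean_rho = mean(rho), rho = rho, n = n, n_reps = n_reps)
}
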