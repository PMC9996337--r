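# Clinical statistics battery: chi-square / Fisher for categorical
# variables, Wilcoxon rank-sum for continuous ones, the pooled
# two-proportion z-test for percentages, and greedy propensity matching.

#' Compare a categorical variable between two groups
#'
#' Pearson chi-square without continuity correction by default, switching to
#' Fisher's exact test (two-sided, hypergeometric point-probability rule)
#' when any observed cell is <= 5. The method actually used is recorded in
#' the result.
#'
#' @param counts 2 x C contingency table of non-negative integers (groups in
#'   rows).
#' @param method `"auto"` (small-cell switch), or force `"chi_square"` /
#'   `"fisher_exact"`.
#' @return list with `method`, `statistic` (NA for Fisher), `p`, `table`.
#' @export
compare_categorical <- function(counts,
                                method = c("auto", "chi_square",
                                           "fisher_exact")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  if (method == "auto")
    method <- if (any(counts <= 5)) "fisher_exact" else "chi_square"
  if (method == "chi_square") {
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(method = "chi_square", statistic = unname(ht$statistic),
         p = ht$p.value, table = counts)
  } else {
    ht <- stats::fisher.test(counts)
    list(method = "fisher_exact", statistic = NA_real_, p = ht$p.value,
         table = counts)
  }
}

#' Compare a continuous variable between two groups
#'
#' Two-sided Wilcoxon rank-sum with tie correction; group medians and
#' quartiles use the linear-interpolation quantile rule and are reported as
#' "median (Q1, Q3)".
#'
#' @param values numeric vector.
#' @param groups two-level label per value.
#' @return list with `method`, `statistic`, `p`, per-group `summary`.
#' @export
compare_continuous <- function(values, groups) {
  res <- compare_alpha(values, groups)
  res$method <- "wilcoxon"
  res
}

#' Pooled two-proportion z-test
#'
#' Two-sided z-test on `x1/n1` vs `x2/n2` with the pooled variance estimate
#' and no continuity correction; the squared statistic equals the 2x2
#' Pearson chi-square exactly.
#'
#' @param x1,n1,x2,n2 successes and totals per group.
#' @param pooled use the pooled variance (default TRUE; unpooled available).
#' @return list with `method`, `statistic` (z), `p`, per-group proportions.
#' @export
compare_proportions <- function(x1, n1, x2, n2, pooled = TRUE) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("successes must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  se <- if (pooled) {
    p <- (x1 + x2) / (n1 + n2)
    sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  } else {
    sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(method = "z_pooled", statistic = z,
       p = 2 * stats::pnorm(-abs(z)),
       proportions = c(p1 = p1, p2 = p2))
}

standardized_mean_diff <- function(x, g) {
  m <- tapply(x, g, mean); v <- tapply(x, g, stats::var)
  s <- sqrt(mean(v))
  if (is.na(s) || s == 0)
    return(if (isTRUE(all.equal(m[1], m[2]))) 0 else Inf)
  unname(abs(m[1] - m[2]) / s)
}

#' Greedy propensity-score matching
#'
#' Fits a logistic model of group membership on the covariates, then matches
#' each treated (second-level group) sample 1:1 to the nearest-score
#' untreated sample without replacement, processing treated samples in
#' descending score order. Standardized mean differences before and after
#' matching are reported per covariate.
#'
#' @param frame clinical frame.
#' @param covariates covariate column names (default age and bmi).
#' @param caliper optional maximum score distance for a valid match.
#' @return list with `matched` (clinical frame subset), `pairs`
#'   (data.frame), `balance` (SMD before/after), `warnings`.
#' @export
propensity_match <- function(frame, covariates = c("age", "bmi"),
                             caliper = NULL) {
  if (!all(covariates %in% names(frame)))
    stop("missing covariates: ",
         paste(setdiff(covariates, names(frame)), collapse = ", "))
  g <- as.factor(frame$group)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("two non-empty groups required")
  X <- as.data.frame(frame)[, covariates, drop = FALSE]
  fit <- stats::glm(g ~ ., data = cbind(X, g = g), family = stats::binomial())
  score <- stats::fitted(fit)
  treated <- which(g == levels(g)[2])
  control <- which(g == levels(g)[1])
  treated <- treated[order(score[treated], decreasing = TRUE)]
  used <- logical(length(score))
  pairs <- list()
  for (t in treated) {
    avail <- control[!used[control]]
    if (!length(avail)) break
    d <- abs(score[avail] - score[t])
    j <- avail[which.min(d)]
    if (!is.null(caliper) && min(d) > caliper) next
    used[j] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(
      treated = frame$sample_id[t], control = frame$sample_id[j],
      distance = min(d), stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated = character(), control = character(),
               distance = numeric())
  if (nrow(pairs) < length(treated))
    warning("only ", nrow(pairs), " of ", length(treated),
            " treated samples matched")
  keep <- frame$sample_id %in% c(pairs$treated, pairs$control)
  matched <- frame[keep, , drop = FALSE]
  attr(matched, "kinds") <- clinical_kinds(frame)
  class(matched) <- class(frame)
  smd <- function(f) vapply(covariates, function(v)
    standardized_mean_diff(f[[v]], as.factor(f$group)), 0)
  balance <- data.frame(covariate = covariates, smd_before = smd(frame),
                        smd_after = if (nrow(pairs)) smd(matched) else NA_real_,
                        row.names = NULL)
  if (nrow(pairs) && any(balance$smd_after > 0.25, na.rm = TRUE))
    warning("post-match imbalance remains (SMD > 0.25) for: ",
            paste(balance$covariate[balance$smd_after > 0.25],
                  collapse = ", "))
  list(matched = matched, pairs = pairs, balance = balance)
}

#' Run the clinical battery over a frame
#'
#' Dispatches per declared kind: binary facets through the pooled
#' two-proportion z-test, categorical through chi-square/Fisher, count and
#' continuous through Wilcoxon. Uses pairwise-complete observations.
#'
#' @param frame clinical frame.
#' @param facets variables to test (default: all typed variables).
#' @return data.frame with one row per facet: kind, method, per-group
#'   summary, statistic, p.
#' @export
clinical_battery <- function(frame, facets = names(clinical_kinds(frame))) {
  kinds <- clinical_kinds(frame)
  g <- as.factor(frame$group)
  lv <- levels(g)
  do.call(rbind, lapply(facets, function(v) {
    x <- frame[[v]]
    ok <- !is.na(x)
    xi <- x[ok]; gi <- droplevels(g[ok])
    res <- switch(kinds[[v]],
      binary = {
        n1 <- sum(gi == lv[1]); n2 <- sum(gi == lv[2])
        r <- compare_proportions(sum(xi[gi == lv[1]]), n1,
                                 sum(xi[gi == lv[2]]), n2)
        r$summary <- sprintf("%d/%d (%.1f%%)",
                             c(sum(xi[gi == lv[1]]), sum(xi[gi == lv[2]])),
                             c(n1, n2), 100 * r$proportions)
        r
      },
      categorical = {
        r <- compare_categorical(table(gi, xi))
        r$summary <- c("", "")
        r
      },
      compare_continuous(xi, gi))
    data.frame(facet = v, kind = kinds[[v]], method = res$method,
               summary_1 = res$summary[1], summary_2 = res$summary[2],
               statistic = res$statistic, p = res$p,
               stringsAsFactors = FALSE)
  }))
}
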