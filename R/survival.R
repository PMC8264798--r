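#' Two-group k-means stratification of samples by module expression
#'
#' Features are per-gene z-scores of `log2(x + pseudocount)` (so that
#' high-abundance classes do not dominate the distance). k-means uses Lloyd
#' iterations from deterministic greedy farthest-first starts: each of 10
#' restarts seeds its first center at a (seeded) random sample and the second
#' at the sample farthest from it; the restart with the lowest total
#' within-cluster sum of squares wins (ties: first). Labels are canonicalized
#' so group 1 has the higher mean module expression.
#'
#' @param expr_submat Module genes x samples matrix (raw abundance).
#' @param k Number of groups (2 for the survival contrast).
#' @param seed Integer seed for the restart draws.
#' @param pseudocount Added before log2.
#' @return Integer vector of labels in `{1, 2}`, named by sample.
#' @export
kmeans_stratify <- function(expr_submat, k = 2, seed = 1L, pseudocount = 0.01) {
  stopifnot(is.matrix(expr_submat))
  n <- ncol(expr_submat)
  if (n < k) stopf("cannot split %d samples into %d groups", n, k)
  lmat <- log2p(expr_submat, pseudocount)
  sds <- apply(lmat, 1, sd)
  if (all(sds == 0)) stopf("no expression variation to cluster on")
  lmat <- lmat[sds > 0, , drop = FALSE]
  feats <- t(scale(t(lmat)))           # genes x samples, z per gene
  x <- t(feats)                        # samples x genes
  set.seed(seed)
  best <- NULL
  for (restart in 1:10) {
    c1 <- x[sample(n, 1), , drop = FALSE]
    d1 <- rowSums(sweep(x, 2, c1, "-")^2)
    c2 <- x[which.max(d1), , drop = FALSE]
    if (all(c1 == c2)) stopf("no expression variation to cluster on")
    km <- suppressWarnings(
      kmeans(x, centers = rbind(c1, c2), algorithm = "Lloyd", iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- best$cluster
  # canonical orientation: group 1 = higher mean module expression
  m1 <- mean(lmat[, labels == 1])
  m2 <- mean(lmat[, labels == 2])
  if (m2 > m1) labels <- 3L - labels
  setNames(as.integer(labels), colnames(expr_submat))
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times Non-negative follow-up times.
#' @param events 1 = death observed, 0 = censored.
#' @return Data.frame step function with columns `time`, `n_risk`, `n_event`,
#'   `surv`, starting at `S(0) = 1`.
#' @export
km_estimator <- function(times, events) {
  if (length(times) == 0) stopf("no observations")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(times), fit$n.risk),
             n_event = c(0, fit$n.event),
             surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time, observed minus expected
#' events in group 1 under the hypergeometric distribution (ties handled by
#' its variance); `chi^2 = (sum(O1 - E1))^2 / sum(V)` on 1 df.
#'
#' @param times,events Follow-up data as in [km_estimator()].
#' @param labels Group labels (exactly 2 distinct values).
#' @return List `chi_square`, `p`.
#' @export
logrank_test <- function(times, events, labels) {
  stopifnot(length(times) == length(events), length(times) == length(labels))
  if (length(unique(labels)) != 2) stopf("log-rank needs exactly 2 groups")
  if (sum(events) < 1)
    stopf("log-rank statistic undefined with zero observed events")
  sd_fit <- survival::survdiff(
    survival::Surv(times, events) ~ g,
    data = data.frame(times = times, events = events, g = factor(labels)))
  chi <- unname(sd_fit$chisq)
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Tumor-vs-normal test of module expression
#'
#' Per-sample module score (mean `log2(x + pseudocount)` over the module's
#' RNAs), compared between conditions by a two-sided Wilcoxon rank-sum test
#' (exact when the combined n is at most 20 and untied, normal approximation
#' with tie correction otherwise). Direction is the sign of the median
#' difference (tumor minus normal).
#'
#' @param module A module (or character vector of gene ids).
#' @param expr_bundle Expression bundle.
#' @param samples Sample table.
#' @param pseudocount Added before log2.
#' @return List `statistic` (U for the tumor group), `p`, `direction`.
#' @export
module_expression_test <- function(module, expr_bundle, samples,
                                   pseudocount = 0.01) {
  score <- module_score(module, expr_bundle, pseudocount)
  cond <- samples$condition[match(names(score), samples$sample_id)]
  xs <- score[cond == "tumor"]
  ys <- score[cond == "normal"]
  if (length(xs) == 0 || length(ys) == 0)
    stopf("both conditions must be present")
  exact <- (length(xs) + length(ys)) <= 20 &&
    !anyDuplicated(c(xs, ys))
  ht <- suppressWarnings(wilcox.test(xs, ys, exact = exact))
  md <- median(xs) - median(ys)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       direction = if (md > 0) "up" else if (md < 0) "down" else "none")
}

#' Survival stratification of one module
#'
#' Tumor samples with complete survival data (missing ones are excluded with
#' a message) are split into two groups by [kmeans_stratify()] on the
#' module's expression; the groups are compared by [logrank_test()] and
#' summarized with per-group Kaplan-Meier curves.
#'
#' @param module A module (or character vector of gene ids).
#' @param expr_bundle Expression bundle.
#' @param samples Sample table with `survival_days` and `event`.
#' @param seed Seed for the k-means restarts.
#' @param pseudocount Added before log2.
#' @return A `stratification` list: `module_id`, `labels`, `group_sizes`,
#'   `chi_square`, `p_logrank`, `km_curves` (list of two KM data.frames).
#' @export
stratify_module <- function(module, expr_bundle, samples, seed = 1L,
                            pseudocount = 0.01) {
  genes <- if (is.character(module)) module else module_nodes(module)
  expr <- rbind(expr_bundle$mrna, expr_bundle$lncrna, expr_bundle$mirna)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0)
    stopf("module RNA '%s' absent from the expression matrices", missing[1])
  tum <- samples[samples$condition == "tumor", , drop = FALSE]
  usable <- !is.na(tum$survival_days) & !is.na(tum$event)
  if (sum(!usable) > 0)
    message(sprintf("excluding %d tumor sample(s) with missing survival",
                    sum(!usable)))
  tum <- tum[usable, , drop = FALSE]
  sub <- expr[genes, tum$sample_id, drop = FALSE]
  labels <- kmeans_stratify(sub, k = 2, seed = seed, pseudocount = pseudocount)
  lr <- logrank_test(tum$survival_days, tum$event, labels)
  km <- lapply(1:2, function(g)
    km_estimator(tum$survival_days[labels == g], tum$event[labels == g]))
  structure(list(module_id = if (is.list(module)) module$module_id else NULL,
                 labels = labels,
                 group_sizes = as.integer(table(factor(labels, 1:2))),
                 chi_square = lr$chi_square, p_logrank = lr$p,
                 km_curves = km),
            class = "stratification")
}
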