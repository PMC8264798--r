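#' Top co-expressed mRNAs of a set of ncRNAs
#'
#' For every (ncRNA, mRNA) pair the Pearson correlation is computed across
#' shared samples; correlations are averaged per mRNA over the ncRNA set and
#' the `top_n` mRNAs by descending average r (ties broken lexicographically)
#' are returned. With `absolute = TRUE` the average of `|r|` is ranked
#' instead.
#'
#' @param ncrna_ids ncRNAs defining the query set.
#' @param ncrna_expr,mrna_expr Expression matrices sharing sample columns.
#' @param top_n Number of partners to return (default 500); fewer are
#'   returned, flagged `short`, when the mRNA pool is smaller.
#' @param absolute Rank by average `|r|` instead of signed average r.
#' @return Data.frame `gene_id`, `avg_r`, ordered; attribute `short` is TRUE
#'   when fewer than `top_n` mRNAs were available.
#' @export
coexpression_partners <- function(ncrna_ids, ncrna_expr, mrna_expr,
                                  top_n = 500, absolute = FALSE) {
  if (!identical(colnames(ncrna_expr), colnames(mrna_expr)))
    stopf("expression matrices must share sample columns")
  if (ncol(mrna_expr) < 3) stopf("need at least 3 samples")
  missing <- setdiff(ncrna_ids, rownames(ncrna_expr))
  if (length(missing) > 0) stopf("ncRNA '%s' absent from matrix", missing[1])
  nc <- ncrna_expr[ncrna_ids, , drop = FALSE]
  keep_nc <- apply(nc, 1, sd) > 0
  keep_m <- apply(mrna_expr, 1, sd) > 0
  if (!all(keep_nc) || !all(keep_m))
    warning(sprintf("dropping %d constant expression row(s)",
                    sum(!keep_nc) + sum(!keep_m)))
  nc <- nc[keep_nc, , drop = FALSE]
  mr <- mrna_expr[keep_m, , drop = FALSE]
  if (nrow(nc) == 0 || nrow(mr) == 0) stopf("no non-constant rows left")
  cc <- cor(t(mr), t(nc))                       # mRNA x ncRNA
  avg <- rowMeans(if (absolute) abs(cc) else cc)
  ord <- order(-avg, names(avg))
  out <- data.frame(gene_id = names(avg)[ord], avg_r = unname(avg[ord]),
                    stringsAsFactors = FALSE)
  short <- nrow(out) < top_n
  if (short) message(sprintf("only %d mRNAs available for top_n = %d",
                             nrow(out), top_n))
  out <- head(out, top_n)
  rownames(out) <- NULL
  attr(out, "short") <- short
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail p: probability of an overlap at least as large as observed when
#' `n` genes are drawn from a universe of `N` containing `K` set members.
#'
#' @param query Character vector of query genes (subset of universe).
#' @param gene_set Character vector of set members (subset of universe).
#' @param universe Character vector of background genes.
#' @return One-row data.frame `k`, `K`, `n`, `N`, `p`.
#' @export
ora_hypergeometric <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  query <- unique(query)
  gene_set <- unique(gene_set)
  if (!all(query %in% universe) || !all(gene_set %in% universe))
    stopf("query and gene set must be subsets of the universe")
  k <- length(intersect(query, gene_set))
  K <- length(gene_set)
  n <- length(query)
  N <- length(universe)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, K = K, n = n, N = N, p = p)
}

#' Over-representation analysis across a gene-set collection
#'
#' @param query Query gene ids.
#' @param sets Named list of gene sets.
#' @param universe Background gene ids.
#' @return Data.frame with one row per set (`set_name`, `k`, `K`, `n`, `N`,
#'   `p`, `q`), BH-adjusted across the collection.
#' @export
ora_collection <- function(query, sets, universe) {
  rows <- lapply(names(sets), function(nm) {
    r <- ora_hypergeometric(query, intersect(sets[[nm]], universe), universe)
    cbind(set_name = nm, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Preranked gene set enrichment (GSEA)
#'
#' Genes are ordered by decreasing weight; the running sum gains
#' `|w| / sum(|w| over members)` at member positions and loses `1 / (N - K)`
#' at non-member positions. ES is the maximum-deviation value of the walk.
#' The null distribution permutes gene labels (random member positions);
#' `p_perm = (1 + #{|ES_b| >= |ES|, same sign}) / (1 + n_perm)` and
#' `NES = ES / mean |same-sign null ES|`.
#'
#' @param weights Named numeric vector (ranking metric, e.g. log2FC).
#' @param gene_set Character vector of members; overlap with the ranking must
#'   be non-empty.
#' @param n_perm Number of gene-label permutations.
#' @param seed Integer seed for the permutations.
#' @return List `es`, `nes`, `p_perm`, `n_perm`.
#' @export
preranked_gsea <- function(weights, gene_set, n_perm = 1000, seed = 1L) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(!is.finite(weights))) stopf("weights must be finite")
  ord <- order(-weights, names(weights))
  w <- weights[ord]
  member <- names(w) %in% gene_set
  if (!any(member)) stopf("gene set has no overlap with the ranking")
  es_stat <- function(member) {
    inc <- abs(w) * member
    denom <- sum(inc)
    steps <- if (denom > 0) inc / denom else member / sum(member)
    n_out <- sum(!member)
    if (n_out > 0) steps <- steps - (!member) / n_out
    running <- cumsum(steps)
    unname(running[which.max(abs(running))])
  }
  es <- es_stat(member)
  N <- length(w)
  K <- sum(member)
  set.seed(seed)
  es_null <- vapply(seq_len(n_perm), function(b) {
    perm <- logical(N)
    perm[sample.int(N, K)] <- TRUE
    es_stat(perm)
  }, numeric(1))
  same <- sign(es_null) == sign(es)
  p <- (1 + sum(same & abs(es_null) >= abs(es))) / (1 + n_perm)
  denom <- mean(abs(es_null[same]))
  nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
  list(es = es, nes = nes, p_perm = p, n_perm = n_perm)
}

#' Single-sample GSEA score matrix
#'
#' Per sample, genes are ranked by expression (average ranks for ties; the
#' most abundant gene has rank N) and the enrichment score is the sum over
#' the full descending walk of the difference between the `rank^tau`-weighted
#' cumulative fraction of set members and the unweighted cumulative fraction
#' of non-members. Scores depend on within-sample ranks only, so they are
#' invariant to monotone transforms of a sample's expression. With
#' `normalize = TRUE` the whole matrix is divided by its range.
#'
#' @param expr Genes x samples expression matrix.
#' @param sets Named list of gene sets.
#' @param tau Rank-weighting exponent (0.25, the ssGSEA convention).
#' @param normalize Divide scores by `max - min` over the matrix.
#' @return A sets x samples `score_matrix` with attributes `method`, `tau`,
#'   `normalized`. Sets with no expressed member get NA scores (warning).
#' @export
ssgsea_scores <- function(expr, sets, tau = 0.25, normalize = TRUE) {
  check_expression_matrix(expr)
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  genes <- rownames(expr)
  member_mat <- vapply(sets, function(s) genes %in% s, logical(nrow(expr)))
  if (all(colSums(member_mat) == 0))
    stopf("no gene set has an expressed member")
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  N <- nrow(expr)
  for (s in seq_len(ncol(expr))) {
    rk <- rank(expr[, s], ties.method = "average")   # N = most abundant
    ordg <- order(-rk, genes)                        # descending walk
    wts <- rk[ordg]^tau
    for (j in seq_along(sets)) {
      mem <- member_mat[ordg, j]
      K <- sum(mem)
      if (K == 0) next
      p_in <- cumsum(wts * mem) / sum(wts * mem)
      p_out <- if (N - K > 0) cumsum(!mem) / (N - K) else rep(0, N)
      scores[j, s] <- sum(p_in - p_out)
    }
  }
  empty <- rowSums(!is.na(scores)) == 0
  if (any(empty))
    warning(sprintf("%d gene set(s) have no expressed member", sum(empty)))
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  structure(scores, method = "ssgsea", tau = tau, normalized = normalize)
}

#' Correlate a module's expression with pathway scores
#'
#' Pearson r and p per gene set between the per-sample module score and each
#' row of the score matrix. Pairs involving a constant vector are returned
#' with NA and flagged.
#'
#' @param module_scores Named per-sample module scores
#'   (see [module_score()]).
#' @param score_matrix Sets x samples matrix from [ssgsea_scores()].
#' @return Data.frame `set_name`, `r`, `p`, `undefined`.
#' @export
module_pathway_correlation <- function(module_scores, score_matrix) {
  shared <- intersect(names(module_scores), colnames(score_matrix))
  if (length(shared) < 3) stopf("need at least 3 shared samples")
  x <- module_scores[shared]
  rows <- lapply(rownames(score_matrix), function(nm) {
    y <- score_matrix[nm, shared]
    if (anyNA(y) || sd(y) == 0 || sd(x) == 0)
      return(data.frame(set_name = nm, r = NA_real_, p = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    ct <- pearson_with_p(x, y)
    data.frame(set_name = nm, r = ct$r, p = ct$p, undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate individual module RNAs with pathway scores
#'
#' Per-RNA analogue of [module_pathway_correlation()]: one correlation per
#' (module RNA, gene set) pair, using the RNA's log2 expression.
#'
#' @param module A module (or character vector of gene ids).
#' @param expr_bundle Expression bundle.
#' @param score_matrix Sets x samples score matrix.
#' @param pseudocount Added before log2.
#' @return Data.frame `gene_id`, `set_name`, `r`, `p`, `undefined`.
#' @export
rna_pathway_correlation <- function(module, expr_bundle, score_matrix,
                                    pseudocount = 0.01) {
  genes <- if (is.character(module)) module else module_nodes(module)
  expr <- rbind(expr_bundle$mrna, expr_bundle$lncrna, expr_bundle$mirna)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0)
    stopf("module RNA '%s' absent from the expression matrices", missing[1])
  rows <- lapply(genes, function(g) {
    tab <- module_pathway_correlation(
      log2p(expr[g, ], pseudocount)[colnames(expr)], score_matrix)
    cbind(gene_id = g, tab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare pathway scores between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test per gene set with BH adjustment across
#' sets.
#'
#' @param score_matrix Sets x samples matrix.
#' @param labels Group labels over the score matrix's samples (2 groups).
#' @return Data.frame `set_name`, `statistic`, `p`, `q`.
#' @export
compare_group_scores <- function(score_matrix, labels) {
  stopifnot(length(labels) == ncol(score_matrix))
  gl <- unique(labels)
  if (length(gl) != 2) stopf("need exactly 2 groups")
  if (min(table(labels)) < 1) stopf("one group is empty")
  rows <- lapply(rownames(score_matrix), function(nm) {
    x <- score_matrix[nm, labels == gl[1]]
    y <- score_matrix[nm, labels == gl[2]]
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    data.frame(set_name = nm, statistic = unname(ht$statistic),
               p = ht$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
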