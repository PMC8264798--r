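#' Differential-expression configuration
#'
#' Defaults follow the conventional two-gate rule: two-sided t-test p < 0.05
#' on log2-transformed abundance and linear-scale fold change > 2
#' (equivalently |log2FC| > 1). No multiple-testing correction is applied by
#' default; `adjust = "BH"` gates on Benjamini-Hochberg q instead.
#'
#' @param p_threshold Significance gate (exclusive).
#' @param fc_threshold Fold-change gate (exclusive), on
#'   `max(mean_tumor/mean_normal, mean_normal/mean_tumor)`.
#' @param min_expressed_fraction Minimum fraction of samples with non-zero
#'   expression for a gene to be tested (inclusive boundary).
#' @param pseudocount Added before log2 for the test statistic and to group
#'   means for the fold change.
#' @param adjust `"none"` or `"BH"`.
#' @return A `de_config` list.
#' @export
de_config <- function(p_threshold = 0.05, fc_threshold = 2,
                      min_expressed_fraction = 0.10, pseudocount = 0.01,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (p_threshold <= 0 || fc_threshold <= 0 || pseudocount < 0)
    stopf("thresholds must be positive")
  if (min_expressed_fraction < 0 || min_expressed_fraction > 1)
    stopf("min_expressed_fraction must be in [0,1]")
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 min_expressed_fraction = min_expressed_fraction,
                 pseudocount = pseudocount, adjust = adjust),
            class = "de_config")
}

#' Drop genes expressed in too few samples
#'
#' Retains exactly the genes with a value > 0 in at least `min_fraction` of
#' the samples; a gene non-zero in exactly the boundary fraction is retained.
#'
#' @param mat Genes x samples matrix.
#' @param min_fraction Fraction in [0,1].
#' @return The filtered matrix (same samples).
#' @export
filter_low_expression <- function(mat, min_fraction = 0.10) {
  check_expression_matrix(mat)
  keep <- rowMeans(mat > 0) >= min_fraction
  if (!any(keep)) warning("low-expression filter removed every gene")
  mat[keep, , drop = FALSE]
}

#' Welch two-sample t-test
#'
#' Two-sided p from the t distribution with Welch-Satterthwaite degrees of
#' freedom. Degenerate inputs follow a documented contract: both groups
#' constant with equal means gives `t = 0, p = 1`; both constant with unequal
#' means gives `t = +/-Inf, p = 0`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return Named list `t`, `p`, `df`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stopf("welch_t needs at least 2 observations per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = NA_real_))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Tumor-vs-normal differential expression
#'
#' For every gene: Welch t-test on `log2(x + pseudocount)`, fold change as the
#' max ratio of linear-scale group means (with pseudocount), and a direction
#' call (`up`/`down`/`ns`) from the joint p and fold-change gates.
#'
#' @param mat Genes x samples matrix (already low-expression filtered if
#'   desired; see [filter_low_expression()]).
#' @param samples Sample table with `sample_id` and `condition`.
#' @param cfg A [de_config()].
#' @return Data.frame with one row per gene: `gene_id`, `mean_tumor`,
#'   `mean_normal`, `fold_change`, `log2fc`, `t_stat`, `p`, `q`, `direction`.
#' @export
run_de <- function(mat, samples, cfg = de_config()) {
  check_expression_matrix(mat)
  stopifnot(inherits(cfg, "de_config"))
  idx <- match(colnames(mat), samples$sample_id)
  if (anyNA(idx)) stopf("samples table is missing ids present in the matrix")
  cond <- samples$condition[idx]
  t_cols <- which(cond == "tumor")
  n_cols <- which(cond == "normal")
  if (length(t_cols) < 3 || length(n_cols) < 3)
    stopf("need both conditions with at least 3 samples (have %d tumor, %d normal)",
          length(t_cols), length(n_cols))
  pc <- cfg$pseudocount
  lmat <- log2p(mat, pc)
  res <- lapply(seq_len(nrow(mat)), function(i) {
    wt <- welch_t(lmat[i, t_cols], lmat[i, n_cols])
    mt <- mean(mat[i, t_cols])
    mn <- mean(mat[i, n_cols])
    l2 <- log2((mt + pc) / (mn + pc))
    c(mt = mt, mn = mn, log2fc = l2, t = wt$t, p = wt$p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    gene_id = rownames(mat),
    mean_tumor = res[, "mt"], mean_normal = res[, "mn"],
    fold_change = 2^abs(res[, "log2fc"]), log2fc = res[, "log2fc"],
    t_stat = res[, "t"], p = res[, "p"],
    stringsAsFactors = FALSE)
  out$q <- if (cfg$adjust == "BH") p.adjust(out$p, "BH") else NA_real_
  p_gate <- if (cfg$adjust == "BH") out$q else out$p
  sig <- p_gate < cfg$p_threshold & out$fold_change > cfg$fc_threshold
  out$direction <- ifelse(!sig, "ns",
                          ifelse(out$mean_tumor > out$mean_normal, "up", "down"))
  rownames(out) <- NULL
  out
}

#' Extract the DE gene ids from a [run_de()] table
#' @param de A run_de result.
#' @return Character vector of gene ids with direction `up` or `down`.
#' @export
de_genes <- function(de) de$gene_id[de$direction != "ns"]
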