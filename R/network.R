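#' Keep miRNA-target pairs with AGO CLIP evidence
#'
#' @param catalog Interaction data.frame (`mirna_id`, `target_id`,
#'   `target_class`, `ago_sites`).
#' @param min_sites Minimum AGO binding sites (default 1: "at least one").
#' @return The filtered catalog (possibly empty).
#' @export
filter_ago <- function(catalog, min_sites = 1) {
  stopifnot(is.data.frame(catalog), "ago_sites" %in% names(catalog))
  catalog[catalog$ago_sites >= min_sites, , drop = FALSE]
}

#' Pearson correlation with two-sided p-value
#'
#' p is derived from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Constant vectors have undefined correlation and raise an error;
#' the network builder drops such pairs.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Named list `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) stopf("need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Build the dysregulated lncRNA-miRNA-mRNA network
#'
#' Three filters applied in order: (0) restrict the AGO-filtered catalog to
#' pairs where both the miRNA and the target are differentially expressed;
#' (1) keep pairs whose expression correlation across ALL samples (tumor and
#' normal pooled) passes `|r| > r_threshold` and `p < p_threshold` (strict
#' inequalities); (2) keep only miRNAs with at least one passing lncRNA edge
#' AND one passing mRNA edge (the shared-miRNA rule), dropping their edges
#' and any targets left isolated.
#'
#' @param de_bundle List of [run_de()] tables named `mrna`, `lncrna`, `mirna`.
#' @param catalog Interaction catalog (already AGO-filtered via
#'   [filter_ago()] if desired).
#' @param expr_bundle `expression_bundle` (or any list of the three matrices)
#'   sharing one sample set.
#' @param r_threshold,p_threshold Edge gates (exclusive).
#' @param require_negative If TRUE, additionally require `r < 0` (miRNA
#'   repression sign); off by default since the gate is on `|r|`.
#' @return A `dysregulated_network`: list with `nodes` (node_id, rna_class,
#'   direction) and `edges` (mirna_id, target_id, target_class, r, p).
#' @export
build_network <- function(de_bundle, catalog, expr_bundle,
                          r_threshold = 0.3, p_threshold = 0.01,
                          require_negative = FALSE) {
  stopifnot(all(c("mrna", "lncrna", "mirna") %in% names(de_bundle)))
  de_part <- function(d, cl)
    data.frame(gene_id = d$gene_id, direction = d$direction,
               class = rep(cl, nrow(d)), stringsAsFactors = FALSE)
  de_tab <- rbind(de_part(de_bundle$mrna, "mRNA"),
                  de_part(de_bundle$lncrna, "lncRNA"),
                  de_part(de_bundle$mirna, "miRNA"))
  de_tab <- de_tab[de_tab$direction != "ns", , drop = FALSE]

  expr <- rbind(expr_bundle$mrna, expr_bundle$lncrna, expr_bundle$mirna)
  samp <- colnames(expr_bundle$mrna)
  if (!identical(colnames(expr_bundle$lncrna), samp) ||
      !identical(colnames(expr_bundle$mirna), samp))
    stopf("expression matrices must share one sample set")

  # step 0: both endpoints DE (and present in expression)
  keep0 <- catalog$mirna_id %in% de_tab$gene_id[de_tab$class == "miRNA"] &
    catalog$target_id %in% de_tab$gene_id[de_tab$class != "miRNA"] &
    catalog$mirna_id %in% rownames(expr) &
    catalog$target_id %in% rownames(expr)
  cand <- catalog[keep0, , drop = FALSE]

  empty <- function() {
    warning("dysregulated network is empty")
    structure(list(
      nodes = data.frame(node_id = character(0), rna_class = character(0),
                         direction = character(0), stringsAsFactors = FALSE),
      edges = data.frame(mirna_id = character(0), target_id = character(0),
                         target_class = character(0), r = numeric(0),
                         p = numeric(0), stringsAsFactors = FALSE)),
      class = "dysregulated_network")
  }
  if (nrow(cand) == 0) return(empty())

  # step 1: correlation gate across all samples
  rp <- vapply(seq_len(nrow(cand)), function(i) {
    x <- expr[cand$mirna_id[i], ]
    y <- expr[cand$target_id[i], ]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- pearson_with_p(x, y)
    c(ct$r, ct$p)
  }, numeric(2))
  cand$r <- rp[1, ]
  cand$p <- rp[2, ]
  dropped_const <- sum(is.na(cand$r))
  if (dropped_const > 0)
    warning(sprintf("%d pair(s) dropped: constant expression", dropped_const))
  pass <- !is.na(cand$r) & abs(cand$r) > r_threshold & cand$p < p_threshold
  if (require_negative) pass <- pass & cand$r < 0
  edges <- cand[pass, , drop = FALSE]
  if (nrow(edges) == 0) return(empty())

  # step 2: shared-miRNA rule, then prune isolated targets
  has_lnc <- tapply(edges$target_class == "lncRNA", edges$mirna_id, any)
  has_mrna <- tapply(edges$target_class == "mRNA", edges$mirna_id, any)
  ok_mir <- names(has_lnc)[has_lnc & has_mrna[names(has_lnc)]]
  edges <- edges[edges$mirna_id %in% ok_mir, , drop = FALSE]
  if (nrow(edges) == 0) return(empty())

  node_ids <- unique(c(edges$mirna_id, edges$target_id))
  nodes <- data.frame(
    node_id = node_ids,
    rna_class = de_tab$class[match(node_ids, de_tab$gene_id)],
    direction = de_tab$direction[match(node_ids, de_tab$gene_id)],
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$mirna_id, edges$target_id),
                 c("mirna_id", "target_id", "target_class", "r", "p")]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "dysregulated_network")
}

#' Degree structure of the network
#'
#' Reports the fractions of nodes with degree below 5 and above 10 (the
#' scale-free sanity check) plus the full degree histogram.
#'
#' @param network A `dysregulated_network`.
#' @return List `frac_deg_lt5`, `frac_deg_gt10`, `histogram` (named table).
#' @export
degree_summary <- function(network) {
  stopifnot(inherits(network, "dysregulated_network"))
  if (nrow(network$nodes) == 0) stopf("network is empty")
  deg <- table(factor(c(network$edges$mirna_id, network$edges$target_id),
                      levels = network$nodes$node_id))
  list(frac_deg_lt5 = mean(deg < 5),
       frac_deg_gt10 = mean(deg > 10),
       histogram = table(as.integer(deg)))
}
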