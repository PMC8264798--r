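# Recovery metrics against a simulated cohort's planted ground truth.

#' Sensitivity and false-positive rate of DE calls against planted truth
#'
#' @param de_bundle List of [run_de()] tables named `mrna`, `lncrna`, `mirna`.
#' @param truth `truth` element of a [simulate_cohort()] result.
#' @return List `sensitivity`, `fpr`, `n_planted`, `n_null` (pooled over the
#'   three RNA classes, restricted to tested genes).
#' @export
de_recovery <- function(de_bundle, truth) {
  tp <- fp <- n_pl <- n_null <- 0
  for (cl in c("mrna", "lncrna", "mirna")) {
    de <- de_bundle[[cl]]
    planted <- truth$de_genes_by_class[[cl]]$gene_id
    called <- de_genes(de)
    tested_planted <- intersect(de$gene_id, planted)
    tested_null <- setdiff(de$gene_id, planted)
    tp <- tp + length(intersect(called, tested_planted))
    fp <- fp + length(intersect(called, tested_null))
    n_pl <- n_pl + length(tested_planted)
    n_null <- n_null + length(tested_null)
  }
  list(sensitivity = tp / n_pl, fpr = fp / n_null,
       n_planted = n_pl, n_null = n_null)
}

#' Precision and recall of network edges against planted regulon edges
#'
#' @param network A `dysregulated_network`.
#' @param truth Simulation truth (`true_edges`).
#' @return List `precision`, `recall`, `n_edges`, `n_true`.
#' @export
edge_recovery <- function(network, truth) {
  got <- paste(network$edges$mirna_id, network$edges$target_id)
  want <- paste(truth$true_edges$mirna_id, truth$true_edges$target_id)
  tp <- length(intersect(got, want))
  list(precision = if (length(got) > 0) tp / length(got) else NA_real_,
       recall = tp / length(want),
       n_edges = length(got), n_true = length(want))
}

#' Adjusted Rand index between detected and planted modules
#'
#' Nodes appearing in either partition are labelled by their module (detected
#' or planted); nodes present in only one partition become singletons on the
#' other side, so missed or extra nodes are penalized rather than pooled.
#'
#' @param module_set A [detect_modules()] result.
#' @param truth Simulation truth (`planted_modules`).
#' @return ARI in [-1, 1] (1 = identical partitions).
#' @export
module_recovery_ari <- function(module_set, truth) {
  det <- lapply(module_set, module_nodes)
  pla <- truth$planted_modules
  # truth re-read from JSON may arrive with equal-sized modules simplified
  # into a matrix (one row per module)
  if (is.matrix(pla)) pla <- split(pla, row(pla))
  all_nodes <- sort(unique(c(unlist(det), unlist(pla))))
  lab <- function(groups, prefix) {
    l <- setNames(paste0("solo_", prefix, "_", all_nodes), all_nodes)
    for (i in seq_along(groups)) l[groups[[i]]] <- paste0(prefix, i)
    l
  }
  mclust::adjustedRandIndex(lab(det, "d"), lab(pla, "p"))
}
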