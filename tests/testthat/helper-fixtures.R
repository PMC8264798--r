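# In-code fixtures shared across test files.

# A tiny expression bundle with chosen per-sample module scores: one gene per
# class whose log2 expression equals the desired score (so the mean module
# score is the score itself).
toy_bundle_with_scores <- function(scores, sample_ids = names(scores)) {
  one <- matrix(2^scores, nrow = 1, dimnames = list(NULL, sample_ids))
  bundle <- list(mrna = one, lncrna = one, mirna = one)
  rownames(bundle$mrna) <- "MG0001"
  rownames(bundle$lncrna) <- "LNC0001"
  rownames(bundle$mirna) <- "MIR0001"
  structure(bundle, class = "expression_bundle")
}

# Hand-built network: edges given as a data.frame; node classes inferred from
# id prefixes (MIR/LNC/MG).
toy_network <- function(edges) {
  ids <- unique(c(edges$mirna_id, edges$target_id))
  cls <- ifelse(startsWith(ids, "MIR"), "miRNA",
                ifelse(startsWith(ids, "LNC"), "lncRNA", "mRNA"))
  nodes <- data.frame(node_id = sort(ids),
                      rna_class = cls[order(ids)],
                      direction = "up", stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges),
            class = "dysregulated_network")
}

# A star: one miRNA hub with lncRNA and mRNA leaves, all edges at |r| = r.
toy_star <- function(hub, n_lnc, n_mrna, r = 0.9, prefix = "") {
  data.frame(
    mirna_id = hub,
    target_id = c(sprintf("LNC%s%02d", prefix, seq_len(n_lnc)),
                  sprintf("MG%s%02d", prefix, seq_len(n_mrna))),
    target_class = c(rep("lncRNA", n_lnc), rep("mRNA", n_mrna)),
    r = r, p = 1e-6, stringsAsFactors = FALSE)
}

# Small seeded cohort used where full default scale is unnecessary.
small_cohort <- function(seed = 7L, ...) {
  simulate_cohort(sim_config(n_mrna = 80, n_lncrna = 40, n_mirna = 20,
                             n_tumor = 30, n_normal = 12, frac_de = 0.3,
                             n_decoy_interactions = 60, seed = seed, ...))
}

# Random survival data with ties and censoring.
random_survival <- function(n, seed) {
  set.seed(seed)
  list(times = sample(1:15, n, replace = TRUE),
       events = rbinom(n, 1, 0.7),
       labels = sample(1:2, n, replace = TRUE))
}
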