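#!/usr/bin/env Rscript
# Stage 5: for each module, split the tumor samples in two by k-means on the
# module's expression, compare survival with the log-rank test, and test the
# module's tumor-vs-normal expression shift with the Wilcoxon rank-sum test.
# Writes results/survival.tsv and per-module Kaplan-Meier curves.

suppressPackageStartupMessages({library(dysnet); library(jsonlite)})

ann <- classify_biotypes("results/cohort/annotation.gtf")
bundle <- load_expression(
  file.path("results/cohort",
            c("mrna_expression.tsv", "lncrna_expression.tsv",
              "mirna_expression.tsv")), ann)
samples <- read_samples("results/cohort/samples.tsv")
mods <- jsonlite::read_json("results/modules.json", simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)

rows <- lapply(mods, function(m) {
  genes <- sort(unname(unlist(m$nodes)))
  st <- stratify_module(genes, bundle, samples, seed = 11L)
  et <- module_expression_test(genes, bundle, samples)
  km <- do.call(rbind, lapply(1:2, function(g)
    cbind(group = g, st$km_curves[[g]])))
  write.table(km, sprintf("results/km_%s.tsv", m$module_id), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: groups %d/%d, log-rank chi2 %.2f (p %.2e); tumor-vs-normal %s (rank-sum p %.2e)",
    m$module_id, st$group_sizes[1], st$group_sizes[2], st$chi_square,
    st$p_logrank, et$direction, et$p))
  data.frame(module_id = m$module_id, group1 = st$group_sizes[1],
             group2 = st$group_sizes[2], chi_square = st$chi_square,
             p_logrank = st$p_logrank, ranksum_p = et$p,
             expression_direction = et$direction)
})
write.table(do.call(rbind, rows), "results/survival.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
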