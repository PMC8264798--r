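#!/usr/bin/env Rscript
# Stage 6: gene-set level analyses. Over-representation of the DE mRNAs in
# the cohort's gene sets (hypergeometric), ssGSEA pathway activity per
# sample, module-pathway correlations, and pathway-score comparison between
# the two survival subpopulations of the first module.

suppressPackageStartupMessages({library(dysnet); library(jsonlite)})

ann <- classify_biotypes("results/cohort/annotation.gtf")
bundle <- load_expression(
  file.path("results/cohort",
            c("mrna_expression.tsv", "lncrna_expression.tsv",
              "mirna_expression.tsv")), ann)
samples <- read_samples("results/cohort/samples.tsv")
sets <- read_gmt("results/cohort/gene_sets.gmt")
truth <- jsonlite::read_json("results/cohort/truth.json", simplifyVector = TRUE)
de_mrna <- read.delim("results/de_mrna.tsv")
mods <- jsonlite::read_json("results/modules.json", simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)

## over-representation of DE mRNAs
ora <- ora_collection(de_genes(de_mrna), sets, de_mrna$gene_id)
ora <- ora[order(ora$p), ]
write.table(ora, "results/ora_de_mrna.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("ORA: %d/%d sets with q < 0.05 (planted enriched: %s)",
                sum(ora$q < 0.05), nrow(ora),
                paste(truth$enriched_sets, collapse = ", ")))
message(sprintf("top sets by p: %s",
                paste(head(ora$set_name, 3), collapse = ", ")))

## functional annotation of the DE lncRNAs by co-expression: the top 500
## co-expressed mRNAs stand in for the ncRNAs in the over-representation test
## (the downregulated lncRNAs, as the coherent direction set; top_n scaled to
## the cohort's 500-mRNA pool — a fixed 500 would swallow the whole universe)
de_lncrna <- read.delim("results/de_lncrna.tsv")
down_lnc <- de_lncrna$gene_id[de_lncrna$direction == "down"]
partners <- coexpression_partners(down_lnc, bundle$lncrna, bundle$mrna,
                                  top_n = 100)
ora_nc <- ora_collection(partners$gene_id, sets, rownames(bundle$mrna))
write.table(ora_nc[order(ora_nc$p), ], "results/ora_lncrna_partners.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("co-expression partners of %d down lncRNAs: top %d mRNAs; %d sets at q < 0.05",
                length(down_lnc), nrow(partners), sum(ora_nc$q < 0.05)))

## ssGSEA pathway activity
scores <- ssgsea_scores(bundle$mrna, sets, tau = 0.25)
write.table(data.frame(set_name = rownames(scores), scores,
                       check.names = FALSE),
            "results/ssgsea_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## module-pathway correlations
corr <- do.call(rbind, lapply(mods, function(m) {
  genes <- sort(unname(unlist(m$nodes)))
  cbind(module_id = m$module_id,
        module_pathway_correlation(module_score(genes, bundle), scores))
}))
write.table(corr, "results/module_pathway_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
strongest <- corr[which.max(abs(corr$r)), ]
message(sprintf("strongest module-pathway correlation: %s ~ %s, r %.2f (p %.2e)",
                strongest$module_id, strongest$set_name, strongest$r,
                strongest$p))

## pathway scores between the survival subpopulations of the module with the
## strongest survival association
surv <- read.delim("results/survival.tsv")
best <- surv$module_id[which.min(surv$p_logrank)]
message(sprintf("comparing subpopulations of %s (log-rank p %.2e)", best,
                min(surv$p_logrank)))
mbest <- mods[[which(vapply(mods, `[[`, character(1), "module_id") == best)]]
genes1 <- sort(unname(unlist(mbest$nodes)))
labels <- stratify_module(genes1, bundle, samples, seed = 11L)$labels
cmp <- compare_group_scores(scores[, names(labels), drop = FALSE], labels)
cmp <- cmp[order(cmp$p), ]
write.table(cmp, "results/group_score_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d/%d pathways differ between the two subpopulations (q < 0.05)",
                sum(cmp$q < 0.05), nrow(cmp)))
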