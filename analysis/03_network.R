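#!/usr/bin/env Rscript
# Stage 3: AGO-filter the interaction catalog, build the dysregulated
# lncRNA-miRNA-mRNA network (both endpoints DE; |r| > 0.3 and p < 0.01
# across all samples; shared-miRNA rule), and summarize its degree
# structure. Writes results/network_edges.tsv.

suppressPackageStartupMessages({library(dysnet); library(jsonlite)})

ann <- classify_biotypes("results/cohort/annotation.gtf")
bundle <- load_expression(
  file.path("results/cohort",
            c("mrna_expression.tsv", "lncrna_expression.tsv",
              "mirna_expression.tsv")), ann)
samples <- read_samples("results/cohort/samples.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json", simplifyVector = TRUE)
filtered <- lapply(bundle, filter_low_expression)
de <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
             function(cl) read.delim(sprintf("results/de_%s.tsv", cl)))

catalog <- read_interactions("results/cohort/interactions.tsv")
message(sprintf("catalog: %d pairs, %d with >= 1 AGO site", nrow(catalog),
                nrow(filter_ago(catalog))))

network <- build_network(de, filter_ago(catalog), filtered,
                         r_threshold = 0.3, p_threshold = 0.01)
write.table(network$edges, "results/network_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- table(network$nodes$rna_class)
message(sprintf("network: %d edges over %d nodes (%s)",
                nrow(network$edges), nrow(network$nodes),
                paste(names(tab), tab, sep = "=", collapse = ", ")))
er <- edge_recovery(network, truth)
message(sprintf("planted-edge recovery: precision %.3f, recall %.3f",
                er$precision, er$recall))
deg <- degree_summary(network)
message(sprintf("degree structure: %.1f%% of nodes with < 5 edges, %.1f%% with > 10",
                100 * deg$frac_deg_lt5, 100 * deg$frac_deg_gt10))
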