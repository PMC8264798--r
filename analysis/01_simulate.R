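#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic tumor/normal cohort and write its
# plain-text fixtures (expression TSVs, GTF, sample metadata, interaction
# catalog, GMT gene sets, ground-truth JSON) under results/cohort/.

suppressPackageStartupMessages(library(dysnet))

seed <- 2024L
cohort <- simulate_cohort(sim_config(seed = seed))
manifest <- write_fixtures(cohort, "results/cohort")

n_de <- vapply(cohort$truth$de_genes_by_class, nrow, integer(1))
message(sprintf("cohort: %d mRNA, %d lncRNA, %d miRNA x %d samples (seed %d)",
                nrow(cohort$expression$mrna), nrow(cohort$expression$lncrna),
                nrow(cohort$expression$mirna), nrow(cohort$samples), seed))
message(sprintf("planted DE genes: %s",
                paste(names(n_de), n_de, sep = "=", collapse = ", ")))
message(sprintf("planted regulon edges: %d; planted modules: %d",
                nrow(cohort$truth$true_edges),
                length(cohort$truth$planted_modules)))
message(sprintf("fixtures written: %s", paste(basename(manifest$files),
                                              collapse = ", ")))
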