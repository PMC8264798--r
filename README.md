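# dysnet

Dysregulated lncRNA–miRNA–mRNA network analysis for tumor-vs-normal
expression cohorts, with a fully synthetic, ground-truthed test bed.

Integrative cancer transcriptomics studies link the three RNA classes into a
single "dysregulated" (ceRNA-style) network: differentially expressed
miRNAs are connected to the differentially expressed lncRNAs and mRNAs they
putatively regulate, edges are kept only when backed by AGO CLIP binding
evidence and by expression correlation, and the resulting network is mined
for small tri-class modules whose expression stratifies patient survival
and tracks immune/metabolic pathway activity. `dysnet` implements that
entire chain as tested, reusable R functions, and — because the public
cohorts such studies use cannot be redistributed — ships a seeded
synthetic-cohort generator with *planted* signal at every level (DE genes,
miRNA regulons, prognostic modules, enriched gene sets) so each stage can
be validated against known truth.

The core statistics, in the field's standard notation:

* DE gate: Welch t-test on `log2(x + c)` with two-sided `p < 0.05` and
  linear fold change `max(m_T/m_N, m_N/m_T) > 2` (`|log2FC| > 1`), after
  removing genes expressed in fewer than 10% of samples.
* Edge gate: Pearson `|r| > 0.3` and `p < 0.01` across all samples, with
  `p` from `t = r sqrt((n-2)/(1-r^2))` on `n-2` df; plus the shared-miRNA
  rule (every miRNA must keep both a lncRNA and an mRNA edge).
* Modules: deterministic `|r|`-ordered union–find agglomeration with a size
  cap, emitting connected tri-class clusters.
* Survival: k-means (k = 2) on z-scored module expression; log-rank
  `chi^2 = (sum(O_1 - E_1))^2 / sum(V)` on 1 df; Kaplan–Meier curves;
  Wilcoxon rank-sum for tumor-vs-normal module expression.
* Gene sets: hypergeometric over-representation
  `p = sum_{i>=k} C(K,i)C(N-K,n-i)/C(N,n)`, preranked GSEA (max-deviation
  running sum, gene-label permutation null), and ssGSEA per-sample scores
  (`rank^0.25`-weighted walk), with module–pathway Pearson correlations.

See `vignettes/dysregulated-network-analysis.Rmd` for the full methods
account, including the generator's model and the design decisions.

## Worked example

The `analysis/` directory holds the numbered drivers of the full study on
the default synthetic cohort; each is a thin script over the package
functions and writes its tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_network.R
Rscript analysis/04_modules.R
Rscript analysis/05_survival.R
Rscript analysis/06_enrichment.R
```

Output (abridged) and what it means:

```
cohort: 500 mRNA, 200 lncRNA, 100 miRNA x 80 samples (seed 2024)
planted DE genes: mrna=100, lncrna=40, mirna=20
mrna: 500 tested, 53 up, 47 down
planted-DE recovery: sensitivity 1.000 (n=160), FPR 0.0000 (n=640)
catalog: 321 pairs, 209 with >= 1 AGO site
network: 21 edges over 24 nodes (lncRNA=6, miRNA=3, mRNA=15)
planted-edge recovery: precision 1.000, recall 1.000
degree structure: 87.5% of nodes with < 5 edges, 0.0% with > 10
M1: 7 interactions with 5 mRNAs, 2 lncRNAs, 1 miRNAs (mean |r| 0.79)
agreement with planted modules: ARI 1.000
M3: groups 23/37, log-rank chi2 21.00 (p 4.58e-06); tumor-vs-normal up (rank-sum p 2.72e-11)
ORA: 4/15 sets with q < 0.05 (planted enriched: PW01, PW02, PW03)
strongest module-pathway correlation: M3 ~ PW01, r 0.93 (p 1.56e-36)
```

Reading it: the DE stage recovers all 160 planted DE genes with no false
positives among the 640 null genes; the two-step edge filter keeps exactly
the 21 planted regulon edges (decoys are eliminated by the DE and
correlation gates); module detection reproduces the three planted
1-miRNA/2-lncRNA/5-mRNA stars (adjusted Rand index 1.0); the module built
from the hazard-driving regulon splits tumor samples into groups with
clearly different survival (log-rank p ≈ 5e-06) while the other two
modules are survival-null, and is overexpressed in tumors; the three
planted-enriched gene sets top the over-representation ranking, and the
prognostic module's expression correlates strongly (r ≈ 0.93) with the
pathway planted to track it.

The same chain is available as a single call:

```r
library(dysnet)
report <- run_pipeline(pipeline_config(sim = sim_config(seed = 1L), seed = 1L))
report$counts$n_modules          # 3
sapply(report$survival, `[[`, "p_logrank")
```

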