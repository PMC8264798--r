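---
title: "Dysregulated lncRNA-miRNA-mRNA network analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dysregulated lncRNA-miRNA-mRNA network analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`dysnet` implements an integrative tumor-vs-normal transcriptome analysis
that links three RNA classes — messenger RNAs, long non-coding RNAs and
microRNAs — into a single *dysregulated network* and interrogates that
network for clinically meaningful structure. The workflow is the one used in
ceRNA-style cancer transcriptomics studies:

1. **Class partitioning.** Genes are routed to mRNA / lncRNA / miRNA classes
   by GENCODE biotype. The lncRNA class accepts both the modern umbrella
   biotype (`lncRNA`) and the older subtype vocabulary (`antisense`,
   `lincRNA`, `processed_transcript`, `sense_intronic`, `sense_overlapping`,
   `TEC`), because public annotations mix releases.
2. **Differential expression.** Genes expressed (non-zero) in fewer than 10%
   of samples are removed; the boundary is inclusive, so a gene at exactly
   10% is kept. Each remaining gene is tested with a Welch two-sample t-test
   on `log2(x + pseudocount)` and called up/down when the two-sided p-value
   is below 0.05 *and* the linear-scale fold change
   `max(mean_T/mean_N, mean_N/mean_T)` exceeds 2. Testing on the log scale
   stabilizes variance; fold change on linear means is the conventional
   reading of "fold change > 2". Welch rather than Student is used because
   tumor and normal groups are unbalanced and heteroscedastic. No
   multiple-testing correction is applied by default (the gate is on raw p);
   Benjamini-Hochberg gating is available via `de_config(adjust = "BH")`.
3. **Interaction evidence.** Candidate miRNA-target pairs come from a
   catalog annotated with AGO CLIP binding-site counts; only pairs with at
   least one AGO site are kept.
4. **Network construction.** Three filters, in order: (0) both the miRNA and
   its target must be differentially expressed; (1) the Pearson correlation
   of their expression across *all* samples (tumor and normal pooled) must
   pass `|r| > 0.3` and `p < 0.01`, both strict; (2) only miRNAs with at
   least one passing lncRNA edge *and* one passing mRNA edge survive (the
   shared-miRNA rule), and targets orphaned by a miRNA's removal are
   dropped, so the final graph has no isolated nodes. The correlation sign
   is not constrained — miRNA repression suggests negative coupling, but the
   gate is on `|r|`; `build_network(require_negative = TRUE)` restores the
   sign constraint.
5. **Module detection.** Connected tri-class subnetworks are extracted with
   a deterministic agglomerative procedure (below) and summarized by class
   composition and interaction count.
6. **Survival stratification.** For each module, tumor samples are split
   into two groups by k-means (k = 2) on the module's expression and the
   groups are compared with the log-rank test; the module's tumor-vs-normal
   expression shift is tested with the Wilcoxon rank-sum test.
7. **Gene-set scoring.** Hypergeometric over-representation of DE genes,
   preranked GSEA, and single-sample GSEA (ssGSEA) pathway-activity scores
   per sample, followed by module-pathway correlation and pathway-score
   comparison between survival subpopulations.

The package ships a synthetic-cohort generator with known planted signal at
every one of these levels, so the whole chain is validated end-to-end
against ground truth rather than by eyeballing.

# Module detection: a deterministic surrogate

The hierarchical edge-clustering algorithms used by popular network-module
plugins weight edges by shared neighbourhoods. On a strictly bipartite
miRNA-target graph that weight degenerates: a miRNA and its target share no
common neighbours by construction. `detect_modules()` therefore uses an
explicitly documented surrogate:

* sort edges by decreasing `|r|`, ties broken lexicographically on
  `(mirna_id, target_id)`;
* sweep the sorted edges through a union-find, merging two clusters only
  when the merged node count stays within `max_size` (default 20);
* emit clusters with `min_size` (default 6) to `max_size` nodes containing
  all three RNA classes (the completeness filter can be disabled), ordered
  by decreasing mean `|r|`.

This is *not* a port of any published hierarchical clustering algorithm; it
was chosen because it is deterministic, order-invariant (the canonical edge
sort makes the output independent of input permutation), testable against
hand-traced merges, and recovers star-like tri-class modules of the kind
such analyses report. The size cap plays the role the published algorithms'
density thresholds play: strong regulon cores are locked in before weak
bridging edges are considered, and a bridge whose merge would exceed the cap
is refused. The defaults (6-20 nodes, no `|r|` floor) are the package's own;
module size floors below 6 admit trivial paths, and caps above ~20 let weak
bridges glue regulons together.

# The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the statistical structure of a
processed bulk cohort; all defaults are fixed study conditions, not tuning
knobs.

* **Scale.** 500 mRNAs, 200 lncRNAs, 100 miRNAs; 60 tumor and 20 normal
  samples. This keeps the tumor:normal imbalance of public tumor cohorts
  (which are an order of magnitude larger) while remaining desk-scale.
* **Expression model.** `log2(abundance)` is Gaussian: a per-gene baseline
  `Uniform(3, 8)`, within-condition dispersion `noise_sd = 0.5` (log2
  units), and for planted DE genes a condition shift drawn from
  `N(2, 0.3)` log2 units with random sign. Log-normal abundance rather than
  counts matches processed (FPKM/TPM-like) matrices, keeps everything
  non-negative, and makes the correlation structure analytically
  controllable. The generator is unit-agnostic.
* **Planted DE.** 20% of each class, balanced up/down.
* **Regulons.** Three star regulons: one DE miRNA hub with 2 DE lncRNA and
  5 DE mRNA targets (the 1/2/5 shape of small reported tri-class modules).
  Each regulon has a per-sample latent factor `f ~ N(0,1)`; the hub loads
  `+a f`, targets `-a f`, with `a` and the private noise chosen so the
  within-condition miRNA-target correlation is `-regulon_strength` (0.8)
  while every gene keeps total within-condition variance `noise_sd^2`. The
  miRNA's DE direction is random per regulon and its targets take the
  opposite direction (miRNA up, targets down).
* **Decoy interactions.** 300 random catalog pairs with no shared factor,
  with AGO site counts that include zeros. Decoys never join two planted-DE
  genes: because edge correlations are computed on the pooled tumor+normal
  samples, *any* co-DE pair is strongly correlated through its group-mean
  offsets, and such decoys would be statistically indistinguishable from
  true regulation. This is the central caveat of pooled-correlation
  filtering — in real cohorts part of the network's edges are co-DE
  artifacts of exactly this kind, and passing tests here says nothing about
  that failure mode.
* **Survival.** Tumor survival is exponential with log-hazard
  `hazard_beta` (default 1.5) per standard deviation of the first regulon's
  mean log2 expression; baseline scale 1000 days. Censoring times are
  independent `Uniform(0, b)` with the horizon `b` solved numerically so
  the expected censored fraction equals `censor_rate` (0.3). This is
  simpler than administrative censoring but sufficient for log-rank power
  properties.
* **Gene sets.** 15 sets of 30 mRNAs; the first three are planted enriched
  (60% planted-DE members). The first additionally contains the prognostic
  module's mRNA targets and draws its remaining DE members from genes with
  the same DE direction as those targets, so its ssGSEA score tracks the
  module's expression with a positive sign. Under pooled-sample correlation
  a direction-balanced set can track a module with either sign, which is a
  statement about the data model, not a bug.

What the generator does **not** emulate: read-level sequencing noise,
batch effects, tumor purity, copy-number confounding, overlapping modules,
administrative censoring, and co-DE decoy interactions (see above). Tests
passing on these cohorts demonstrate the pipeline's correctness and
recovery properties under the stated model, not robustness to those
real-data phenomena.

# Survival stratification details

k-means operates on per-gene z-scores of `log2(x + pseudocount)` — without
standardization the abundance scale of mRNAs would dominate the distance.
Initialization is deterministic given the seed: ten restarts, each seeding
the first center at a random sample and the second at the farthest sample,
Lloyd iterations, best total within-cluster sum of squares wins, ties to the
first restart. Labels are canonicalized so group 1 has the higher mean
module expression, making output stable across seeds for separable data.
Tumor samples with missing survival fields are excluded at stratification
time (with a message), not at load time.

One property worth spelling out: the planted prognostic score is a
*continuous* latent factor, so the inertia-optimal k-means boundary need not
sit at the score's median. The stratification labels are a threshold split
of the true score (observed agreement with the best threshold >= 0.97
across seeds), but their agreement with the *median* split varies (0.72 to
0.97 in our checks). Tests therefore assert the threshold property and the
correct assignment of the outer score quartiles, not agreement with a
median split.

The rank-sum test of module expression uses the exact distribution when the
combined sample count is at most 20 and the scores are untied, and the
normal approximation with tie correction otherwise.

# Gene-set machinery

* **ORA**: upper-tail hypergeometric
  `p = sum_{i>=k} C(K,i) C(N-K,n-i) / C(N,n)`, BH-adjusted across a
  collection.
* **Preranked GSEA**: running sum with member increments `|w|` normalized
  over the set and uniform `1/(N-K)` decrements at non-member positions; ES
  is the maximum-deviation value; the null permutes gene labels
  (`p = (1 + #{|ES_b| >= |ES|, same sign}) / (1 + n_perm)`,
  `NES = ES / mean |same-sign null ES|`). Gene-label permutation is the only
  scheme available to preranked input. Ranking weights default to log2 fold
  changes when the ranking comes from a DE table.
* **ssGSEA**: per sample, genes ranked by expression (average ranks for
  ties, most abundant = rank N); the score is the *sum over the full walk*
  of the weighted in-set cumulative fraction (weights `rank^tau`,
  `tau = 0.25`) minus the unweighted out-of-set cumulative fraction, with
  optional normalization of the whole matrix by its range. The exponent and
  range normalization follow the ssGSEA convention. Scores depend only on
  within-sample ranks, hence are invariant to monotone per-sample
  transforms.

# Numerical and degeneracy contracts

* `welch_t`: both groups constant and equal gives `t = 0, p = 1`; both
  constant and unequal gives `t = ±Inf, p = 0` (documented, no crash).
* `pearson_with_p`: constant vectors raise an error; the network builder
  drops such pairs with a warning instead of crashing.
* Log-rank requires at least one observed event; Kaplan-Meier censoring
  reduces the risk set without stepping the curve.
* The low-expression filter warns (not errors) when it removes every gene;
  an empty network is returned with a warning, and an empty module set is
  an empty list.
* Thresholds are strict inequalities (`|r| > 0.3`, `p < 0.01`, `p < 0.05`,
  `FC > 2`) matching how such gates are customarily printed.
* All tie-breaks (edge sort, ranking ties, module ordering) are
  lexicographic, for reproducibility over arbitrariness.
* Stage seeds are derived from one global seed per stage name
  (`stage_seed()`), so adding a stage does not shift another stage's random
  stream; the full pipeline is bit-identical under a fixed configuration
  and seed.

# Problem sizes used by the test suite

The validation suite exercises: the default cohort (500/200/100 genes,
60 + 20 samples) for recovery properties; reduced cohorts (80/40/20 genes)
for pipeline determinism checks; 60/30/20-gene cohorts with 100 tumor
samples for the log-rank operating characteristics (50 simulation seeds at
`hazard_beta = 1` for power, 200 at `hazard_beta = 0` for the false
detection rate — the null rate is a small probability, so it is estimated
on more seeds than the power, which sits near 1); and 50-instance batches
of random small inputs for every statistic's brute-force oracle comparison.

# Known limitations

* Pooled-sample correlation inflates edge evidence for co-DE pairs; the
  generator sidesteps this (see above) and a real-data analysis should
  treat pooled-|r| edges between strongly DE genes with suspicion, or use
  `require_negative = TRUE`.
* The module detector is a surrogate, not a reimplementation of any
  published plugin; module boundaries on dense networks will differ from
  those tools.
* Exactly one planted module drives hazard; detection of *which* module is
  prognostic is assessed by the log-rank p-value, and the other modules
  are true negatives.
* No Cox regression or multivariate adjustment; the survival analysis is
  the two-group nonparametric contrast.
* Gene identifiers are required unique across classes; duplicate symbols
  must be resolved upstream.
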