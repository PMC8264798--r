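#' Configuration for the synthetic tumor/normal cohort generator
#'
#' The generator emulates the statistical structure of a processed bulk
#' transcriptome cohort (non-negative abundances for mRNA, lncRNA and miRNA;
#' tumor and normal samples; survival follow-up), with known planted signal at
#' every level that the downstream analysis is supposed to recover:
#' up/down-regulated genes, miRNA regulons inducing negative miRNA-target
#' correlation through a shared latent factor, star-shaped tri-class modules
#' whose expression drives survival hazard, decoy interactions, and gene sets
#' enriched in planted differential genes.
#'
#' @param n_mrna,n_lncrna,n_mirna Number of genes per RNA class.
#' @param n_tumor,n_normal Sample counts per condition (each must be >= 3 so
#'   the downstream t-test is defined).
#' @param frac_de Fraction of genes planted as differentially expressed in
#'   each class.
#' @param de_log2fc_mean,de_log2fc_sd Mean and SD (log2 units) of planted
#'   effect sizes.
#' @param n_regulons Number of planted miRNA regulons (star: one miRNA hub
#'   regulating `n_lnc_per_regulon` lncRNAs and `n_mrna_per_regulon` mRNAs).
#' @param regulon_strength Target absolute within-condition Pearson
#'   correlation between a regulon miRNA and its targets, in (0, 1).
#' @param n_decoy_interactions Number of catalog interactions that carry no
#'   planted co-regulation.
#' @param n_modules Number of regulon stars recorded as planted modules
#'   (`<= n_regulons`); the first one drives survival.
#' @param hazard_beta Log-hazard increase per standard deviation of the
#'   prognostic module's mean expression.
#' @param censor_rate Expected fraction of tumor samples censored, in [0, 1].
#' @param baseline_scale Baseline survival scale (days): mean survival time of
#'   a sample with average module expression.
#' @param noise_sd Within-condition dispersion on the log2 scale.
#' @param n_lnc_per_regulon,n_mrna_per_regulon Targets per regulon star.
#' @param n_gene_sets Number of gene sets generated; the first
#'   `n_enriched_sets` are built to over-represent planted DE mRNAs.
#' @param n_enriched_sets Number of planted-enriched gene sets.
#' @param gene_set_size Members per gene set.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   cohort bit-identically.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mrna = 500, n_lncrna = 200, n_mirna = 100,
                       n_tumor = 60, n_normal = 20,
                       frac_de = 0.2,
                       de_log2fc_mean = 2, de_log2fc_sd = 0.3,
                       n_regulons = 3, regulon_strength = 0.8,
                       n_decoy_interactions = 300,
                       n_modules = 3,
                       hazard_beta = 1.5, censor_rate = 0.3,
                       baseline_scale = 1000, noise_sd = 0.5,
                       n_lnc_per_regulon = 2, n_mrna_per_regulon = 5,
                       n_gene_sets = 15, n_enriched_sets = 3,
                       gene_set_size = 30,
                       seed = 1L) {
  cfg <- list(n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_tumor = n_tumor, n_normal = n_normal, frac_de = frac_de,
              de_log2fc_mean = de_log2fc_mean, de_log2fc_sd = de_log2fc_sd,
              n_regulons = n_regulons, regulon_strength = regulon_strength,
              n_decoy_interactions = n_decoy_interactions,
              n_modules = n_modules, hazard_beta = hazard_beta,
              censor_rate = censor_rate, baseline_scale = baseline_scale,
              noise_sd = noise_sd,
              n_lnc_per_regulon = n_lnc_per_regulon,
              n_mrna_per_regulon = n_mrna_per_regulon,
              n_gene_sets = n_gene_sets, n_enriched_sets = n_enriched_sets,
              gene_set_size = gene_set_size,
              seed = as.integer(seed))
  counts <- c("n_mrna", "n_lncrna", "n_mirna", "n_tumor", "n_normal",
              "n_regulons", "n_modules", "n_gene_sets", "gene_set_size")
  for (f in counts)
    if (cfg[[f]] < 1) stopf("config field %s must be a positive count", f)
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stopf("frac_de must be in [0,1]")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stopf("censor_rate must be in [0,1]")
  if (cfg$regulon_strength <= 0 || cfg$regulon_strength >= 1)
    stopf("regulon_strength must be in (0,1)")
  if (cfg$noise_sd <= 0) stopf("noise_sd must be > 0")
  if (cfg$n_tumor < 3 || cfg$n_normal < 3)
    stopf("need at least 3 samples per condition (t-test undefined below)")
  n_de <- round(cfg$frac_de * c(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna))
  if (any(n_de < 1))
    stopf("frac_de plants fewer than one DE gene in some class")
  if (cfg$n_modules > cfg$n_regulons)
    stopf("n_modules must not exceed n_regulons")
  if (cfg$n_regulons > n_de[3])
    stopf("not enough planted DE miRNAs for %d regulons", cfg$n_regulons)
  if (cfg$n_regulons * cfg$n_lnc_per_regulon > n_de[2] ||
      cfg$n_regulons * cfg$n_mrna_per_regulon > n_de[1])
    stopf("not enough planted DE targets for %d disjoint regulons",
          cfg$n_regulons)
  structure(cfg, class = "sim_config")
}

#' Simulate a complete synthetic cohort with ground truth
#'
#' Expression is log-normal: `log2(abundance)` is Gaussian around a per-gene
#' baseline, with a planted condition shift for DE genes and a shared latent
#' factor per regulon loading positively on the miRNA hub and negatively on
#' its targets (miRNA up implies target down). Survival times for tumor
#' samples are exponential with log-hazard proportional to the standardized
#' mean expression of the prognostic module; censoring times are independent
#' uniform, with the horizon solved so the expected censored fraction matches
#' `censor_rate`.
#'
#' @param config A [sim_config()].
#' @return A `cohort` list with elements `expression` (list of three matrices:
#'   `mrna`, `lncrna`, `mirna`), `samples` (sample table), `interactions`
#'   (miRNA-target catalog), `gene_sets` (named list), `annotation`
#'   (gene_id/biotype/rna_class table) and `truth` (planted signal).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ids <- list(
    mrna   = sprintf("MG%04d", seq_len(cfg$n_mrna)),
    lncrna = sprintf("LNC%04d", seq_len(cfg$n_lncrna)),
    mirna  = sprintf("MIR%04d", seq_len(cfg$n_mirna))
  )
  n_s <- cfg$n_tumor + cfg$n_normal
  sample_ids <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                  sprintf("N%03d", seq_len(cfg$n_normal)))
  is_tumor <- c(rep(1, cfg$n_tumor), rep(0, cfg$n_normal))

  # --- plant DE genes -------------------------------------------------------
  n_de <- list(mrna   = round(cfg$frac_de * cfg$n_mrna),
               lncrna = round(cfg$frac_de * cfg$n_lncrna),
               mirna  = round(cfg$frac_de * cfg$n_mirna))
  de_idx <- lapply(names(ids), function(cl)
    sort(sample(seq_along(ids[[cl]]), n_de[[cl]])))
  names(de_idx) <- names(ids)

  # regulons claim the first DE genes of each class; remaining DE genes get
  # balanced random directions
  reg <- list()
  used <- list(mrna = integer(0), lncrna = integer(0), mirna = integer(0))
  for (r in seq_len(cfg$n_regulons)) {
    mir_i <- de_idx$mirna[r]
    lnc_i <- de_idx$lncrna[(r - 1) * cfg$n_lnc_per_regulon +
                             seq_len(cfg$n_lnc_per_regulon)]
    mrna_i <- de_idx$mrna[(r - 1) * cfg$n_mrna_per_regulon +
                            seq_len(cfg$n_mrna_per_regulon)]
    sgn <- sample(c(1, -1), 1)
    reg[[r]] <- list(mirna = ids$mirna[mir_i], lnc = ids$lncrna[lnc_i],
                     mrna = ids$mrna[mrna_i], sign = sgn,
                     mir_idx = mir_i, lnc_idx = lnc_i, mrna_idx = mrna_i)
    used$mirna <- c(used$mirna, mir_i)
    used$lncrna <- c(used$lncrna, lnc_i)
    used$mrna <- c(used$mrna, mrna_i)
  }

  direction <- lapply(names(ids), function(cl) {
    d <- rep(0L, length(ids[[cl]]))
    free <- setdiff(de_idx[[cl]], used[[cl]])
    if (length(free) > 0) {
      n_up <- ceiling(length(free) / 2)
      up <- sample(free, n_up)
      d[up] <- 1L
      d[setdiff(free, up)] <- -1L
    }
    d
  })
  names(direction) <- names(ids)
  for (r in reg) {
    direction$mirna[r$mir_idx] <- as.integer(r$sign)
    direction$lncrna[r$lnc_idx] <- as.integer(-r$sign)
    direction$mrna[r$mrna_idx] <- as.integer(-r$sign)
  }

  lfc <- lapply(names(ids), function(cl) {
    l <- rep(0, length(ids[[cl]]))
    idx <- de_idx[[cl]]
    l[idx] <- pmax(rnorm(length(idx), cfg$de_log2fc_mean, cfg$de_log2fc_sd),
                   0.25)
    l
  })
  names(lfc) <- names(ids)

  # --- expression -----------------------------------------------------------
  # within-condition variance is noise_sd^2 for every gene; regulon members
  # split it between the shared factor and private noise so that the
  # within-condition miRNA-target correlation is -regulon_strength
  rho <- cfg$regulon_strength
  a <- cfg$noise_sd * sqrt(rho)        # factor loading
  s_e <- cfg$noise_sd * sqrt(1 - rho)  # private noise of regulon members
  factors <- matrix(rnorm(n_s * cfg$n_regulons), n_s, cfg$n_regulons)

  loading <- lapply(names(ids), function(cl)
    rep(0, length(ids[[cl]])))
  names(loading) <- names(ids)
  factor_of <- lapply(names(ids), function(cl)
    rep(NA_integer_, length(ids[[cl]])))
  names(factor_of) <- names(ids)
  for (r in seq_along(reg)) {
    loading$mirna[reg[[r]]$mir_idx] <- a
    factor_of$mirna[reg[[r]]$mir_idx] <- r
    loading$lncrna[reg[[r]]$lnc_idx] <- -a
    factor_of$lncrna[reg[[r]]$lnc_idx] <- r
    loading$mrna[reg[[r]]$mrna_idx] <- -a
    factor_of$mrna[reg[[r]]$mrna_idx] <- r
  }

  expr <- list()
  for (cl in names(ids)) {
    n_g <- length(ids[[cl]])
    mu <- runif(n_g, 3, 8)
    noise_sd_g <- ifelse(loading[[cl]] != 0, s_e, cfg$noise_sd)
    logx <- matrix(rnorm(n_g * n_s, 0, 1), n_g, n_s) * noise_sd_g
    logx <- logx + mu +
      outer(direction[[cl]] * lfc[[cl]], is_tumor)
    has_f <- which(loading[[cl]] != 0)
    for (g in has_f)
      logx[g, ] <- logx[g, ] + loading[[cl]][g] * factors[, factor_of[[cl]][g]]
    m <- 2^logx
    dimnames(m) <- list(ids[[cl]], sample_ids)
    expr[[cl]] <- m
  }

  # --- interaction catalog --------------------------------------------------
  planted <- do.call(rbind, lapply(reg, function(r)
    data.frame(mirna_id = r$mirna,
               target_id = c(r$lnc, r$mrna),
               target_class = c(rep("lncRNA", length(r$lnc)),
                                rep("mRNA", length(r$mrna))),
               stringsAsFactors = FALSE)))
  planted$ago_sites <- 1L + rpois(nrow(planted), 2)

  de_flag <- list(
    mrna = seq_along(ids$mrna) %in% de_idx$mrna,
    lncrna = seq_along(ids$lncrna) %in% de_idx$lncrna,
    mirna = seq_along(ids$mirna) %in% de_idx$mirna)

  # decoys: uniform random miRNA x target pairs, excluding planted pairs and
  # pairs where both endpoints carry planted DE (a co-DE pair is strongly
  # correlated across the pooled cohort, which would make the planted edge
  # set unidentifiable); AGO site counts include zeros so the AGO filter has
  # work to do
  targets_all <- data.frame(
    target_id = c(ids$lncrna, ids$mrna),
    target_class = c(rep("lncRNA", cfg$n_lncrna), rep("mRNA", cfg$n_mrna)),
    de = c(de_flag$lncrna, de_flag$mrna),
    stringsAsFactors = FALSE)
  decoys <- NULL
  want <- cfg$n_decoy_interactions
  seen <- paste(planted$mirna_id, planted$target_id)
  guard <- 0
  while (want > 0 && guard < 60) {
    guard <- guard + 1
    mi <- sample(seq_len(cfg$n_mirna), 2 * want, replace = TRUE)
    ti <- sample(nrow(targets_all), 2 * want, replace = TRUE)
    cand <- data.frame(mirna_id = ids$mirna[mi],
                       target_id = targets_all$target_id[ti],
                       target_class = targets_all$target_class[ti],
                       stringsAsFactors = FALSE)
    both_de <- de_flag$mirna[mi] & targets_all$de[ti]
    key <- paste(cand$mirna_id, cand$target_id)
    keep <- !both_de & !(key %in% seen) & !duplicated(key)
    cand <- cand[keep, , drop = FALSE]
    cand <- head(cand, want)
    seen <- c(seen, paste(cand$mirna_id, cand$target_id))
    decoys <- rbind(decoys, cand)
    want <- cfg$n_decoy_interactions - NROW(decoys)
  }
  decoys$ago_sites <- rpois(nrow(decoys), 1)
  interactions <- rbind(planted, decoys)
  rownames(interactions) <- NULL

  # --- survival -------------------------------------------------------------
  prog <- reg[[1]]
  prog_nodes <- c(prog$mirna, prog$lnc, prog$mrna)
  all_log2 <- rbind(log2(expr$mrna), log2(expr$lncrna), log2(expr$mirna))
  score <- colMeans(all_log2[prog_nodes, seq_len(cfg$n_tumor), drop = FALSE])
  z <- as.numeric(scale(score))
  lambda <- exp(cfg$hazard_beta * z) / cfg$baseline_scale
  t_event <- rexp(cfg$n_tumor, rate = lambda)
  if (cfg$censor_rate <= 0) {
    time <- t_event
    event <- rep(1L, cfg$n_tumor)
  } else {
    lam0 <- mean(lambda)
    # choose the uniform censoring horizon b so that E P(C < T) = censor_rate
    f <- function(b) (1 - exp(-lam0 * b)) / (lam0 * b) - cfg$censor_rate
    b <- uniroot(f, lower = 1e-6 / lam0, upper = 1e6 / lam0)$root
    c_time <- runif(cfg$n_tumor, 0, b)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
  }
  samples <- data.frame(
    sample_id = sample_ids,
    condition = c(rep("tumor", cfg$n_tumor), rep("normal", cfg$n_normal)),
    survival_days = c(round(time, 3), rep(NA_real_, cfg$n_normal)),
    event = c(event, rep(NA_integer_, cfg$n_normal)),
    stringsAsFactors = FALSE)

  # --- gene sets ------------------------------------------------------------
  de_mrna_ids <- ids$mrna[de_idx$mrna]
  non_de_mrna_ids <- setdiff(ids$mrna, de_mrna_ids)
  # DE mRNAs sharing the direction of the prognostic module's targets; the
  # first enriched set draws from these so its per-sample score tracks the
  # module's expression with a positive sign
  prog_dir_ids <- ids$mrna[direction$mrna == -reg[[1]]$sign &
                             seq_along(ids$mrna) %in% de_idx$mrna]
  gene_sets <- list()
  set_names <- sprintf("PW%02d", seq_len(cfg$n_gene_sets))
  for (i in seq_len(cfg$n_gene_sets)) {
    if (i <= cfg$n_enriched_sets) {
      core <- if (i == 1) prog$mrna else character(0)
      n_de_m <- max(round(0.6 * cfg$gene_set_size) - length(core), 0)
      pool <- if (i == 1) setdiff(prog_dir_ids, core)
              else setdiff(de_mrna_ids, core)
      n_de_m <- min(n_de_m, length(pool))
      members <- c(core,
                   sample(pool, n_de_m),
                   sample(non_de_mrna_ids,
                          cfg$gene_set_size - n_de_m - length(core)))
    } else {
      members <- sample(ids$mrna, cfg$gene_set_size)
    }
    gene_sets[[set_names[i]]] <- sort(members)
  }

  # --- annotation -----------------------------------------------------------
  lnc_biotypes <- c("lincRNA", "antisense", "lncRNA", "processed_transcript",
                    "sense_intronic", "sense_overlapping", "TEC")
  annotation <- data.frame(
    gene_id = c(ids$mrna, ids$lncrna, ids$mirna),
    biotype = c(rep("protein_coding", cfg$n_mrna),
                sample(lnc_biotypes, cfg$n_lncrna, replace = TRUE),
                rep("miRNA", cfg$n_mirna)),
    stringsAsFactors = FALSE)
  annotation$rna_class <- biotype_to_class(annotation$biotype)

  truth <- list(
    de_genes_by_class = lapply(names(ids), function(cl)
      data.frame(gene_id = ids[[cl]][de_idx[[cl]]],
                 direction = ifelse(direction[[cl]][de_idx[[cl]]] > 0,
                                    "up", "down"),
                 log2fc = direction[[cl]][de_idx[[cl]]] *
                   lfc[[cl]][de_idx[[cl]]],
                 stringsAsFactors = FALSE)),
    true_edges = planted[, c("mirna_id", "target_id", "target_class")],
    planted_modules = lapply(reg[seq_len(cfg$n_modules)], function(r)
      sort(c(r$mirna, r$lnc, r$mrna))),
    prognostic_module_index = 1L,
    prognostic_score = setNames(z, sample_ids[seq_len(cfg$n_tumor)]),
    enriched_sets = set_names[seq_len(cfg$n_enriched_sets)],
    regulon_signs = vapply(reg, `[[`, numeric(1), "sign"))
  names(truth$de_genes_by_class) <- names(ids)

  structure(list(expression = expr, samples = samples,
                 interactions = interactions, gene_sets = gene_sets,
                 annotation = annotation, truth = truth, config = cfg),
            class = "cohort")
}

#' Write a simulated cohort to plain-text fixtures
#'
#' Emits one expression TSV per RNA class, a gene-line GTF, a sample metadata
#' TSV, a miRNA-target interaction TSV, a GMT gene-set file, and a
#' ground-truth JSON sidecar. The seven cohort input files round-trip
#' bit-identically through the package readers; the truth JSON is not a
#' pipeline input and is referenced separately in the manifest.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return A manifest list: `files` (the 7 input files) and `truth` (path of
#'   the ground-truth JSON).
#' @export
write_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stopf("cannot create directory '%s'", dir)
  files <- c(
    mrna_expression = "mrna_expression.tsv",
    lncrna_expression = "lncrna_expression.tsv",
    mirna_expression = "mirna_expression.tsv",
    annotation = "annotation.gtf",
    samples = "samples.tsv",
    interactions = "interactions.tsv",
    gene_sets = "gene_sets.gmt")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  write_expression_tsv(cohort$expression$mrna, paths[["mrna_expression"]])
  write_expression_tsv(cohort$expression$lncrna, paths[["lncrna_expression"]])
  write_expression_tsv(cohort$expression$mirna, paths[["mirna_expression"]])
  write_gene_gtf(cohort$annotation, paths[["annotation"]])
  write_samples_tsv(cohort$samples, paths[["samples"]])
  write_interactions_tsv(cohort$interactions, paths[["interactions"]])
  write_gmt(cohort$gene_sets, paths[["gene_sets"]])
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(files = paths, truth = truth_path)
}
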