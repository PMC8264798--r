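#' Configuration for a full pipeline run
#'
#' Inputs come either from a simulated cohort (`sim`) or from a fixture
#' directory written by [write_fixtures()] (`input_dir`); exactly one must be
#' given. All stage seeds are derived deterministically from the single
#' global `seed` via [stage_seed()].
#'
#' @param sim A [sim_config()], or NULL when reading fixtures.
#' @param input_dir Fixture directory, or NULL when simulating.
#' @param de A [de_config()].
#' @param r_threshold,p_threshold Network edge gates.
#' @param min_ago_sites AGO evidence floor for catalog pairs.
#' @param modules A [module_params()].
#' @param tau ssGSEA rank-weight exponent.
#' @param seed Global seed.
#' @param out_dir Optional directory for stage artifacts (TSV/JSON).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            de = de_config(), r_threshold = 0.3,
                            p_threshold = 0.01, min_ago_sites = 1,
                            modules = module_params(), tau = 0.25,
                            seed = 1L, out_dir = NULL) {
  if (is.null(sim) && is.null(input_dir))
    stopf("pipeline_config: either 'sim' or 'input_dir' must be given")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stopf("pipeline_config: input_dir '%s' does not exist", input_dir)
  structure(list(sim = sim, input_dir = input_dir, de = de,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 min_ago_sites = min_ago_sites, modules = modules,
                 tau = tau, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

read_cohort_fixtures <- function(dir) {
  ann <- classify_biotypes(file.path(dir, "annotation.gtf"))
  bundle <- load_expression(
    file.path(dir, c("mrna_expression.tsv", "lncrna_expression.tsv",
                     "mirna_expression.tsv")), ann)
  list(expression = bundle,
       samples = read_samples(file.path(dir, "samples.tsv")),
       interactions = read_interactions(file.path(dir, "interactions.tsv")),
       gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
       annotation = ann)
}

#' Run the full dysregulated-network analysis
#'
#' Stages, in order: cohort acquisition (simulate or read fixtures),
#' low-expression filtering, per-class differential expression, AGO filtering
#' of the interaction catalog, correlation-validated network construction,
#' module detection, per-module survival stratification and tumor-vs-normal
#' expression tests, ssGSEA pathway scoring with module-pathway correlations
#' and group-score comparisons. A rerun with the same configuration and seed
#' reproduces the report bit-identically. Any stage failure aborts with the
#' stage name; if `out_dir` is set, a `FAILED` marker naming the stage is
#' left next to the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage counts and result tables, a
#'   consistency-check flag, the package version and the configuration echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- "setup"
  fail <- function(e) {
    if (!is.null(out_dir))
      writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }
  tryCatch({
    stage <- "cohort"
    cohort <- if (!is.null(config$input_dir))
      read_cohort_fixtures(config$input_dir)
    else simulate_cohort(config$sim)
    bundle <- cohort$expression
    samples <- cohort$samples

    stage <- "filter"
    filtered <- lapply(bundle, filter_low_expression,
                       min_fraction = config$de$min_expressed_fraction)
    class(filtered) <- "expression_bundle"
    n_filtered <- vapply(names(bundle), function(cl)
      nrow(bundle[[cl]]) - nrow(filtered[[cl]]), integer(1))

    stage <- "differential_expression"
    de <- lapply(filtered, run_de, samples = samples, cfg = config$de)
    de_counts <- lapply(de, function(d)
      c(tested = nrow(d), up = sum(d$direction == "up"),
        down = sum(d$direction == "down")))

    stage <- "ago_filter"
    n_cat <- nrow(cohort$interactions)
    catalog <- filter_ago(cohort$interactions, config$min_ago_sites)

    stage <- "network"
    network <- suppressWarnings(
      build_network(de, catalog, filtered,
                    r_threshold = config$r_threshold,
                    p_threshold = config$p_threshold))
    deg <- if (nrow(network$nodes) > 0) degree_summary(network) else NULL

    stage <- "modules"
    mods <- detect_modules(network, config$modules)

    stage <- "survival"
    surv_seed <- stage_seed(config$seed, "survival")
    surv <- lapply(mods, function(m) {
      st <- suppressMessages(
        stratify_module(m, filtered, samples, seed = surv_seed))
      et <- module_expression_test(m, filtered, samples)
      c(list(module_id = m$module_id), module_summary(m),
        list(group_sizes = st$group_sizes, chi_square = st$chi_square,
             p_logrank = st$p_logrank, ranksum_p = et$p,
             expression_direction = et$direction))
    })

    stage <- "enrichment"
    scores <- suppressWarnings(
      ssgsea_scores(filtered$mrna, cohort$gene_sets, tau = config$tau))
    mod_corr <- lapply(mods, function(m)
      cbind(module_id = m$module_id,
            module_pathway_correlation(module_score(m, filtered), scores),
            stringsAsFactors = FALSE))
    mod_corr <- if (length(mod_corr) > 0) do.call(rbind, mod_corr) else NULL
    group_cmp <- if (length(mods) > 0) {
      lab <- suppressMessages(stratify_module(mods[[1]], filtered, samples,
                                              seed = surv_seed))$labels
      compare_group_scores(scores[, names(lab), drop = FALSE], lab)
    } else NULL

    stage <- "report"
    report <- list(
      version = as.character(packageVersion("dysnet")),
      seed = config$seed,
      counts = list(
        genes_low_expression_filtered = n_filtered,
        de = de_counts,
        catalog_interactions = n_cat,
        catalog_after_ago = nrow(catalog),
        network_nodes = nrow(network$nodes),
        network_nodes_by_class = table(network$nodes$rna_class),
        network_edges = nrow(network$edges),
        n_modules = length(mods)),
      degree = deg,
      modules = lapply(mods, module_summary),
      survival = surv,
      module_pathway_correlation = mod_corr,
      group_score_comparison = group_cmp,
      config = config)
    report$checks_passed <- check_report_consistency(report, de, network, mods)
    class(report) <- "run_report"

    if (!is.null(out_dir)) write_report_artifacts(report, de, network, mods,
                                                  scores, out_dir)
    report
  }, error = fail)
}

# Internal consistency gates enforced before a report is returned.
check_report_consistency <- function(report, de, network, mods) {
  ok <- TRUE
  for (cl in names(de)) {
    cc <- report$counts$de[[cl]]
    ok <- ok && (cc["up"] + cc["down"] <= cc["tested"])
  }
  ok <- ok && report$counts$network_nodes ==
    sum(report$counts$network_nodes_by_class)
  ok <- ok && all(vapply(report$modules, function(m)
    m$n_nodes == m$n_mrna + m$n_lncrna + m$n_mirna, logical(1)))
  if (!ok) stopf("run report failed internal consistency checks")
  ok
}

write_report_artifacts <- function(report, de, network, mods, scores,
                                   out_dir) {
  for (cl in names(de))
    data.table::fwrite(de[[cl]], file.path(out_dir, sprintf("de_%s.tsv", cl)),
                       sep = "\t", quote = FALSE)
  data.table::fwrite(network$edges, file.path(out_dir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(
    lapply(mods, function(m) list(module_id = m$module_id, nodes = m$nodes,
                                  summary = module_summary(m))),
    file.path(out_dir, "modules.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  surv_tab <- do.call(rbind, lapply(report$survival, function(s)
    data.frame(module_id = s$module_id, n_nodes = s$n_nodes,
               n_interactions = s$n_interactions,
               group1 = s$group_sizes[1], group2 = s$group_sizes[2],
               chi_square = s$chi_square, p_logrank = s$p_logrank,
               ranksum_p = s$ranksum_p,
               expression_direction = s$expression_direction)))
  if (!is.null(surv_tab))
    data.table::fwrite(surv_tab, file.path(out_dir, "survival.tsv"),
                       sep = "\t", quote = FALSE)
  data.table::fwrite(data.table::as.data.table(scores, keep.rownames = "set_name"),
                     file.path(out_dir, "ssgsea_scores.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(report$module_pathway_correlation))
    data.table::fwrite(report$module_pathway_correlation,
                       file.path(out_dir, "module_pathway_correlation.tsv"),
                       sep = "\t", quote = FALSE)
  rep_out <- report
  rep_out$config <- NULL
  jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
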