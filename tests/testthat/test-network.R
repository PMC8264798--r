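# Build a bundle + DE tables + catalog for hand-constructed correlation
# structure: each gene's expression is given directly.
hand_instance <- function(gene_values, classes, catalog, n_samples) {
  samp <- sprintf("s%02d", seq_len(n_samples))
  mats <- lapply(c(mRNA = "mRNA", lncRNA = "lncRNA", miRNA = "miRNA"),
                 function(cl) {
    ids <- names(classes)[classes == cl]
    m <- do.call(rbind, gene_values[ids])
    if (is.null(m)) m <- matrix(0, 0, n_samples)
    dimnames(m) <- list(ids, samp)
    m
  })
  bundle <- list(mrna = mats$mRNA, lncrna = mats$lncRNA, mirna = mats$miRNA)
  de <- lapply(bundle, function(m)
    data.frame(gene_id = rownames(m), direction = rep("up", nrow(m)),
               stringsAsFactors = FALSE))
  list(bundle = bundle, de = de, catalog = catalog)
}

test_that("AGO filter keeps pairs with enough binding sites", {
  cat <- data.frame(mirna_id = paste0("m", 1:5), target_id = paste0("t", 1:5),
                    target_class = "mRNA", ago_sites = c(2L, 0L, 1L, 0L, 3L))
  expect_equal(nrow(filter_ago(cat)), 3)
  expect_equal(nrow(filter_ago(cat, min_sites = 1)), 3)
  expect_true(all(filter_ago(cat)$ago_sites >= 1))
  expect_equal(nrow(filter_ago(cat, min_sites = 3)), 1)
})

test_that("pearson_with_p handles perfect correlation and rejects constants", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_error(pearson_with_p(x, rep(1, 5)), "constant")
  expect_error(pearson_with_p(1:2, 2:3), "n >= 3")
})

test_that("pearson p follows the t-transform on random instances", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- pearson_with_p(x, y)
    ref <- oracle_pearson(x, y)
    expect_equal(got$r, ref$r, tolerance = 1e-9)
    expect_equal(got$p, ref$p, tolerance = 1e-9)
  }
  # a modest correlation at small n is far from the p < 0.01 gate
  set.seed(8)
  reps <- replicate(200, {
    x <- rnorm(10); y <- rnorm(10)
    r <- cor(x, y)
    if (abs(r - 0.3) < 0.05) oracle_pearson(x, y)$p else NA
  })
  expect_gt(min(reps, na.rm = TRUE), 0.3)
})

test_that("shared-miRNA rule keeps only miRNAs bridging both target classes", {
  n <- 30
  set.seed(11)
  f1 <- rnorm(n); f2 <- rnorm(n)
  vals <- list(
    MIR01 = 2^(5 + f1), LNC01 = 2^(5 - f1),
    MG01 = 2^(5 - f1), MG02 = 2^(5 - f1 + rnorm(n, 0, 0.2)),
    MIR02 = 2^(5 + f2), MG03 = 2^(5 - f2), MG04 = 2^(5 - f2))
  cls <- c(MIR01 = "miRNA", LNC01 = "lncRNA", MG01 = "mRNA", MG02 = "mRNA",
           MIR02 = "miRNA", MG03 = "mRNA", MG04 = "mRNA")
  cat <- data.frame(
    mirna_id = c("MIR01", "MIR01", "MIR01", "MIR02", "MIR02"),
    target_id = c("LNC01", "MG01", "MG02", "MG03", "MG04"),
    target_class = c("lncRNA", "mRNA", "mRNA", "mRNA", "mRNA"),
    ago_sites = 1L, stringsAsFactors = FALSE)
  inst <- hand_instance(vals, cls, cat, n)
  net <- build_network(inst$de, inst$catalog, inst$bundle)
  # MIR02 has no lncRNA edge: dropped with its targets
  expect_equal(nrow(net$nodes), 4)
  expect_equal(nrow(net$edges), 3)
  expect_identical(sort(unique(net$edges$mirna_id)), "MIR01")
  expect_false("MG03" %in% net$nodes$node_id)
  # invariant: every surviving miRNA bridges both classes
  for (m in unique(net$edges$mirna_id)) {
    cls_m <- net$edges$target_class[net$edges$mirna_id == m]
    expect_true(all(c("lncRNA", "mRNA") %in% cls_m))
  }
})

test_that("edges below the correlation gate are excluded regardless of p", {
  n <- 200
  set.seed(3)
  f <- rnorm(n)
  # r about 0.25: highly significant at n = 200 yet below the |r| gate
  vals <- list(MIR01 = 2^(5 + f),
               LNC01 = 2^(5 - 0.26 * f + rnorm(n)),
               MG01 = 2^(5 - f))
  cls <- c(MIR01 = "miRNA", LNC01 = "lncRNA", MG01 = "mRNA")
  cat <- data.frame(mirna_id = "MIR01", target_id = c("LNC01", "MG01"),
                    target_class = c("lncRNA", "mRNA"), ago_sites = 1L,
                    stringsAsFactors = FALSE)
  inst <- hand_instance(vals, cls, cat, n)
  r_lnc <- cor(log2(vals$MIR01), log2(vals$LNC01))
  expect_lt(abs(r_lnc), 0.3)
  expect_lt(oracle_pearson(vals$MIR01, vals$LNC01)$p, 0.01)
  # with the weak lncRNA edge excluded, MIR01 loses its lncRNA support
  expect_warning(net <- build_network(inst$de, inst$catalog, inst$bundle),
                 "empty")
  expect_equal(nrow(net$edges), 0)
})

test_that("no DE miRNAs yields an empty network with a warning", {
  n <- 10
  vals <- list(MIR01 = 2^rnorm(n, 5), MG01 = 2^rnorm(n, 5))
  cls <- c(MIR01 = "miRNA", MG01 = "mRNA")
  cat <- data.frame(mirna_id = "MIR01", target_id = "MG01",
                    target_class = "mRNA", ago_sites = 1L)
  inst <- hand_instance(vals, cls, cat, n)
  inst$de$mirna$direction <- "ns"
  expect_warning(net <- build_network(inst$de, inst$catalog, inst$bundle),
                 "empty")
  expect_equal(nrow(net$nodes), 0)
})

test_that("build_network equals the brute-force double-loop filter on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    n_mir <- 4; n_lnc <- 6; n_mrna <- 10
    ids <- c(sprintf("MIR%02d", 1:n_mir), sprintf("LNC%02d", 1:n_lnc),
             sprintf("MG%02d", 1:n_mrna))
    cls <- c(rep("miRNA", n_mir), rep("lncRNA", n_lnc), rep("mRNA", n_mrna))
    names(cls) <- ids
    f <- rnorm(n)
    vals <- lapply(ids, function(id) {
      if (runif(1) < 0.5) 2^(5 + sample(c(-1, 1), 1) * f + rnorm(n, 0, 0.6))
      else 2^rnorm(n, 5)
    })
    names(vals) <- ids
    targets <- ids[cls != "miRNA"]
    cat <- expand.grid(mirna_id = ids[cls == "miRNA"], target_id = targets,
                       stringsAsFactors = FALSE)
    cat <- cat[runif(nrow(cat)) < 0.5, ]
    cat$target_class <- unname(cls[cat$target_id])
    cat$ago_sites <- 1L
    inst <- hand_instance(vals, cls, cat, n)
    # random subset of genes is DE
    for (k in names(inst$de)) {
      d <- inst$de[[k]]
      d$direction[runif(nrow(d)) < 0.3] <- "ns"
      inst$de[[k]] <- d
    }
    de_mir <- inst$de$mirna$gene_id[inst$de$mirna$direction != "ns"]
    de_tgt <- c(inst$de$mrna$gene_id[inst$de$mrna$direction != "ns"],
                inst$de$lncrna$gene_id[inst$de$lncrna$direction != "ns"])
    expr <- do.call(rbind, lapply(vals, rbind))
    rownames(expr) <- ids
    ref <- oracle_build_network(de_mir, de_tgt, as.list(cls), cat, expr)
    got <- suppressWarnings(build_network(inst$de, cat, inst$bundle))
    key <- function(d) sort(paste(d$mirna_id, d$target_id))
    expect_identical(key(got$edges), key(ref))
  }
})

test_that("raising the correlation threshold never adds edges", {
  co <- small_cohort(seed = 6L)
  filtered <- lapply(co$expression, filter_low_expression)
  de <- lapply(filtered, run_de, samples = co$samples)
  cat <- filter_ago(co$interactions)
  n_edges <- vapply(c(0.3, 0.5, 0.7, 0.9), function(r)
    nrow(suppressWarnings(
      build_network(de, cat, filtered, r_threshold = r))$edges), numeric(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("degree summary counts fractions from the node degrees", {
  star <- toy_star("MIR01", 2, 10, r = 0.9)
  net <- toy_network(star)
  ds <- degree_summary(net)
  expect_equal(ds$frac_deg_lt5, 12 / 13)
  expect_equal(ds$frac_deg_gt10, 1 / 13)
  single <- toy_network(toy_star("MIR01", 1, 0, r = 0.5))
  ds1 <- degree_summary(single)
  expect_equal(ds1$frac_deg_lt5, 1)
  expect_equal(ds1$frac_deg_gt10, 0)
  empty <- suppressWarnings(build_network(
    list(mrna = data.frame(gene_id = character(0), direction = character(0)),
         lncrna = data.frame(gene_id = character(0), direction = character(0)),
         mirna = data.frame(gene_id = character(0), direction = character(0))),
    data.frame(mirna_id = character(0), target_id = character(0),
               target_class = character(0), ago_sites = integer(0)),
    toy_bundle_with_scores(c(a = 1, b = 2, c = 3))))
  expect_error(degree_summary(empty), "empty")
})
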