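toy_expr <- function(n_genes, n_samples, seed = 1, prefix = "g") {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 5), n_genes, n_samples,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

test_that("coexpression partners rank by average correlation with lexicographic ties", {
  nc <- toy_expr(1, 20, seed = 2, prefix = "nc")
  mr <- toy_expr(10, 20, seed = 3, prefix = "m")
  mr["m01", ] <- nc["nc01", ]                # identical: r = 1
  res <- coexpression_partners("nc01", nc, mr, top_n = 5)
  expect_identical(res$gene_id[1], "m01")
  expect_equal(res$avg_r[1], 1)
  expect_equal(nrow(res), 5)
  # pool smaller than top_n: everything returned, flagged short
  expect_message(res2 <- coexpression_partners("nc01", nc, mr, top_n = 500),
                 "only 10")
  expect_equal(nrow(res2), 10)
  expect_true(attr(res2, "short"))
})

test_that("coexpression ranking equals the brute-force double loop", {
  nc <- toy_expr(3, 15, seed = 4, prefix = "nc")
  mr <- toy_expr(10, 15, seed = 5, prefix = "m")
  res <- coexpression_partners(rownames(nc), nc, mr, top_n = 10)
  avg <- vapply(rownames(mr), function(g) {
    rs <- vapply(rownames(nc), function(h) {
      oracle_pearson(mr[g, ], nc[h, ])$r
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  ord <- order(-avg, names(avg))
  expect_identical(res$gene_id, names(avg)[ord])
  expect_equal(res$avg_r, unname(avg[ord]), tolerance = 1e-12)
})

test_that("hypergeometric ORA reproduces the exact combinatorial tail", {
  u <- paste0("g", 1:20)
  res <- ora_hypergeometric(u[1:5], u[c(1:4, 10)], u)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 4)
  # zero overlap: the upper tail carries full mass
  expect_equal(ora_hypergeometric(u[1:5], u[11:15], u)$p - 1, 0,
               tolerance = 1e-12)
  expect_gte(ora_hypergeometric(u[1:5], u[11:15], u)$k, 0)
  # query = universe: the single possible outcome
  expect_equal(ora_hypergeometric(u, u[1:5], u)$p, 1, tolerance = 1e-12)
  expect_error(ora_hypergeometric("g1", "g1", character(0)), "universe")
  expect_error(ora_hypergeometric("zz", "g1", u), "subset")
})

test_that("hypergeometric p matches exhaustive subset enumeration for small universes", {
  set.seed(6)
  for (i in 1:20) {
    N <- sample(6:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    u <- paste0("g", seq_len(N))
    q <- sample(u, n)
    s <- u[seq_len(K)]
    k <- length(intersect(q, s))
    got <- ora_hypergeometric(q, s, u)$p
    expect_equal(got, oracle_hyper_enum(k, K, n, N), tolerance = 1e-9)
    expect_equal(got, oracle_hyper_sum(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("BH adjustment across a collection preserves the p ordering", {
  u <- paste0("g", 1:50)
  sets <- list(A = u[1:10], B = u[11:30], C = u[c(1:5, 31:35)])
  res <- ora_collection(u[1:12], sets, u)
  expect_equal(nrow(res), 3)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_equal(order(res$p), order(res$q))
})

test_that("preranked ES matches the brute-force walk and its symmetries", {
  w <- setNames(seq(10, 1), paste0("g", 1:10))
  res <- preranked_gsea(w, c("g1", "g2"), n_perm = 200, seed = 1L)
  # both members sit atop the ranking: the running sum peaks at 1
  expect_equal(res$es, 1, tolerance = 1e-12)
  expect_equal(res$es, oracle_es_preranked(w, c("g1", "g2")),
               tolerance = 1e-12)
  expect_true(res$p_perm >= 1 / 201 && res$p_perm <= 1)

  # reversing the ranking puts the set at the bottom: ES negates
  res_rev <- preranked_gsea(setNames(rev(unname(w)), names(w)),
                            c("g1", "g2"), n_perm = 200, seed = 1L)
  expect_lt(res_rev$es, 0)
  expect_equal(abs(res_rev$es), abs(oracle_es_preranked(
    setNames(rev(unname(w)), names(w)), c("g1", "g2"))), tolerance = 1e-12)

  expect_error(preranked_gsea(w, c("zz"), n_perm = 10), "no overlap")
})

test_that("preranked ES equals the walk oracle on random instances", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    w <- setNames(rnorm(n), paste0("g", seq_len(n)))
    members <- sample(names(w), sample(2:5, 1))
    got <- preranked_gsea(w, members, n_perm = 10, seed = i)$es
    expect_equal(got, oracle_es_preranked(w, members), tolerance = 1e-9)
  }
})

test_that("ssGSEA scores match the walk oracle and depend only on ranks", {
  expr <- toy_expr(10, 4, seed = 8)
  sets <- list(top = rownames(expr)[order(-expr[, 1])][1:3],
               other = rownames(expr)[4:6])
  sc <- ssgsea_scores(expr, sets, tau = 0, normalize = FALSE)
  for (s in colnames(expr))
    for (nm in names(sets))
      expect_equal(sc[nm, s],
                   oracle_ssgsea_one(expr[, s], rownames(expr), sets[[nm]], 0),
                   tolerance = 1e-9)
  # tau = 0.25 as well
  sc25 <- ssgsea_scores(expr, sets, tau = 0.25, normalize = FALSE)
  expect_equal(sc25["top", 2],
               oracle_ssgsea_one(expr[, 2], rownames(expr), sets$top, 0.25),
               tolerance = 1e-9)

  # identical rankings give identical columns
  expr2 <- expr
  expr2[, 2] <- expr2[, 1] * 3
  sc2 <- ssgsea_scores(expr2, sets, normalize = FALSE)
  expect_equal(sc2[, 1], sc2[, 2])

  # monotone within-sample transform leaves scores unchanged
  expr3 <- expr
  expr3[, 3] <- exp(expr3[, 3] / max(expr3[, 3]))
  sc3 <- ssgsea_scores(expr3, sets, normalize = FALSE)
  expect_equal(unname(sc3[, 3]),
               unname(ssgsea_scores(expr, sets, normalize = FALSE)[, 3]))

  # an unexpressed set scores NA with a warning
  expect_warning(scna <- ssgsea_scores(expr, c(sets, list(ghost = "zz")),
                                       normalize = FALSE),
                 "no expressed member")
  expect_true(all(is.na(scna["ghost", ])))
})

test_that("module-pathway correlation flags undefined pairs and finds planted structure", {
  expr <- toy_expr(10, 30, seed = 9)
  sets <- list(A = rownames(expr)[1:4], B = rownames(expr)[5:8])
  sc <- ssgsea_scores(expr, sets)
  ms <- setNames(as.numeric(sc["A", ]), colnames(sc))
  tab <- module_pathway_correlation(ms, sc)
  expect_equal(tab$r[tab$set_name == "A"], 1, tolerance = 1e-12)
  sc_const <- rbind(sc, C = 1)
  tab2 <- module_pathway_correlation(ms, sc_const)
  expect_true(tab2$undefined[tab2$set_name == "C"])
  expect_true(is.na(tab2$r[tab2$set_name == "C"]))
})

test_that("the planted-enriched pathway tracks the prognostic module positively", {
  co <- simulate_cohort(sim_config(seed = 23L))
  filtered <- lapply(co$expression, filter_low_expression)
  sc <- ssgsea_scores(filtered$mrna, co$gene_sets)
  pm <- co$truth$planted_modules[[co$truth$prognostic_module_index]]
  ms <- module_score(pm, filtered)
  tab <- module_pathway_correlation(ms, sc)
  planted <- co$truth$enriched_sets[1]
  expect_gt(tab$r[tab$set_name == planted], 0)
  expect_lt(tab$p[tab$set_name == planted], 0.01)
  # shuffling sample labels destroys the correlation
  set.seed(1)
  null_r <- replicate(20, {
    ms_perm <- setNames(sample(ms), names(ms))
    module_pathway_correlation(ms_perm, sc)$r[tab$set_name == planted]
  })
  expect_lt(mean(abs(null_r)), 0.25)
})

test_that("group score comparison tests every set and needs two groups", {
  expr <- toy_expr(20, 24, seed = 10)
  sets <- list(A = rownames(expr)[1:5], B = rownames(expr)[6:10],
               C = rownames(expr)[11:15])
  sc <- ssgsea_scores(expr, sets)
  labels <- rep(1:2, each = 12)
  res <- compare_group_scores(sc, labels)
  expect_equal(nrow(res), length(sets))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_error(compare_group_scores(sc, rep(1, 24)), "2 groups")

  # identical groups: null p
  sc_dup <- cbind(sc[, 1:12], sc[, 1:12])
  colnames(sc_dup) <- paste0("x", 1:24)
  res_dup <- compare_group_scores(sc_dup, labels)
  expect_true(all(res_dup$p > 0.9))

  # a planted two-SD shift is detected
  set.seed(11)
  base <- matrix(rnorm(2 * 80), 2, 80,
                 dimnames = list(c("S1", "S2"), paste0("s", 1:80)))
  shifted <- base
  shifted["S1", 41:80] <- shifted["S1", 41:80] + 2
  res_shift <- compare_group_scores(shifted, rep(1:2, each = 40))
  expect_lt(res_shift$p[res_shift$set_name == "S1"], 0.01)
  expect_gt(res_shift$p[res_shift$set_name == "S2"], 0.05)
})
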