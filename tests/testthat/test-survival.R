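test_that("k-means stratification splits separable clouds and canonicalizes labels", {
  set.seed(2)
  n <- 30
  hi <- matrix(2^rnorm(5 * (n / 2), 10, 0.1), 5)
  lo <- matrix(2^rnorm(5 * (n / 2), 0.5, 0.1), 5)
  m <- cbind(hi, lo)
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:n))
  labels <- kmeans_stratify(m, seed = 1L)
  expect_identical(unname(labels[1:(n / 2)]), rep(1L, n / 2))
  expect_identical(unname(labels[(n / 2 + 1):n]), rep(2L, n / 2))
  # group 1 is always the high-expression group, whatever the seed
  for (s in 2:5)
    expect_identical(kmeans_stratify(m, seed = s), labels)
})

test_that("two samples split one per group; degenerate input errors", {
  m <- matrix(c(1, 2, 10, 20), 2, dimnames = list(c("g1", "g2"),
                                                  c("s1", "s2")))
  labels <- kmeans_stratify(m, seed = 3L)
  expect_setequal(unname(labels), 1:2)
  expect_error(kmeans_stratify(m[, 1, drop = FALSE]), "cannot split")
  flat <- matrix(1, 2, 5, dimnames = list(c("g1", "g2"), paste0("s", 1:5)))
  expect_error(kmeans_stratify(flat), "variation")
})

test_that("stratification labels track the planted prognostic score", {
  # on a continuous latent score k-means recovers a threshold split of the
  # truth (the boundary itself is data-driven, not pinned to the median)
  for (s in c(31L, 5L, 9L)) {
    co <- simulate_cohort(sim_config(seed = s))
    pm <- co$truth$planted_modules[[co$truth$prognostic_module_index]]
    expr <- do.call(rbind, co$expression)
    tumor <- co$samples$sample_id[co$samples$condition == "tumor"]
    labels <- kmeans_stratify(expr[pm, tumor], seed = 17L)
    z <- co$truth$prognostic_score[tumor]
    thr_agree <- max(vapply(c(-Inf, sort(z)), function(c0)
      max(mean((labels == 1) == (z > c0)),
          mean((labels == 2) == (z > c0))), numeric(1)))
    expect_gte(thr_agree, 0.9)
    # the extreme quarters of the planted score land in the right group
    outer <- z >= quantile(z, 0.75) | z <= quantile(z, 0.25)
    hi <- z >= median(z)
    outer_agree <- max(mean((labels[outer] == 1) == hi[outer]),
                       mean((labels[outer] == 2) == hi[outer]))
    expect_gte(outer_agree, 0.9)
  }
})

test_that("Kaplan-Meier estimator matches product-limit arithmetic", {
  km <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(km$time, c(0, 1, 2, 3))
  expect_equal(km$surv[km$time == 0], 1)

  km2 <- km_estimator(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 2], 2 / 3)  # censoring: no step
  expect_equal(km2$surv[km2$time == 3], 0)

  # without censoring KM equals the empirical survival function
  set.seed(4)
  times <- sample(1:20, 15, replace = TRUE)
  km3 <- km_estimator(times, rep(1, 15))
  for (i in seq_len(nrow(km3)))
    expect_equal(km3$surv[i], mean(times > km3$time[i]))

  expect_error(km_estimator(numeric(0), numeric(0)), "no observations")
})

test_that("log-rank matches the brute-force O-E computation and its contracts", {
  same <- list(times = c(1, 2, 3, 4), events = c(1, 1, 1, 1))
  lr <- logrank_test(c(same$times, same$times), c(same$events, same$events),
                     rep(1:2, each = 4))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  t6 <- c(1, 2, 3, 4, 5, 6); e6 <- rep(1, 6); g6 <- rep(1:2, each = 3)
  got <- logrank_test(t6, e6, g6)
  ref <- oracle_logrank(t6, e6, g6)
  expect_equal(got$chi_square, ref$chi_square, tolerance = 1e-8)

  swap <- logrank_test(t6, e6, 3 - g6)
  expect_equal(swap$chi_square, got$chi_square, tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(1, 2)), "zero observed events")
  expect_error(logrank_test(1:3, c(1, 1, 1), c(1, 1, 1)), "2 groups")
})

test_that("log-rank agrees with the reference on random censored datasets", {
  for (seed in 1:50) {
    d <- random_survival(n = sample(10:40, 1), seed = seed)
    if (sum(d$events) == 0 || length(unique(d$labels)) < 2) next
    got <- logrank_test(d$times, d$events, d$labels)
    ref <- oracle_logrank(d$times, d$events, d$labels)
    expect_equal(got$chi_square, ref$chi_square, tolerance = 1e-8)
    expect_equal(got$p, ref$p, tolerance = 1e-8)
  }
})

test_that("module expression test recovers the exact rank-sum p and direction", {
  scores <- c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6)
  bundle <- toy_bundle_with_scores(scores)
  samples <- data.frame(sample_id = names(scores),
                        condition = c(rep("tumor", 3), rep("normal", 3)),
                        stringsAsFactors = FALSE)
  res <- module_expression_test(c("MG0001", "LNC0001", "MIR0001"),
                                bundle, samples, pseudocount = 0)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  expect_identical(res$direction, "down")
  ref <- oracle_ranksum_exact(1:3, 4:6)
  expect_equal(res$p, ref$p)

  expect_error(module_expression_test("GHOST", bundle, samples), "GHOST")
})

test_that("identical score distributions give a null rank-sum p", {
  set.seed(5)
  vals <- rnorm(40, 5)
  scores <- setNames(vals, sprintf("s%02d", 1:40))
  bundle <- toy_bundle_with_scores(scores)
  samples <- data.frame(sample_id = names(scores),
                        condition = rep(c("tumor", "normal"), 20),
                        stringsAsFactors = FALSE)
  ps <- replicate(20, {
    samples$condition <- sample(samples$condition)
    module_expression_test("MG0001", bundle, samples)$p
  })
  expect_gt(mean(ps), 0.3)
})

test_that("stratify_module excludes samples with missing survival and reports curves", {
  co <- small_cohort(seed = 12L)
  co$samples$survival_days[co$samples$condition == "tumor"][1:3] <- NA
  pm <- co$truth$planted_modules[[1]]
  expect_message(st <- stratify_module(pm, co$expression, co$samples,
                                       seed = 2L),
                 "excluding 3")
  expect_equal(sum(st$group_sizes),
               sum(co$samples$condition == "tumor") - 3)
  expect_length(st$km_curves, 2)
  for (km in st$km_curves) {
    expect_equal(km$surv[1], 1)
    expect_true(all(diff(km$surv) <= 1e-12))
  }
  expect_true(st$p_logrank > 0 && st$p_logrank <= 1)
})
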