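# Independent brute-force reference implementations used to cross-check the
# package's statistics. Deliberately written as plain loops over the defining
# formulas, sharing no code with the implementation paths they verify.

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  xm <- x - mean(x); ym <- y - mean(y)
  r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Log-rank chi-square from the defining O-E / hypergeometric-variance sums
# at each distinct event time.
oracle_logrank <- function(times, events, labels) {
  g1 <- labels == unique(labels)[1]
  o_minus_e <- 0
  v <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# Exact two-sided rank-sum p by enumerating every group assignment.
oracle_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combos <- combn(length(pooled), n)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  u_all <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

# Upper-tail hypergeometric p by exhaustive enumeration of all n-subsets.
oracle_hyper_enum <- function(k, K, n, N) {
  universe <- seq_len(N)
  members <- seq_len(K)
  combos <- combn(N, n)
  hits <- apply(combos, 2, function(q) sum(q %in% members) >= k)
  mean(hits)
}

# Upper-tail hypergeometric p from the combinatorial sum.
oracle_hyper_sum <- function(k, K, n, N) {
  s <- 0
  for (i in k:min(K, n))
    s <- s + choose(K, i) * choose(N - K, n - i)
  s / choose(N, n)
}

# Preranked GSEA enrichment score by an explicit step-by-step walk.
oracle_es_preranked <- function(weights, gene_set) {
  ord <- order(-weights, names(weights))
  w <- weights[ord]
  member <- names(w) %in% gene_set
  wsum <- sum(abs(w[member]))
  n_out <- sum(!member)
  running <- 0
  best <- 0
  for (i in seq_along(w)) {
    if (member[i]) running <- running + abs(w[[i]]) / wsum
    else running <- running - 1 / n_out
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}

# Single-sample GSEA score for one sample by an explicit walk.
oracle_ssgsea_one <- function(values, genes, gene_set, tau) {
  rk <- rank(values, ties.method = "average")
  ord <- order(-rk, genes)
  member <- genes[ord] %in% gene_set
  wts <- rk[ord]^tau
  N <- length(values)
  K <- sum(member)
  w_in <- 0
  n_out_seen <- 0
  total_in <- sum(wts[member])
  es <- 0
  for (i in seq_len(N)) {
    if (member[i]) w_in <- w_in + wts[[i]] else n_out_seen <- n_out_seen + 1
    es <- es + w_in / total_in - n_out_seen / (N - K)
  }
  unname(es)
}

# Kaplan-Meier product-limit estimate by an explicit loop.
oracle_km <- function(times, events) {
  s <- 1
  out <- data.frame(time = 0, surv = 1)
  for (tt in sort(unique(times[events == 1]))) {
    n_risk <- sum(times >= tt)
    d <- sum(times == tt & events == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = tt, surv = s))
  }
  out
}

# Brute-force two-step network filter: double loop over the catalog, then the
# shared-miRNA rule, no shortcuts.
oracle_build_network <- function(de_mirna, de_targets, target_class, catalog,
                                 expr, r_threshold = 0.3, p_threshold = 0.01) {
  edges <- list()
  for (i in seq_len(nrow(catalog))) {
    m <- catalog$mirna_id[i]; tg <- catalog$target_id[i]
    if (!(m %in% de_mirna) || !(tg %in% de_targets)) next
    ct <- oracle_pearson(expr[m, ], expr[tg, ])
    if (abs(ct$r) > r_threshold && ct$p < p_threshold)
      edges[[length(edges) + 1]] <-
        data.frame(mirna_id = m, target_id = tg,
                   target_class = target_class[[tg]],
                   stringsAsFactors = FALSE)
  }
  if (length(edges) == 0)
    return(data.frame(mirna_id = character(0), target_id = character(0)))
  e <- do.call(rbind, edges)
  keep_mir <- character(0)
  for (m in unique(e$mirna_id)) {
    cls <- e$target_class[e$mirna_id == m]
    if (any(cls == "lncRNA") && any(cls == "mRNA"))
      keep_mir <- c(keep_mir, m)
  }
  e[e$mirna_id %in% keep_mir, c("mirna_id", "target_id"), drop = FALSE]
}
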