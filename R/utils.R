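#' @importFrom stats cor cor.test kmeans p.adjust pchisq phyper pt rexp rnorm
#'   rpois runif sd t.test uniroot wilcox.test median quantile setNames
#' @importFrom utils head packageVersion
NULL

# log2 transform with pseudocount; the scale every test statistic works on
log2p <- function(x, pseudocount = 0.01) log2(x + pseudocount)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage-specific seed from a global seed
#'
#' Stochastic stages (k-means restarts, GSEA permutations) each draw their own
#' seed from the run's global seed so that inserting or reordering stages does
#' not silently shift the random streams of the others.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Validate an expression matrix: numeric, finite, non-negative, unique ids.
check_expression_matrix <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stopf("%s must have unique gene ids as rownames", what)
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stopf("%s must have unique sample ids as colnames", what)
  if (any(!is.finite(mat))) stopf("%s contains non-finite values", what)
  if (any(mat < 0)) stopf("%s contains negative values", what)
  invisible(mat)
}
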