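#' Parameters for deterministic module detection
#'
#' @param max_size Largest allowed module (node cap on merges).
#' @param min_size Smallest emitted module.
#' @param min_edge_strength Minimum `|r|` for an edge to drive merging.
#' @param require_all_classes Keep only modules containing at least one node
#'   of each RNA class.
#' @return A `module_params` list.
#' @export
module_params <- function(max_size = 20, min_size = 6,
                          min_edge_strength = 0, require_all_classes = TRUE) {
  if (min_size < 2 || min_size > max_size)
    stopf("need 2 <= min_size <= max_size")
  structure(list(max_size = max_size, min_size = min_size,
                 min_edge_strength = min_edge_strength,
                 require_all_classes = require_all_classes),
            class = "module_params")
}

#' Detect tri-class modules by size-capped agglomerative edge clustering
#'
#' A deterministic surrogate for hierarchical edge clustering on this
#' bipartite network (where common-neighbour edge weights degenerate): edges
#' are processed in order of decreasing `|r|` (ties broken lexicographically
#' on `(mirna_id, target_id)`) through a union-find, merging two clusters only
#' when the merged size stays within `max_size`. The resulting partition is
#' filtered to clusters within the size bounds that contain all three RNA
#' classes (when required). Output is invariant to the input order of nodes
#' and edges.
#'
#' @param network A `dysregulated_network`.
#' @param params A [module_params()].
#' @return A `module_set`: list of modules ordered by decreasing mean `|r|`,
#'   each with `module_id`, `nodes` (split by class), `edges` (induced),
#'   `mean_abs_r`.
#' @export
detect_modules <- function(network, params = module_params()) {
  stopifnot(inherits(network, "dysregulated_network"),
            inherits(params, "module_params"))
  edges <- network$edges
  nodes <- network$nodes
  if (nrow(edges) == 0) return(structure(list(), class = "module_set"))

  eord <- order(-abs(edges$r), edges$mirna_id, edges$target_id)
  edges_sorted <- edges[eord, , drop = FALSE]
  edges_sorted <- edges_sorted[abs(edges_sorted$r) >= params$min_edge_strength,
                               , drop = FALSE]

  ids <- sort(nodes$node_id)
  parent <- seq_along(ids)
  size <- rep(1L, length(ids))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges_sorted))) {
    a <- find(match(edges_sorted$mirna_id[k], ids))
    b <- find(match(edges_sorted$target_id[k], ids))
    if (a != b && size[a] + size[b] <= params$max_size) {
      parent[b] <- a
      size[a] <- size[a] + size[b]
    }
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  clusters <- split(ids, comp)

  mods <- list()
  for (cl in clusters) {
    if (length(cl) < params$min_size || length(cl) > params$max_size) next
    ncls <- nodes$rna_class[match(cl, nodes$node_id)]
    if (params$require_all_classes &&
        !all(c("mRNA", "lncRNA", "miRNA") %in% ncls)) next
    ind <- edges$mirna_id %in% cl & edges$target_id %in% cl
    e <- edges[ind, , drop = FALSE]
    e <- e[order(e$mirna_id, e$target_id), , drop = FALSE]
    rownames(e) <- NULL
    mods[[length(mods) + 1]] <- list(
      nodes = list(mrna = sort(cl[ncls == "mRNA"]),
                   lncrna = sort(cl[ncls == "lncRNA"]),
                   mirna = sort(cl[ncls == "miRNA"])),
      edges = e,
      mean_abs_r = mean(abs(e$r)))
  }
  if (length(mods) == 0) return(structure(list(), class = "module_set"))
  first_node <- vapply(mods, function(m)
    min(unlist(m$nodes)), character(1))
  ord <- order(-vapply(mods, `[[`, numeric(1), "mean_abs_r"), first_node)
  mods <- mods[ord]
  for (i in seq_along(mods)) mods[[i]]$module_id <- sprintf("M%d", i)
  structure(mods, class = "module_set")
}

#' Per-class node counts and interaction count of a module
#'
#' @param module One element of a `module_set`.
#' @return List `n_mrna`, `n_lncrna`, `n_mirna`, `n_nodes`, `n_interactions`.
#' @export
module_summary <- function(module) {
  stopifnot(is.list(module), !is.null(module$nodes), !is.null(module$edges))
  list(n_mrna = length(module$nodes$mrna),
       n_lncrna = length(module$nodes$lncrna),
       n_mirna = length(module$nodes$mirna),
       n_nodes = length(unlist(module$nodes)),
       n_interactions = nrow(module$edges))
}

#' All node ids of a module
#' @param module A module.
#' @return Sorted character vector.
#' @export
module_nodes <- function(module) sort(unname(unlist(module$nodes)))

#' Per-sample module score: mean log2 abundance over the module's RNAs
#'
#' @param module A module (or any character vector of gene ids).
#' @param expr_bundle Expression bundle with the three class matrices.
#' @param pseudocount Added before log2.
#' @return Named numeric vector over samples.
#' @export
module_score <- function(module, expr_bundle, pseudocount = 0.01) {
  genes <- if (is.character(module)) module else module_nodes(module)
  expr <- rbind(expr_bundle$mrna, expr_bundle$lncrna, expr_bundle$mirna)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0)
    stopf("module RNA '%s' absent from the expression matrices", missing[1])
  colMeans(log2p(expr[genes, , drop = FALSE], pseudocount))
}
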