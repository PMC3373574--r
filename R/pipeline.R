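# End-to-end orchestration: union graph -> ELI-scored alignment graph ->
# multi-ortholog correction -> local pruning -> seed enumeration/selection ->
# batch expansion into modules.

#' Align two PPI networks and discover conserved modules
#'
#' Runs the full pipeline and returns the discovered modules together with
#' the per-stage statistics (union/alignment graph sizes before and after
#' correction and pruning) that are the first thing to inspect on real data.
#'
#' @param net1,net2 [weighted_network()] objects.
#' @param hom a [homology_map()] (`p1` in `net1`, `p2` in `net2`).
#' @param prune_t local pruning threshold in (0, 1); see
#'   [prune_alignment_graph()].
#' @param k seed subgraph size (default 4).
#' @param min_module_size smallest emitted module, in alignment-graph nodes.
#' @param tight_factor expansion acceptance multiplier; see
#'   [accept_candidate()].
#' @param max_subgraphs enumeration cap; see
#'   [enumerate_connected_ksubgraphs()].
#' @param require_clique_seeds restrict seeds to k-cliques; see
#'   [select_seeds()].
#' @param verbose print per-stage statistics as the pipeline runs.
#' @return list of class `ppialign_result`: `modules`, `alignment_graph`,
#'   `stats` (stage statistics) and the resolved `config`.
#' @export
align_ppi <- function(net1, net2, hom, prune_t = 0.5, k = 4L,
                      min_module_size = 5L, tight_factor = 1,
                      max_subgraphs = 5e6, require_clique_seeds = FALSE,
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  ug <- build_union_graph(net1, net2, hom)
  us <- union_stats(ug)
  say("union graph: ", us$n_nodes, " nodes (", us$n_composite,
      " composite), ", us$n_edges, " edges (", us$n_edges_both, " conserved)")

  ag <- build_alignment_graph(ug)
  raw_nodes <- nrow(ag$nodes); raw_edges <- nrow(ag$edges)
  say("raw alignment graph: ", raw_nodes, " nodes, ", raw_edges, " edges")

  ag <- correct_multiortholog(ag)
  ag <- prune_alignment_graph(ag, t = prune_t)
  say("pruned alignment graph (t=", prune_t, "): ", nrow(ag$nodes),
      " nodes, ", nrow(ag$edges), " edges")

  pool <- enumerate_connected_ksubgraphs(ag, k = k,
                                         max_subgraphs = max_subgraphs)
  say("enumerated ", nrow(pool$sets), " connected ", k, "-subgraphs",
      if (pool$truncated) " (truncated)")
  sel <- select_seeds(pool, ag, require_clique = require_clique_seeds)
  say("selected ", length(sel$seed_rows), " node-disjoint seeds")

  modules <- discover_modules(ag, pool, sel, min_module_size = min_module_size,
                              tight_factor = tight_factor)
  say("emitted ", length(modules), " modules of >= ", min_module_size, " nodes")

  structure(list(
    modules = modules,
    alignment_graph = ag,
    stats = list(union = us,
                 alignment_raw = list(nodes = raw_nodes, edges = raw_edges),
                 alignment_pruned = list(nodes = nrow(ag$nodes),
                                         edges = nrow(ag$edges)),
                 prune = ag$prune_stats,
                 n_subgraphs = nrow(pool$sets),
                 subgraphs_truncated = pool$truncated,
                 n_seeds = length(sel$seed_rows),
                 n_modules = length(modules)),
    config = list(prune_t = prune_t, k = k, min_module_size = min_module_size,
                  tight_factor = tight_factor, max_subgraphs = max_subgraphs,
                  require_clique_seeds = require_clique_seeds)),
    class = "ppialign_result")
}

#' @export
print.ppialign_result <- function(x, ...) {
  s <- x$stats
  cat("ppialign_result: ", s$n_modules, " modules from ", s$n_seeds,
      " seeds\n", sep = "")
  cat("  union graph: ", s$union$n_nodes, " nodes / ", s$union$n_edges,
      " edges; alignment graph: ", s$alignment_raw$nodes, " -> ",
      s$alignment_pruned$nodes, " nodes, ", s$alignment_raw$edges, " -> ",
      s$alignment_pruned$edges, " edges after correction + pruning\n", sep = "")
  invisible(x)
}
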