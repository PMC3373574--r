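# Union graph: the merged two-network structure over composite (ortholog-pair)
# and simple (unmatched-protein) nodes that carries every input edge with a
# species support label.

composite_id <- function(p1, p2) paste(p1, p2, sep = "|")
simple_id <- function(p, species_idx) {
  if (!length(p)) return(character())
  paste0(p, "::", species_idx)
}

#' Merge two networks and a homology map into the union graph
#'
#' Composite nodes are created for homology pairs whose proteins both occur in
#' their respective networks; every remaining network protein becomes a simple
#' node. Each input edge (u, v) with weight w in species s induces a union
#' edge of score w and support s between every node containing u and every
#' node containing v (a protein may occur in several composite nodes, so one
#' input edge can be replicated). When the same unordered node pair receives
#' an edge from both species the edge is stored once with support `"both"` and
#' score equal to the sum of the two contributions.
#'
#' @param net1,net2 [weighted_network()] objects for species 1 and 2.
#' @param hom a [homology_map()]; `p1` refers to `net1`, `p2` to `net2`.
#' @return object of class `union_graph` with elements:
#'   \describe{
#'     \item{nodes}{data.frame `id`, `type` ("composite"/"simple"), `p1`, `p2`
#'       (underlying proteins; for simple nodes one of them is `NA`),
#'       `conf` (homology confidence; `NA` for simple nodes).}
#'     \item{edges}{data.frame `a`, `b` (node ids, `a < b`), `support`
#'       ("1", "2" or "both") and `score`.}
#'     \item{species}{the two species labels.}
#'   }
#' @export
build_union_graph <- function(net1, net2, hom) {
  stopifnot(inherits(net1, "weighted_network"), inherits(net2, "weighted_network"),
            inherits(hom, "homology_map"))
  keep <- hom$p1 %in% net1$nodes & hom$p2 %in% net2$nodes
  comp <- hom[keep, , drop = FALSE]
  comp_ids <- composite_id(comp$p1, comp$p2)

  matched1 <- unique(comp$p1)
  matched2 <- unique(comp$p2)
  simple1 <- setdiff(net1$nodes, matched1)
  simple2 <- setdiff(net2$nodes, matched2)

  nodes <- rbind(
    data.frame(id = comp_ids, type = rep("composite", length(comp_ids)),
               p1 = comp$p1, p2 = comp$p2, conf = comp$conf),
    data.frame(id = simple_id(simple1, 1L), type = rep("simple", length(simple1)),
               p1 = simple1, p2 = rep(NA_character_, length(simple1)),
               conf = rep(NA_real_, length(simple1))),
    data.frame(id = simple_id(simple2, 2L), type = rep("simple", length(simple2)),
               p1 = rep(NA_character_, length(simple2)), p2 = simple2,
               conf = rep(NA_real_, length(simple2)))
  )
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  # protein -> containing union-node ids, per species
  map1 <- data.table::data.table(
    p = c(comp$p1, simple1),
    node = c(comp_ids, simple_id(simple1, 1L)))
  map2 <- data.table::data.table(
    p = c(comp$p2, simple2),
    node = c(comp_ids, simple_id(simple2, 2L)))

  expand_edges <- function(net, map, species_idx) {
    ed <- data.table::as.data.table(net$edges)
    if (!nrow(ed)) {
      return(data.table::data.table(a = character(), b = character(),
                                    score = numeric(), species = character()))
    }
    x <- merge(ed, map, by.x = "a", by.y = "p", allow.cartesian = TRUE)
    data.table::setnames(x, "node", "na")
    x <- merge(x, map, by.x = "b", by.y = "p", allow.cartesian = TRUE)
    data.table::setnames(x, "node", "nb")
    x <- x[x$na != x$nb, ]
    lo <- pmin(x$na, x$nb); hi <- pmax(x$na, x$nb)
    data.table::data.table(a = lo, b = hi, score = x$w,
                           species = as.character(species_idx))
  }

  e1 <- expand_edges(net1, map1, 1L)
  e2 <- expand_edges(net2, map2, 2L)
  all_e <- rbind(e1, e2)
  if (nrow(all_e)) {
    edges <- all_e[, list(
      support = if (length(unique(species)) == 2L) "both" else species[1],
      score = sum(score)), by = c("a", "b")]
    data.table::setkeyv(edges, c("a", "b"))
    edges <- as.data.frame(edges)
  } else {
    edges <- data.frame(a = character(), b = character(),
                        support = character(), score = numeric())
  }

  structure(list(nodes = nodes, edges = edges,
                 species = c(net1$species, net2$species)),
            class = "union_graph")
}

#' Summary statistics of a union graph
#'
#' @param ug a `union_graph`.
#' @return list with node counts (composite, simple, total) and edge counts by
#'   support class.
#' @export
union_stats <- function(ug) {
  supp <- table(factor(ug$edges$support, levels = c("1", "2", "both")))
  list(
    n_composite = sum(ug$nodes$type == "composite"),
    n_simple = sum(ug$nodes$type == "simple"),
    n_nodes = nrow(ug$nodes),
    n_edges = nrow(ug$edges),
    n_edges_species1 = unname(supp[["1"]]),
    n_edges_species2 = unname(supp[["2"]]),
    n_edges_both = unname(supp[["both"]])
  )
}

#' @export
print.union_graph <- function(x, ...) {
  s <- union_stats(x)
  cat("union_graph (", paste(x$species, collapse = " / "), "): ",
      s$n_composite, " composite + ", s$n_simple, " simple nodes, ",
      s$n_edges, " edges (", s$n_edges_both, " conserved)\n", sep = "")
  invisible(x)
}

#' Dump a union graph as TSV (debug aid)
#' @param ug a `union_graph`.
#' @param path output path.
#' @export
write_union_graph <- function(ug, path) {
  ed <- ug$edges
  writeLines(c("#nodeA\tnodeB\tsupport\tscore",
               sprintf("%s\t%s\t%s\t%s", ed$a, ed$b, ed$support,
                       format(ed$score, digits = 15))), path)
  invisible(NULL)
}
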