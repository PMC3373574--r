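# Alignment graph construction: Jaccard-style edge scoring over direct and
# length-2 path evidence in the union graph (the "extended local interactome"
# of a pair of ortholog-pair nodes), followed by multiple-ortholog rank
# correction and local pruning.

# A length-2 union-graph path is *valid* (non-spurious) iff a single species
# supports both of its edges; support "both" satisfies either species. A path
# supported by species 1 on one edge and species 2 only on the other
# corresponds to no path in either input network and is ignored.
supports_compatible <- function(s1, s2) s1 == s2 | s1 == "both" | s2 == "both"

directed_union_edges <- function(ug) {
  ed <- ug$edges
  data.table::data.table(
    from = c(ed$a, ed$b), to = c(ed$b, ed$a),
    score = c(ed$score, ed$score), support = c(ed$support, ed$support))
}

# Bulk computation of all per-pair path evidence and per-node path masses.
# Returns: pairs (a < b, w1, p2, n2) over composite pairs with any valid path
# of length <= 2, and per-composite-node totals S1 (direct union-edge score to
# composite neighbours) and S2 (total score of valid length-2 paths to other
# composite nodes; intermediates may be simple or composite).
eli_tables <- function(ug) {
  is_comp <- ug$nodes$type == "composite"
  comp_ids <- ug$nodes$id[is_comp]
  E <- directed_union_edges(ug)
  E$from_comp <- E$from %in% comp_ids
  E$to_comp <- E$to %in% comp_ids

  # direct evidence
  dir_cc <- E[E$from_comp & E$to_comp, ]
  if (nrow(dir_cc)) {
    S1 <- dir_cc[, list(S1 = sum(score)), by = "from"]
    w1 <- dir_cc[dir_cc$from < dir_cc$to,
                 list(a = from, b = to, w1 = score)]
  } else {
    S1 <- data.table::data.table(from = character(), S1 = numeric())
    w1 <- data.table::data.table(a = character(), b = character(), w1 = numeric())
  }

  # length-2 paths: composite -> (any) -> composite, species-compatible edges
  lhs <- E[E$from_comp, list(from, mid = to, s1 = score, sup1 = support)]
  rhs <- E[E$to_comp, list(mid = from, to, s2 = score, sup2 = support)]
  P <- merge(lhs, rhs, by = "mid", allow.cartesian = TRUE)
  P <- P[P$from != P$to & supports_compatible(P$sup1, P$sup2), ]
  if (nrow(P)) {
    P$pscore <- P$s1 + P$s2
    S2 <- P[, list(S2 = sum(pscore)), by = "from"]
    P2 <- P[P$from < P$to,
            list(p2 = sum(pscore), n2 = .N), by = c("from", "to")]
    data.table::setnames(P2, c("from", "to"), c("a", "b"))
  } else {
    S2 <- data.table::data.table(from = character(), S2 = numeric())
    P2 <- data.table::data.table(a = character(), b = character(),
                                 p2 = numeric(), n2 = integer())
  }

  pairs <- merge(w1, P2, by = c("a", "b"), all = TRUE)
  pairs$w1[is.na(pairs$w1)] <- 0
  pairs$p2[is.na(pairs$p2)] <- 0
  pairs$n2[is.na(pairs$n2)] <- 0L

  s1v <- stats::setNames(rep(0, length(comp_ids)), comp_ids)
  s1v[S1$from] <- S1$S1
  s2v <- stats::setNames(rep(0, length(comp_ids)), comp_ids)
  s2v[S2$from] <- S2$S2
  list(pairs = pairs, S1 = s1v, S2 = s2v)
}

#' Direct and valid length-2 paths between two composite nodes
#'
#' Returns the direct union-edge score between `a` and `b` (0 when absent) and
#' every non-spurious length-2 path `a - x - b`: paths whose two edges are
#' supported by a common species (support `"both"` counts for either). Each
#' path is scored by the sum of its two union-edge scores.
#'
#' @param ug a `union_graph`.
#' @param a,b distinct composite node ids.
#' @return list with `w1` (direct score) and `paths` (data.frame `mid`,
#'   `score`, one row per valid length-2 path).
#' @export
valid_paths <- function(ug, a, b) {
  check_composite(ug, c(a, b))
  if (a == b) stop("'a' and 'b' must be distinct composite nodes")
  E <- directed_union_edges(ug)
  dir <- E[E$from == a & E$to == b, ]
  w1 <- if (nrow(dir)) dir$score[1] else 0
  ea <- E[E$from == a & E$to != b, list(mid = to, s1 = score, sup1 = support)]
  eb <- E[E$to == b & E$from != a, list(mid = from, s2 = score, sup2 = support)]
  P <- merge(ea, eb, by = "mid", allow.cartesian = TRUE)
  P <- P[supports_compatible(P$sup1, P$sup2), ]
  paths <- data.frame(mid = P$mid, score = P$s1 + P$s2)
  paths <- paths[order(paths$mid), , drop = FALSE]
  rownames(paths) <- NULL
  list(w1 = w1, paths = paths)
}

check_composite <- function(ug, ids) {
  comp <- ug$nodes$id[ug$nodes$type == "composite"]
  miss <- setdiff(ids, comp)
  if (length(miss))
    stop("not (a) composite node(s) of the union graph: ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Extended-local-interactome (ELI) score of a composite-node pair
#'
#' The edge score of the alignment graph. The direct component is the
#' Jaccard-style ratio of the direct union-edge score w1(a, b) over the union
#' of the two endpoints' direct path masses, `w1 / (S1(a) + S1(b) - w1)`; the
#' indirect component is the analogous ratio for valid length-2 paths,
#' `P2 / (S2(a) + S2(b) - P2)`. Per-node masses S1 and S2 sum path scores to
#' *composite* endpoints only (intermediate nodes of length-2 paths may be
#' simple). A component with zero numerator (or denominator) is 0.
#'
#' @param ug a `union_graph`.
#' @param a,b distinct composite node ids.
#' @return list of class `eli_breakdown`: `w1`, `direct_denominator`, `p2`,
#'   `indirect_denominator`, `c_dir`, `c_ind`, `total`, `path_count_len2`.
#' @export
eli_score <- function(ug, a, b) {
  check_composite(ug, c(a, b))
  tab <- eli_tables(ug)
  lo <- min(a, b); hi <- max(a, b)
  row <- tab$pairs[tab$pairs$a == lo & tab$pairs$b == hi, ]
  w1 <- if (nrow(row)) row$w1 else 0
  p2 <- if (nrow(row)) row$p2 else 0
  n2 <- if (nrow(row)) row$n2 else 0L
  dd <- tab$S1[[a]] + tab$S1[[b]] - w1
  di <- tab$S2[[a]] + tab$S2[[b]] - p2
  out <- list(
    w1 = w1, direct_denominator = dd,
    p2 = p2, indirect_denominator = di,
    c_dir = if (w1 > 0 && dd > 0) w1 / dd else 0,
    c_ind = if (p2 > 0 && di > 0) p2 / di else 0,
    path_count_len2 = as.integer(n2))
  out$total <- out$c_dir + out$c_ind
  class(out) <- "eli_breakdown"
  out
}

#' Build the raw alignment graph from a union graph
#'
#' Nodes are the composite (ortholog-pair) nodes of the union graph, scored by
#' their homology confidence; an edge joins every pair of composite nodes with
#' a positive ELI score, i.e. pairs at distance at most 2 in the union graph
#' connected by at least one valid path. Candidate pairs are found by scanning
#' 1- and 2-hop neighbourhoods, never all pairs. Composite nodes left without
#' any alignment edge are dropped.
#'
#' @param ug a `union_graph`.
#' @return object of class `alignment_graph` with `nodes` (data.frame `id`,
#'   `p1`, `p2`, `node_score`) and `edges` (data.frame `a`, `b`, `w1`, `p2`,
#'   `path_count`, `c_dir`, `c_ind`, `total`, `corrected`); `corrected` equals
#'   `total` until [correct_multiortholog()] is applied.
#' @export
build_alignment_graph <- function(ug) {
  tab <- eli_tables(ug)
  pr <- tab$pairs
  dd <- tab$S1[pr$a] + tab$S1[pr$b] - pr$w1
  di <- tab$S2[pr$a] + tab$S2[pr$b] - pr$p2
  c_dir <- ifelse(pr$w1 > 0 & dd > 0, pr$w1 / dd, 0)
  c_ind <- ifelse(pr$p2 > 0 & di > 0, pr$p2 / di, 0)
  total <- c_dir + c_ind
  keep <- total > 0
  edges <- data.frame(a = pr$a, b = pr$b, w1 = pr$w1, p2 = pr$p2,
                      path_count = pr$n2, c_dir = c_dir, c_ind = c_ind,
                      total = total, corrected = total)[keep, , drop = FALSE]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL

  nd <- ug$nodes[ug$nodes$type == "composite", , drop = FALSE]
  used <- nd$id %in% c(edges$a, edges$b)
  nodes <- data.frame(id = nd$id[used], p1 = nd$p1[used], p2 = nd$p2[used],
                      node_score = nd$conf[used])
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  structure(list(nodes = nodes, edges = edges, species = ug$species,
                 corrected_applied = FALSE, prune_stats = NULL),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat("alignment_graph: ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges",
      if (isTRUE(x$corrected_applied)) " (multi-ortholog corrected)",
      if (!is.null(x$prune_stats)) sprintf(" (pruned at t=%g)", x$prune_stats$t),
      "\n", sep = "")
  invisible(x)
}

#' Multiple-ortholog rank correction of alignment-edge scores
#'
#' Proteins with several putative orthologs occur in several composite nodes.
#' For each node x and each maximal group of >= 2 of x's neighbours that share
#' the same underlying protein of one species, the edges (x, neighbour) are
#' ranked by raw ELI score (descending; ties broken by lexicographic neighbour
#' id) and each score is divided by its rank, leaving the top-ranked edge of
#' every group unchanged. An edge caught by groups for both species (or from
#' both of its endpoints) is divided once, by the maximum of its ranks. This
#' is applied before pruning.
#'
#' @param ag an `alignment_graph` with raw ELI scores.
#' @return the graph with `corrected` and `rank_divisor` filled in.
#' @export
correct_multiortholog <- function(ag) {
  ed <- ag$edges
  n_e <- nrow(ed)
  divisor <- rep(1L, n_e)
  if (n_e) {
    p1 <- stats::setNames(ag$nodes$p1, ag$nodes$id)
    p2 <- stats::setNames(ag$nodes$p2, ag$nodes$id)
    ends <- data.table::data.table(
      edge = rep(seq_len(n_e), 2L),
      x = c(ed$a, ed$b), nbr = c(ed$b, ed$a),
      score = rep(ed$total, 2L))
    ends$nbr_p1 <- p1[ends$nbr]
    ends$nbr_p2 <- p2[ends$nbr]
    for (sp in c("nbr_p1", "nbr_p2")) {
      grp <- ends[, list(edge, nbr, score, key = paste(x, get(sp), sep = "\r"))]
      grp <- grp[, n := .N, by = "key"][n >= 2L, ]
      if (nrow(grp)) {
        data.table::setorderv(grp, c("key", "score", "nbr"),
                              order = c(1L, -1L, 1L))
        grp[, rank := seq_len(.N), by = "key"]
        agg <- grp[, list(r = max(rank)), by = "edge"]
        divisor[agg$edge] <- pmax(divisor[agg$edge], agg$r)
      }
    }
  }
  ag$edges$rank_divisor <- divisor
  ag$edges$corrected <- ed$total / divisor
  ag$corrected_applied <- TRUE
  ag
}

#' Local pruning of the alignment graph
#'
#' Scores of edges incident to one node fall off sharply, so a local rule is
#' used instead of a global cutoff: with m(u) the maximum corrected score
#' among edges incident to u (computed before any deletion), an edge (u, v) is
#' deleted when its corrected score is below `t * m(u)` or below `t * m(v)`.
#' Nodes left without edges are removed. Thresholds t in 0.3-0.7 behave
#' similarly on real networks; the default is the midpoint 0.5.
#'
#' @param ag an `alignment_graph` (normally after [correct_multiortholog()]).
#' @param t pruning threshold, strictly between 0 and 1.
#' @return the pruned graph; `prune_stats` records edge/node counts before and
#'   after.
#' @export
prune_alignment_graph <- function(ag, t = 0.5) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0, t < 1)
  ed <- ag$edges
  before_e <- nrow(ed); before_n <- nrow(ag$nodes)
  if (before_e) {
    m <- tapply(c(ed$corrected, ed$corrected), c(ed$a, ed$b), max)
    keep <- ed$corrected >= t * m[ed$a] & ed$corrected >= t * m[ed$b]
    ed <- ed[keep, , drop = FALSE]
    rownames(ed) <- NULL
  }
  nodes <- ag$nodes[ag$nodes$id %in% c(ed$a, ed$b), , drop = FALSE]
  rownames(nodes) <- NULL
  ag$edges <- ed
  ag$nodes <- nodes
  ag$prune_stats <- list(t = t, edges_before = before_e, edges_after = nrow(ed),
                         nodes_before = before_n, nodes_after = nrow(nodes),
                         nodes_removed = before_n - nrow(nodes))
  ag
}

#' Dump an alignment graph as TSV (debug aid)
#' @param ag an `alignment_graph`.
#' @param path output path.
#' @export
write_alignment_graph <- function(ag, path) {
  ed <- ag$edges
  writeLines(c("#nodeA\tnodeB\tc_dir\tc_ind\ttotal\tcorrected",
               sprintf("%s\t%s\t%s\t%s\t%s\t%s", ed$a, ed$b,
                       format(ed$c_dir, digits = 15),
                       format(ed$c_ind, digits = 15),
                       format(ed$total, digits = 15),
                       format(ed$corrected, digits = 15))), path)
  invisible(NULL)
}
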