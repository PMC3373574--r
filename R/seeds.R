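# Seed generation: enumerate every connected k-subgraph of the pruned
# alignment graph exactly once (ESU-style anchored enumeration), score
# subgraphs additively, and pick node-disjoint top scorers as seeds.

# Integer-indexed view of an alignment graph: nodes in lexicographic id order
# (this is the arbitrary total order used by the enumeration), adjacency
# lists, dense corrected-score matrix and node score vector.
ag_index <- function(ag) {
  ids <- ag$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  W <- matrix(0, n, n)
  if (nrow(ag$edges)) {
    ia <- idx[ag$edges$a]; ib <- idx[ag$edges$b]
    W[cbind(ia, ib)] <- ag$edges$corrected
    W[cbind(ib, ia)] <- ag$edges$corrected
  }
  adj <- lapply(seq_len(n), function(i) which(W[i, ] > 0))
  list(ids = ids, n = n, idx = idx, W = W, adj = adj,
       node_score = ag$nodes$node_score)
}

#' Enumerate all connected k-subgraphs of an alignment graph
#'
#' Anchored (ESU-style) enumeration: nodes are totally ordered
#' (lexicographically by id); for each anchor u every connected node-induced
#' subgraph of size k whose minimum node is u is grown by extending only with
#' higher-ordered nodes from the exclusive neighbourhood, so each subgraph is
#' produced exactly once. Enumeration stops with a warning once
#' `max_subgraphs` subgraphs have been collected.
#'
#' @param ag an `alignment_graph` (normally corrected and pruned).
#' @param k subgraph size, >= 2.
#' @param max_subgraphs hard cap on the number of enumerated subgraphs.
#' @return object of class `ksubgraphs`: list with `sets` (integer matrix,
#'   one row per subgraph, node indices ascending), `ids` (node id vector
#'   mapping indices to composite-node ids), `k` and `truncated`.
#' @export
enumerate_connected_ksubgraphs <- function(ag, k = 4L, max_subgraphs = 5e6) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2")
  gi <- ag_index(ag)
  n <- gi$n
  acc <- new.env(parent = emptyenv())
  acc$rows <- vector("list", 1024L)
  acc$count <- 0L
  acc$truncated <- FALSE

  emit <- function(sub) {
    if (acc$count >= max_subgraphs) { acc$truncated <- TRUE; return(FALSE) }
    acc$count <- acc$count + 1L
    if (acc$count > length(acc$rows)) length(acc$rows) <- 2L * length(acc$rows)
    acc$rows[[acc$count]] <- sub
    TRUE
  }

  extend <- function(sub, ext, seen, v) {
    if (acc$truncated) return()
    if (length(sub) == k - 1L) {
      for (w in ext) if (!emit(sort(c(sub, w)))) return()
      return()
    }
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      nb <- gi$adj[[w]]
      fresh <- nb[nb > v & !seen[nb]]
      seen2 <- seen
      seen2[fresh] <- TRUE
      seen2[w] <- TRUE
      extend(c(sub, w), c(ext, fresh), seen2, v)
      if (acc$truncated) return()
    }
  }

  if (k <= n) {
    for (v in seq_len(n)) {
      nb <- gi$adj[[v]]
      ext0 <- nb[nb > v]
      if (k == 1L) { emit(v); next }
      seen <- logical(n)
      seen[v] <- TRUE
      seen[nb] <- TRUE
      extend(v, ext0, seen, v)
      if (acc$truncated) break
    }
  }
  if (acc$truncated)
    warning("subgraph enumeration truncated at max_subgraphs = ", max_subgraphs)

  sets <- if (acc$count) do.call(rbind, acc$rows[seq_len(acc$count)])
          else matrix(integer(), 0L, k)
  structure(list(sets = sets, ids = gi$ids, k = k, truncated = acc$truncated),
            class = "ksubgraphs")
}

#' @export
print.ksubgraphs <- function(x, ...) {
  cat("ksubgraphs: ", nrow(x$sets), " connected ", x$k, "-subgraphs over ",
      length(x$ids), " nodes", if (x$truncated) " (truncated)", "\n", sep = "")
  invisible(x)
}

#' Score a node set in the alignment graph
#'
#' Additive score: sum of node scores (homology confidences) plus sum of the
#' corrected scores of the edges induced by the set.
#'
#' @param nodes character vector of composite node ids.
#' @param ag an `alignment_graph`.
#' @return numeric score.
#' @export
score_subgraph <- function(nodes, ag) {
  gi <- ag_index(ag)
  miss <- setdiff(nodes, gi$ids)
  if (length(miss)) stop("unknown alignment-graph node(s): ",
                         paste(miss, collapse = ", "))
  i <- gi$idx[nodes]
  sum(gi$node_score[i]) + sum(gi$W[i, i, drop = FALSE]) / 2
}

score_sets <- function(sets, gi) {
  if (!nrow(sets)) return(numeric())
  apply(sets, 1L, function(i) {
    sum(gi$node_score[i]) + sum(gi$W[i, i, drop = FALSE]) / 2
  })
}

set_sort_key <- function(sets, ids) {
  if (!nrow(sets)) return(character())
  apply(sets, 1L, function(i) paste(ids[i], collapse = "\r"))
}

#' Select node-disjoint top-scoring subgraphs as seeds
#'
#' Greedy sweep in descending score order (ties broken by the
#' lexicographically smallest node-id set): a subgraph becomes a seed iff it
#' shares no node with a previously selected seed. Non-seed subgraphs remain
#' in the pool and are used during module expansion.
#'
#' @param ss a `ksubgraphs` object.
#' @param ag the `alignment_graph` the subgraphs were enumerated from.
#' @param require_clique if TRUE only fully connected (clique) subgraphs are
#'   eligible as seeds (a stricter reading of "top ranking fully connected
#'   subgraphs"); the pool used for expansion is unaffected.
#' @return list of class `seed_selection`: `seed_rows` (row indices of
#'   `ss$sets` chosen as seeds, in selection order), `scores` (scores of all
#'   pool subgraphs), `order` (ranking permutation of the pool).
#' @export
select_seeds <- function(ss, ag, require_clique = FALSE) {
  gi <- ag_index(ag)
  sets <- ss$sets
  scores <- score_sets(sets, gi)
  if (!nrow(sets)) {
    return(structure(list(seed_rows = integer(), scores = scores,
                          order = integer()), class = "seed_selection"))
  }
  ord <- order(-scores, set_sort_key(sets, ss$ids))
  eligible <- rep(TRUE, nrow(sets))
  if (require_clique) {
    full <- ss$k * (ss$k - 1L) / 2
    eligible <- apply(sets, 1L, function(i)
      sum(gi$W[i, i, drop = FALSE] > 0) / 2 == full)
  }
  used <- logical(gi$n)
  seed_rows <- integer()
  for (r in ord) {
    if (!eligible[r]) next
    s <- sets[r, ]
    if (!any(used[s])) {
      used[s] <- TRUE
      seed_rows <- c(seed_rows, r)
    }
  }
  structure(list(seed_rows = seed_rows, scores = scores, order = ord),
            class = "seed_selection")
}
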