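# Module discovery: grow each seed by iterative *batch* expansion. At every
# step, each pooled k-subgraph sharing at least one node with the current
# module is a candidate; a candidate is accepted when its frontier (nodes
# outside the module) connects to the module with more reliable edges than to
# the rest of the alignment graph, and all accepted subgraphs are added at
# once. Decisions within one step are taken against the step-start snapshot,
# so they are independent of candidate order.

#' Partition frontier-incident edges of a candidate subgraph
#'
#' For a candidate k-subgraph `g` sharing at least one node with module `M`,
#' the frontier is `g \ M`. Edges incident to frontier nodes are classified by
#' the other endpoint: within `g` (excluded from both sums), in `M \ g`
#' (weight total `W_M`), or in the rest of the graph `N` (weight total `W_N`).
#'
#' @param ag an `alignment_graph`.
#' @param M character vector of module node ids.
#' @param g character vector of candidate subgraph node ids.
#' @return `NULL` when `g` is entirely inside `M` (skip signal), otherwise a
#'   list of class `frontier_ledger`: `frontier`, `W_M`, `W_N`, and per
#'   frontier node the edge classes `E_g`, `E_M`, `E_N` (data.frames with
#'   `other`, `weight`).
#' @export
partition_edges <- function(ag, M, g) {
  gi <- ag_index(ag)
  stopifnot(all(M %in% gi$ids), all(g %in% gi$ids))
  if (!length(intersect(g, M)))
    stop("candidate subgraph must share at least one node with the module")
  front <- setdiff(g, M)
  if (!length(front)) return(NULL)
  gidx <- gi$idx[g]; midx <- gi$idx[setdiff(M, g)]
  nidx <- setdiff(seq_len(gi$n), union(gi$idx[union(M, g)], integer()))
  per_node <- lapply(front, function(f) {
    fi <- gi$idx[[f]]
    nb <- gi$adj[[fi]]
    cls <- function(which_idx) {
      o <- intersect(nb, which_idx)
      data.frame(other = gi$ids[o], weight = gi$W[fi, o])
    }
    list(E_g = cls(setdiff(gidx, fi)), E_M = cls(midx), E_N = cls(nidx))
  })
  names(per_node) <- front
  W_M <- sum(vapply(per_node, function(x) sum(x$E_M$weight), 0))
  W_N <- sum(vapply(per_node, function(x) sum(x$E_N$weight), 0))
  structure(list(frontier = front, W_M = W_M, W_N = W_N, per_node = per_node),
            class = "frontier_ledger")
}

#' Acceptance rule for a candidate subgraph
#'
#' A candidate is accepted when its frontier connects to the module more
#' strongly than to the rest of the network: `W_M > tight_factor * W_N`,
#' strictly (ties reject). With the default `tight_factor = 1` a frontier
#' with no edges to the rest of the network (`W_N = 0`) and any positive
#' connection to the module is always accepted — the tightly-connected
#' degenerate case.
#'
#' @param ledger a `frontier_ledger` from [partition_edges()] (or `NULL`,
#'   which is rejected).
#' @param tight_factor multiplier on `W_N`; values > 1 demand proportionally
#'   stronger module attachment.
#' @return logical.
#' @export
accept_candidate <- function(ledger, tight_factor = 1) {
  if (is.null(ledger)) return(FALSE)
  ledger$W_M > tight_factor * ledger$W_N
}

# Fast internal expansion on the integer-indexed graph.
# sets: pool matrix (rows = k-subgraphs, integer node indices);
# node2sub: list mapping node index -> pool row indices.
expand_module_idx <- function(gi, seed_idx, sets, node2sub, tight_factor = 1) {
  n <- gi$n
  M <- logical(n)
  M[seed_idx] <- TRUE
  steps <- list()
  iter <- 0L
  wTot <- rowSums(gi$W)
  repeat {
    iter <- iter + 1L
    mvec <- as.numeric(M)
    wM <- as.vector(gi$W %*% mvec)     # per-node edge mass into the module
    cand <- unique(unlist(node2sub[which(M)], use.names = FALSE))
    accepted <- integer()
    newly <- logical(n)
    for (r in cand) {
      S <- sets[r, ]
      f <- S[!M[S]]
      if (!length(f)) next
      WS <- gi$W[f, S, drop = FALSE]            # frontier -> within-g edges
      Sm <- S[M[S]]
      WSm <- gi$W[f, Sm, drop = FALSE]          # frontier -> g-nodes also in M
      W_M <- sum(wM[f]) - sum(WSm)
      W_N <- sum(wTot[f]) - sum(wM[f]) - (sum(WS) - sum(WSm))
      if (W_M > tight_factor * W_N) {
        accepted <- c(accepted, r)
        newly[f] <- TRUE
      }
    }
    if (!any(newly)) break
    M <- M | newly
    steps[[iter]] <- accepted
  }
  list(members = which(M), steps = steps)
}

#' Expand one seed into a module
#'
#' Starting from the seed's nodes, repeatedly evaluate every pooled subgraph
#' sharing at least one node with the current module against the module
#' snapshot, and add the union of all accepted subgraphs' nodes at once; stop
#' when no candidate is accepted. Growth is monotone, so termination is
#' guaranteed.
#'
#' @param ag an `alignment_graph`.
#' @param seed_nodes character vector of seed node ids.
#' @param pool a `ksubgraphs` object (the full enumeration, seeds included).
#' @param tight_factor see [accept_candidate()].
#' @return list with `nodes` (module node ids) and `steps` (per iteration,
#'   the list of accepted subgraphs as node-id vectors).
#' @export
expand_module <- function(ag, seed_nodes, pool, tight_factor = 1) {
  gi <- ag_index(ag)
  stopifnot(all(seed_nodes %in% gi$ids))
  node2sub <- pool_node_index(pool, gi$n)
  res <- expand_module_idx(gi, gi$idx[seed_nodes], pool$sets, node2sub,
                           tight_factor)
  list(nodes = gi$ids[res$members],
       steps = lapply(seq_along(res$steps), function(i)
         list(iteration = i,
              accepted = lapply(res$steps[[i]], function(r)
                gi$ids[pool$sets[r, ]]))))
}

pool_node_index <- function(pool, n) {
  node2sub <- vector("list", n)
  if (nrow(pool$sets)) {
    long <- data.frame(node = as.vector(t(pool$sets)),
                       row = rep(seq_len(nrow(pool$sets)), each = pool$k))
    spl <- split(long$row, long$node)
    node2sub[as.integer(names(spl))] <- spl
  }
  node2sub
}

#' Discover conserved modules from selected seeds
#'
#' Expands every seed independently with [expand_module()] semantics, drops
#' modules below `min_module_size` nodes (the seed plus at least one
#' successful expansion step), removes duplicate node sets (first seed wins)
#' and orders the result by module score descending. Modules may overlap.
#'
#' @param ag an `alignment_graph`.
#' @param pool a `ksubgraphs` enumeration.
#' @param selection a `seed_selection` from [select_seeds()].
#' @param min_module_size minimum emitted module size (nodes).
#' @param tight_factor see [accept_candidate()].
#' @return list of `ppi_module` objects, each with `id`, `nodes`, `seed`,
#'   `steps`, per-species projections `proj1`/`proj2`, and score components.
#' @export
discover_modules <- function(ag, pool, selection, min_module_size = 5L,
                             tight_factor = 1) {
  gi <- ag_index(ag)
  node2sub <- pool_node_index(pool, gi$n)
  p1 <- stats::setNames(ag$nodes$p1, ag$nodes$id)
  p2 <- stats::setNames(ag$nodes$p2, ag$nodes$id)

  mods <- list()
  seen_sets <- character()
  for (r in selection$seed_rows) {
    seed_idx <- pool$sets[r, ]
    res <- expand_module_idx(gi, seed_idx, pool$sets, node2sub, tight_factor)
    if (length(res$members) < min_module_size) next
    key <- paste(res$members, collapse = ",")
    if (key %in% seen_sets) next
    seen_sets <- c(seen_sets, key)
    ids <- gi$ids[res$members]
    i <- res$members
    node_sum <- sum(gi$node_score[i])
    edge_sum <- sum(gi$W[i, i, drop = FALSE]) / 2
    mods[[length(mods) + 1L]] <- structure(list(
      id = NA_character_,
      nodes = ids,
      seed = list(nodes = gi$ids[seed_idx], score = selection$scores[r]),
      steps = lapply(seq_along(res$steps), function(s)
        list(iteration = s,
             accepted = lapply(res$steps[[s]], function(rr)
               gi$ids[pool$sets[rr, ]]))),
      proj1 = sort(unique(unname(p1[ids]))),
      proj2 = sort(unique(unname(p2[ids]))),
      node_score_sum = node_sum,
      edge_score_sum = edge_sum,
      score = node_sum + edge_sum), class = "ppi_module")
  }
  mods <- order_modules(mods)
  for (i in seq_along(mods)) mods[[i]]$id <- sprintf("M%03d", i)
  mods
}

#' @export
print.ppi_module <- function(x, ...) {
  cat("ppi_module ", x$id, ": ", length(x$nodes), " ortholog-pair nodes (",
      length(x$proj1), "+", length(x$proj2), " proteins), score ",
      format(x$score, digits = 4), "\n", sep = "")
  invisible(x)
}
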