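# Test fixtures and independent brute-force oracles. Everything here is
# deliberately written with plain loops and matrix arithmetic, independent of
# the package's join-based and recursive implementations.

# Build a union_graph object directly from parts (tests only).
make_union_graph <- function(comp, simple1 = character(), simple2 = character(),
                             edges = data.frame(a = character(), b = character(),
                                                support = character(),
                                                score = numeric())) {
  # comp: data.frame p1, p2, conf
  ids <- paste(comp$p1, comp$p2, sep = "|")
  nodes <- rbind(
    data.frame(id = ids, type = rep("composite", nrow(comp)),
               p1 = comp$p1, p2 = comp$p2, conf = comp$conf),
    if (length(simple1))
      data.frame(id = paste0(simple1, "::1"), type = "simple", p1 = simple1,
                 p2 = NA_character_, conf = NA_real_),
    if (length(simple2))
      data.frame(id = paste0(simple2, "::2"), type = "simple",
                 p1 = NA_character_, p2 = simple2, conf = NA_real_))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  edges <- data.frame(a = lo, b = hi, support = edges$support,
                      score = edges$score)
  structure(list(nodes = nodes, edges = edges, species = c("sp1", "sp2")),
            class = "union_graph")
}

# Random union graph with <= n_comp composite and <= n_simple simple nodes.
random_union_graph <- function(n_comp = 8, n_simple = 5, p_edge = 0.35) {
  comp <- data.frame(p1 = sprintf("a%02d", seq_len(n_comp)),
                     p2 = sprintf("b%02d", seq_len(n_comp)),
                     conf = round(runif(n_comp, 0.2, 1), 3))
  s1 <- sprintf("x%02d", seq_len(n_simple))
  ids <- c(paste(comp$p1, comp$p2, sep = "|"),
           if (n_simple) paste0(s1, "::1"))
  prs <- utils::combn(ids, 2)
  pick <- runif(ncol(prs)) < p_edge
  prs <- prs[, pick, drop = FALSE]
  edges <- data.frame(a = prs[1, ], b = prs[2, ],
                      support = sample(c("1", "2", "both"), ncol(prs),
                                       replace = TRUE),
                      score = round(runif(ncol(prs), 0.1, 2), 3))
  make_union_graph(comp, simple1 = s1, edges = edges)
}

# Exhaustive all-pairs, all-paths ELI oracle: triple loops over node triples.
# Returns a data.frame a, b, c_dir, c_ind, total over composite pairs with a
# positive total.
oracle_alignment_edges <- function(ug) {
  ids <- ug$nodes$id
  n <- length(ids)
  pos <- setNames(seq_len(n), ids)
  W <- matrix(0, n, n)
  SUP <- matrix("", n, n)
  for (r in seq_len(nrow(ug$edges))) {
    i <- pos[[ug$edges$a[r]]]; j <- pos[[ug$edges$b[r]]]
    W[i, j] <- W[j, i] <- ug$edges$score[r]
    SUP[i, j] <- SUP[j, i] <- ug$edges$support[r]
  }
  comp <- which(ug$nodes$type == "composite")
  ok <- function(s1, s2) s1 == s2 || s1 == "both" || s2 == "both"

  S1 <- numeric(n); S2 <- numeric(n)
  P2 <- matrix(0, n, n); W1 <- matrix(0, n, n)
  for (a in comp) {
    for (b in comp) {
      if (a == b) next
      if (W[a, b] > 0) {
        S1[a] <- S1[a] + W[a, b]
        W1[a, b] <- W[a, b]
      }
      for (x in seq_len(n)) {
        if (x == a || x == b) next
        if (W[a, x] > 0 && W[x, b] > 0 && ok(SUP[a, x], SUP[x, b])) {
          sc <- W[a, x] + W[x, b]
          S2[a] <- S2[a] + sc
          P2[a, b] <- P2[a, b] + sc
        }
      }
    }
  }
  out <- NULL
  for (a in comp) for (b in comp) {
    if (ids[a] >= ids[b]) next
    w1 <- W1[a, b]; p2 <- P2[a, b]
    cd <- if (w1 > 0) w1 / (S1[a] + S1[b] - w1) else 0
    ci <- if (p2 > 0) p2 / (S2[a] + S2[b] - p2) else 0
    if (cd + ci > 0)
      out <- rbind(out, data.frame(a = ids[a], b = ids[b], c_dir = cd,
                                   c_ind = ci, total = cd + ci))
  }
  if (is.null(out))
    out <- data.frame(a = character(), b = character(), c_dir = numeric(),
                      c_ind = numeric(), total = numeric())
  out[order(out$a, out$b), , drop = FALSE]
}

# Build an alignment_graph object directly from parts (tests only).
make_alignment_graph <- function(nodes, edges) {
  # nodes: data.frame id, p1, p2, node_score; edges: data.frame a, b, total
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  ed <- data.frame(a = lo, b = hi, w1 = edges$total, p2 = 0,
                   path_count = 0L, c_dir = edges$total, c_ind = 0,
                   total = edges$total, corrected = edges$total)
  ed <- ed[order(ed$a, ed$b), , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = ed, species = c("sp1", "sp2"),
                 corrected_applied = FALSE, prune_stats = NULL),
            class = "alignment_graph")
}

# Random alignment graph over n nodes with given edge density; proteins are
# reused across nodes with some probability so multi-ortholog groups occur.
random_alignment_graph <- function(n = 12, density = 0.3, share_prob = 0.4) {
  p1 <- sprintf("a%02d", sample.int(ceiling(n * (1 - share_prob / 2)), n,
                                    replace = TRUE))
  p2 <- sprintf("b%02d", sample.int(ceiling(n * (1 - share_prob / 2)), n,
                                    replace = TRUE))
  id <- sprintf("n%02d_%s|%s", seq_len(n), p1, p2)
  nodes <- data.frame(id = id, p1 = p1, p2 = p2,
                      node_score = round(runif(n, 0.2, 1), 3))
  prs <- utils::combn(id, 2)
  pick <- runif(ncol(prs)) < density
  prs <- prs[, pick, drop = FALSE]
  edges <- data.frame(a = prs[1, ], b = prs[2, ],
                      total = round(runif(ncol(prs), 0.05, 2), 4))
  make_alignment_graph(nodes, edges)
}

# Independent connected-k-subgraph enumeration: all C(n, k) subsets, with a
# matrix-power reachability test for connectedness.
brute_force_ksubgraphs <- function(ag, k) {
  ids <- sort(ag$nodes$id)
  n <- length(ids)
  if (n < k) return(character())
  pos <- setNames(seq_len(n), ids)
  A <- matrix(0, n, n)
  if (nrow(ag$edges)) {
    ia <- pos[ag$edges$a]; ib <- pos[ag$edges$b]
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  subs <- utils::combn(n, k)
  keep <- vapply(seq_len(ncol(subs)), function(j) {
    s <- subs[, j]
    B <- A[s, s] + diag(k)
    R <- B
    for (i in seq_len(k - 1)) R <- R %*% B
    all(R[1, ] > 0)
  }, TRUE)
  apply(subs[, keep, drop = FALSE], 2, function(s)
    paste(ids[s], collapse = "\r"))
}

subgraph_keys <- function(ss) {
  if (!nrow(ss$sets)) return(character())
  apply(ss$sets, 1, function(i) paste(sort(ss$ids[i]), collapse = "\r"))
}

# Module connectivity check through igraph (independent of the package).
module_connected <- function(ag, nodes) {
  g <- alignment_graph_to_igraph(ag)
  sub <- igraph::induced_subgraph(g, nodes)
  igraph::is_connected(sub)
}

# Small planted-complex simulation used by several expansion tests.
small_benchmark <- function(seed = 7) {
  simulate_paired_networks(sim_config(
    n_proteins = 80, n_complexes = 3, complex_size_range = c(6, 8),
    p_in = 0.7, p_out = 0.01, false_negative_rate = 0.1,
    ortholog_noise = 0.2, rng_seed = seed))
}
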