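test_that("valid_paths separates direct edges, valid and spurious 2-paths", {
  comp <- data.frame(p1 = c("a1", "b1"), p2 = c("a2", "b2"), conf = c(1, 1))
  ab <- c("a1|a2", "b1|b2")

  # direct conserved edge, no intermediates
  ug <- make_union_graph(comp, edges = data.frame(
    a = ab[1], b = ab[2], support = "both", score = 0.7))
  vp <- valid_paths(ug, ab[1], ab[2])
  expect_equal(vp$w1, 0.7)
  expect_equal(nrow(vp$paths), 0L)

  # cross-species-only 2-path is spurious
  ug <- make_union_graph(comp, simple1 = "x", edges = data.frame(
    a = c(ab[1], "x::1"), b = c("x::1", ab[2]),
    support = c("1", "2"), score = c(0.5, 0.5)))
  vp <- valid_paths(ug, ab[1], ab[2])
  expect_equal(vp$w1, 0)
  expect_equal(nrow(vp$paths), 0L)

  # support "both" satisfies either species
  ug <- make_union_graph(comp, simple1 = "x", edges = data.frame(
    a = c(ab[1], "x::1"), b = c("x::1", ab[2]),
    support = c("both", "1"), score = c(2.0, 0.5)))
  vp <- valid_paths(ug, ab[1], ab[2])
  expect_equal(vp$w1, 0)
  expect_equal(vp$paths$score, 2.5)

  expect_error(valid_paths(ug, "x::1", ab[1]), "composite")
  expect_error(valid_paths(ug, ab[1], ab[1]), "distinct")
})

test_that("an isolated conserved pair scores c_dir = 1", {
  comp <- data.frame(p1 = c("a1", "b1"), p2 = c("a2", "b2"), conf = c(1, 1))
  ug <- make_union_graph(comp, edges = data.frame(
    a = "a1|a2", b = "b1|b2", support = "both", score = 1.3))
  e <- eli_score(ug, "a1|a2", "b1|b2")
  expect_equal(e$c_dir, 1)
  expect_equal(e$c_ind, 0)
  expect_equal(e$total, 1)
})

test_that("pairs with no valid path of length <= 2 get no alignment edge", {
  # chain a - s - s2 - b: distance 3
  comp <- data.frame(p1 = c("a1", "b1"), p2 = c("a2", "b2"), conf = c(1, 1))
  ug <- make_union_graph(comp, simple1 = c("x", "y"), edges = data.frame(
    a = c("a1|a2", "x::1", "y::1"), b = c("x::1", "y::1", "b1|b2"),
    support = c("1", "1", "1"), score = c(0.5, 0.5, 0.5)))
  e <- eli_score(ug, "a1|a2", "b1|b2")
  expect_equal(e$total, 0)
  ag <- build_alignment_graph(ug)
  expect_equal(nrow(ag$edges), 0L)
  expect_equal(nrow(ag$nodes), 0L)   # isolated nodes dropped
})

test_that("alignment graph matches the exhaustive path oracle on random graphs", {
  set.seed(101)
  for (rep in 1:30) {
    ug <- random_union_graph(n_comp = sample(3:10, 1),
                             n_simple = sample(0:6, 1),
                             p_edge = runif(1, 0.1, 0.5))
    ag <- build_alignment_graph(ug)
    orc <- oracle_alignment_edges(ug)
    expect_equal(nrow(ag$edges), nrow(orc))
    expect_equal(as.character(ag$edges$a), as.character(orc$a))
    expect_equal(as.character(ag$edges$b), as.character(orc$b))
    expect_equal(as.numeric(ag$edges$c_dir), as.numeric(orc$c_dir),
                 tolerance = 1e-12)
    expect_equal(as.numeric(ag$edges$c_ind), as.numeric(orc$c_ind),
                 tolerance = 1e-12)
    expect_equal(as.numeric(ag$edges$total), as.numeric(orc$total),
                 tolerance = 1e-12)
  }
})

test_that("ELI components are bounded, symmetric, and monotone in added paths", {
  set.seed(202)
  for (rep in 1:15) {
    ug <- random_union_graph(n_comp = sample(4:8, 1), n_simple = sample(0:4, 1))
    ag <- build_alignment_graph(ug)
    expect_true(all(ag$edges$c_dir >= 0 & ag$edges$c_dir <= 1))
    expect_true(all(ag$edges$c_ind >= 0 & ag$edges$c_ind <= 1))
    expect_true(all(ag$edges$total > 0 & ag$edges$total <= 2))
  }

  # symmetry of the pair score in argument order
  ug <- random_union_graph(n_comp = 6, n_simple = 3)
  comp <- ug$nodes$id[ug$nodes$type == "composite"]
  for (i in 1:4) {
    p <- sample(comp, 2)
    e1 <- eli_score(ug, p[1], p[2])
    e2 <- eli_score(ug, p[2], p[1])
    expect_identical(e1$total, e2$total)
    expect_identical(e1$c_dir, e2$c_dir)
  }

  # adding one more valid a-b length-2 path never decreases c_ind
  comp <- data.frame(p1 = c("a1", "b1", "c1"), p2 = c("a2", "b2", "c2"),
                     conf = c(1, 1, 1))
  base_edges <- data.frame(
    a = c("a1|a2", "x::1", "a1|a2"), b = c("x::1", "b1|b2", "c1|c2"),
    support = c("1", "1", "both"), score = c(0.4, 0.6, 1.0))
  ug0 <- make_union_graph(comp, simple1 = c("x", "y"), edges = base_edges)
  e0 <- eli_score(ug0, "a1|a2", "b1|b2")
  ug1 <- make_union_graph(comp, simple1 = c("x", "y"), edges = rbind(
    base_edges,
    data.frame(a = c("a1|a2", "y::1"), b = c("y::1", "b1|b2"),
               support = c("1", "1"), score = c(0.3, 0.2))))
  e1 <- eli_score(ug1, "a1|a2", "b1|b2")
  expect_gte(e1$c_ind, e0$c_ind)
  expect_equal(e1$path_count_len2, e0$path_count_len2 + 1L)
})

test_that("multi-ortholog correction divides by rank with deterministic ties", {
  # x with three neighbours sharing the same species-1 protein
  nodes <- data.frame(id = c("x1|x2", "q1|a2", "q1|b2", "q1|c2"),
                      p1 = c("x1", "q1", "q1", "q1"),
                      p2 = c("x2", "a2", "b2", "c2"),
                      node_score = rep(1, 4))
  edges <- data.frame(a = rep("x1|x2", 3), b = c("q1|a2", "q1|b2", "q1|c2"),
                      total = c(0.9, 0.6, 0.3))
  ag <- make_alignment_graph(nodes, edges)
  ag <- correct_multiortholog(ag)
  got <- ag$edges[order(-ag$edges$total), ]
  expect_equal(got$corrected, c(0.9, 0.6 / 2, 0.3 / 3))

  # a group of one is unchanged
  nodes1 <- data.frame(id = c("x1|x2", "q1|a2"), p1 = c("x1", "q1"),
                       p2 = c("x2", "a2"), node_score = c(1, 1))
  ag1 <- make_alignment_graph(nodes1, data.frame(a = "x1|x2", b = "q1|a2",
                                                 total = 0.4))
  ag1 <- correct_multiortholog(ag1)
  expect_equal(ag1$edges$corrected, 0.4)

  # tie: ranks follow lexicographic neighbour id
  edges_tie <- data.frame(a = rep("x1|x2", 2), b = c("q1|a2", "q1|b2"),
                          total = c(0.5, 0.5))
  agt <- make_alignment_graph(nodes[1:3, ], edges_tie)
  agt <- correct_multiortholog(agt)
  nbr <- ifelse(agt$edges$a == "x1|x2", agt$edges$b, agt$edges$a)
  expect_equal(agt$edges$corrected[nbr == "q1|a2"], 0.5)
  expect_equal(agt$edges$corrected[nbr == "q1|b2"], 0.25)
})

test_that("correction never increases scores and keeps group tops; brute-force agreement", {
  set.seed(303)
  for (rep in 1:20) {
    ag <- random_alignment_graph(n = sample(8:15, 1), density = 0.4)
    agc <- correct_multiortholog(ag)
    expect_true(all(agc$edges$corrected <= agc$edges$total + 1e-15))
    # independent recomputation of each edge's divisor
    ed <- agc$edges
    p1 <- setNames(agc$nodes$p1, agc$nodes$id)
    p2 <- setNames(agc$nodes$p2, agc$nodes$id)
    div <- rep(1, nrow(ed))
    for (i in seq_len(nrow(ed))) {
      for (end in 1:2) {
        x <- if (end == 1) ed$a[i] else ed$b[i]
        nbr <- if (end == 1) ed$b[i] else ed$a[i]
        for (pp in list(p1, p2)) {
          grp_rows <- which((ed$a == x & pp[ed$b] == pp[[nbr]]) |
                            (ed$b == x & pp[ed$a] == pp[[nbr]]))
          if (length(grp_rows) < 2) next
          other <- ifelse(ed$a[grp_rows] == x, ed$b[grp_rows], ed$a[grp_rows])
          ord <- order(-ed$total[grp_rows], other)
          rank_i <- which(grp_rows[ord] == i)
          div[i] <- max(div[i], rank_i)
        }
      }
    }
    expect_equal(ed$corrected, ed$total / div, tolerance = 1e-12)
  }
})

test_that("pruning enforces the local threshold rule at both endpoints", {
  # hub u with scores 1.0 / 0.6 / 0.3 at t = 0.5: the 0.3 edge goes
  nodes <- data.frame(id = sprintf("n%d|m%d", 1:4, 1:4),
                      p1 = sprintf("n%d", 1:4), p2 = sprintf("m%d", 1:4),
                      node_score = rep(1, 4))
  edges <- data.frame(a = rep("n1|m1", 3), b = c("n2|m2", "n3|m3", "n4|m4"),
                      total = c(1.0, 0.6, 0.3))
  ag <- make_alignment_graph(nodes, edges)
  ag <- correct_multiortholog(ag)
  agp <- prune_alignment_graph(ag, t = 0.5)
  expect_equal(sort(agp$edges$corrected), c(0.6, 1.0))
  # the leaf whose only edge failed is removed
  expect_false("n4|m4" %in% agp$nodes$id)
  expect_equal(agp$prune_stats$nodes_removed, 1L)

  # all equal scores: nothing deleted
  edges_eq <- data.frame(a = rep("n1|m1", 3), b = c("n2|m2", "n3|m3", "n4|m4"),
                         total = rep(0.4, 3))
  age <- correct_multiortholog(make_alignment_graph(nodes, edges_eq))
  expect_equal(nrow(prune_alignment_graph(age, 0.7)$edges), 3L)

  expect_error(prune_alignment_graph(ag, t = 0), "TRUE")
})

test_that("surviving edges satisfy the t-rule w.r.t. pre-pruning maxima (brute force)", {
  set.seed(404)
  for (rep in 1:20) {
    t <- runif(1, 0.3, 0.7)
    ag <- correct_multiortholog(random_alignment_graph(n = 14, density = 0.35))
    ed0 <- ag$edges
    m <- tapply(c(ed0$corrected, ed0$corrected), c(ed0$a, ed0$b), max)
    agp <- prune_alignment_graph(ag, t)
    # single-pass semantics: survivors pass at both endpoints, and every
    # deleted edge fails at at least one endpoint, all w.r.t. ed0 maxima
    keep0 <- ed0$corrected >= t * m[ed0$a] & ed0$corrected >= t * m[ed0$b]
    expect_equal(nrow(agp$edges), sum(keep0))
    expect_true(all(agp$edges$corrected >= t * m[agp$edges$a] - 1e-15))
    expect_true(all(agp$edges$corrected >= t * m[agp$edges$b] - 1e-15))
    expect_true(all(agp$nodes$id %in% c(agp$edges$a, agp$edges$b)))
  }
})
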