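# Evaluation protocol: recovery of reference complexes (precision/recall/F1,
# best match, small-complex rule, hypergeometric enrichment) and module
# connectivity significance against degree-preserving random networks.

#' Precision, recall and F1 of a module projection against a complex
#'
#' Precision is the fraction of module proteins also in the complex, recall
#' the fraction of complex proteins found in the module, and F1 their
#' harmonic mean (0 when the overlap is empty).
#'
#' @param module_set,complex_set non-empty character vectors of protein ids.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
prf1 <- function(module_set, complex_set) {
  if (!length(module_set) || !length(complex_set))
    stop("both protein sets must be non-empty")
  module_set <- unique(module_set); complex_set <- unique(complex_set)
  tp <- length(intersect(module_set, complex_set))
  precision <- tp / length(module_set)
  recall <- tp / length(complex_set)
  f1 <- if (tp == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

module_projection <- function(m, species) {
  if (species == 1 || identical(species, "1")) m$proj1 else m$proj2
}

#' Best-matching module for each reference complex
#'
#' For every catalog complex with at least `min_complex_size` members, finds
#' the module whose projection for the given species maximizes F1 (ties:
#' higher precision, then lexicographically smaller module id). Matches with
#' F1 > 0.3 are flagged high-quality. When `universe_size` is supplied (the
#' number of proteins in that species' input network), a one-sided
#' hypergeometric enrichment p-value is computed for each best match and
#' Benjamini-Hochberg adjusted across complexes.
#'
#' @param catalog a [complex_catalog()].
#' @param modules list of `ppi_module` objects.
#' @param species 1 or 2: which projection to compare.
#' @param min_complex_size smallest complex considered (default 4).
#' @param universe_size optional universe for [fisher_enrichment()].
#' @return data.frame with one row per retained complex: `complex_id`,
#'   `best_module_id`, `TP`, `FP`, `FN`, `precision`, `recall`, `f1`,
#'   `high_quality`, and when `universe_size` is given `fisher_p`,
#'   `fisher_p_adjusted`.
#' @export
best_matches <- function(catalog, modules, species, min_complex_size = 4L,
                         universe_size = NULL) {
  ids <- names(catalog)
  keep <- vapply(catalog, length, 1L) >= min_complex_size
  ids <- ids[keep]
  out <- lapply(ids, function(cid) {
    cx <- catalog[[cid]]
    best <- NULL
    for (m in modules) {
      pr <- prf1(module_projection(m, species), cx)
      cand <- list(id = m$id, pr = pr,
                   overlap = length(intersect(module_projection(m, species), cx)),
                   msize = length(unique(module_projection(m, species))))
      if (is.null(best) ||
          pr[["f1"]] > best$pr[["f1"]] ||
          (pr[["f1"]] == best$pr[["f1"]] &&
           (pr[["precision"]] > best$pr[["precision"]] ||
            (pr[["precision"]] == best$pr[["precision"]] && cand$id < best$id))))
        best <- cand
    }
    if (is.null(best)) {
      return(data.frame(complex_id = cid, best_module_id = NA_character_,
                        TP = 0L, FP = 0L, FN = length(cx), precision = 0,
                        recall = 0, f1 = 0, high_quality = FALSE,
                        overlap = 0L, module_size = 0L))
    }
    data.frame(complex_id = cid, best_module_id = best$id,
               TP = best$overlap, FP = best$msize - best$overlap,
               FN = length(cx) - best$overlap,
               precision = best$pr[["precision"]], recall = best$pr[["recall"]],
               f1 = best$pr[["f1"]], high_quality = best$pr[["f1"]] > 0.3,
               overlap = best$overlap, module_size = best$msize)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(complex_id = character(), best_module_id = character(),
                      TP = integer(), FP = integer(), FN = integer(),
                      precision = numeric(), recall = numeric(), f1 = numeric(),
                      high_quality = logical(), overlap = integer(),
                      module_size = integer())
  if (!is.null(universe_size) && nrow(res)) {
    res$fisher_p <- vapply(seq_len(nrow(res)), function(i) {
      cx <- catalog[[res$complex_id[i]]]
      fisher_enrichment_counts(res$overlap[i], length(cx),
                               res$module_size[i], universe_size)
    }, 0)
    res$fisher_p_adjusted <- stats::p.adjust(res$fisher_p, method = "BH")
  }
  res$overlap <- NULL
  res$module_size <- NULL
  res
}

#' Small-complex recovery
#'
#' A reference complex of 2-3 proteins is considered recovered when at least
#' two of its proteins occur in the projection of some module of at most
#' `max_module_nodes` alignment-graph nodes.
#'
#' @param catalog a [complex_catalog()].
#' @param modules list of `ppi_module` objects.
#' @param species 1 or 2.
#' @param max_module_nodes size cap on eligible modules (default 20).
#' @return character vector of recovered complex ids.
#' @export
small_complex_recovery <- function(catalog, modules, species,
                                   max_module_nodes = 20L) {
  small <- names(catalog)[vapply(catalog, length, 1L) %in% 2:3]
  eligible <- Filter(function(m) length(m$nodes) <= max_module_nodes, modules)
  recovered <- vapply(small, function(cid) {
    cx <- catalog[[cid]]
    any(vapply(eligible, function(m)
      length(intersect(module_projection(m, species), cx)) >= 2L, TRUE))
  }, TRUE)
  small[recovered]
}

fisher_enrichment_counts <- function(overlap, complex_size, module_size,
                                     universe_size) {
  stats::phyper(overlap - 1L, complex_size, universe_size - complex_size,
                module_size, lower.tail = FALSE)
}

#' One-sided hypergeometric (Fisher) enrichment p-value
#'
#' Probability of observing an overlap at least as large as the one seen
#' between a module projection and a reference complex, drawing the module
#' from a universe of `universe_size` proteins (that species' input network).
#'
#' @param module_set,complex_set character vectors of protein ids.
#' @param universe_size integer universe size, at least the size of the union.
#' @return p-value in (0, 1].
#' @export
fisher_enrichment <- function(module_set, complex_set, universe_size) {
  module_set <- unique(module_set); complex_set <- unique(complex_set)
  if (universe_size < length(union(module_set, complex_set)))
    stop("universe smaller than the union of the two sets")
  fisher_enrichment_counts(length(intersect(module_set, complex_set)),
                           length(complex_set), length(module_set),
                           universe_size)
}

#' Degree-preserving randomization of a weighted network
#'
#' Double-edge-swap Markov chain: `swap_factor * |E|` swap attempts, each
#' picking two edges (a,b), (c,d) and rewiring to (a,d), (c,b); swaps that
#' would create a self-loop or a duplicate edge are rejected. Weights travel
#' with their rewired edges. The degree sequence is preserved exactly.
#'
#' @param net a [weighted_network()] with at least 2 edges.
#' @param rng_seed integer seed (the chain is deterministic given it).
#' @param swap_factor attempted swaps per edge (default 10).
#' @return a new [weighted_network()] over the same node set.
#' @export
degree_preserving_randomize <- function(net, rng_seed, swap_factor = 10L) {
  ed <- net$edges
  ne <- nrow(ed)
  if (ne < 2L) return(net)
  nd <- net$nodes
  n <- length(nd)
  idx <- stats::setNames(seq_len(n), nd)
  ea <- unname(idx[ed$a]); eb <- unname(idx[ed$b])
  key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  exists <- logical(n * n)
  exists[key(ea, eb)] <- TRUE
  nsw <- as.integer(swap_factor * ne)
  with_seed(rng_seed, {
    pick1 <- sample.int(ne, nsw, replace = TRUE)
    pick2 <- sample.int(ne, nsw, replace = TRUE)
    flip <- stats::runif(nsw) < 0.5
  })
  for (s in seq_len(nsw)) {
    i <- pick1[s]; j <- pick2[s]
    if (i == j) next
    a <- ea[i]; b <- eb[i]
    if (flip[s]) { c <- eb[j]; d <- ea[j] } else { c <- ea[j]; d <- eb[j] }
    # propose (a,d) and (c,b)
    if (a == d || c == b) next
    if (length(unique(c(a, b, c, d))) < 4L) next
    k1 <- key(a, d); k2 <- key(c, b)
    if (exists[k1] || exists[k2]) next
    exists[key(a, b)] <- FALSE
    exists[key(c, d)] <- FALSE
    exists[k1] <- TRUE
    exists[k2] <- TRUE
    ea[i] <- a; eb[i] <- d
    ea[j] <- c; eb[j] <- b
  }
  weighted_network(data.frame(a = nd[ea], b = nd[eb], w = ed$w),
                   net$species, nodes = nd)
}

induced_edge_count <- function(exists_vec, n, members) {
  if (length(members) < 2L) return(0L)
  prs <- utils::combn(sort(members), 2L)
  sum(exists_vec[(prs[1, ] - 1) * n + prs[2, ]])
}

#' Connectivity significance of modules via degree-preserving nulls
#'
#' For each module and each species, the observed number of interactions
#' induced by the module's protein projection is compared to its distribution
#' over `R` degree-preserving randomizations of that species' network,
#' yielding `z = (L_obs - mu) / sigma` (0 when `sigma = 0` and `L_obs = mu`,
#' otherwise signed infinity). Each module's `z_module` is the maximum of its
#' two per-species Z-scores, so a module poorly connected in one species can
#' still be called significant through its ortholog counterpart. The
#' empirical p-value recomputes `z_module` within every randomization and is
#' `(r + 1) / (R + 1)` with `r` the number of randomizations reaching a
#' `z_module` at least as large as the observed one.
#'
#' @param modules list of `ppi_module` objects (or any list whose elements
#'   carry `proj1`/`proj2` character vectors and optionally `id`).
#' @param net1,net2 the two input [weighted_network()]s.
#' @param R number of randomizations per species (paper-scale default 1000).
#' @param rng_seed integer seed.
#' @param swap_factor see [degree_preserving_randomize()].
#' @return data.frame with per-module `L_obs`, `mu`, `sigma`, `z` for each
#'   species, `z_module` and `p_empirical`.
#' @export
connectivity_significance <- function(modules, net1, net2, R = 1000L,
                                      rng_seed = 1L, swap_factor = 10L) {
  nets <- list(net1, net2)
  nmod <- length(modules)
  ids <- vapply(seq_len(nmod), function(i) {
    m <- modules[[i]]
    if (!is.null(m$id) && !is.na(m$id)) m$id else sprintf("set%03d", i)
  }, "")
  seeds <- with_seed(rng_seed, sample.int(2^30, 2L * R))

  L_obs <- matrix(0L, nmod, 2L)
  L_rand <- array(0L, c(nmod, 2L, R))
  for (sp in 1:2) {
    net <- nets[[sp]]
    n <- length(net$nodes)
    idx <- stats::setNames(seq_len(n), net$nodes)
    members <- lapply(modules, function(m) {
      pr <- if (sp == 1L) m$proj1 else m$proj2
      absent <- setdiff(pr, net$nodes)
      if (length(absent))
        message("proteins absent from network ", net$species, " treated as ",
                "degree-0: ", paste(absent, collapse = ", "))
      unname(idx[intersect(pr, net$nodes)])
    })
    make_exists <- function(w) {
      ex <- logical(n * n)
      ia <- unname(idx[w$edges$a]); ib <- unname(idx[w$edges$b])
      ex[(pmin(ia, ib) - 1) * n + pmax(ia, ib)] <- TRUE
      ex
    }
    ex0 <- make_exists(net)
    L_obs[, sp] <- vapply(members, function(mm)
      induced_edge_count(ex0, n, mm), 0L)
    for (r in seq_len(R)) {
      rn <- degree_preserving_randomize(net, seeds[(sp - 1L) * R + r],
                                        swap_factor)
      exr <- make_exists(rn)
      L_rand[, sp, r] <- vapply(members, function(mm)
        induced_edge_count(exr, n, mm), 0L)
    }
  }

  zval <- function(l, mu, sigma) {
    len <- max(length(l), length(mu), length(sigma))
    l <- rep_len(l, len); mu <- rep_len(mu, len); sigma <- rep_len(sigma, len)
    ifelse(sigma > 0, (l - mu) / sigma,
           ifelse(l == mu, 0, sign(l - mu) * Inf))
  }
  out <- lapply(seq_len(nmod), function(i) {
    mu <- c(mean(L_rand[i, 1, ]), mean(L_rand[i, 2, ]))
    sigma <- c(stats::sd(L_rand[i, 1, ]), stats::sd(L_rand[i, 2, ]))
    z_obs <- zval(L_obs[i, ], mu, sigma)
    z_mod <- max(z_obs)
    z_rand <- pmax(zval(L_rand[i, 1, ], mu[1], sigma[1]),
                   zval(L_rand[i, 2, ], mu[2], sigma[2]))
    r <- sum(z_rand >= z_mod)
    data.frame(module_id = ids[i],
               L_obs1 = L_obs[i, 1], mu1 = mu[1], sigma1 = sigma[1], z1 = z_obs[1],
               L_obs2 = L_obs[i, 2], mu2 = mu[2], sigma2 = sigma[2], z2 = z_obs[2],
               z_module = z_mod, p_empirical = (r + 1) / (R + 1))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
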