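# Synthetic paired-network generator: two species networks with planted
# conserved complexes, per-edge reliabilities, species-specific false-negative
# edge loss and a noisy many-to-many orthology map, so the whole pipeline and
# its evaluation can run without any external database.

#' Configuration for the paired-network simulator
#'
#' The defaults define the package's standard benchmark: 300 proteins per
#' species, 10 planted conserved complexes of 6-10 proteins, within-complex
#' interaction probability 0.6 (drawn once on the shared complex template,
#' modelling conserved interactions), a per-species independent
#' false-negative rate of 0.2 on those edges, Erdos-Renyi background at
#' density 0.005, and 30% extra spurious many-to-many ortholog pairs on top
#' of the true 1-1 core. Reliabilities are Beta-distributed: `rel_true`
#' (shape pair, mean 0.75) for within-complex edges and the true ortholog
#' core, `rel_background` (mean ~0.29) for background edges and spurious
#' ortholog pairs.
#'
#' @param n_proteins proteins per species.
#' @param n_complexes number of planted conserved complexes.
#' @param complex_size_range inclusive (min, max) complex size.
#' @param p_in within-complex edge probability (shared template).
#' @param p_out background edge probability, per species.
#' @param false_negative_rate per-species probability of losing a template
#'   edge (in [0, 1]).
#' @param ortholog_noise fraction of spurious cross pairs added to the 1-1
#'   ortholog core.
#' @param rel_true,rel_background Beta shape pairs for reliabilities.
#' @param rng_seed integer seed; the whole simulation is deterministic in it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 300L, n_complexes = 10L,
                       complex_size_range = c(6L, 10L), p_in = 0.6,
                       p_out = 0.005, false_negative_rate = 0.2,
                       ortholog_noise = 0.3, rel_true = c(6, 2),
                       rel_background = c(2, 5), rng_seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_complexes = as.integer(n_complexes),
              complex_size_range = as.integer(complex_size_range),
              p_in = p_in, p_out = p_out,
              false_negative_rate = false_negative_rate,
              ortholog_noise = ortholog_noise,
              rel_true = rel_true, rel_background = rel_background,
              rng_seed = as.integer(rng_seed))
  if (cfg$n_proteins < 1L) stop("n_proteins must be positive")
  if (cfg$n_complexes < 0L) stop("n_complexes must be non-negative")
  if (length(cfg$complex_size_range) != 2L ||
      cfg$complex_size_range[1] > cfg$complex_size_range[2] ||
      cfg$complex_size_range[1] < 2L)
    stop("complex_size_range must be (min, max) with 2 <= min <= max")
  if (cfg$n_complexes * cfg$complex_size_range[2] > cfg$n_proteins)
    stop("planted complexes cannot exceed the protein universe")
  if (!(cfg$p_out >= 0 && cfg$p_out < cfg$p_in && cfg$p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1")
  if (cfg$false_negative_rate < 0 || cfg$false_negative_rate > 1)
    stop("false_negative_rate must lie in [0, 1]")
  if (cfg$ortholog_noise < 0) stop("ortholog_noise must be >= 0")
  structure(cfg, class = "sim_config")
}

rbeta_unit <- function(n, shape) {
  pmin(pmax(stats::rbeta(n, shape[1], shape[2]), 1e-6), 1)
}

all_pairs <- function(members) {
  if (length(members) < 2L) return(matrix(integer(), 2L, 0L))
  utils::combn(sort(members), 2L)
}

#' Simulate a pair of species networks with planted conserved complexes
#'
#' Proteins are labelled `s1_0001...` / `s2_0001...` with an implicit 1-1
#' ortholog core `s1_i <-> s2_i`. Complexes are disjoint protein index sets;
#' a shared within-complex edge template is drawn with probability `p_in` per
#' pair and then thinned independently per species at the false-negative
#' rate, so a template edge survives in both species (is conserved) with
#' probability `(1 - f)^2`. Background edges are drawn per species over pairs
#' not sharing a complex. The homology map is the full 1-1 core plus
#' `ortholog_noise * n_proteins` spurious random cross pairs with
#' background-level confidences.
#'
#' @param cfg a [sim_config()].
#' @return list with `net1`, `net2` ([weighted_network()]), `hom`
#'   ([homology_map()]) and `truth` (class `sim_truth`: per-species planted
#'   catalogs `catalog1`/`catalog2`, the `core` pair table and the injected
#'   `spurious` pairs).
#' @export
simulate_paired_networks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_proteins
  name1 <- sprintf("s1_%04d", seq_len(n))
  name2 <- sprintf("s2_%04d", seq_len(n))

  with_seed(cfg$rng_seed, {
    # planted complexes: disjoint member index sets
    size_choices <- seq(cfg$complex_size_range[1], cfg$complex_size_range[2])
    sizes <- if (cfg$n_complexes)
      size_choices[sample.int(length(size_choices), cfg$n_complexes,
                              replace = TRUE)] else integer()
    pool <- sample.int(n, sum(sizes))
    members <- split(pool, rep(seq_along(sizes), times = sizes))
    in_complex <- integer(n)
    for (i in seq_along(members)) in_complex[members[[i]]] <- i

    # shared within-complex template, thinned per species
    template <- do.call(cbind, c(lapply(members, all_pairs),
                                 list(matrix(integer(), 2L, 0L))))
    drawn <- stats::runif(ncol(template)) < cfg$p_in
    template <- template[, drawn, drop = FALSE]
    keep1 <- stats::runif(ncol(template)) >= cfg$false_negative_rate
    keep2 <- stats::runif(ncol(template)) >= cfg$false_negative_rate

    # per-species background over pairs not sharing a complex
    backgr <- function() {
      prs <- utils::combn(n, 2L)
      same <- in_complex[prs[1, ]] != 0L &
        in_complex[prs[1, ]] == in_complex[prs[2, ]]
      cand <- prs[, !same, drop = FALSE]
      cand[, stats::runif(ncol(cand)) < cfg$p_out, drop = FALSE]
    }
    bg1 <- backgr(); bg2 <- backgr()

    build_net <- function(tpl, bg, names_sp, label) {
      ed <- cbind(tpl, bg)
      w <- c(rbeta_unit(ncol(tpl), cfg$rel_true),
             rbeta_unit(ncol(bg), cfg$rel_background))
      weighted_network(
        data.frame(a = names_sp[ed[1, ]], b = names_sp[ed[2, ]], w = w),
        label, nodes = names_sp)
    }
    net1 <- build_net(template[, keep1, drop = FALSE], bg1, name1, "species1")
    net2 <- build_net(template[, keep2, drop = FALSE], bg2, name2, "species2")

    # homology: 1-1 core plus spurious many-to-many noise
    core <- data.frame(p1 = name1, p2 = name2,
                       conf = rbeta_unit(n, cfg$rel_true))
    n_spur <- round(cfg$ortholog_noise * n)
    spur <- data.frame(p1 = character(), p2 = character(), conf = numeric())
    if (n_spur > 0) {
      i <- sample.int(n, 4L * n_spur, replace = TRUE)
      j <- sample.int(n, 4L * n_spur, replace = TRUE)
      ok <- i != j            # off-core pairs only
      i <- i[ok][seq_len(min(n_spur, sum(ok)))]
      j <- j[ok][seq_len(min(n_spur, sum(ok)))]
      spur <- unique(data.frame(p1 = name1[i], p2 = name2[j]))
      spur$conf <- rbeta_unit(nrow(spur), cfg$rel_background)
    }
    hom <- homology_map(rbind(core, spur))
  })

  truth <- structure(list(
    catalog1 = complex_catalog(stats::setNames(
      lapply(members, function(m) name1[m]),
      sprintf("plant%02d", seq_along(members)))),
    catalog2 = complex_catalog(stats::setNames(
      lapply(members, function(m) name2[m]),
      sprintf("plant%02d", seq_along(members)))),
    core = core[, c("p1", "p2")],
    spurious = spur[, c("p1", "p2")]), class = "sim_truth")

  list(net1 = net1, net2 = net2, hom = hom, truth = truth)
}

#' Recovery report against the planted truth
#'
#' Scores a set of discovered modules against the planted complexes the way
#' reference catalogs are scored on real data, per species: for every planted
#' complex the best-match F1 of any module projection. The cross-species
#' mapping accuracy is the fraction of module ortholog-pair nodes that are
#' true-core pairs.
#'
#' @param modules list of `ppi_module` objects.
#' @param truth the `sim_truth` from [simulate_paired_networks()].
#' @return list with `per_complex` (data.frame: complex, species, best F1 and
#'   best module), `mean_best_f1`, `frac_f1_gt_0.3`, `frac_f1_gt_0.5`
#'   (fractions of (complex, species) pairs above the thresholds) and
#'   `mapping_accuracy`.
#' @export
recovery_report <- function(modules, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  cats <- list(truth$catalog1, truth$catalog2)
  rows <- list()
  for (sp in 1:2) {
    cat_sp <- cats[[sp]]
    for (cid in names(cat_sp)) {
      best_f1 <- 0; best_id <- NA_character_
      for (m in modules) {
        f1 <- prf1(module_projection(m, sp), cat_sp[[cid]])[["f1"]]
        if (f1 > best_f1) { best_f1 <- f1; best_id <- m$id }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(complex_id = cid, species = sp, best_f1 = best_f1,
                   best_module_id = best_id)
    }
  }
  per_complex <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(complex_id = character(), species = integer(),
                  best_f1 = numeric(), best_module_id = character())

  core_key <- paste(truth$core$p1, truth$core$p2)
  node_pairs <- unlist(lapply(modules, function(m) m$nodes))
  acc <- if (length(node_pairs)) {
    mean(sub("\\|", " ", node_pairs) %in% core_key)
  } else NA_real_

  list(per_complex = per_complex,
       mean_best_f1 = if (nrow(per_complex)) mean(per_complex$best_f1) else NA_real_,
       frac_f1_gt_0.3 = if (nrow(per_complex)) mean(per_complex$best_f1 > 0.3) else NA_real_,
       frac_f1_gt_0.5 = if (nrow(per_complex)) mean(per_complex$best_f1 > 0.5) else NA_real_,
       mapping_accuracy = acc)
}
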