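# Tabular input/output and normalization into the package's domain types.
# All formats are tab-delimited UTF-8; lines starting with "#" are comments.

#' Construct a weighted PPI network
#'
#' A `weighted_network` is an undirected graph of proteins with a per-edge
#' reliability score in (0, 1]. Self-loops are not allowed and each unordered
#' protein pair occurs at most once.
#'
#' @param edges data.frame with columns `a`, `b` (protein identifiers,
#'   character) and `w` (reliability in (0, 1]).
#' @param species_label short label naming the species/network.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   proteins occurring in `edges`. Extra isolated nodes may be supplied.
#' @return object of class `weighted_network` with elements `species`,
#'   `nodes` (character) and `edges` (data.frame `a`, `b`, `w` with `a < b`).
#' @export
weighted_network <- function(edges, species_label, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "w") %in% names(edges)))
  a <- as.character(edges$a); b <- as.character(edges$b)
  w <- as.numeric(edges$w)
  if (any(is.na(w))) stop("non-numeric edge weight")
  if (any(w <= 0 | w > 1)) {
    stop("edge reliabilities must lie in (0, 1]; offending values: ",
         paste(utils::head(w[w <= 0 | w > 1], 3), collapse = ", "))
  }
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped from network '", species_label, "'")
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  # canonical unordered orientation, then max-merge duplicates
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  if (length(a)) {
    dt <- data.table::data.table(a = a, b = b, w = w)
    dt <- dt[, list(w = max(w)), by = c("a", "b")]
    data.table::setkeyv(dt, c("a", "b"))
    ed <- as.data.frame(dt)
  } else {
    ed <- data.frame(a = character(), b = character(), w = numeric())
  }
  nd <- sort(unique(c(ed$a, ed$b, as.character(nodes))))
  structure(list(species = species_label, nodes = nd, edges = ed),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network '", x$species, "': ", length(x$nodes), " proteins, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Construct a homology map
#'
#' Scored, possibly many-to-many associations between proteins of two species
#' (Inparanoid-style). Duplicate pairs are merged keeping the maximum
#' confidence.
#'
#' @param records data.frame with columns `p1`, `p2` (identifiers in species 1
#'   and 2) and `conf` (confidence in (0, 1]).
#' @return object of class `homology_map`: data.frame `p1`, `p2`, `conf`.
#' @export
homology_map <- function(records) {
  stopifnot(is.data.frame(records), all(c("p1", "p2", "conf") %in% names(records)))
  p1 <- as.character(records$p1); p2 <- as.character(records$p2)
  conf <- as.numeric(records$conf)
  if (any(is.na(conf))) stop("non-numeric homology confidence")
  if (any(conf <= 0 | conf > 1)) stop("homology confidences must lie in (0, 1]")
  if (length(p1)) {
    dt <- data.table::data.table(p1 = p1, p2 = p2, conf = conf)
    dt <- dt[, list(conf = max(conf)), by = c("p1", "p2")]
    data.table::setkeyv(dt, c("p1", "p2"))
    df <- as.data.frame(dt)
  } else {
    df <- data.frame(p1 = character(), p2 = character(), conf = numeric())
  }
  structure(df, class = c("homology_map", "data.frame"))
}

#' @export
print.homology_map <- function(x, ...) {
  cat("homology_map: ", nrow(x), " scored ortholog pairs (",
      length(unique(x$p1)), " x ", length(unique(x$p2)), " proteins)\n", sep = "")
  invisible(x)
}

#' Construct a complex catalog
#'
#' Reference catalog of protein complexes for one species (CYC2008/CORUM
#' style): a named list mapping complex id to a set of member proteins.
#'
#' @param complexes named list of character vectors (members, deduplicated).
#' @return object of class `complex_catalog`.
#' @export
complex_catalog <- function(complexes) {
  stopifnot(is.list(complexes))
  if (length(complexes)) {
    if (is.null(names(complexes)) || anyDuplicated(names(complexes)))
      stop("complex ids must be unique and non-empty")
    complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
    if (any(vapply(complexes, length, 1L) == 0L))
      stop("complex member sets must be non-empty")
  }
  structure(complexes, class = "complex_catalog")
}

read_tsv_rows <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

parse_three_col <- function(path, what) {
  rows <- read_tsv_rows(path)
  if (!length(rows$lines))
    return(data.frame(a = character(), b = character(), w = numeric()))
  fields <- strsplit(rows$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(what, " parse error at line ", rows$lineno[bad[1]],
         ": expected >= 3 tab-separated fields, got ", nf[bad[1]])
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  wchr <- vapply(fields, `[[`, "", 3L)
  w <- suppressWarnings(as.numeric(wchr))
  # optional single header line, detected by a non-numeric third field
  if (is.na(w[1]) && length(w) >= 1L) {
    a <- a[-1]; b <- b[-1]; w <- w[-1]; rows$lineno <- rows$lineno[-1]
  }
  if (anyNA(w))
    stop(what, " parse error at line ", rows$lineno[which(is.na(w))[1]],
         ": non-numeric score")
  data.frame(a = a, b = b, w = w)
}

#' Read a weighted PPI network from a TSV edge list
#'
#' Expects at least three tab-separated columns: protein A, protein B,
#' reliability in (0, 1]. An optional header line is detected by a non-numeric
#' third field. Duplicate rows for the same unordered pair keep the maximum
#' weight; self-loops are dropped with a warning.
#'
#' @param path path to the TSV file.
#' @param species_label label for the network.
#' @return a [weighted_network()].
#' @export
read_network <- function(path, species_label) {
  df <- parse_three_col(path, "network")
  weighted_network(data.frame(a = df$a, b = df$b, w = df$w), species_label)
}

#' Read a homology table from TSV
#'
#' Columns: id in species 1, id in species 2, confidence in (0, 1]. Duplicate
#' pairs keep the maximum confidence.
#'
#' @param path path to the TSV file.
#' @return a [homology_map()].
#' @export
read_homology <- function(path) {
  df <- parse_three_col(path, "homology")
  homology_map(data.frame(p1 = df$a, p2 = df$b, conf = df$w))
}

#' Read a complex catalog (GMT-like)
#'
#' One complex per line: complex id, then tab-separated member identifiers.
#'
#' @param path path to the file.
#' @return a [complex_catalog()].
#' @export
read_complexes <- function(path) {
  rows <- read_tsv_rows(path)
  if (!length(rows$lines)) return(complex_catalog(list()))
  fields <- strsplit(rows$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad))
    stop("catalog parse error at line ", rows$lineno[bad[1]],
         ": expected complex id plus >= 1 member")
  ids <- vapply(fields, `[[`, "", 1L)
  members <- lapply(fields, function(f) f[-1])
  names(members) <- ids
  complex_catalog(members)
}

#' Write a weighted network as a TSV edge list
#' @param net a [weighted_network()].
#' @param path output path.
#' @export
write_network <- function(net, path) {
  ed <- net$edges
  writeLines(c("#protein_a\tprotein_b\treliability",
               sprintf("%s\t%s\t%s", ed$a, ed$b, format(ed$w, digits = 15))),
             path)
  invisible(NULL)
}

#' Write a homology map as TSV
#' @param hom a [homology_map()].
#' @param path output path.
#' @export
write_homology <- function(hom, path) {
  writeLines(c("#protein_species1\tprotein_species2\tconfidence",
               sprintf("%s\t%s\t%s", hom$p1, hom$p2, format(hom$conf, digits = 15))),
             path)
  invisible(NULL)
}

#' Write a complex catalog (GMT-like)
#' @param catalog a [complex_catalog()].
#' @param path output path.
#' @export
write_complexes <- function(catalog, path) {
  lines <- vapply(names(catalog), function(id) {
    paste(c(id, catalog[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(NULL)
}

#' Write discovered modules
#'
#' Writes one TSV record per module (id, score, seed nodes, composite nodes as
#' `protein1|protein2`, per-species projections) plus a JSON sidecar carrying
#' full provenance (the subgraphs accepted at each expansion step). Output
#' ordering is deterministic: score descending, ties by lexicographically
#' smallest node set.
#'
#' @param modules list of modules as returned by [discover_modules()].
#' @param path output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return invisibly, the ordered module list.
#' @export
write_modules <- function(modules, path) {
  modules <- order_modules(modules)
  header <- paste("module_id", "n_nodes", "score", "node_score_sum",
                  "edge_score_sum", "seed_nodes", "composite_nodes",
                  "proteins_species1", "proteins_species2", sep = "\t")
  recs <- vapply(modules, function(m) {
    paste(m$id, length(m$nodes), format(m$score, digits = 15),
          format(m$node_score_sum, digits = 15),
          format(m$edge_score_sum, digits = 15),
          paste(sort(m$seed$nodes), collapse = ","),
          paste(sort(m$nodes), collapse = ","),
          paste(sort(m$proj1), collapse = ","),
          paste(sort(m$proj2), collapse = ","), sep = "\t")
  }, "")
  writeLines(c(header, recs), path)
  side <- lapply(modules, function(m) {
    list(id = m$id, nodes = sort(m$nodes), seed = sort(m$seed$nodes),
         score = m$score,
         steps = lapply(m$steps, function(s)
           list(iteration = s$iteration,
                accepted = lapply(s$accepted, sort))))
  })
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(modules)
}

order_modules <- function(modules) {
  if (!length(modules)) return(modules)
  sc <- vapply(modules, function(m) m$score, 0)
  key <- vapply(modules, function(m) paste(sort(m$nodes), collapse = "\r"), "")
  modules[order(-sc, key)]
}
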