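#' Load a filtered protein-interaction network from an edge list
#'
#' Accepts a STRING-dialect edge table (`protein1`, `protein2`,
#' `combined_score`, or the first three columns in that order) as a file
#' path or data.frame. Scores on the 0-1000 integer scale are auto-detected
#' and rescaled to \[0, 1\]; self-loops are dropped, duplicate undirected
#' edges are collapsed keeping the maximum score, and edges below
#' `score_threshold` are removed.
#'
#' @param edges path to a TSV file or a data.frame.
#' @param score_threshold minimum combined score kept (default 0.4, the
#'   medium-confidence cutoff).
#' @return an undirected `igraph` graph with edge attribute `weight`.
#' @export
load_network <- function(edges, score_threshold = 0.4) {
  if (is.character(edges)) {
    df <- read.delim(edges, header = TRUE, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(edges, stringsAsFactors = FALSE)
  }
  if (ncol(df) < 3) stop("edge table needs 3 columns", call. = FALSE)
  df <- df[, 1:3]
  names(df) <- c("protein1", "protein2", "combined_score")
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(!is.finite(score) | !nzchar(df$protein1) | !nzchar(df$protein2))
  if (length(bad)) {
    stop(sprintf("malformed edge row at line %d", bad[1] + 1L), call. = FALSE)
  }
  if (max(score) > 1) score <- score / 1000
  df$combined_score <- score
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  # canonical undirected key, keep max score across duplicates
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  key <- paste(a, b, sep = "\r")
  best <- tapply(df$combined_score, key, max)
  ab <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  edges_clean <- data.frame(from = ab[, 1], to = ab[, 2],
                            weight = as.numeric(best),
                            stringsAsFactors = FALSE)
  edges_clean <- edges_clean[edges_clean$weight >= score_threshold, ,
                             drop = FALSE]
  if (nrow(edges_clean) == 0) {
    warning("no edges pass the score threshold; returning an empty network")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  igraph::graph_from_data_frame(edges_clean, directed = FALSE)
}

# highest k-core of a graph: the subgraph induced by vertices of maximal
# coreness, together with that coreness value
.highest_kcore <- function(g) {
  if (igraph::vcount(g) == 0) return(list(graph = g, k = 0))
  core <- igraph::coreness(g)
  kmax <- max(core)
  list(graph = igraph::induced_subgraph(g, which(core == kmax)), k = kmax)
}

.density_of <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Density-based module detection (MCODE-style)
#'
#' Stage 1 weights every node by its core-clustering coefficient (density of
#' the highest k-core of its closed neighborhood) times that core's k
#' number; nodes below `degree_cutoff` get weight zero. Stage 2 grows
#' modules greedily from the highest-weight unassigned seed, including
#' neighbors whose weight is at least `(1 - node_score_cutoff)` times the
#' seed weight; a node belongs to at most one module. Stage 3 drops modules
#' without a `k_core`-core and (with `haircut`) iteratively removes
#' singly-connected members. Ties are broken lexicographically by node name
#' throughout, so the output is deterministic.
#'
#' @param net `igraph` graph from [load_network()].
#' @param degree_cutoff minimum degree for a nonzero node weight.
#' @param node_score_cutoff inclusion slack relative to the seed weight.
#' @param k_core minimum core a reported module must contain.
#' @param haircut remove singly-connected module members.
#' @param fluff unused (kept for interface parity; fluff is off).
#' @return list of class `bb_modules`: `modules` (list of
#'   `list(members, seed, size, density, score)` ordered by descending
#'   score) and `node_weights` (named numeric).
#' @export
mcode_detect <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, haircut = TRUE, fluff = FALSE) {
  n <- igraph::vcount(net)
  if (n == 0 || igraph::ecount(net) == 0) {
    return(structure(list(modules = list(), node_weights = numeric(0)),
                     class = "bb_modules"))
  }
  vnames <- igraph::V(net)$name
  deg <- igraph::degree(net)
  weights <- numeric(n)
  names(weights) <- vnames
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  for (i in seq_len(n)) {
    if (deg[i] < degree_cutoff) next
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(net, nb)
    hk <- .highest_kcore(sub)
    weights[i] <- hk$k * .density_of(hk$graph)
  }

  assigned <- logical(n)
  modules <- list()
  ord <- order(-weights, vnames)
  for (seed_i in ord) {
    if (assigned[seed_i] || weights[seed_i] <= 0) next
    thresh <- (1 - node_score_cutoff) * weights[seed_i]
    members <- seed_i
    assigned[seed_i] <- TRUE
    queue <- seed_i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- as.integer(adj[[v]])
      ok <- nb[!assigned[nb] & weights[nb] >= thresh]
      if (length(ok)) {
        assigned[ok] <- TRUE
        members <- c(members, ok)
        queue <- c(queue, ok)
      }
    }
    sub <- igraph::induced_subgraph(net, members)
    if (max(igraph::coreness(sub)) < k_core) next
    if (haircut) {
      repeat {
        dd <- igraph::degree(sub)
        drop <- which(dd < 2)
        if (length(drop) == 0 || igraph::vcount(sub) - length(drop) < 2) break
        sub <- igraph::delete_vertices(sub, drop)
      }
    }
    mem <- sort(igraph::V(sub)$name)
    modules[[length(modules) + 1L]] <- list(
      members = mem, seed = vnames[seed_i], size = length(mem),
      density = .density_of(sub), score = .density_of(sub) * length(mem)
    )
  }
  if (length(modules)) {
    scores <- vapply(modules, `[[`, numeric(1), "score")
    seeds <- vapply(modules, `[[`, character(1), "seed")
    modules <- modules[order(-scores, seeds)]
  }
  structure(list(modules = modules, node_weights = weights),
            class = "bb_modules")
}

#' Gene-set enrichment of detected modules
#'
#' Each module's member genes are tested against every set of a GMT-style
#' collection with [hypergeom_enrich()]; Benjamini-Hochberg correction is
#' applied within each module across sets, and results with an overlap below
#' `min_genes` are removed after testing.
#'
#' @param modules `bb_modules` object.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe gene universe.
#' @param min_genes minimum overlap retained (default 3).
#' @param fdr_q FDR threshold for the `enriched` flag.
#' @return data.frame with `module_id`, `module_seed`, and the
#'   [hypergeom_enrich()] columns; empty modules are skipped.
#' @export
module_enrichment <- function(modules, collection, universe, min_genes = 3,
                              fdr_q = 0.05) {
  rows <- lapply(seq_along(modules$modules), function(i) {
    mod <- modules$modules[[i]]
    if (length(mod$members) == 0) {
      message("skipping empty module ", i)
      return(NULL)
    }
    e <- hypergeom_enrich(mod$members, collection, universe, fdr_q = fdr_q)
    e <- e[e$k >= min_genes, , drop = FALSE]
    if (nrow(e) == 0) return(NULL)
    cbind(module_id = i, module_seed = mod$seed, e)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(module_id = integer(), module_seed = character(),
                      group = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical()))
  }
  do.call(rbind, rows)
}

#' Export a network to GraphML
#' @param net `igraph` graph.
#' @param path output file path.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
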