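# From-scratch implementation of the MCODE complex-detection algorithm:
# core-clustering-coefficient vertex weighting, seeded greedy expansion and
# haircut/fluff post-processing, with the plug-in's documented defaults.

#' MCODE parameters
#'
#' Defaults mirror the Cytoscape plug-in: seeds need degree >= 2, neighbours
#' join a complex when their weight is within 20% of the seed weight
#' (`node_score_cutoff = 0.2`), reported complexes must contain a 2-core,
#' expansion depth is effectively unbounded (`max_depth = 100`), the 2-core
#' haircut is on and fluff is off.
#'
#' @param degree_cutoff Minimum degree for a vertex to seed a complex.
#' @param node_score_cutoff Admission slack relative to the seed weight.
#' @param k_core A complex must contain a k-core of this order.
#' @param max_depth Maximum expansion distance from the seed.
#' @param haircut Iteratively remove complex nodes of within-complex degree < 2.
#' @param fluff Add boundary neighbours whose neighbourhood density exceeds
#'   `fluff_density`.
#' @param fluff_density Density threshold used when `fluff = TRUE`.
#' @return List of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, max_depth = 100, haircut = TRUE,
                         fluff = FALSE, fluff_density = 0.5) {
  if (degree_cutoff < 1 || k_core < 1 || max_depth < 1)
    lnc_validation_error("degree_cutoff, k_core and max_depth must be positive")
  if (node_score_cutoff < 0 || node_score_cutoff > 1)
    lnc_validation_error("node_score_cutoff must lie in [0, 1]")
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff, k_core = k_core,
                 max_depth = max_depth, haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density),
            class = "mcode_params")
}

# Internal: edge density of an igraph subgraph (2E / V(V-1)).
graph_density <- function(g) {
  v <- igraph::vcount(g)
  if (v < 2) return(0)
  2 * igraph::ecount(g) / (v * (v - 1))
}

#' MCODE vertex weight (core-clustering coefficient x core number)
#'
#' The closed neighbourhood of `v` is reduced to its highest k-core; the
#' weight is that core number `k` multiplied by the core's edge density
#' `2E / (V (V - 1))`. A vertex whose core has fewer than 2 nodes weighs 0.
#'
#' @param network Gene network (igraph).
#' @param v Node id (name) or vector of ids; defaults to all vertices.
#' @return Named numeric vector of weights.
#' @export
vertex_weight <- function(network, v = igraph::V(network)$name) {
  adj <- igraph::adjacent_vertices(network, v)
  vapply(seq_along(v), function(i) {
    nb <- unique(c(v[i], igraph::as_ids(adj[[i]])))
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(network, nb)
    cores <- igraph::coreness(sub)
    k <- max(cores)
    if (k < 1) return(0)
    core <- igraph::induced_subgraph(sub, which(cores == k))
    if (igraph::vcount(core) < 2) return(0)
    k * graph_density(core)
  }, numeric(1), USE.NAMES = FALSE) -> w
  setNames(w, v)
}

# Internal: iterative 2-core haircut on a set of node names.
haircut_nodes <- function(network, nodes) {
  repeat {
    if (length(nodes) < 3) return(nodes)
    sub <- igraph::induced_subgraph(network, nodes)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg < 2]
    if (!length(drop)) return(nodes)
    nodes <- setdiff(nodes, drop)
  }
}

#' Detect dense modules with MCODE
#'
#' Seeds are taken in descending vertex weight (ties break by node id).
#' From each unvisited seed, neighbours are admitted when their weight is at
#' least `(1 - node_score_cutoff)` times the seed weight, recursively up to
#' `max_depth`; every node belongs to at most one module. Modules that do
#' not contain a `k_core` are discarded; the haircut removes peripheral
#' nodes of within-module degree < 2. The module score is its edge density
#' multiplied by its size.
#'
#' @param network Gene network (igraph), simple and undirected.
#' @param params An [mcode_params()] list.
#' @return List of class `mcode_modules`; each element has `node_ids`,
#'   `score`, `size`, `seed_id`. Sorted by score (desc), size (desc),
#'   seed id.
#' @export
mcode <- function(network, params = mcode_params()) {
  validate_gene_network(network)
  nv <- igraph::vcount(network)
  if (nv == 0) return(structure(list(), class = "mcode_modules"))
  names_v <- igraph::V(network)$name
  w <- vertex_weight(network, names_v)
  deg <- igraph::degree(network)
  order_seeds <- names_v[order(-w[names_v], names_v)]
  visited <- new.env(parent = emptyenv())
  modules <- list()

  neighbors_of <- function(node)
    igraph::V(network)$name[igraph::neighbors(network, node)]

  for (seed in order_seeds) {
    if (!is.null(visited[[seed]])) next
    if (deg[[seed]] < params$degree_cutoff) next
    sw <- w[[seed]]
    if (sw <= 0) next
    threshold <- sw * (1 - params$node_score_cutoff)
    member <- c(seed)
    visited[[seed]] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < params$max_depth) {
      nxt <- character(0)
      for (node in frontier) {
        for (nb in neighbors_of(node)) {
          if (!is.null(visited[[nb]])) next
          if (w[[nb]] >= threshold) {
            visited[[nb]] <- TRUE
            member <- c(member, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    # post-processing
    sub <- igraph::induced_subgraph(network, member)
    if (max(igraph::coreness(sub), 0) < params$k_core) next
    if (params$haircut) member <- haircut_nodes(network, member)
    if (length(member) < 2) next
    if (params$fluff) {
      boundary <- setdiff(
        unique(unlist(lapply(member, neighbors_of))), member)
      for (nb in boundary) {
        if (!is.null(visited[[nb]])) next
        nbh <- unique(c(nb, neighbors_of(nb)))
        dens <- graph_density(igraph::induced_subgraph(network, nbh))
        if (dens > params$fluff_density) {
          visited[[nb]] <- TRUE
          member <- c(member, nb)
        }
      }
    }
    msub <- igraph::induced_subgraph(network, member)
    modules[[length(modules) + 1]] <- list(
      node_ids = sort(member),
      score = graph_density(msub) * length(member),
      size = length(member),
      seed_id = seed)
  }
  if (length(modules)) {
    ord <- order(-vapply(modules, `[[`, numeric(1), "score"),
                 -vapply(modules, `[[`, numeric(1), "size"),
                 vapply(modules, `[[`, character(1), "seed_id"))
    modules <- modules[ord]
  }
  structure(modules, class = "mcode_modules")
}

#' @export
print.mcode_modules <- function(x, ...) {
  cat("MCODE modules:", length(x), "\n")
  for (i in seq_along(head(x, 10))) {
    cat(sprintf(" %2d. score=%.3f size=%d seed=%s\n", i, x[[i]]$score,
                x[[i]]$size, x[[i]]$seed_id))
  }
  invisible(x)
}

#' Write MCODE modules to TSV
#'
#' Columns: module_id, score, size, seed_id, node_ids (comma-separated).
#'
#' @param modules An `mcode_modules` list.
#' @param path Output TSV path.
#' @export
write_modules <- function(modules, path) {
  df <- data.frame(
    module_id = seq_along(modules),
    score = vapply(modules, `[[`, numeric(1), "score"),
    size = vapply(modules, `[[`, numeric(1), "size"),
    seed_id = vapply(modules, `[[`, character(1), "seed_id"),
    node_ids = vapply(modules, function(mm)
      paste(mm$node_ids, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
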