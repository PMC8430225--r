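# Gene-network container and the topological statistics used to
# characterise the lncRNA-TF network: power-law degree fit, clustering
# coefficient, average shortest path, permutation nulls and hub extraction.

#' Construct a typed gene network
#'
#' Networks are simple undirected igraph objects with a `node_type` vertex
#' attribute (`lncRNA`, `TF` or `m6A`) and an `edge_type` edge attribute
#' (`ceRNA`, `PPI`, `coexpr` or `feedback`; parallel edges of different
#' types between the same pair collapse to one edge whose label joins both,
#' e.g. `"ceRNA+PPI"`).
#'
#' @param edges data.frame with columns `source`, `target`, `edge_type`.
#' @param node_types Named character vector mapping node id to type.
#' @return An igraph object passing [validate_gene_network()].
#' @export
gene_network <- function(edges, node_types) {
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(validate_gene_network(g))
  }
  if (any(edges$source == edges$target))
    lnc_validation_error("self-loops are not allowed in a gene network")
  ids <- unique(c(edges$source, edges$target))
  missing_t <- setdiff(ids, names(node_types))
  if (length(missing_t))
    lnc_validation_error(paste0("nodes without a type label: ",
                                paste(head(missing_t, 5), collapse = ", ")))
  # collapse duplicate edges, merging their type labels
  key <- ifelse(edges$source < edges$target,
                paste(edges$source, edges$target, sep = "\r"),
                paste(edges$target, edges$source, sep = "\r"))
  types <- vapply(split(edges$edge_type, key), function(tt)
    paste(sort(unique(unlist(strsplit(tt, "+", fixed = TRUE)))), collapse = "+"),
    character(1))
  uq <- do.call(rbind, strsplit(names(types), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = uq[, 1], to = uq[, 2], edge_type = unname(types),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, node_type = unname(node_types[ids]),
                          stringsAsFactors = FALSE))
  validate_gene_network(g)
}

#' @rdname gene_network
#' @param network igraph object to validate.
#' @export
validate_gene_network <- function(network) {
  if (!igraph::is_igraph(network)) lnc_validation_error("not an igraph object")
  if (igraph::is_directed(network)) lnc_validation_error("network must be undirected")
  if (igraph::vcount(network) == 0) return(network)
  if (any(igraph::which_loop(network)))
    lnc_validation_error("network contains self-loops")
  if (any(igraph::which_multiple(network)))
    lnc_validation_error("network contains duplicate edges")
  if (is.null(igraph::V(network)$name))
    lnc_validation_error("network vertices must be named")
  if (is.null(igraph::V(network)$node_type))
    lnc_validation_error("network vertices must carry node_type")
  ok <- igraph::V(network)$node_type %in% c("lncRNA", "TF", "m6A")
  if (!all(ok)) lnc_validation_error("node_type must be lncRNA, TF or m6A")
  if (igraph::ecount(network) > 0 && is.null(igraph::E(network)$edge_type))
    lnc_validation_error("network edges must carry edge_type")
  network
}

#' Merge significant ceRNA pairs with TF-TF PPI edges into one network
#'
#' The lncRNA-TF network is the union of all significant lncRNA-TF ceRNA
#' pairs and the protein-protein interactions among the participating TFs.
#' Isolated nodes never arise (every node enters through an edge).
#'
#' @param cerna_pairs data.frame from [call_cerna_pairs()]; only rows with
#'   `significant == TRUE` are admitted.
#' @param ppi_edges Optional data.frame with columns `a`, `b`, both TFs. An
#'   edge touching an id classed as lncRNA is a validation error.
#' @return A gene network (igraph).
#' @export
build_network <- function(cerna_pairs, ppi_edges = NULL) {
  sig <- cerna_pairs[cerna_pairs$significant, , drop = FALSE]
  lnc_ids <- unique(sig$lnc_id)
  edges <- data.frame(source = sig$lnc_id, target = sig$tf_id,
                      edge_type = rep("ceRNA", nrow(sig)),
                      stringsAsFactors = FALSE)
  tf_ids <- unique(sig$tf_id)
  if (!is.null(ppi_edges) && nrow(ppi_edges) > 0) {
    touch <- c(ppi_edges$a, ppi_edges$b)
    bad <- intersect(touch, unique(cerna_pairs$lnc_id))
    if (length(bad))
      lnc_validation_error(paste0("PPI edge touches non-TF id(s): ",
                                  paste(head(bad, 5), collapse = ", ")))
    edges <- rbind(edges, data.frame(source = ppi_edges$a, target = ppi_edges$b,
                                     edge_type = "PPI", stringsAsFactors = FALSE))
    tf_ids <- unique(c(tf_ids, touch))
  }
  node_types <- setNames(c(rep("lncRNA", length(lnc_ids)),
                           rep("TF", length(tf_ids))),
                         c(lnc_ids, tf_ids))
  gene_network(edges, node_types)
}

#' Fit a power law to the degree distribution
#'
#' Computes the empirical degree distribution P(k) over distinct degrees
#' k >= 1 with nonzero count and regresses log10 P(k) on log10 k by ordinary
#' least squares. A scale-free network gives an approximately linear log-log
#' relationship; `alpha` is minus the slope and `r2` the coefficient of
#' determination of the fit.
#'
#' @param network Gene network (igraph).
#' @return List with `alpha` and `r2`.
#' @export
fit_power_law <- function(network) {
  deg <- igraph::degree(network)
  deg <- deg[deg >= 1]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  if (length(k) < 3)
    lnc_stop("power-law fit needs >= 3 distinct positive degrees",
             "lncnet_insufficient_data")
  pk <- as.numeric(tab) / sum(tab)
  fit <- stats::lm(log10(pk) ~ log10(k))
  res <- stats::residuals(fit)
  ss_tot <- sum((log10(pk) - mean(log10(pk)))^2)
  list(alpha = -unname(stats::coef(fit)[2]),
       r2 = 1 - sum(res^2) / ss_tot)
}

#' Mean local clustering coefficient
#'
#' Average over all nodes of the local clustering coefficient (observed
#' triangles among a node's neighbours divided by `choose(degree, 2)`);
#' nodes of degree < 2 contribute 0.
#'
#' @param network Gene network (igraph).
#' @return A proportion in `[0, 1]`.
#' @export
clustering_coefficient <- function(network) {
  if (igraph::vcount(network) < 1)
    lnc_stop("clustering coefficient needs >= 1 node", "lncnet_insufficient_data")
  igraph::transitivity(network, type = "localaverage", isolates = "zero")
}

#' Average shortest path length
#'
#' Mean unweighted shortest-path length over all unordered node pairs of the
#' largest connected component (computed by breadth-first search). When the
#' network is disconnected the restriction to the largest component is noted
#' via a message.
#'
#' @param network Gene network (igraph).
#' @return A positive number.
#' @export
average_shortest_path <- function(network) {
  comp <- igraph::components(network)
  if (max(comp$csize, 0) < 2)
    lnc_stop("no connected component with >= 2 nodes",
             "lncnet_insufficient_data")
  if (comp$no > 1) {
    lnc_log("network is disconnected; ASPL computed on the largest component (",
            max(comp$csize), " nodes)")
  }
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(network, which(comp$membership == big))
  igraph::mean_distance(sub, directed = FALSE)
}

#' Permutation test of a topological statistic
#'
#' Compares an observed network statistic (mean clustering coefficient or
#' average shortest path length) with its distribution over random null
#' networks. Two null schemes are available: `gnm` draws a uniform random
#' simple graph with the same node and edge counts; `degree_preserving`
#' rewires the observed network by double-edge swaps (10 |E| trials),
#' preserving the full degree sequence. The empirical p-value uses the
#' add-one estimator `(#{null >= obs} + 1) / (n_perm + 1)` (mirrored for
#' `alternative = "less"`), so it is never smaller than `1/(n_perm + 1)`.
#'
#' @param network Gene network (igraph).
#' @param statistic `"cc"` (clustering coefficient) or `"aspl"`.
#' @param n_perm Number of null networks (>= 1).
#' @param scheme `"gnm"` or `"degree_preserving"`.
#' @param alternative `"greater"` or `"less"`.
#' @param seed Integer seed; draws are fully reproducible.
#' @return List of class `lncnet_permutation` with observed value, null
#'   draws, p-value and null mean/sd.
#' @export
permutation_test <- function(network, statistic = c("cc", "aspl"),
                             n_perm = 1000,
                             scheme = c("gnm", "degree_preserving"),
                             alternative = c("greater", "less"),
                             seed = 1L) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  alternative <- match.arg(alternative)
  if (n_perm < 1) lnc_validation_error("n_perm must be >= 1")
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  if (m > choose(n, 2))
    lnc_validation_error("more edges than a simple graph allows")
  stat_fun <- switch(statistic,
    cc = clustering_coefficient,
    aspl = average_shortest_path)
  observed <- stat_fun(network)
  nulls <- with_stream_seed(seed, paste0("perm_", statistic, "_", scheme), {
    vapply(seq_len(n_perm), function(i) {
      g <- if (scheme == "gnm") {
        igraph::sample_gnm(n, m, directed = FALSE)
      } else {
        igraph::rewire(network, igraph::keeping_degseq(niter = 10 * m))
      }
      stat_fun(g)
    }, numeric(1))
  })
  extreme <- if (alternative == "greater") sum(nulls >= observed)
             else sum(nulls <= observed)
  p <- (extreme + 1) / (n_perm + 1)
  structure(list(statistic = statistic, observed = observed, nulls = nulls,
                 p = p, null_mean = mean(nulls), null_sd = stats::sd(nulls),
                 n_perm = n_perm, scheme = scheme, alternative = alternative),
            class = "lncnet_permutation")
}

#' @export
print.lncnet_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %s nulls, n_perm=%d)\n observed=%.4f null mean=%.4f (sd %.4f) p=%.4g (%s)\n",
    x$statistic, x$scheme, x$n_perm, x$observed, x$null_mean, x$null_sd,
    x$p, x$alternative))
  invisible(x)
}

#' Extract hub genes (top degree fraction)
#'
#' Hubs are the `ceiling(fraction * n_nodes)` nodes of highest degree; ties
#' at the cutoff break by node id (ascending) for determinism.
#'
#' @param network Gene network (igraph).
#' @param fraction Fraction of nodes to keep (default 0.10).
#' @return Character vector of hub node ids, ordered by decreasing degree.
#' @export
extract_hubs <- function(network, fraction = 0.10) {
  n <- igraph::vcount(network)
  if (n == 0) lnc_validation_error("cannot extract hubs from an empty network")
  k <- ceiling(fraction * n)
  deg <- igraph::degree(network)
  nm <- igraph::V(network)$name
  ord <- order(-deg, nm)
  nm[ord][seq_len(k)]
}

#' Full topology report
#'
#' Bundles node/edge counts, the power-law fit, clustering coefficient,
#' average shortest path and their permutation-null p-values (clustering
#' tested as `greater`, path length as `less`, matching the expectation that
#' a real regulatory network is more clustered and more compact than a
#' random graph of the same size).
#'
#' @param network Gene network (igraph).
#' @param config An [default_config()] list (uses `n_permutations`,
#'   `permutation_scheme`, `rng_seed`, `hub_fraction`).
#' @return List of class `lncnet_topology_report`.
#' @export
topology_report <- function(network, config = default_config()) {
  pl <- fit_power_law(network)
  perm_cc <- permutation_test(network, "cc", config$n_permutations,
                              config$permutation_scheme, "greater",
                              config$rng_seed)
  perm_aspl <- permutation_test(network, "aspl", config$n_permutations,
                                config$permutation_scheme, "less",
                                config$rng_seed)
  structure(list(
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    powerlaw_alpha = pl$alpha,
    powerlaw_r2 = pl$r2,
    clustering_coeff = perm_cc$observed,
    avg_short_path = perm_aspl$observed,
    perm_p_cc = perm_cc$p,
    perm_p_aspl = perm_aspl$p,
    null_summaries = list(
      cc = list(mean = perm_cc$null_mean, sd = perm_cc$null_sd,
                n_perm = perm_cc$n_perm),
      aspl = list(mean = perm_aspl$null_mean, sd = perm_aspl$null_sd,
                  n_perm = perm_aspl$n_perm)),
    hubs = extract_hubs(network, config$hub_fraction)),
    class = "lncnet_topology_report")
}

#' @export
print.lncnet_topology_report <- function(x, ...) {
  cat(sprintf(
    paste0("Gene network: %d nodes, %d edges\n",
           " power law: alpha=%.3f R2=%.3f\n",
           " clustering coefficient: %.4f (perm p=%.4g)\n",
           " average shortest path: %.4f (perm p=%.4g)\n",
           " hubs (top fraction): %d genes\n"),
    x$n_nodes, x$n_edges, x$powerlaw_alpha, x$powerlaw_r2,
    x$clustering_coeff, x$perm_p_cc, x$avg_short_path, x$perm_p_aspl,
    length(x$hubs)))
  invisible(x)
}
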