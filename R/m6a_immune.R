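# lncRNA-m6A regulator co-expression network, key-gene extraction and
# lncRNA vs immune-infiltration correlation analysis.

#' Bipartite co-expression network between two gene sets
#'
#' Computes the Pearson correlation between every gene of `expr_a` (e.g.
#' lncRNAs) and every gene of `expr_b` (e.g. m6A regulators) across the
#' shared, identically ordered samples, and keeps pairs passing the cutoff.
#' `mode = "absolute"` admits `|PCC| > cutoff` (strong negative
#' co-expression included); `mode = "signed"` requires `PCC > cutoff`.
#'
#' @param expr_a,expr_b Expression matrices with identical sample columns
#'   and disjoint gene sets.
#' @param cutoff Correlation cutoff (default 0.6).
#' @param mode `"absolute"` (default) or `"signed"`.
#' @param type_a,type_b Node types for the two sides (defaults "lncRNA",
#'   "m6A").
#' @return A gene network (igraph); edges carry the `pcc` attribute and
#'   `edge_type = "coexpr"`.
#' @export
correlation_network <- function(expr_a, expr_b, cutoff = 0.6,
                                mode = c("absolute", "signed"),
                                type_a = "lncRNA", type_b = "m6A") {
  mode <- match.arg(mode)
  if (!identical(colnames(expr_a), colnames(expr_b)))
    lnc_validation_error("expression matrices must share identically ordered samples")
  overlap <- intersect(rownames(expr_a), rownames(expr_b))
  if (length(overlap))
    lnc_validation_error("gene sets of the two sides must be disjoint")
  pcc <- cor(t(expr_a), t(expr_b))
  pass <- if (mode == "absolute") abs(pcc) > cutoff else pcc > cutoff
  pass[is.na(pass)] <- FALSE
  idx <- which(pass, arr.ind = TRUE)
  edges <- data.frame(source = rownames(expr_a)[idx[, 1]],
                      target = rownames(expr_b)[idx[, 2]],
                      edge_type = rep("coexpr", nrow(idx)),
                      stringsAsFactors = FALSE)
  node_types <- setNames(
    c(rep(type_a, nrow(expr_a)), rep(type_b, nrow(expr_b))),
    c(rownames(expr_a), rownames(expr_b)))
  g <- gene_network(edges, node_types)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$pcc <- pcc[cbind(idx[, 1], idx[, 2])]
  g
}

#' Key genes of a network by degree
#'
#' Genes whose degree is strictly greater than `min_degree_exclusive`
#' (default 2, i.e. degree > 2), sorted by degree descending then id.
#'
#' @param network Gene network (igraph).
#' @param min_degree_exclusive Exclusive degree threshold.
#' @return Character vector of gene ids.
#' @export
key_genes <- function(network, min_degree_exclusive = 2) {
  if (igraph::vcount(network) == 0) return(character(0))
  deg <- igraph::degree(network)
  sel <- deg > min_degree_exclusive
  nm <- igraph::V(network)$name[sel]
  d <- deg[sel]
  nm[order(-d, nm)]
}

#' Correlate lncRNA expression with immune-infiltration scores
#'
#' One row per (lncRNA, cell type): correlation estimate, its p-value
#' (Pearson t-test or Spearman), and a Benjamini-Hochberg q across the full
#' grid. A constant score column yields a row with `r = NA` flagged as
#' degenerate.
#'
#' @param lnc_expr Expression matrix (lncRNAs x samples).
#' @param infil Infiltration matrix (samples x cell types).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: lncRNA, cell_type, r, p, bh_q, degenerate.
#' @export
immune_correlation <- function(lnc_expr, infil,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(colnames(lnc_expr), rownames(infil))
  if (length(shared) < 3)
    lnc_validation_error("need >= 3 shared samples")
  le <- lnc_expr[, shared, drop = FALSE]
  im <- infil[shared, , drop = FALSE]
  grid <- expand.grid(lncRNA = rownames(le), cell_type = colnames(im),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- le[grid$lncRNA[i], ]
    y <- im[, grid$cell_type[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
  })
  out <- data.frame(
    lncRNA = grid$lncRNA, cell_type = grid$cell_type,
    r = vapply(res, `[[`, numeric(1), "r"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$bh_q <- p.adjust(out$p, method = "BH")
  out$degenerate = vapply(res, `[[`, logical(1), "degenerate")
  out
}

#' Stratify patients by infiltration of one immune cell type
#'
#' Mean-split on the chosen cell type's estimation score using the same
#' boundary rule as [stratify_by_mean()]; labels are `enriched` (above the
#' mean) / `other`, ready for [km_logrank()].
#'
#' @param infil Infiltration matrix (samples x cell types).
#' @param cell_type Column to stratify on.
#' @return Named character vector of labels per sample.
#' @export
stratify_by_infiltration <- function(infil, cell_type) {
  if (!cell_type %in% colnames(infil))
    lnc_validation_error(paste0("cell type '", cell_type,
                                "' absent from infiltration matrix"))
  lab <- stratify_by_mean(infil[, cell_type])
  out <- ifelse(lab == "high", "enriched", "other")
  setNames(out, rownames(infil))
}
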