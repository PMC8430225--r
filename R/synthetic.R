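# Seed-deterministic generators emulating the statistical structure of the
# pipeline's inputs (shared-miRNA target overlap, planted co-expression,
# exponential survival with planted hazards, planted dense graph modules,
# planted motif occurrences), each emitting machine-readable ground truth.

#' Simulate a miRNA-target interaction universe with planted ceRNA pairs
#'
#' Every gene's miRNA target set is drawn i.i.d. at `base_rate`; each
#' planted (lncRNA, TF) pair additionally shares `overlap_boost` dedicated
#' miRNAs (disjoint across planted pairs), creating the target-set overlap
#' that the hypergeometric test is designed to detect.
#'
#' @param n_mirna Size of the miRNA universe.
#' @param n_lnc,n_tf Numbers of lncRNAs / TFs.
#' @param base_rate Per-(gene, miRNA) interaction probability in `[0, 1)`.
#' @param overlap_boost Dedicated shared miRNAs per planted pair.
#' @param planted data.frame with columns lnc, tf (ids like "LNC0001",
#'   "TF001") or NULL.
#' @param seed Integer seed.
#' @return List: `interactions` (an [interaction_set()]), `truth` (list with
#'   `planted_pairs`).
#' @export
simulate_interactions <- function(n_mirna, n_lnc, n_tf, base_rate = 0.02,
                                  overlap_boost = 10, planted = NULL,
                                  seed = 1L) {
  if (base_rate < 0 || base_rate >= 1)
    lnc_validation_error("base_rate must lie in [0, 1)")
  if (overlap_boost > n_mirna)
    lnc_validation_error("overlap_boost cannot exceed n_mirna")
  mirnas <- sprintf("miR-%04d", seq_len(n_mirna))
  lncs <- sprintf("LNC%04d", seq_len(n_lnc))
  tfs <- sprintf("TF%03d", seq_len(n_tf))
  if (!is.null(planted)) {
    bad <- c(setdiff(planted$lnc, lncs), setdiff(planted$tf, tfs))
    if (length(bad))
      lnc_validation_error(paste0("planted ids outside the universe: ",
                                  paste(head(bad, 5), collapse = ", ")))
    if (nrow(planted) * overlap_boost > n_mirna)
      lnc_validation_error("not enough miRNAs for dedicated planted overlaps")
  }
  genes <- c(lncs, tfs)
  with_stream_seed(seed, "interactions", {
    targets_of <- lapply(genes, function(g) {
      mirnas[runif(n_mirna) < base_rate]
    })
    names(targets_of) <- genes
    if (!is.null(planted) && nrow(planted) > 0) {
      pool <- sample(mirnas, nrow(planted) * overlap_boost)
      for (i in seq_len(nrow(planted))) {
        ded <- pool[((i - 1) * overlap_boost + 1):(i * overlap_boost)]
        targets_of[[planted$lnc[i]]] <-
          union(targets_of[[planted$lnc[i]]], ded)
        targets_of[[planted$tf[i]]] <-
          union(targets_of[[planted$tf[i]]], ded)
      }
    }
    gene_class <- setNames(c(rep("lncRNA", n_lnc), rep("TF", n_tf)), genes)
    list(interactions = interaction_set(mirnas, targets_of, gene_class),
         truth = list(planted_pairs = planted))
  })
}

#' Simulate expression with planted co-expressed pairs
#'
#' Each planted pair with target correlation `rho` is generated from a
#' shared standard-normal latent factor:
#' `x = sqrt(rho) z + sqrt(1 - rho) e1`, `y = sqrt(rho) z + sqrt(1 - rho) e2`,
#' so the population correlation is exactly `rho`; all other genes are
#' independent Gaussian noise. Expression is on an arbitrary log-like scale
#' (`noise_sd` rescales every profile and does not change correlations).
#'
#' @param gene_ids All gene ids to simulate.
#' @param planted data.frame with columns a, b, rho (disjoint gene pairs) or
#'   NULL.
#' @param n_samples Number of samples (>= 3).
#' @param noise_sd Global scale of the expression values (> 0).
#' @param seed Integer seed.
#' @return Expression matrix (genes x samples).
#' @export
simulate_expression <- function(gene_ids, planted = NULL, n_samples = 300,
                                noise_sd = 1, seed = 1L) {
  if (n_samples < 3) lnc_validation_error("n_samples must be >= 3")
  if (noise_sd <= 0) lnc_validation_error("noise_sd must be positive")
  if (!is.null(planted) && nrow(planted) > 0) {
    if (any(planted$rho <= -1 | planted$rho >= 1))
      lnc_validation_error("target correlations must lie in (-1, 1)")
    pg <- c(planted$a, planted$b)
    if (anyDuplicated(pg))
      lnc_validation_error("planted pairs must be disjoint")
    if (!all(pg %in% gene_ids))
      lnc_validation_error("planted genes missing from gene_ids")
  }
  with_stream_seed(seed, "expression", {
    ex <- matrix(rnorm(length(gene_ids) * n_samples), length(gene_ids),
                 n_samples,
                 dimnames = list(gene_ids,
                                 sprintf("S%04d", seq_len(n_samples))))
    if (!is.null(planted) && nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        rho <- planted$rho[i]
        z <- rnorm(n_samples)
        sgn <- sign(rho); rho_a <- abs(rho)
        ex[planted$a[i], ] <- sqrt(rho_a) * z +
          sqrt(1 - rho_a) * rnorm(n_samples)
        ex[planted$b[i], ] <- sgn * sqrt(rho_a) * z +
          sqrt(1 - rho_a) * rnorm(n_samples)
      }
    }
    ex * noise_sd
  })
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(sum_i beta_i Exp(i))` per patient; censoring times
#' are exponential with rate `censor_rate`. Observed time is the minimum and
#' the event indicator records whether death preceded censoring.
#'
#' @param expr Expression matrix (genes x samples).
#' @param coefs Named numeric vector of true log-hazard coefficients (names
#'   must be rows of `expr`); may be empty for a null model.
#' @param baseline_rate,censor_rate Positive exponential rates.
#' @param seed Integer seed.
#' @return Clinical data.frame (sample_id, time, event).
#' @export
simulate_survival <- function(expr, coefs, baseline_rate = 0.1,
                              censor_rate = 0.02, seed = 1L) {
  if (baseline_rate <= 0 || censor_rate <= 0)
    lnc_validation_error("rates must be positive")
  missing_g <- setdiff(names(coefs), rownames(expr))
  if (length(missing_g))
    lnc_validation_error(paste0("coef genes absent from expression: ",
                                paste(missing_g, collapse = ", ")))
  ns <- ncol(expr)
  lp <- if (length(coefs)) {
    as.vector(crossprod(expr[names(coefs), , drop = FALSE], coefs))
  } else rep(0, ns)
  with_stream_seed(seed, "survival", {
    t_event <- rexp(ns, rate = baseline_rate * exp(lp))
    t_cens <- rexp(ns, rate = censor_rate)
    data.frame(sample_id = colnames(expr),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a background graph with planted dense modules
#'
#' An Erdos-Renyi `G(n, p)` background plus vertex-disjoint planted cliques,
#' each attached to the background by exactly one bridge edge. Node types
#' alternate lncRNA/TF so the result is a valid gene network.
#'
#' @param n_background Background vertex count.
#' @param p_background Background edge probability.
#' @param clique_sizes Integer vector of planted clique sizes (each >= 3).
#' @param seed Integer seed.
#' @return List: `network` (igraph), `truth` (list `planted_modules` of node
#'   id sets).
#' @export
simulate_modular_graph <- function(n_background = 100, p_background = 0.03,
                                   clique_sizes = c(5, 6), seed = 1L) {
  if (any(clique_sizes < 3))
    lnc_validation_error("clique sizes must be >= 3")
  bg_ids <- sprintf("BG%03d", seq_len(n_background))
  with_stream_seed(seed, "modular_graph", {
    g <- igraph::sample_gnp(n_background, p_background, directed = FALSE)
    igraph::V(g)$name <- bg_ids
    cliques <- list()
    for (ci in seq_along(clique_sizes)) {
      sz <- clique_sizes[ci]
      ids <- sprintf("M%d_%02d", ci, seq_len(sz))
      cliques[[ci]] <- ids
      g <- igraph::add_vertices(g, sz, name = ids)
      pairs <- utils::combn(ids, 2)
      g <- igraph::add_edges(g, as.vector(rbind(pairs[1, ], pairs[2, ])))
      bridge_bg <- sample(bg_ids, 1)
      bridge_cl <- sample(ids, 1)
      g <- igraph::add_edges(g, c(bridge_bg, bridge_cl))
    }
    igraph::V(g)$node_type <- rep(c("lncRNA", "TF"),
                                  length.out = igraph::vcount(g))
    if (igraph::ecount(g) > 0) igraph::E(g)$edge_type <- "coexpr"
    list(network = validate_gene_network(g),
         truth = list(planted_modules = cliques))
  })
}

#' Simulate sequences with planted motif occurrences
#'
#' Background bases are i.i.d. from the stated frequencies; each sequence
#' receives `planted_sites` motif occurrences sampled column-wise from the
#' PWM's frequency model at recorded non-overlapping offsets, reverse-
#' complemented when the recorded strand is '-'. Each sequence doubles as a
#' scannable region (whole-sequence BED) owned by a synthetic lncRNA.
#'
#' @param pwm An [pwm_from_counts()] object.
#' @param n_seq Number of sequences.
#' @param seq_len Length of each sequence (bp).
#' @param planted_sites Sites planted per sequence (0 for pure background).
#' @param background Base frequencies used for background positions.
#' @param seed Integer seed.
#' @return List: `sequences` (named character), `regions` (data.frame usable
#'   by [scan_regions()]), `truth` (data.frame seq_id, offset, strand).
#' @export
simulate_sequences <- function(pwm, n_seq = 50, seq_len = 500,
                               planted_sites = 1,
                               background = rep(0.25, 4), seed = 1L) {
  stopifnot(inherits(pwm, "lncnet_pwm"))
  background <- background / sum(background)
  w <- pwm$width
  if (planted_sites * 2 * w > seq_len)
    lnc_validation_error("sequences too short for the requested sites")
  with_stream_seed(seed, "sequences", {
    seq_ids <- sprintf("seq%03d", seq_len(n_seq))
    truth <- list()
    seqs <- vapply(seq_len(n_seq), function(i) {
      chars <- sample(BASES, seq_len, replace = TRUE, prob = background)
      if (planted_sites > 0) {
        # non-overlapping offsets via slot partitioning
        n_slots <- floor(seq_len / w)
        slots <- sample(seq_len(n_slots), planted_sites)
        for (sl in slots) {
          off <- (sl - 1) * w
          word <- vapply(seq_len(w), function(j)
            sample(BASES, 1, prob = pwm$freq[j, ]), character(1))
          strand <- sample(c("+", "-"), 1)
          if (strand == "-")
            word <- rev(c(A = "T", C = "G", G = "C", T = "A")[word])
          chars[(off + 1):(off + w)] <- word
          truth[[length(truth) + 1]] <<- data.frame(
            seq_id = seq_ids[i], offset = off, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
      paste(chars, collapse = "")
    }, character(1))
    names(seqs) <- seq_ids
    regions <- data.frame(
      chrom = seq_ids, start = 0L, end = seq_len, strand = ".",
      role = "promoter", owner_gene = sprintf("LNC%04d", seq_len(n_seq)),
      name = paste0(seq_ids, "_promoter"), stringsAsFactors = FALSE)
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seq_id = character(0), offset = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    list(sequences = seqs, regions = regions, truth = truth_df)
  })
}

#' Simulate immune-infiltration scores with planted lncRNA correlations
#'
#' Each planted (lncRNA, cell type) pair makes the cell type's score a noisy
#' copy of the lncRNA profile at the target correlation; other cell types
#' are independent noise.
#'
#' @param lnc_expr Expression matrix (lncRNAs x samples).
#' @param cell_types Character vector of cell type names.
#' @param planted data.frame with columns lnc, cell_type, rho, or NULL.
#' @param seed Integer seed.
#' @return Samples x cell-types score matrix.
#' @export
simulate_infiltration <- function(lnc_expr, cell_types, planted = NULL,
                                  seed = 1L) {
  ns <- ncol(lnc_expr)
  with_stream_seed(seed, "infiltration", {
    m <- matrix(rnorm(ns * length(cell_types)), ns, length(cell_types),
                dimnames = list(colnames(lnc_expr), cell_types))
    if (!is.null(planted) && nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        rho <- planted$rho[i]
        x <- scale(lnc_expr[planted$lnc[i], ])[, 1]
        m[, planted$cell_type[i]] <- rho * x +
          sqrt(1 - rho^2) * rnorm(ns)
      }
    }
    m
  })
}

#' One-call synthetic study
#'
#' Generates a coherent set of pipeline inputs: a miRNA-target universe with
#' planted ceRNA pairs, an expression matrix in which exactly those pairs
#' are co-expressed, and survival outcomes driven by a planted hazard on the
#' first planted pair's genes.
#'
#' @param n_mirna,n_lnc,n_tf Universe sizes.
#' @param n_planted Number of planted ceRNA pairs.
#' @param rho Target co-expression of planted pairs.
#' @param overlap_boost Dedicated shared miRNAs per planted pair.
#' @param base_rate Background interaction rate.
#' @param n_samples Number of patients.
#' @param hazard_beta True log-hazard coefficient on the planted genes.
#' @param seed Integer seed.
#' @return List: interactions, expression, clinical, truth.
#' @export
simulate_study <- function(n_mirna = 400, n_lnc = 200, n_tf = 50,
                           n_planted = 20, rho = 0.75, overlap_boost = 10,
                           base_rate = 0.02, n_samples = 300,
                           hazard_beta = 0.5, seed = 1L) {
  planted <- data.frame(
    lnc = sprintf("LNC%04d", seq_len(n_planted)),
    tf = sprintf("TF%03d", seq_len(n_planted)),
    stringsAsFactors = FALSE)
  si <- simulate_interactions(n_mirna, n_lnc, n_tf, base_rate,
                              overlap_boost, planted, seed)
  gene_ids <- names(si$interactions$gene_class)
  pl_expr <- data.frame(a = planted$lnc, b = planted$tf, rho = rho,
                        stringsAsFactors = FALSE)
  expr <- simulate_expression(gene_ids, pl_expr, n_samples, seed = seed)
  coefs <- setNames(hazard_beta, planted$lnc[1])
  clinical <- simulate_survival(expr, coefs, seed = seed)
  list(interactions = si$interactions, expression = expr,
       clinical = clinical,
       truth = list(planted_pairs = planted, rho = rho,
                    hazard_coefs = coefs))
}
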