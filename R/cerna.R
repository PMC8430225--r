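# ceRNA pair inference: expression filtering, the hypergeometric
# shared-miRNA test and Pearson co-expression calling of significant
# lncRNA-TF pairs.

#' Remove genes with excessive zero expression
#'
#' Drops genes whose fraction of zero-expression samples is strictly greater
#' than `max_zero_fraction` (a gene with exactly the cutoff fraction is
#' retained). Sample set and the order of the surviving genes are unchanged.
#'
#' @param expr Expression matrix (genes x samples).
#' @param max_zero_fraction Proportion in `[0, 1]`; default 0.7.
#' @return The filtered expression matrix.
#' @export
filter_expression <- function(expr, max_zero_fraction = 0.7) {
  validate_expression(expr)
  if (max_zero_fraction < 0 || max_zero_fraction > 1)
    lnc_validation_error("max_zero_fraction must lie in [0, 1]")
  zf <- rowMeans(expr == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep)) warning("all genes removed by the zero-fraction filter")
  expr[keep, , drop = FALSE]
}

#' Hypergeometric upper-tail p-value for shared miRNA targets
#'
#' Probability of observing at least `r` shared miRNAs between a lncRNA
#' targeting `n` miRNAs and a TF targeting `t` miRNAs, out of a universe of
#' `m` miRNAs:
#' \deqn{p = 1 - \sum_{i=0}^{r-1} \frac{\binom{t}{i}\binom{m-t}{n-i}}{\binom{m}{n}}}
#' The upper tail is summed directly in log space (via `lchoose`), so the
#' computation is stable for universes of 1e5 miRNAs and more; terms with
#' `n - i > m - t` contribute zero.
#'
#' @param m Size of the miRNA universe.
#' @param n Number of miRNAs interacting with the lncRNA (`n <= m`).
#' @param t Number of miRNAs interacting with the TF (`t <= m`).
#' @param r Observed number of shared miRNAs (`0 <= r <= min(n, t)`).
#' @return P(X >= r) for hypergeometric X; all arguments may be vectors of a
#'   common length.
#' @export
#' @examples
#' hypergeom_pvalue(4, 2, 2, 2)  # 1/6
hypergeom_pvalue <- function(m, n, t, r) {
  k <- max(length(m), length(n), length(t), length(r))
  m <- rep_len(m, k); n <- rep_len(n, k); t <- rep_len(t, k); r <- rep_len(r, k)
  if (any(m < 0) || any(n < 0) || any(t < 0) || any(r < 0) ||
      any(n > m) || any(t > m) || any(r > pmin(n, t)))
    lnc_stop("require 0 <= n, t <= m and 0 <= r <= min(n, t)",
             "lncnet_domain_error")
  vapply(seq_len(k), function(j) {
    if (r[j] == 0) return(1)
    i <- r[j]:min(n[j], t[j])
    lt <- lchoose(t[j], i) + lchoose(m[j] - t[j], n[j] - i) -
      lchoose(m[j], n[j])
    min(1, sum(exp(lt)))
  }, numeric(1))
}

#' Pearson correlation with exact t-test p-value
#'
#' Sample Pearson coefficient with the standard two-sided p-value from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n_obs`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) lnc_validation_error("x and y differ in length")
  n <- length(x)
  if (n < 3) lnc_validation_error("need >= 3 paired observations")
  if (anyNA(x) || anyNA(y)) lnc_validation_error("missing values not allowed")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    lnc_stop("zero-variance input", "lncnet_degenerate_input")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tv), df = n - 2)
  }
  list(r = r, p = p, n_obs = n)
}

# Internal: vectorized two-sided p for a matrix of Pearson r at n samples.
pearson_p_matrix <- function(r, n) {
  p <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  ok <- abs(r) < 1
  tv <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(tv), df = n - 2)
  p
}

#' Call significant lncRNA-TF ceRNA pairs
#'
#' For every (lncRNA, TF) pair present in both the interaction set and the
#' expression matrix, computes the shared-miRNA count `r_shared`, its
#' hypergeometric upper-tail p-value, the Pearson correlation across samples
#' and its t-test p-value. A pair is significant when
#' `hyper_p < hyper_p_cutoff` and `pcc > pcc_cutoff` (signed: strong
#' negative co-expression does not qualify) and `pcc_p < pcc_p_cutoff`.
#' A Benjamini-Hochberg q-value over the hypergeometric p-values is attached
#' for information only; the significance call uses the raw thresholds.
#' Genes with constant expression are skipped with a logged reason.
#'
#' @param interactions An [interaction_set()].
#' @param expr Expression matrix covering the lncRNAs and TFs (typically
#'   after [filter_expression()]).
#' @param config An [default_config()] list.
#' @return data.frame with columns lnc_id, tf_id, r_shared, hyper_p, pcc,
#'   pcc_p, bh_q, significant, sorted by (hyper_p, -pcc, lnc_id, tf_id).
#' @export
call_cerna_pairs <- function(interactions, expr, config = default_config()) {
  stopifnot(inherits(interactions, "interaction_set"))
  m <- length(interactions$mirna_ids)
  if (m == 0) lnc_validation_error("empty miRNA universe")
  cls <- interactions$gene_class
  lnc_all <- names(cls)[cls == "lncRNA"]
  tf_all <- names(cls)[cls == "TF"]
  if (!length(lnc_all) || !length(tf_all))
    lnc_validation_error("interaction set must contain both lncRNAs and TFs")

  keep <- rownames(expr)
  sds <- apply(expr, 1, stats::sd)
  const <- keep[sds == 0]
  if (length(const))
    lnc_log("skipping ", length(const), " constant-expression gene(s)")
  usable <- setdiff(keep, const)
  lnc <- intersect(lnc_all, usable)
  tf <- intersect(tf_all, usable)
  skipped <- length(setdiff(c(lnc_all, tf_all), c(lnc, tf)))
  if (skipped) lnc_log(skipped, " gene(s) lack usable expression; pairs skipped")
  if (!length(lnc) || !length(tf))
    lnc_validation_error("no lncRNA/TF with usable expression")

  # shared-miRNA counts via a binary membership matrix
  memb <- function(genes) {
    mm <- matrix(FALSE, length(genes), m,
                 dimnames = list(genes, interactions$mirna_ids))
    for (g in genes) mm[g, interactions$targets_of[[g]]] <- TRUE
    mm
  }
  Ml <- memb(lnc)
  Mt <- memb(tf)
  r_shared <- Ml %*% t(Mt)                       # |lnc| x |tf|
  n_l <- rowSums(Ml)
  t_t <- rowSums(Mt)

  pcc <- cor(t(expr[lnc, , drop = FALSE]), t(expr[tf, , drop = FALSE]))
  pcc_p <- pearson_p_matrix(pcc, ncol(expr))

  df <- data.frame(
    lnc_id = rep(lnc, times = length(tf)),
    tf_id = rep(tf, each = length(lnc)),
    r_shared = as.vector(r_shared),
    n_lnc = rep(unname(n_l), times = length(tf)),
    t_tf = rep(unname(t_t), each = length(lnc)),
    pcc = as.vector(pcc),
    pcc_p = as.vector(pcc_p),
    stringsAsFactors = FALSE)
  df$hyper_p <- hypergeom_pvalue(m, df$n_lnc, df$t_tf, df$r_shared)
  df$bh_q <- p.adjust(df$hyper_p, method = "BH")
  df$significant <- df$hyper_p < config$hyper_p_cutoff &
    df$pcc > config$pcc_cutoff & df$pcc_p < config$pcc_p_cutoff
  df <- df[order(df$hyper_p, -df$pcc, df$lnc_id, df$tf_id), ]
  rownames(df) <- NULL
  df[, c("lnc_id", "tf_id", "r_shared", "hyper_p", "pcc", "pcc_p", "bh_q",
         "significant")]
}
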