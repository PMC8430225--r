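# Shared fixtures built in code at test time.

# Small typed graph from an edge list given as a two-column matrix of ids.
toy_network <- function(edges, types = NULL) {
  if (nrow(edges) == 0) {
    return(gene_network(data.frame(source = character(0),
                                   target = character(0),
                                   edge_type = character(0)),
                        setNames(character(0), character(0))))
  }
  df <- data.frame(source = edges[, 1], target = edges[, 2],
                   edge_type = "ceRNA", stringsAsFactors = FALSE)
  ids <- unique(c(df$source, df$target))
  if (is.null(types)) types <- setNames(rep("TF", length(ids)), ids)
  gene_network(df, types)
}

# Complete graph on the given ids.
toy_clique <- function(ids) {
  toy_network(t(utils::combn(ids, 2)))
}

# Exhaustive hypergeometric upper-tail oracle by direct pmf summation.
hyper_oracle <- function(m, n, t, r) {
  if (r == 0) return(1)
  i <- r:min(n, t)
  sum(choose(t, i) * choose(m - t, n - i)) / choose(m, n)
}

# A sharp PWM: dominant base per column with the given count, 1 elsewhere.
sharp_pwm <- function(width, dom_count = 200, name = "TFX", seed = 2,
                      pseudocount = 0.1) {
  set.seed(seed)
  dom <- sample(1:4, width, replace = TRUE)
  cts <- matrix(1, width, 4)
  cts[cbind(seq_len(width), dom)] <- dom_count
  pwm_from_counts(cts, name, pseudocount = pseudocount)
}

# Graph whose degree histogram is EXACTLY proportional to k^-2.5 at
# k in {1, 4, 16, 64}: counts 32768/k^2.5 = (32768, 1024, 32, 1) are
# integers. Realized with disjoint stars (centre degree k, leaves degree 1)
# topped up with disjoint edges to reach the exact degree-1 count.
powerlaw_fixture <- function() {
  mk_star <- function(centre, k)
    cbind(centre, paste0(centre, "L", seq_len(k)))
  edges <- do.call(rbind, c(
    list(mk_star("c64", 64)),
    lapply(1:32, function(i) mk_star(paste0("c16_", i), 16)),
    lapply(1:1024, function(i) mk_star(paste0("c4_", i), 4))))
  n_leaves <- 64 + 32 * 16 + 1024 * 4
  n_pair <- (32768 - n_leaves) / 2
  pairs <- cbind(paste0("pA", seq_len(n_pair)), paste0("pB", seq_len(n_pair)))
  toy_network(rbind(edges, pairs))
}

# Brute-force Breslow partial log-likelihood for one covariate.
breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}
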