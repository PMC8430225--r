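# Univariate Cox fitting, the risk-score model, mean-split stratification,
# Kaplan-Meier estimation, log-rank testing and Mantel-Cox hazard ratios.

#' Univariate Cox regression for one covariate
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson starting from
#' beta = 0 (score tolerance 1e-8, at most 50 iterations, via the survival
#' package); the standard error comes from the observed information and the
#' p-value from a two-sided Wald z test.
#'
#' @param x Covariate vector (e.g. one gene's expression across patients).
#' @param time Follow-up times (>= 0).
#' @param event Event indicators (1 = death, 0 = censored).
#' @return List of class `lncnet_coxfit`: beta, se, hr = exp(beta), p,
#'   n_events, converged.
#' @export
cox_univariate <- function(x, time, event) {
  ok <- is.finite(x) & is.finite(time) & !is.na(event)
  if (any(!ok)) {
    lnc_log("dropping ", sum(!ok), " sample(s) with missing time/event/covariate")
    x <- x[ok]; time <- time[ok]; event <- event[ok]
  }
  if (sum(event) < 2)
    lnc_stop("need >= 2 observed events", "lncnet_degenerate_input")
  if (stats::var(x) == 0)
    lnc_stop("constant covariate", "lncnet_degenerate_input")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- beta / se
  structure(list(beta = beta, se = se, hr = exp(beta),
                 p = 2 * stats::pnorm(-abs(z)), n_events = sum(event),
                 converged = converged),
            class = "lncnet_coxfit")
}

#' @export
print.lncnet_coxfit <- function(x, ...) {
  cat(sprintf("Cox fit: beta=%.4f (se %.4f), HR=%.3f, p=%.3g, events=%d%s\n",
              x$beta, x$se, x$hr, x$p, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Build a multi-gene risk model from univariate Cox coefficients
#'
#' Fits a univariate Cox model per signature gene; the per-patient risk
#' score is the coefficient-weighted sum of expression,
#' `RiskScore = sum_i r_i Exp(i)`, and the stratification threshold is the
#' mean risk score across patients.
#'
#' @param expr Expression matrix (genes x samples).
#' @param clinical Clinical table (sample_id, time, event) matching the
#'   expression samples.
#' @param gene_ids Signature genes (must be rows of `expr`).
#' @return List of class `lncnet_risk_model`: gene_ids, coefs, threshold,
#'   fits.
#' @export
build_risk_model <- function(expr, clinical, gene_ids) {
  missing_g <- setdiff(gene_ids, rownames(expr))
  if (length(missing_g))
    lnc_validation_error(paste0("genes absent from expression: ",
                                paste(head(missing_g, 5), collapse = ", ")))
  idx <- match(clinical$sample_id, colnames(expr))
  if (anyNA(idx))
    lnc_validation_error("clinical samples missing from expression matrix")
  fits <- lapply(gene_ids, function(g)
    cox_univariate(expr[g, idx], clinical$time, clinical$event))
  coefs <- vapply(fits, `[[`, numeric(1), "beta")
  model <- structure(list(gene_ids = gene_ids, coefs = coefs,
                          threshold = NA_real_,
                          fits = setNames(fits, gene_ids)),
                     class = "lncnet_risk_model")
  scores <- risk_score(expr[, idx, drop = FALSE], model)
  model$threshold <- mean(scores)
  model
}

#' Per-sample risk scores
#'
#' `score(sample) = sum_i r_i * Exp(i, sample)` over the model's signature
#' genes.
#'
#' @param expr Expression matrix containing all model genes.
#' @param model An `lncnet_risk_model` (or list with gene_ids and coefs).
#' @return Named numeric vector of scores (one per sample/column).
#' @export
risk_score <- function(expr, model) {
  missing_g <- setdiff(model$gene_ids, rownames(expr))
  if (length(missing_g))
    lnc_validation_error(paste0("model genes absent from expression: ",
                                paste(missing_g, collapse = ", ")))
  sub <- expr[model$gene_ids, , drop = FALSE]
  setNames(as.vector(crossprod(sub, model$coefs)), colnames(expr))
}

#' Mean-split stratification into high / low groups
#'
#' `high` when the value is strictly greater than the mean, `low` otherwise
#' (the value == mean boundary maps to `low`). All-equal input yields all
#' `low` with a warning.
#'
#' @param values Numeric vector (>= 2 samples).
#' @return Character vector of labels ("high"/"low"), names preserved.
#' @export
stratify_by_mean <- function(values) {
  if (length(values) < 2) lnc_validation_error("need >= 2 samples to stratify")
  mu <- mean(values)
  lab <- ifelse(values > mu, "high", "low")
  if (all(lab == "low"))
    warning("degenerate split: no sample above the mean")
  if (!is.null(names(values))) names(lab) <- names(values)
  lab
}

#' Kaplan-Meier curves, log-rank test and Mantel-Cox hazard ratio
#'
#' Compares two patient groups: product-limit Kaplan-Meier curves per group,
#' the log-rank chi-square with its df = 1 p-value, and the Mantel-Cox
#' hazard ratio `(O1/E1) / (O2/E2)` with the "high" (or "enriched") label as
#' group 1. If one group has zero events, the HR is not estimable (NA); the
#' chi-square is still computed.
#'
#' @param groups Two-level label vector per sample.
#' @param time Follow-up times.
#' @param event Event indicators (1 = death, 0 = censored).
#' @return List of class `lncnet_surv_comparison`: chi2, p, hr, group1,
#'   obs/exp per group, km_curves (data.frame time, surv, group).
#' @export
km_logrank <- function(groups, time, event) {
  ok <- !is.na(groups) & is.finite(time) & !is.na(event)
  if (any(!ok)) {
    lnc_log("dropping ", sum(!ok), " sample(s) with missing data")
    groups <- groups[ok]; time <- time[ok]; event <- event[ok]
  }
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2)
    lnc_validation_error("km_logrank needs exactly two groups")
  g1 <- if ("high" %in% lev) "high" else if ("enriched" %in% lev) "enriched"
        else lev[1]
  g2 <- setdiff(lev, g1)
  f <- factor(as.character(groups), levels = c(g1, g2))
  sd <- survival::survdiff(survival::Surv(time, event) ~ f)
  chi2 <- unname(sd$chisq)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  O <- sd$obs; E <- sd$exp
  hr <- if (any(O == 0) || any(E == 0)) NA_real_ else
    (O[1] / E[1]) / (O[2] / E[2])
  sf <- survival::survfit(survival::Surv(time, event) ~ f)
  strata_lab <- rep(sub("^f=", "", names(sf$strata)), sf$strata)
  km <- data.frame(time = sf$time, surv = sf$surv, group = strata_lab,
                   stringsAsFactors = FALSE)
  structure(list(chi2 = chi2, p = p, hr = unname(hr), group1 = g1,
                 obs = setNames(as.vector(O), c(g1, g2)),
                 exp = setNames(as.vector(E), c(g1, g2)),
                 km_curves = km),
            class = "lncnet_surv_comparison")
}

#' @export
print.lncnet_surv_comparison <- function(x, ...) {
  cat(sprintf(
    "Log-rank: chi2=%.4f p=%.4g; Mantel-Cox HR (%s vs other)=%s\n",
    x$chi2, x$p, x$group1,
    if (is.na(x$hr)) "not estimable" else sprintf("%.3f", x$hr)))
  invisible(x)
}

#' Risk-score survival analysis for a gene signature
#'
#' Convenience wrapper chaining [build_risk_model()], [risk_score()],
#' [stratify_by_mean()] and [km_logrank()].
#'
#' @inheritParams build_risk_model
#' @return List: model, scores, labels, comparison.
#' @export
risk_survival_analysis <- function(expr, clinical, gene_ids) {
  model <- build_risk_model(expr, clinical, gene_ids)
  idx <- match(clinical$sample_id, colnames(expr))
  scores <- risk_score(expr[, idx, drop = FALSE], model)
  labels <- stratify_by_mean(scores)
  comparison <- km_logrank(labels, clinical$time, clinical$event)
  list(model = model, scores = scores, labels = labels,
       comparison = comparison)
}
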