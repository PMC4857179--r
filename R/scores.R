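# Model-selection metrics: BIC with effective-sample-size corrections, AIC,
# and mixed-model likelihood ratio tests.

metric_labels <- c("BIC_M", "BIC_J", "BIC_Y", "BIC_C", "AIC_M", "LRT_M",
                   "BIC_F", "AIC_F", "LRT_F")

#' Configure a model-selection metric
#'
#' The metric determines both which node likelihood is used (integrated
#' mixed-model likelihood for the `_M/_J/_Y/_C` variants; the naive IID
#' likelihood for the `_F` variants) and the penalty or test threshold:
#'
#' * `BIC_M` / `BIC_F`: `-2 loglik + p log(n_e)` with `n_e` the full sample
#'   size (number of events for survival nodes);
#' * `BIC_J`: Jones' effective sample size `1' C^{-1} 1`;
#' * `BIC_Y`: family-exchangeable effective sample size (Yang-style);
#' * `BIC_C`: number of clusters (most liberal correction);
#' * `AIC_M` / `AIC_F`: `-2 loglik + 2 p`;
#' * `LRT_M` / `LRT_F`: forward-selection by likelihood ratio test at level
#'   `alpha`, optionally Bonferroni-adjusted per node.
#'
#' @param metric one of `r paste(metric_labels, collapse = ", ")`.
#' @param alpha test level for LRT metrics (default 0.05).
#' @param bonferroni divide `alpha` by the number of level-1 candidate parents
#'   of the node (application mode); the adjusted level is held fixed across
#'   levels.
#' @return A `score_config` object.
#' @export
score_config <- function(metric, alpha = 0.05, bonferroni = FALSE) {
  abort_if(!is.character(metric) || length(metric) != 1L ||
             !metric %in% metric_labels, sprintf(
    "unknown metric '%s' (valid: %s)", paste(metric, collapse = ","),
    paste(metric_labels, collapse = ", ")))
  structure(
    list(metric = metric,
         type = if (grepl("^LRT", metric)) "LRT"
                else if (grepl("^AIC", metric)) "AIC" else "BIC",
         mixed = !grepl("_F$", metric),
         alpha = alpha, bonferroni = bonferroni),
    class = "score_config"
  )
}

as_score_config <- function(x) {
  if (inherits(x, "score_config")) x else score_config(x)
}

#' @export
print.score_config <- function(x, ...) {
  cat(sprintf("<score_config> %s%s\n", x$metric,
              if (x$type == "LRT") sprintf(" (alpha=%g%s)", x$alpha,
                if (x$bonferroni) ", Bonferroni" else "") else ""))
  invisible(x)
}

#' Effective sample sizes for correlated data
#'
#' `effective_n_jones()` computes `n_e = 1' C^{-1} 1`, where `C` is the
#' correlation matrix of `V = gamma2 * A + sigma2 * I`, evaluated per cluster
#' block and summed. `effective_n_yang()` computes a family-based
#' exchangeable-equivalent size `sum_f n_f^2 / (1' C_f 1)` with
#' `C_f = h2 * A_f + (1 - h2) I`; by Cauchy-Schwarz it never exceeds Jones'
#' value at the same `h2`, and the default `h2 = 1` uses the full relatedness
#' structure. `effective_n_cluster()` returns the number of clusters, the most
#' liberal correction.
#'
#' @param corr a [correlation_model].
#' @param gamma2,sigma2 variance components of the fitted node model.
#' @param rho within-cluster correlation (exchangeable/AR1 kinds).
#' @return Effective sample size (scalar).
#' @export
effective_n_jones <- function(corr, gamma2, sigma2, rho = NULL) {
  abort_if(sigma2 <= 0 && gamma2 <= 0, "need a positive-definite covariance")
  if (corr$kind == "iid" || gamma2 <= 0) return(corr$n)
  u1 <- structure_u1(corr, rho)
  total <- 0
  for (b in u1) {
    v <- sigma2 + gamma2 * b$s
    abort_if(any(v <= 0), "singular implied correlation matrix")
    # blocks have unit diagonal after scaling: diag(V) = gamma2 + sigma2
    total <- total + (gamma2 + sigma2) * sum(b$u1^2 / v)
  }
  total
}

#' @param kin a `kinship_matrix` (or kinship-kind [correlation_model]).
#' @param h2 heritability at which the implied family correlation is taken;
#'   the default 1 uses the full relatedness structure.
#' @rdname effective_n_jones
#' @export
effective_n_yang <- function(kin, h2 = 1) {
  abort_if(h2 < 0 || h2 > 1, "h2 must be in [0, 1]")
  if (inherits(kin, "correlation_model")) {
    abort_if(kin$kind != "kinship",
             "effective_n_yang needs family (kinship) structure")
    kin <- kin$kinship
  }
  stopifnot(inherits(kin, "kinship_matrix"))
  sum(vapply(kin$blocks, function(A) {
    m <- nrow(A)
    m^2 / (h2 * sum(A) + (1 - h2) * m)
  }, 0))
}

#' @rdname effective_n_jones
#' @export
effective_n_cluster <- function(corr) {
  stopifnot(inherits(corr, "correlation_model"))
  n_clusters(corr)
}

# Effective sample size of a fitted model under a metric. Survival nodes use
# the number of events for the full-sample-size BIC variants.
metric_effective_n <- function(model, cfg, corr) {
  switch(cfg$metric,
    BIC_M = , BIC_F =
      if (identical(model$family, "cox")) model$d else model$n,
    BIC_J = {
      abort_if(is.null(corr), "BIC_J needs the correlation model")
      if (identical(model$family, "cox"))
        effective_n_jones(corr, model$gamma2, 1, rho = model$rho)
      else effective_n_jones(corr, model$gamma2, model$sigma2,
                             rho = model$rho)
    },
    BIC_Y = {
      abort_if(is.null(corr) || corr$kind != "kinship",
               "BIC_Y needs family (kinship) structure")
      effective_n_yang(corr)
    },
    BIC_C = {
      abort_if(is.null(corr), "BIC_C needs the correlation model")
      effective_n_cluster(corr)
    },
    stop(sprintf("metric %s has no effective sample size", cfg$metric),
         call. = FALSE)
  )
}

#' Score a fitted node model under a metric
#'
#' BIC variants return `-2 loglik + p_eff log(n_e)`; AIC returns
#' `-2 loglik + 2 p_eff`. Lower is better. The naive (`_F`) metrics must be
#' given the IID fit, the others the integrated-likelihood fit.
#'
#' @param model a fitted node model (`gaussian_mixed_model` or
#'   `cox_frailty_model`).
#' @param cfg a [score_config] (or metric name).
#' @param corr the [correlation_model] (needed by the effective-sample-size
#'   variants).
#' @return The score (scalar; lower is better).
#' @export
score_model <- function(model, cfg, corr = NULL) {
  cfg <- as_score_config(cfg)
  abort_if(cfg$type == "LRT",
           "LRT metrics are threshold rules; use lrt_pvalue()")
  if (cfg$type == "AIC") return(-2 * model$loglik + 2 * model$p_eff)
  ne <- metric_effective_n(model, cfg, corr)
  -2 * model$loglik + model$p_eff * log(ne)
}

#' Likelihood ratio test between nested node models
#'
#' `p = P(chi^2_df > 2 (loglik_full - loglik_reduced))` with `df` the
#' difference in fixed-effect counts. Variance components are re-estimated
#' under both models (they are present under both hypotheses, so the usual
#' chi-square reference applies to the fixed-effect test).
#'
#' @param full,reduced fitted node models; `reduced`'s fixed effects must be
#'   nested in `full`'s.
#' @param tol tolerance for a negative statistic before it is treated as an
#'   optimizer failure.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt_pvalue <- function(full, reduced, tol = 1e-3) {
  df <- length(full$beta) - length(reduced$beta)
  abort_if(df < 1, "full model must have more fixed effects than reduced")
  stat <- 2 * (full$loglik - reduced$loglik)
  abort_if(is.finite(stat) && stat < -tol, sprintf(
    "negative LRT statistic (%.4g): optimizer failure in nested fits", stat))
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
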