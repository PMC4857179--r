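# Shared reduced-replicate study runs used by several acceptance tests;
# computed once per session.

.study_cache <- new.env(parent = emptyenv())

cached_gaussian_null <- function() {
  if (is.null(.study_cache$gauss)) {
    sc <- simulation_scenario("gaussian", gamma2 = 1, sigma2 = 1,
                              n_families = 582, reps = 200, seed = 101)
    .study_cache$gauss <- run_null_study(
      sc, metrics = c("BIC_M", "BIC_J", "BIC_Y", "BIC_C", "AIC_M", "LRT_M",
                      "BIC_F", "AIC_F", "LRT_F"))
  }
  .study_cache$gauss
}

cached_survival_null <- function() {
  if (is.null(.study_cache$surv)) {
    sc <- simulation_scenario("survival", gamma2 = 1, n_families = 30,
                              reps = 60, seed = 103)
    .study_cache$surv <- run_null_study(sc, metrics = c("LRT_M", "LRT_F"))
  }
  .study_cache$surv
}

study_row <- function(res, metric) res$table[res$table$metric == metric, ]

# Standard error of the difference between two metrics' false positive
# counts on shared replicates (paired by replicate).
paired_fpr_diff <- function(res, m1, m2) {
  d <- res$fp[, m1] / mean(res$tests[, m1]) -
    res$fp[, m2] / mean(res$tests[, m2])
  list(diff = mean(d), se = stats::sd(d) / sqrt(nrow(res$fp)))
}
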