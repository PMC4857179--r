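# Orchestration of the simulation studies: null (Type-I error) studies, power
# studies at matched empirical levels, and the small-network comparison of
# IID versus clustered sampling.

#' Define a simulation scenario
#'
#' Describes one cell of the simulation studies: a family cohort, a trait
#' model, and the covariate layout. With `sigma2 = 1`, genetic variances
#' `gamma2 = 1/3, 1, 3` give heritabilities 0.25, 0.5, 0.75.
#'
#' @param trait `"gaussian"` or `"survival"`.
#' @param gamma2 genetic (frailty) variance.
#' @param sigma2 error variance (Gaussian trait).
#' @param n_families number of template families.
#' @param template family template (see [make_synthetic_cohort()]).
#' @param n_null number of null SNP covariates gene-dropped per replicate.
#' @param maf_min minimum sample minor allele frequency of the SNPs.
#' @param effect_tier `NULL` for a null study, or `"weak"`, `"moderate"`,
#'   `"strong"` for 3 true-effect covariates of that tier.
#' @param effect_rho pairwise correlation of the true-effect covariates.
#' @param censoring censoring configuration for survival traits (see
#'   [simulate_survival_trait()]).
#' @param reps number of simulation replicates.
#' @param seed master seed; per-replicate seeds are derived by a counter
#'   scheme.
#' @return A `simulation_scenario` object.
#' @export
simulation_scenario <- function(trait = c("gaussian", "survival"),
                                gamma2 = 1, sigma2 = 1, n_families = 582,
                                template = "llfs8", n_null = 10,
                                maf_min = 0.05, effect_tier = NULL,
                                effect_rho = 0,
                                censoring = list(type = "uniform", rate = 0.2),
                                reps = 1000, seed = 1) {
  trait <- match.arg(trait)
  abort_if(reps < 1, "reps must be >= 1")
  abort_if(gamma2 < 0 || sigma2 <= 0, "invalid variance components")
  structure(
    list(trait = trait, gamma2 = gamma2, sigma2 = sigma2,
         n_families = n_families, template = template, n_null = n_null,
         maf_min = maf_min, effect_tier = effect_tier,
         effect_rho = effect_rho, censoring = censoring,
         reps = as.integer(reps), seed = seed,
         h2 = gamma2 / (gamma2 + sigma2)),
    class = "simulation_scenario"
  )
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "<simulation_scenario> %s trait, h2=%.2f, %d families (%s), %d null SNPs%s, %d reps\n",
    x$trait, x$h2, x$n_families, x$template, x$n_null,
    if (!is.null(x$effect_tier)) sprintf(", 3 %s effects", x$effect_tier)
    else "", x$reps))
  invisible(x)
}

scenario_cohort <- function(scenario) {
  ped <- make_synthetic_cohort(scenario$n_families, scenario$template)
  kin <- kinship_from_pedigree(ped)
  list(ped = ped, kin = kin,
       corr = correlation_model("kinship", kinship = kin))
}

# Simulate one replicate's data set (trait + covariates) for a scenario.
simulate_replicate <- function(scenario, cohort, rep_seed) {
  with_seed(rep_seed, {
    G <- gene_drop_snps(cohort$ped, scenario$n_null, scenario$maf_min)
    n <- nrow(G)
    eff <- NULL
    lin <- 0
    if (!is.null(scenario$effect_tier)) {
      eff <- simulate_effect_covariates(
        n, tier = scenario$effect_tier, rho = scenario$effect_rho,
        corr = cohort$corr, gamma2 = scenario$gamma2,
        sigma2 = scenario$sigma2)
      lin <- as.numeric(eff$X %*% eff$beta)
    }
    if (scenario$trait == "gaussian") {
      y <- lin + simulate_gaussian_trait(cohort$corr, scenario$gamma2,
                                         scenario$sigma2)
      dat <- data.frame(y = y)
    } else {
      sv <- if (is.null(eff))
        simulate_survival_trait(cohort$corr, scenario$gamma2,
                                censoring = scenario$censoring)
      else
        simulate_survival_trait(cohort$corr, scenario$gamma2,
                                beta = eff$beta, X = eff$X,
                                censoring = scenario$censoring)
      dat <- data.frame(time = sv$time, status = sv$status)
    }
    if (!is.null(eff)) dat <- cbind(dat, as.data.frame(eff$X))
    dat <- cbind(dat, as.data.frame(G))
    list(data = dat,
         true_cols = if (!is.null(eff)) colnames(eff$X) else character(0),
         null_cols = colnames(G))
  })
}

scenario_node <- function(scenario, candidates) {
  if (scenario$trait == "gaussian")
    node_spec("y", "gaussian", candidates = candidates)
  else
    node_spec("surv", "survival", candidates = candidates,
              time = "time", event = "status")
}

# Per-level false-positive and test counts from a forward-search trace.
trace_level_counts <- function(trace, max_level = 5L) {
  lev <- pmin(trace$level, max_level)
  fp <- tests <- numeric(max_level)
  for (l in seq_len(max_level)) {
    fp[l] <- sum(trace$pass[lev == l])
    tests[l] <- sum(lev == l)
  }
  list(fp = fp, tests = tests)
}

#' Null (Type-I error) study of the forward-search selection metrics
#'
#' Per replicate, a trait with no true covariate effects is simulated on the
#' scenario cohort together with gene-dropped null SNPs; each metric's
#' forward search is run on the same data set. Every test that rejects (LRT
#' p-value below alpha, or a score improvement for BIC/AIC) is a false
#' positive at its search level. FPR is the total number of false positives
#' over the total number of tests; FWER is the fraction of replicates with at
#' least one false positive.
#'
#' @param scenario a [simulation_scenario] with `effect_tier = NULL`.
#' @param metrics character vector of metric names or list of
#'   [score_config]s.
#' @param progress print a line every 100 replicates.
#' @return A `study_result`: list with `table` (per-metric level counts,
#'   total tests, FPR, FWER, and Monte-Carlo standard errors), the
#'   per-replicate count matrices, and the scenario.
#' @export
run_null_study <- function(scenario, metrics = c("LRT_M", "LRT_F"),
                           progress = FALSE) {
  abort_if(!is.null(scenario$effect_tier),
           "null study requires a scenario without true effects")
  cfgs <- lapply(metrics, as_score_config)
  labels <- vapply(cfgs, `[[`, "", "metric")
  cohort <- scenario_cohort(scenario)
  reps <- scenario$reps
  fp <- tests <- matrix(0L, reps, length(cfgs),
                        dimnames = list(NULL, labels))
  any_fp <- matrix(FALSE, reps, length(cfgs), dimnames = list(NULL, labels))
  level_fp <- level_tests <- matrix(0, length(cfgs), 5L,
                                    dimnames = list(labels, NULL))
  for (r in seq_len(reps)) {
    sim <- simulate_replicate(scenario, cohort, derive_seed(scenario$seed, r))
    node <- scenario_node(scenario, sim$null_cols)
    fitter <- node_fitter(node, sim$data, cohort$corr, sim$null_cols)
    for (m in seq_along(cfgs)) {
      sel <- forward_select_node(node, sim$data, cohort$corr, cfgs[[m]],
                                 candidates = sim$null_cols, fitter = fitter)
      lc <- trace_level_counts(sel$trace)
      level_fp[m, ] <- level_fp[m, ] + lc$fp
      level_tests[m, ] <- level_tests[m, ] + lc$tests
      fp[r, m] <- sum(lc$fp)
      tests[r, m] <- sum(lc$tests)
      any_fp[r, m] <- fp[r, m] > 0L
    }
    if (progress && r %% 100L == 0L)
      message(sprintf("  null study: replicate %d/%d", r, reps))
  }
  new_study_result(scenario, labels, fp, tests, any_fp, level_fp, level_tests)
}

new_study_result <- function(scenario, labels, fp, tests, any_fp,
                             level_fp, level_tests) {
  reps <- nrow(fp)
  fpr <- colSums(fp) / colSums(tests)
  fwer <- colMeans(any_fp)
  se_fpr <- vapply(seq_along(labels), function(m) {
    resid <- fp[, m] - fpr[m] * tests[, m]
    sqrt(sum(resid^2) / max(1, reps - 1) / reps) / mean(tests[, m])
  }, 0)
  tab <- data.frame(
    metric = labels,
    fp_l1 = level_fp[, 1L], fp_l2 = level_fp[, 2L], fp_l3 = level_fp[, 3L],
    fp_l4 = level_fp[, 4L], fp_l5plus = level_fp[, 5L],
    tot_test = rowSums(level_tests),
    fpr = fpr, fwer = fwer,
    se_fpr = se_fpr, se_fwer = sqrt(fwer * (1 - fwer) / reps),
    row.names = NULL
  )
  structure(list(table = tab, fp = fp, tests = tests, any_fp = any_fp,
                 reps = reps, scenario = scenario),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d replicates\n", x$reps))
  print(x$table, digits = 4)
  invisible(x)
}

#' Power study at matched empirical levels
#'
#' Per replicate, the trait is generated with 3 true-effect covariates of the
#' scenario's tier plus the null SNPs, and each metric's forward search runs
#' over all candidates. Power is the probability of detecting all three true
#' covariates in a run. To compare an LRT against a BIC variant at equal
#' false positive rates, pass the BIC's empirical FPR from a null study as
#' `matched_alpha`; it replaces `alpha` in all LRT configs.
#'
#' @param scenario a [simulation_scenario] with a non-null `effect_tier`.
#' @param metrics metric names or [score_config]s.
#' @param matched_alpha optional level substituted into LRT metrics.
#' @param progress print a line every 100 replicates.
#' @return list with `power` (named vector), `se`, `detected` (reps x metric
#'   matrix of counts of true covariates found), and the scenario.
#' @export
run_power_study <- function(scenario, metrics = c("BIC_M", "LRT_M"),
                            matched_alpha = NULL, progress = FALSE) {
  abort_if(is.null(scenario$effect_tier),
           "power study requires a scenario with true effects")
  cfgs <- lapply(metrics, as_score_config)
  if (!is.null(matched_alpha)) {
    cfgs <- lapply(cfgs, function(cfg) {
      if (cfg$type == "LRT") cfg$alpha <- matched_alpha
      cfg
    })
  }
  labels <- vapply(cfgs, `[[`, "", "metric")
  cohort <- scenario_cohort(scenario)
  reps <- scenario$reps
  detected <- matrix(0L, reps, length(cfgs), dimnames = list(NULL, labels))
  for (r in seq_len(reps)) {
    sim <- simulate_replicate(scenario, cohort, derive_seed(scenario$seed, r))
    cands <- c(sim$true_cols, sim$null_cols)
    node <- scenario_node(scenario, cands)
    fitter <- node_fitter(node, sim$data, cohort$corr, cands)
    for (m in seq_along(cfgs)) {
      sel <- forward_select_node(node, sim$data, cohort$corr, cfgs[[m]],
                                 candidates = cands, fitter = fitter)
      detected[r, m] <- sum(sim$true_cols %in% sel$parents)
    }
    if (progress && r %% 100L == 0L)
      message(sprintf("  power study: replicate %d/%d", r, reps))
  }
  success <- detected == 3L
  power <- colMeans(success)
  list(power = power, se = sqrt(power * (1 - power) / reps),
       detected = detected, reps = reps, scenario = scenario)
}

# Fixed 5-node Gaussian benchmark network: Y1 -> Y3 <- Y2, Y3 -> Y4 -> Y5.
figure_network <- list(
  nodes = paste0("Y", 1:5),
  parents = list(Y1 = character(0), Y2 = character(0),
                 Y3 = c("Y1", "Y2"), Y4 = "Y3", Y5 = "Y4"),
  beta = 0.5
)

#' IID versus clustered sampling on a small benchmark network
#'
#' Simulates a 5-variable Gaussian network (two roots feeding a collider,
#' followed by a chain) under (a) IID observations and (b) a clustered cohort
#' in which every variable carries a kinship random effect at the scenario
#' heritability, then relearns the structure along the true ordering with the
#' requested metrics. Errors are extra or missing parents relative to the
#' generating network; FPR is errors over tests performed, and FWER the
#' fraction of replicates with at least one error.
#'
#' @param reps replicates per regime.
#' @param seed master seed.
#' @param n_families number of families (clusters) in the clustered regime;
#'   the IID regime uses the same total n.
#' @param metrics metric names or [score_config]s (naive metrics show the
#'   inflation; `LRT_M` shows its repair).
#' @param gamma2 per-node genetic variance in the clustered regime
#'   (`sigma2 = 1`).
#' @param template family template.
#' @return list of `study_result`-like tables per regime plus recovery
#'   counts.
#' @export
run_figure1_study <- function(reps, seed = 1, n_families = 581,
                              metrics = c("BIC_F", "AIC_F", "LRT_F"),
                              gamma2 = 1, template = "llfs8") {
  abort_if(reps < 1, "reps must be >= 1")
  cfgs <- lapply(metrics, as_score_config)
  labels <- vapply(cfgs, `[[`, "", "metric")
  ped <- make_synthetic_cohort(n_families, template)
  kin <- kinship_from_pedigree(ped)
  corr_clu <- correlation_model("kinship", kinship = kin)
  n <- length(kin$ids)
  corr_iid <- correlation_model("iid", n = n)
  net <- figure_network
  out <- list()
  for (regime in c("iid", "clustered")) {
    corr <- if (regime == "iid") corr_iid else corr_clu
    g2 <- if (regime == "iid") 0 else gamma2
    err <- tests <- matrix(0L, reps, length(cfgs),
                           dimnames = list(NULL, labels))
    recovered <- matrix(FALSE, reps, length(cfgs),
                        dimnames = list(NULL, labels))
    for (r in seq_len(reps)) {
      sim <- with_seed(derive_seed(seed + 7e5, r), {
        dat <- list()
        for (nd in net$nodes) {
          base <- simulate_gaussian_trait(corr, g2, 1)
          pa <- net$parents[[nd]]
          dat[[nd]] <- base + if (length(pa) > 0)
            net$beta * Reduce(`+`, dat[pa]) else 0
        }
        as.data.frame(dat)
      })
      fitters <- lapply(stats::setNames(net$nodes, net$nodes), function(nd) {
        k <- match(nd, net$nodes)
        node_fitter(node_spec(nd, "gaussian"), sim, corr,
                    net$nodes[seq_len(k - 1L)])
      })
      for (m in seq_along(cfgs)) {
        ok <- TRUE
        for (k in seq_along(net$nodes)) {
          nd <- net$nodes[k]
          sel <- forward_select_node(
            node_spec(nd, "gaussian"), sim, corr, cfgs[[m]],
            candidates = net$nodes[seq_len(k - 1L)], fitter = fitters[[nd]])
          derr <- length(setdiff(sel$parents, net$parents[[nd]])) +
            length(setdiff(net$parents[[nd]], sel$parents))
          err[r, m] <- err[r, m] + derr
          tests[r, m] <- tests[r, m] + nrow(sel$trace)
          if (derr > 0) ok <- FALSE
        }
        recovered[r, m] <- ok
      }
    }
    out[[regime]] <- data.frame(
      metric = labels,
      recovered = colSums(recovered),
      fpr = colSums(err) / colSums(tests),
      fwer = colMeans(err > 0),
      se_fwer = sqrt(colMeans(err > 0) * (1 - colMeans(err > 0)) / reps),
      row.names = NULL
    )
  }
  out$reps <- reps
  out
}

#' Write a study-result table as TSV
#'
#' @param result a `study_result`.
#' @param path output path.
#' @export
write_study_tsv <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
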