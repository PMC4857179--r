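test_that("gaussian trait generator reproduces the target covariance", {
  kin1 <- kinship_from_pedigree(make_synthetic_cohort(1))
  c1 <- correlation_model("kinship", kinship = kin1)
  set.seed(81)
  draws <- vapply(1:8000, function(i) simulate_gaussian_trait(c1, 1, 1),
                  numeric(8))
  emp <- cov(t(draws))
  dimnames(emp) <- list(kin1$ids, kin1$ids)
  V <- as.matrix(kin1) + diag(8)
  # entrywise within 3 SEs (normal fourth-moment approximation)
  se <- 3 * sqrt((outer(diag(V), diag(V)) + V^2) / 8000)
  expect_true(all(abs(emp - V) < se + 0.02))
  # sib pairs: covariance 2 * k * gamma2 = 0.5
  expect_equal(emp["F0001_S1", "F0001_S2"], 0.5, tolerance = 0.1)
})

test_that("spectral transform reconstructs the target covariance exactly", {
  co <- small_cohort(3)
  Tm <- mixbn:::covariance_transform(co$corr, 1.7, 0.6)
  V <- 1.7 * as.matrix(co$kin) + 0.6 * diag(co$corr$n)
  expect_lt(max(abs(as.matrix(Matrix::tcrossprod(Tm)) - V)), 1e-8)
})

test_that("gaussian generator with gamma2 = 0 is IID", {
  co <- small_cohort(100)
  y <- simulate_gaussian_trait(co$corr, 0, 1, seed = 82)
  Y <- matrix(y, nrow = 8)
  expect_lt(abs(cor(Y[1, ], Y[2, ])), 0.3)
  expect_equal(sd(y), 1, tolerance = 0.15)
})

test_that("generators are deterministic given a seed", {
  co <- small_cohort(3)
  expect_identical(simulate_gaussian_trait(co$corr, 1, 1, seed = 9),
                   simulate_gaussian_trait(co$corr, 1, 1, seed = 9))
  expect_identical(gene_drop_snps(co$ped, 4, 0.05, seed = 9),
                   gene_drop_snps(co$ped, 4, 0.05, seed = 9))
  s1 <- simulate_survival_trait(co$corr, 1, seed = 9)
  s2 <- simulate_survival_trait(co$corr, 1, seed = 9)
  expect_identical(s1$time, s2$time)
})

test_that("baseline survival times are Weibull(2, 2)", {
  n <- 8000
  sd <- simulate_survival_trait(correlation_model("iid", n = n), 0,
                                censoring = list(type = "none"), seed = 83)
  expect_true(all(sd$status == 1))
  ks <- suppressWarnings(
    stats::ks.test(sd$time, function(q) stats::pweibull(q, 2, 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("proportional hazards acts in the right direction", {
  n <- 5000
  set.seed(84)
  x <- rnorm(n)
  sd <- simulate_survival_trait(correlation_model("iid", n = n), 0,
                                beta = 0.8, X = matrix(x),
                                censoring = list(type = "none"), seed = 85)
  expect_lt(cor(x, sd$time, method = "spearman"), -0.2)
})

test_that("censoring fraction is calibrated at the null", {
  co <- small_cohort(400)
  sd <- simulate_survival_trait(co$corr, 0, seed = 86)
  expect_equal(mean(sd$status == 0), 0.2, tolerance = 0.04)
})

test_that("frailty induces positive association of relatives' event times", {
  co <- small_cohort(1500)
  sd <- simulate_survival_trait(co$corr, 1,
                                censoring = list(type = "none"), seed = 87)
  Tm <- matrix(sd$time, nrow = 8)
  tau <- cor(Tm[1, ], Tm[2, ], method = "kendall") # sib pairs
  expect_gt(tau, 0.05)
})

test_that("effect covariates: correlation, tiers, and calibrated power", {
  eff0 <- simulate_effect_covariates(5000, "moderate", rho = 0, seed = 88)
  expect_lt(max(abs(cor(eff0$X)[upper.tri(diag(3))])), 0.05)
  eff5 <- simulate_effect_covariates(5000, "moderate", rho = 0.5, seed = 88)
  expect_equal(mean(cor(eff5$X)[upper.tri(diag(3))]), 0.5, tolerance = 0.05)
  b <- vapply(c("weak", "moderate", "strong"), function(tier)
    simulate_effect_covariates(10, tier, 0, seed = 1)$beta[1], 0)
  expect_true(all(diff(b) > 0))
  expect_error(simulate_effect_covariates(10, "moderate", rho = 1), "rho")
  expect_error(simulate_effect_covariates(10, "huge"), "tier")
})

test_that("marginal power of a calibrated tier matches its definition", {
  co <- small_cohort(582)
  n <- co$corr$n
  b <- calibrate_effect_size(co$corr, 1, 1, target_power = 0.6,
                             alpha = 0.005)
  X0 <- matrix(1, n, 1)
  hits <- vapply(1:120, function(s) {
    with_seed <- mixbn:::with_seed
    with_seed(3000 + s, {
      x <- rnorm(n)
      y <- b * x + simulate_gaussian_trait(co$corr, 1, 1)
      f0 <- fit_gaussian_mixed(y, X0, co$corr)
      f1 <- fit_gaussian_mixed(y, cbind(X0, x), co$corr)
      lrt_pvalue(f1, f0)$p_value < 0.005
    })
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.6), 0.1 + 3 * mc_se(0.6, 120))
})

test_that("repeated-measures generator matches its design", {
  sim0 <- simulate_repeated_measures(3000, 2.75, within_corr = 0,
                                     seed = 89)
  expect_equal(nrow(sim0$data), 3000 * 2.75, tolerance = 0.05)
  sim5 <- simulate_repeated_measures(4000, 3, within_corr = 0.5, seed = 90)
  d <- sim5$data
  first2 <- do.call(rbind, lapply(split(d$y, d$subject), function(v)
    if (length(v) >= 2) v[1:2]))
  expect_equal(cor(first2[, 1], first2[, 2]), 0.5, tolerance = 0.05)
  d0 <- sim0$data
  f2 <- do.call(rbind, lapply(split(d0$y, d0$subject), function(v)
    if (length(v) >= 2) v[1:2]))
  expect_lt(abs(cor(f2[, 1], f2[, 2])), 0.05)
})
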