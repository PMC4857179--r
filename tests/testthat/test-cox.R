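make_surv_fixture <- function(n_families = 8, gamma2 = 1, seed = 41,
                              beta = numeric(0), X = NULL) {
  co <- small_cohort(n_families)
  sd <- simulate_survival_trait(co$corr, gamma2, beta = beta, X = X,
                                seed = seed)
  list(co = co, sd = sd)
}

test_that("penalized partial likelihood reduces to the Cox partial likelihood", {
  fx <- make_surv_fixture()
  n <- fx$co$corr$n
  set.seed(42)
  x <- rnorm(n)
  b <- 0.37
  fit <- survival::coxph(survival::Surv(fx$sd$time, fx$sd$status) ~ x,
                         ties = "breslow", init = b,
                         control = survival::coxph.control(iter.max = 0))
  pen <- penalized_partial_loglik(fx$sd, beta = b, R = numeric(n),
                                  gamma2 = 1, corr = fx$co$corr,
                                  X = matrix(x))
  expect_equal(pen, fit$loglik[2], tolerance = 1e-8)
})

test_that("partial likelihood matches manual risk-set enumeration on n = 3", {
  t3 <- c(2, 1, 3); d3 <- c(1, 1, 1)
  eta <- c(0.2, -0.4, 0.9)
  # ordered events: t=1 (all at risk), t=2 (subjects 1,3), t=3 (subject 3)
  manual <- (eta[2] - log(sum(exp(eta)))) +
    (eta[1] - log(exp(eta[1]) + exp(eta[3]))) +
    (eta[3] - log(exp(eta[3])))
  prep <- mixbn:::cox_prep(t3, d3)
  expect_equal(mixbn:::cox_pl_core(eta[prep$ord], prep)$loglik, manual)
})

test_that("penalized likelihood is invariant to joint subject permutation", {
  fx <- make_surv_fixture(4)
  n <- fx$co$corr$n
  set.seed(43)
  R <- rnorm(n, 0, 0.3)
  v1 <- penalized_partial_loglik(fx$sd, numeric(0), R, 0.8, fx$co$corr)
  fam_order <- rev(levels(fx$co$kin$fam))
  perm <- unlist(lapply(fam_order, function(f) which(fx$co$kin$fam == f)))
  kin2 <- fx$co$kin
  kin2$blocks <- kin2$blocks[fam_order]
  kin2$ids <- kin2$ids[perm]
  kin2$fam <- factor(as.character(kin2$fam)[perm], levels = fam_order)
  sd2 <- survival_data(fx$sd$time[perm], fx$sd$status[perm])
  v2 <- penalized_partial_loglik(sd2, numeric(0), R[perm], 0.8,
                                 correlation_model("kinship", kinship = kin2))
  expect_equal(v2, v1, tolerance = 1e-10)
})

test_that("null-frailty limit recovers the ordinary Cox fit", {
  fx <- make_surv_fixture(10, gamma2 = 0.5, seed = 44)
  n <- fx$co$corr$n
  set.seed(45)
  x <- matrix(rnorm(n))
  sd <- simulate_survival_trait(fx$co$corr, 0.5, beta = 0.5, X = x, seed = 46)
  cph <- survival::coxph(survival::Surv(sd$time, sd$status) ~ x,
                         ties = "breslow")
  lap <- mixbn:::cox_laplace_at(
    mixbn:::cox_context(sd, fx$co$corr, Xall = x),
    mixbn:::cox_context(sd, fx$co$corr, Xall = x)$Xall_s,
    gamma2 = 1e-8, beta = 0, R = numeric(n))
  expect_equal(lap$fit$beta, unname(coef(cph)), tolerance = 1e-4)
  expect_equal(lap$loglik, cph$loglik[2], tolerance = 1e-3)
  iid <- fit_cox_iid(sd, X = x)
  expect_equal(unname(iid$beta), unname(coef(cph)))
})

test_that("Laplace approximation agrees with Gauss-Hermite quadrature", {
  # one family of 3 sampled subjects: the full frailty integral is 3-dim
  ped <- pedigree(fam = rep("f", 3), id = c("fa", "mo", "kid"),
                  father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"))
  kin <- kinship_from_pedigree(ped)
  corr <- correlation_model("kinship", kinship = kin)
  sd <- simulate_survival_trait(corr, 1, seed = 47,
                                censoring = list(type = "none"))
  A <- as.matrix(kin)
  for (g2 in c(0.3, 1)) {
    gh <- gh_marginal_cox_loglik(sd$time, sd$status, eta_fixed = 0,
                                 gamma2 = g2, A = A, k = 24)
    lap <- laplace_loglik_cox(sd, gamma2 = g2, corr = corr)
    expect_lt(abs(lap - gh), 0.1)
  }
})

test_that("frailty variance is detected when present", {
  co <- small_cohort(25)
  pos <- vapply(1:12, function(s) {
    sd <- simulate_survival_trait(co$corr, 1.5, seed = 600 + s)
    fit_cox_frailty(sd, co$corr)$gamma2 > 0.05
  }, TRUE)
  expect_gt(mean(pos), 0.5)
})

test_that("naive Cox fit solves the score equation (bisection oracle)", {
  t4 <- c(1, 2, 3, 4); d4 <- c(1, 1, 1, 0); x4 <- c(1, 0, 1, 0)
  sd <- survival_data(t4, d4)
  fit <- fit_cox_iid(sd, X = matrix(x4))
  pl <- function(b) {
    eta <- b * x4
    (eta[1] - log(sum(exp(eta)))) +
      (eta[2] - log(sum(exp(eta[2:4])))) +
      (eta[3] - log(sum(exp(eta[3:4]))))
  }
  score <- function(b) (pl(b + 1e-6) - pl(b - 1e-6)) / 2e-6
  root <- uniroot(score, c(-5, 5), tol = 1e-10)$root
  expect_equal(unname(fit$beta), root, tolerance = 1e-5)
  expect_equal(fit$loglik, pl(root), tolerance = 1e-8)
})

test_that("null covariate at large n has a near-zero hazard ratio", {
  set.seed(48)
  n <- 2000
  sd <- simulate_survival_trait(correlation_model("iid", n = n), 0, seed = 49)
  x <- matrix(rnorm(n))
  fit <- fit_cox_iid(sd, X = x)
  expect_lt(abs(fit$beta), 0.1)
})

test_that("integrated likelihood is monotone in nested covariates", {
  fx <- make_surv_fixture(12, gamma2 = 1, seed = 50)
  n <- fx$co$corr$n
  set.seed(51)
  X <- cbind(a = rnorm(n), b = rnorm(n))
  f0 <- fit_cox_frailty(fx$sd, fx$co$corr)
  f1 <- fit_cox_frailty(fx$sd, fx$co$corr, X = X[, 1, drop = FALSE],
                        gamma2_hint = f0$gamma2,
                        warm_start = list(beta = 0, R = f0$R))
  f2 <- fit_cox_frailty(fx$sd, fx$co$corr, X = X,
                        gamma2_hint = f1$gamma2,
                        warm_start = list(beta = c(0, 0), R = f1$R))
  expect_gte(f1$loglik, f0$loglik - 1e-4)
  expect_gte(f2$loglik, f1$loglik - 1e-4)
})

test_that("all-censored data is rejected with a clear error", {
  sd <- survival_data(c(1, 2, 3), c(0, 0, 0))
  co <- small_cohort(1)
  expect_error(fit_cox_iid(sd), "no events")
  expect_error(penalized_partial_loglik(sd, numeric(0), numeric(3), 1,
                                        co$corr), "no events")
})
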