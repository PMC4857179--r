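# Independent oracles used to validate the package's fast paths.

# Dense multivariate-normal log-likelihood with beta profiled by GLS,
# evaluated straight from a Cholesky of the full covariance matrix.
dense_mvn_loglik <- function(y, X, V) {
  n <- length(y)
  L <- chol(V)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  beta <- solve(crossprod(Xw), crossprod(Xw, yw))
  r <- yw - Xw %*% beta
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

# Brute-force ML over (gamma2, sigma2) through the dense oracle: coarse grid
# followed by a quasi-Newton refinement.
dense_ml_loglik <- function(y, X, A) {
  obj <- function(par) -dense_mvn_loglik(y, X,
    exp(par[1]) * A + exp(par[2]) * diag(nrow(A)))
  best <- c(0, 0); bval <- Inf
  for (lg in log(c(1e-4, .1, .3, 1, 3))) for (ls in log(c(.1, .5, 1, 3))) {
    v <- obj(c(lg, ls))
    if (v < bval) { bval <- v; best <- c(lg, ls) }
  }
  -stats::optim(best, obj, method = "BFGS",
                control = list(reltol = 1e-14))$value
}

# Monte-Carlo estimate of the additive relationship matrix by gene dropping
# uniquely labelled founder alleles and counting identity-by-descent sharing.
gene_drop_kinship <- function(ped, ndrops = 2e4, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  depth <- mixbn:::pedigree_depths(ped)
  ord <- order(depth)
  sampled <- which(ped$sampled)
  m <- length(sampled)
  acc <- matrix(0, m, m)
  for (rep in seq_len(ndrops)) {
    a1 <- a2 <- integer(n)
    lab <- 0L
    for (i in ord) {
      if (is.na(ped$father[i])) {
        a1[i] <- lab + 1L; a2[i] <- lab + 2L; lab <- lab + 2L
      } else {
        fa <- idx[[ped$father[i]]]; mo <- idx[[ped$mother[i]]]
        a1[i] <- if (runif(1) < .5) a1[fa] else a2[fa]
        a2[i] <- if (runif(1) < .5) a1[mo] else a2[mo]
      }
    }
    s1 <- a1[sampled]; s2 <- a2[sampled]
    # kinship = P(one random allele from each is IBD); average the 4 pairings
    share <- (outer(s1, s1, "==") + outer(s1, s2, "==") +
              outer(s2, s1, "==") + outer(s2, s2, "==")) / 4
    acc <- acc + share
  }
  k <- acc / ndrops
  diag(k) <- 0.5 # non-inbred self-kinship by definition
  2 * k
}

# Gauss-Hermite nodes/weights by the Golub-Welsch eigenvalue method.
gauss_hermite <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Vectorized Breslow partial log-likelihood over columns of an eta matrix.
cox_pl_columns <- function(eta, time, status) {
  ord <- order(time)
  d <- status[ord]
  E <- exp(eta[ord, , drop = FALSE])
  S <- apply(E, 2, function(col) rev(cumsum(rev(col))))
  colSums(d * (eta[ord, , drop = FALSE] - log(S)))
}

# Marginal (frailty-integrated) Cox partial likelihood by product-rule
# Gauss-Hermite quadrature over the whole frailty vector; only feasible for a
# handful of subjects.
gh_marginal_cox_loglik <- function(time, status, eta_fixed, gamma2, A,
                                   k = 20) {
  n <- length(time)
  gh <- gauss_hermite(k)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), n))
  Z <- matrix(gh$nodes[as.matrix(grids)], ncol = n)
  logw <- rowSums(matrix(log(gh$weights)[as.matrix(grids)], ncol = n))
  L <- t(chol(gamma2 * A)) # lower triangular
  Rmat <- sqrt(2) * (L %*% t(Z))
  ll <- cox_pl_columns(Rmat + eta_fixed, time, status)
  # log of pi^{-n/2} * sum w * exp(ll)
  m <- max(logw + ll)
  m + log(sum(exp(logw + ll - m))) - n / 2 * log(pi)
}

# Rejection-rate standard error helper.
mc_se <- function(p, n) sqrt(p * (1 - p) / n)
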