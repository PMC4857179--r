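# Cox proportional-hazards nodes with correlated log-normal frailty.
#
# The frailty vector R (one element per subject) is N(0, gamma2 * A) with A
# the additive relationship matrix, so family members share correlated
# log-hazard deviations. The integrated partial likelihood is approximated by
# Laplace's method: maximize the penalized partial likelihood over (beta, R)
# by Newton-Raphson, then subtract half the log-determinant of the scaled
# curvature; the frailty variance is profiled by outer one-dimensional search.
# All internal computation happens in time-sorted order; because the Breslow
# risk sets are nested, the n x n partial-likelihood Hessian has the
# "min-kernel" form diag(mu) - D_e M D_e with M_jl = G_min(j,l), and is built
# in O(n^2).

#' Assemble survival data
#'
#' @param time observed times `t = min(T, C)`, all > 0.
#' @param status event indicator `delta = I(T <= C)` in {0, 1}.
#' @return A `survival_data` data frame.
#' @export
survival_data <- function(time, status) {
  abort_if(any(time <= 0), "times must be positive")
  abort_if(!all(status %in% c(0, 1)), "status must be 0/1")
  out <- data.frame(time = as.numeric(time), status = as.integer(status))
  class(out) <- c("survival_data", "data.frame")
  out
}

as_survival_data <- function(data) {
  if (!inherits(data, "survival_data")) data <- survival_data(data$time, data$status)
  data
}

# Risk-set bookkeeping in time-sorted order (Breslow handling of ties: all
# events at a tied time share the risk set of that time). Returned as an
# environment so the min-index matrix can be attached lazily.
cox_prep <- function(time, status) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]
  ds <- as.integer(status[ord])
  grp <- cumsum(c(TRUE, ts[-1L] != ts[-n]))
  prep <- new.env(parent = emptyenv())
  prep$n <- n
  prep$d <- sum(ds)
  prep$ord <- ord
  prep$inv <- order(ord)
  prep$delta <- ds
  prep$grp_first <- match(grp, grp)
  prep$grp_last <- n + 1L - match(grp, rev(grp))
  prep
}

# pmin(i, j) over sorted indices, cached (fixed per data set).
cox_min_index <- function(prep) {
  if (is.null(prep$iMin)) {
    i <- seq_len(prep$n)
    prep$iMin <- pmin(rep(i, times = prep$n), rep(i, each = prep$n))
  }
  prep$iMin
}

# Breslow partial log-likelihood and derivatives with respect to the linear
# predictor, in sorted order.
cox_pl_core <- function(es, prep, hessian = FALSE) {
  c0 <- max(es)
  ee <- exp(es - c0)
  Sp <- rev(cumsum(rev(ee)))
  Sg <- Sp[prep$grp_first]
  ll <- sum(prep$delta * (es - c0 - log(Sg)))
  h1 <- cumsum(prep$delta / Sg)
  B <- h1[prep$grp_last]
  out <- list(loglik = ll, grad = prep$delta - ee * B)
  if (hessian) {
    h2 <- cumsum(prep$delta / Sg^2)
    G <- h2[prep$grp_last]
    M <- G[cox_min_index(prep)]
    dim(M) <- c(prep$n, prep$n)
    Hs <- -tcrossprod(ee) * M
    diag(Hs) <- diag(Hs) + ee * B
    out$hessian <- Hs
  }
  out
}

# Block-diagonal inverse and log-determinant of A over the sampled set; a
# ridge of 1e-8 is added to near-singular blocks. Cached on the correlation
# model (original subject order).
kinship_inverse <- function(corr) {
  hit <- corr$cache$ainv
  if (!is.null(hit)) return(hit)
  se <- structure_eigen(corr)
  n <- corr$n
  Ainv <- matrix(0, n, n)
  logdet <- 0
  for (b in seq_along(se$idx)) {
    i <- se$idx[[b]]
    s <- se$s[i]
    if (min(s) < 1e-8) s <- s + 1e-8
    U <- se$U[[b]]
    Ainv[i, i] <- U %*% (t(U) / s)
    logdet <- logdet + sum(log(s))
  }
  out <- list(Ainv = Ainv, logdet = logdet)
  corr$cache$ainv <- out
  out
}

# Shared per-data-set context for frailty fits: sorted design pieces and the
# sorted penalty matrix, so candidate-parent fits reuse them.
cox_context <- function(data, corr, Xall = NULL) {
  data <- as_survival_data(data)
  corr <- as_corr(corr)
  abort_if(sum(data$status) == 0, "no events in the data")
  prep <- cox_prep(data$time, data$status)
  ki <- kinship_inverse(corr)
  list(prep = prep,
       Ainv_s = ki$Ainv[prep$ord, prep$ord],
       logdetA = ki$logdet,
       Xall_s = if (!is.null(Xall))
         as.matrix(Xall)[prep$ord, , drop = FALSE])
}

# Inner Newton-Raphson on (beta, R) of the penalized partial likelihood at
# fixed gamma2 (sorted order). Returns mode, curvature and Laplace pieces.
cox_inner_newton <- function(prep, Xs, Qmat, beta, R, offset = NULL,
                             max_iter = 50L, tol = 1e-6) {
  p <- if (is.null(Xs)) 0L else ncol(Xs)
  eta <- R + (if (p > 0) as.numeric(Xs %*% beta) else 0) + (offset %||% 0)
  pen <- function(R) sum(R * (Qmat %*% R)) / 2
  core <- cox_pl_core(eta, prep, hessian = TRUE)
  obj <- core$loglik - pen(R)
  moved <- Inf
  for (it in seq_len(max_iter)) {
    H <- core$hessian
    Hpen <- H + Qmat
    gR <- core$grad - as.numeric(Qmat %*% R)
    ch <- tryCatch(chol(Hpen), error = function(e) NULL)
    if (is.null(ch)) # curvature not PD away from the mode: ridge and retry
      ch <- chol(Hpen + diag(1e-6 * max(diag(Hpen)), nrow(Hpen)))
    if (p > 0) {
      gB <- crossprod(Xs, core$grad)
      HX <- H %*% Xs
      W <- backsolve(ch, backsolve(ch, HX, transpose = TRUE))
      Sb <- crossprod(Xs, HX) - crossprod(HX, W)
      db <- tryCatch(solve(Sb, gB - crossprod(W, gR)),
                     error = function(e)
                       stop("singular curvature for fixed effects",
                            call. = FALSE))
      dR <- backsolve(ch, backsolve(ch, gR - HX %*% db, transpose = TRUE))
      db <- as.numeric(db)
    } else {
      db <- numeric(0)
      dR <- backsolve(ch, backsolve(ch, gR, transpose = TRUE))
    }
    dR <- as.numeric(dR)
    step <- 1
    repeat {
      beta_new <- beta + step * db
      R_new <- R + step * dR
      eta_new <- R_new + (if (p > 0) as.numeric(Xs %*% beta_new) else 0) +
        (offset %||% 0)
      obj_new <- cox_pl_core(eta_new, prep)$loglik - pen(R_new)
      if (is.finite(obj_new) && (obj_new >= obj - 1e-12)) break
      step <- step / 2
      abort_if(step < 1e-8,
               "inner Newton-Raphson failed to improve (step underflow)")
    }
    moved <- obj_new - obj
    beta <- beta_new; R <- R_new; eta <- eta_new
    core <- cox_pl_core(eta, prep, hessian = TRUE)
    obj <- core$loglik - pen(R)
    if (moved < tol)
      return(list(beta = beta, R = R, loglik_pen = obj, core = core,
                  iter = it))
  }
  stop(sprintf(
    "inner Newton-Raphson did not converge in %d iterations (last step %.3g)",
    max_iter, moved), call. = FALSE)
}

# Laplace integrated partial log-likelihood at fixed gamma2:
# loglik_pen - log det(I + gamma2 * A * H) / 2 (all in sorted order).
cox_laplace_at <- function(ctx, Xs, gamma2, beta, R, offset = NULL) {
  prep <- ctx$prep
  Qmat <- ctx$Ainv_s / gamma2
  fit <- cox_inner_newton(prep, Xs, Qmat, beta, R, offset = offset)
  ch <- chol(fit$core$hessian + Qmat)
  logdet <- 2 * sum(log(diag(ch))) + prep$n * log(gamma2) + ctx$logdetA
  list(loglik = fit$loglik_pen - logdet / 2, fit = fit)
}

# Core outer/inner optimization shared by fit_cox_frailty and the search
# fitter. Xs in sorted order (or NULL).
cox_frailty_engine <- function(ctx, Xs, names_beta = NULL, gamma2_hint = NULL,
                               outer_tol = 1e-3, warm = NULL,
                               refine = c("brent", "quad")) {
  refine <- match.arg(refine)
  prep <- ctx$prep
  p <- if (is.null(Xs)) 0L else ncol(Xs)
  state <- new.env(parent = emptyenv())
  state$beta <- warm$beta %||% numeric(p)
  state$R <- warm$R %||% numeric(prep$n)
  state$best <- NULL
  objective <- function(lg) {
    res <- cox_laplace_at(ctx, Xs, exp(lg), state$beta, state$R)
    state$beta <- res$fit$beta
    state$R <- res$fit$R
    if (is.null(state$best) || res$loglik > state$best$loglik) {
      state$best <- res
      state$best$gamma2 <- exp(lg)
    }
    res$loglik
  }
  lo_full <- log(1e-6); hi_full <- log(10)
  brent <- function(lo, hi) {
    opt <- stats::optimize(objective, lower = lo, upper = hi, maximum = TRUE,
                           tol = outer_tol)
    if ((opt$maximum - lo < 2 * outer_tol && lo > lo_full + 1e-9) ||
        (hi - opt$maximum < 2 * outer_tol && hi < hi_full - 1e-9)) {
      stats::optimize(objective, lower = lo_full, upper = hi_full,
                      maximum = TRUE, tol = outer_tol)
    }
  }
  if (refine == "quad" && !is.null(gamma2_hint) && gamma2_hint > 0) {
    # warm refit: the variance profile barely moves between nested models, so
    # a local quadratic step around the hint suffices; fall back to a full
    # bracketed search when the parabola disagrees
    ctr <- min(max(log(gamma2_hint), lo_full + 0.3), hi_full - 0.3)
    delta <- 0.3
    f0 <- objective(ctr)
    fm <- objective(ctr - delta)
    fp <- objective(ctr + delta)
    denom <- fm - 2 * f0 + fp
    vertex <- if (denom < -1e-12)
      ctr + 0.5 * delta * (fm - fp) / denom else NA_real_
    if (is.finite(vertex) && abs(vertex - ctr) <= 1.5) {
      objective(min(max(vertex, lo_full), hi_full))
    } else {
      brent(lo_full, hi_full)
    }
  } else if (!is.null(gamma2_hint) && gamma2_hint > 0) {
    lo <- max(lo_full, log(gamma2_hint) - log(8))
    hi <- min(hi_full, log(gamma2_hint) + log(8))
    # evaluating at the hint first guarantees nested fits never score below
    # the reduced model's optimum by more than the inner tolerance
    objective(log(gamma2_hint))
    brent(lo, hi)
  } else {
    brent(lo_full, hi_full)
  }
  best <- state$best
  new_cox_model(
    beta = best$fit$beta, names_beta = names_beta,
    gamma2 = best$gamma2, loglik = best$loglik,
    p_eff = p + 1L, n = prep$n, d = prep$d,
    R = best$fit$R[prep$inv]
  )
}

#' Penalized Cox partial log-likelihood with correlated frailty
#'
#' Breslow partial log-likelihood at linear predictor `X beta + R`, minus the
#' Gaussian penalty `R' (gamma2 A)^{-1} R / 2` induced by the frailty prior
#' `R ~ N(0, gamma2 * A)`.
#'
#' @param data a `survival_data` (or data frame with `time`, `status`).
#' @param beta fixed-effect coefficients (may be empty).
#' @param R frailty vector, length n (original subject order).
#' @param gamma2 frailty variance, > 0.
#' @param corr a kinship [correlation_model] (or `kinship_matrix`).
#' @param X covariate matrix (required when `beta` is non-empty).
#' @return Penalized partial log-likelihood (scalar).
#' @export
penalized_partial_loglik <- function(data, beta, R, gamma2, corr, X = NULL) {
  data <- as_survival_data(data)
  corr <- as_corr(corr)
  abort_if(gamma2 <= 0, "gamma2 must be > 0")
  abort_if(sum(data$status) == 0, "no events in the data")
  eta <- R
  if (length(beta) > 0) {
    X <- as.matrix(X)
    eta <- eta + as.numeric(X %*% beta)
  }
  prep <- cox_prep(data$time, data$status)
  ki <- kinship_inverse(corr)
  cox_pl_core(eta[prep$ord], prep)$loglik -
    sum(R * (ki$Ainv %*% R)) / (2 * gamma2)
}

#' Laplace-approximate integrated Cox partial log-likelihood
#'
#' At fixed frailty variance `gamma2`, maximizes the penalized partial
#' likelihood over the frailty vector (and `beta` unless supplied fixed), and
#' returns the Laplace approximation to the partial likelihood with the
#' frailty integrated out:
#' `loglik_pen(R_hat) - log det(I + gamma2 * A * H(R_hat)) / 2`.
#'
#' @inheritParams penalized_partial_loglik
#' @param beta optional fixed coefficients held constant; by default the
#'   fixed effects are profiled out.
#' @return Integrated partial log-likelihood (scalar).
#' @export
laplace_loglik_cox <- function(data, gamma2, corr, X = NULL, beta = NULL) {
  abort_if(gamma2 <= 0, "gamma2 must be > 0")
  ctx <- cox_context(data, corr, Xall = X)
  prep <- ctx$prep
  if (!is.null(beta) && length(beta) > 0) {
    offset <- as.numeric(ctx$Xall_s %*% beta)
    res <- cox_laplace_at(ctx, NULL, gamma2, numeric(0), numeric(prep$n),
                          offset = offset)
  } else {
    p <- if (is.null(X)) 0L else ncol(as.matrix(X))
    res <- cox_laplace_at(ctx, ctx$Xall_s, gamma2, numeric(p),
                          numeric(prep$n))
  }
  res$loglik
}

new_cox_model <- function(beta, names_beta, gamma2, loglik, p_eff, n, d,
                          R = NULL, converged = TRUE) {
  structure(
    list(beta = stats::setNames(beta, names_beta), gamma2 = gamma2,
         loglik = loglik, p_eff = p_eff, n = n, d = d, R = R,
         rho = NULL, family = "cox", converged = converged),
    class = c("cox_frailty_model", "mixbn_node_model")
  )
}

#' Fit a Cox node with correlated log-normal frailty
#'
#' Maximizes the Laplace-approximate integrated partial likelihood: an inner
#' Newton-Raphson over `(beta, R)` of the penalized partial likelihood nested
#' in an outer one-dimensional search over the frailty variance `gamma2` on a
#' log scale over `[1e-6, 10]`. Ties are handled by the Breslow
#' approximation.
#'
#' @param data a `survival_data` (or data frame with `time`, `status`), with
#'   at least one event.
#' @param corr a kinship [correlation_model] (or `kinship_matrix`).
#' @param X optional covariate matrix.
#' @param gamma2_hint optional starting value; the outer search brackets
#'   around it (widening to the full range if the optimum lands on the
#'   bracket edge), and the hint itself is always evaluated.
#' @param outer_tol tolerance of the outer search on log(gamma2).
#' @param warm_start optional list with elements `beta`, `R` (original
#'   subject order) starting the inner Newton-Raphson.
#' @return A `cox_frailty_model` with `beta`, `gamma2`, the integrated
#'   partial log-likelihood `loglik`, `p_eff` (= p + 1 for the frailty
#'   variance), `n`, number of events `d`, and the frailty mode `R`.
#' @export
fit_cox_frailty <- function(data, corr, X = NULL, gamma2_hint = NULL,
                            outer_tol = 1e-3, warm_start = NULL) {
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) == 0L) X <- NULL
  }
  ctx <- cox_context(data, corr, Xall = X)
  warm <- if (!is.null(warm_start))
    list(beta = warm_start$beta, R = warm_start$R[ctx$prep$ord])
  cox_frailty_engine(ctx, ctx$Xall_s, names_beta = colnames(X),
                     gamma2_hint = gamma2_hint, outer_tol = outer_tol,
                     warm = warm)
}

#' Ordinary Cox proportional-hazards fit (no frailty)
#'
#' Standard Cox partial-likelihood maximization (Breslow ties) used by the
#' naive selection metrics; delegates to [survival::coxph()] when covariates
#' are present.
#'
#' @inheritParams fit_cox_frailty
#' @return A `cox_frailty_model` with `gamma2 = 0` and `p_eff = p`.
#' @export
fit_cox_iid <- function(data, X = NULL) {
  data <- as_survival_data(data)
  abort_if(sum(data$status) == 0, "no events in the data")
  prep <- cox_prep(data$time, data$status)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) == 0L) X <- NULL
  }
  if (is.null(X)) {
    ll <- cox_pl_core(numeric(prep$n), prep)$loglik
    return(new_cox_model(numeric(0), NULL, 0, ll, 0L, prep$n, prep$d))
  }
  fit <- survival::coxph(
    survival::Surv(data$time, data$status) ~ X, ties = "breslow"
  )
  new_cox_model(
    beta = unname(stats::coef(fit)), names_beta = colnames(X),
    gamma2 = 0, loglik = fit$loglik[2L], p_eff = ncol(X),
    n = prep$n, d = prep$d
  )
}

#' @export
print.cox_frailty_model <- function(x, ...) {
  cat(sprintf(
    "<cox_frailty_model> n=%d events=%d loglik=%.3f gamma2=%.4f p=%d\n",
    x$n, x$d, x$loglik, x$gamma2, length(x$beta)))
  invisible(x)
}
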