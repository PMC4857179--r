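#' Correlation model for a set of observations
#'
#' Describes the within-cluster covariance structure used by the
#' random-effects-augmented node likelihoods. Four kinds are supported:
#'
#' * `"kinship"`: family-based data; the covariance of a trait is
#'   `V = gamma2 * A + sigma2 * I`, with `A = 2K` the block-diagonal additive
#'   relationship matrix.
#' * `"exchangeable"` / `"ar1"`: repeated-measures data; the random-effect
#'   covariance is block diagonal over subjects with constant (exchangeable)
#'   or autoregressive within-subject correlation `rho`.
#' * `"iid"`: independent observations (no random effect).
#'
#' The per-block eigendecompositions of the structure matrix are computed once
#' and cached, so that every candidate-parent fit on the same data set reuses
#' the same rotation.
#'
#' @param kind one of `"kinship"`, `"exchangeable"`, `"ar1"`, `"iid"`.
#' @param kinship a `kinship_matrix` (required for `kind = "kinship"`); data
#'   rows must follow `kinship$ids` order.
#' @param cluster cluster/subject assignment (required for exchangeable/AR1
#'   kinds; ignored for kinship, where families are the clusters).
#' @param n number of observations (required for `kind = "iid"` when `cluster`
#'   is absent).
#' @return An object of class `correlation_model`.
#' @export
correlation_model <- function(kind = c("kinship", "exchangeable", "ar1", "iid"),
                              kinship = NULL, cluster = NULL, n = NULL) {
  kind <- match.arg(kind)
  if (kind == "kinship") {
    abort_if(is.null(kinship) || !inherits(kinship, "kinship_matrix"),
             "kind 'kinship' requires a kinship_matrix")
    cluster <- kinship$fam
    n <- length(kinship$ids)
  } else if (kind %in% c("exchangeable", "ar1")) {
    abort_if(is.null(cluster), sprintf("kind '%s' requires a cluster assignment",
                                       kind))
    cluster <- factor(cluster, levels = unique(cluster))
    n <- length(cluster)
  } else {
    if (is.null(cluster)) {
      abort_if(is.null(n), "kind 'iid' requires n or cluster")
      cluster <- factor(seq_len(n))
    } else {
      cluster <- factor(cluster, levels = unique(cluster))
      n <- length(cluster)
    }
  }
  obj <- list(kind = kind, n = as.integer(n), cluster = cluster,
              kinship = kinship, cache = new.env(parent = emptyenv()))
  class(obj) <- "correlation_model"
  obj
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> kind=%s, n=%d, clusters=%d\n",
              x$kind, x$n, nlevels(x$cluster)))
  invisible(x)
}

n_clusters <- function(corr) nlevels(corr$cluster)

# Row indices of each cluster, cached.
cluster_index <- function(corr) {
  if (is.null(corr$cache$idx))
    corr$cache$idx <- split(seq_len(corr$n), corr$cluster)
  corr$cache$idx
}

# Eigendecomposition of the per-block structure matrix (A_f for kinship,
# correlation block for exchangeable/AR1 at a given rho). Returns
# list(U = list per block, s = full-length eigenvalue vector, idx).
# Identical blocks share a single eigendecomposition.
structure_eigen <- function(corr, rho = NULL) {
  key <- if (corr$kind %in% c("exchangeable", "ar1"))
    sprintf("eig_%s_%.10f", corr$kind, rho) else "eig_kinship"
  hit <- corr$cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- cluster_index(corr)
  s <- numeric(corr$n)
  U <- vector("list", length(idx))
  if (corr$kind == "iid") {
    for (b in seq_along(idx)) U[[b]] <- diag(length(idx[[b]]))
    s[] <- 1 # identity structure: gamma2 adds homogeneous variance
  } else {
    blocks <- switch(corr$kind,
      kinship = corr$kinship$blocks,
      lapply(idx, function(i) corr_block(corr$kind, length(i), rho))
    )
    seen <- new.env(parent = emptyenv())
    for (b in seq_along(idx)) {
      Ab <- blocks[[b]]
      hkey <- paste(c(dim(Ab)[1L], signif(Ab[upper.tri(Ab, diag = TRUE)], 12)),
                    collapse = ",")
      e <- seen[[hkey]]
      if (is.null(e)) {
        e <- eigen(Ab, symmetric = TRUE)
        abort_if(min(e$values) < -1e-8,
                 "structure matrix block is not positive semi-definite")
        e$values <- pmax(e$values, 0)
        seen[[hkey]] <- e
      }
      U[[b]] <- e$vectors
      s[idx[[b]]] <- e$values
    }
  }
  out <- list(U = U, s = s, idx = idx)
  corr$cache[[key]] <- out
  out
}

# Correlation block for repeated-measures structures.
corr_block <- function(kind, m, rho) {
  if (kind == "exchangeable") {
    R <- matrix(rho, m, m); diag(R) <- 1; R
  } else {
    rho^abs(outer(seq_len(m), seq_len(m), "-"))
  }
}

# Sparse block-diagonal rotation matrix t(U) mapping data to the eigenbasis.
rotation_matrix <- function(corr, rho = NULL) {
  key <- if (corr$kind %in% c("exchangeable", "ar1"))
    sprintf("rot_%s_%.10f", corr$kind, rho) else "rot"
  hit <- corr$cache[[key]]
  if (!is.null(hit)) return(hit)
  se <- structure_eigen(corr, rho)
  ii <- unlist(lapply(seq_along(se$idx), function(b)
    rep(se$idx[[b]], each = length(se$idx[[b]]))), use.names = FALSE)
  jj <- unlist(lapply(seq_along(se$idx), function(b)
    rep(se$idx[[b]], times = length(se$idx[[b]]))), use.names = FALSE)
  # entry (a, b) of each block must be t(U)[a, b] = U[b, a]; with jj varying
  # fastest the values enumerate U column-major
  xx <- unlist(lapply(se$U, as.numeric), use.names = FALSE)
  Ut <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                             dims = c(corr$n, corr$n))
  out <- list(Ut = Ut, s = se$s)
  corr$cache[[key]] <- out
  out
}

# Rotate columns of a vector/matrix into the structure eigenbasis.
rotate_data <- function(corr, M, rho = NULL) {
  if (corr$kind == "iid") return(as.matrix(M))
  rot <- rotation_matrix(corr, rho)
  as.matrix(rot$Ut %*% M)
}

# Per-block t(U) %*% 1 and eigenvalues, used by closed-form effective sample
# sizes; cached.
structure_u1 <- function(corr, rho = NULL) {
  key <- if (corr$kind %in% c("exchangeable", "ar1"))
    sprintf("u1_%s_%.10f", corr$kind, rho) else "u1"
  hit <- corr$cache[[key]]
  if (!is.null(hit)) return(hit)
  se <- structure_eigen(corr, rho)
  out <- lapply(seq_along(se$U), function(b)
    list(u1 = colSums(se$U[[b]]), s = se$s[se$idx[[b]]]))
  corr$cache[[key]] <- out
  out
}
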