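# K2-style forward selection of node parents, ordering enumeration, global
# network scoring, and Markov-blanket extraction.

#' Specify a network node
#'
#' @param name node label. For Gaussian nodes this is the data column; for
#'   survival nodes the data columns are given by `time` and `event`.
#' @param kind `"gaussian"` or `"survival"`.
#' @param candidates candidate-parent node names considered by the search
#'   (`NULL` = decided by the ordering).
#' @param root forced root: never receives parents.
#' @param sink forced sink: placed last in every ordering and never used as a
#'   parent.
#' @param time,event data columns holding the observed time and event
#'   indicator (survival nodes).
#' @return A `node_spec` object.
#' @export
node_spec <- function(name, kind = c("gaussian", "survival"),
                      candidates = NULL, root = FALSE, sink = FALSE,
                      time = NULL, event = NULL) {
  kind <- match.arg(kind)
  abort_if(root && sink, "a node cannot be both root and sink")
  abort_if(root && length(candidates) > 0,
           "forced roots must have an empty candidate-parent set")
  if (kind == "survival")
    abort_if(is.null(time) || is.null(event),
             "survival nodes need 'time' and 'event' columns")
  structure(list(name = name, kind = kind, candidates = candidates,
                 root = root, sink = sink, time = time, event = event),
            class = "node_spec")
}

# Memoizing fitter for one node: fits (and caches) models indexed by parent
# set and likelihood family. `parent_cols` are column names in `data`;
# candidate parents are rotated once so every candidate fit reuses the same
# eigenbasis.
node_fitter <- function(node, data, corr, all_candidates) {
  cache <- new.env(parent = emptyenv())
  cand_cols <- all_candidates
  if (node$kind == "gaussian") {
    y <- data[[node$name]]
    abort_if(is.null(y), sprintf("column '%s' not found", node$name))
    Xall <- cbind(`(Intercept)` = rep(1, length(y)))
    if (length(cand_cols) > 0)
      Xall <- cbind(Xall, as.matrix(data[cand_cols]))
    if (corr$kind != "iid") {
      yt <- rotate_data(corr, y)
      Xt_all <- rotate_data(corr, Xall)
      s <- rotation_matrix(corr)$s
    }
    function(parents, mixed) {
      key <- paste(c(if (mixed) "M" else "F", sort(parents)), collapse = "|")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      cols <- c("(Intercept)", parents)
      fit <- if (mixed && corr$kind != "iid") {
        best <- optimize_h2(yt, Xt_all[, cols, drop = FALSE], s)
        new_gaussian_model(
          kind = corr$kind, beta = best$beta, names_beta = cols,
          gamma2 = best$gamma2, sigma2 = best$sigma2, loglik = best$loglik,
          p_eff = length(cols) + 2L, n = length(y), h2 = best$h2,
          degenerate = best$tau2 < 1e-12
        )
      } else if (mixed) {
        fit_gaussian_mixed(y, Xall[, cols, drop = FALSE], corr)
      } else {
        fit_gaussian_iid(y, Xall[, cols, drop = FALSE])
      }
      cache[[key]] <- fit
      fit
    }
  } else {
    sdat <- survival_data(data[[node$time]], data[[node$event]])
    Xall <- if (length(cand_cols) > 0) as.matrix(data[cand_cols]) else NULL
    ctx <- if (corr$kind != "iid") cox_context(sdat, corr, Xall = Xall)
    warm <- new.env(parent = emptyenv())
    function(parents, mixed) {
      key <- paste(c(if (mixed) "M" else "F", sort(parents)), collapse = "|")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      fit <- if (mixed && corr$kind != "iid") {
        Xs <- if (length(parents) > 0)
          ctx$Xall_s[, parents, drop = FALSE] else NULL
        ws <- if (!is.null(warm$R))
          list(beta = numeric(length(parents)), R = warm$R) else NULL
        f <- cox_frailty_engine(ctx, Xs, names_beta = parents,
                                gamma2_hint = warm$gamma2,
                                outer_tol = 5e-3, warm = ws,
                                refine = "quad")
        if (is.null(warm$R)) {
          warm$R <- f$R[ctx$prep$ord]
          warm$gamma2 <- f$gamma2
        }
        f
      } else {
        Xp <- if (length(parents) > 0) Xall[, parents, drop = FALSE] else NULL
        fit_cox_iid(sdat, X = Xp)
      }
      cache[[key]] <- fit
      fit
    }
  }
}

score_with_ne <- function(model, cfg, ne) {
  if (cfg$type == "AIC") -2 * model$loglik + 2 * model$p_eff
  else -2 * model$loglik + model$p_eff * log(ne)
}

#' Forward selection of one node's parents
#'
#' K2-style forward search: starting from the parent-free model, every
#' remaining candidate is evaluated at each level. For BIC/AIC metrics a
#' candidate "passes" when it improves (lowers) the current score and the
#' best passing candidate is added; for LRT metrics a candidate passes when
#' its nested likelihood-ratio p-value is below `alpha` (optionally
#' Bonferroni-adjusted by the number of level-1 candidates) and the smallest
#' p-value is added. The search stops at the first level with no passing
#' candidate. Every candidate evaluation is logged as one test in the trace.
#'
#' For the effective-sample-size BIC variants the effective n is recomputed
#' at each level from the current (reduced) model's variance components and
#' used to score both the current model and all candidates at that level.
#'
#' @param node a [node_spec].
#' @param data data frame holding the node and candidate columns.
#' @param corr a [correlation_model].
#' @param cfg a [score_config] (or metric name).
#' @param candidates candidate-parent column names (defaults to
#'   `node$candidates`).
#' @param fitter optional memoizing fitter from a previous call on the same
#'   data (lets several metrics share fits).
#' @return list with `model` (the selected `FittedNodeModel`), `parents`,
#'   and `trace` (one row per test: level, candidate, statistic, p-value,
#'   score, pass, selected).
#' @export
forward_select_node <- function(node, data, corr, cfg,
                                candidates = node$candidates, fitter = NULL) {
  cfg <- as_score_config(cfg)
  candidates <- candidates %||% character(0)
  if (node$root) candidates <- character(0)
  if (is.null(fitter)) fitter <- node_fitter(node, data, corr, candidates)
  mixed <- cfg$mixed
  alpha_eff <- if (cfg$bonferroni && length(candidates) > 0)
    cfg$alpha / length(candidates) else cfg$alpha
  current <- fitter(character(0), mixed)
  parents <- character(0)
  remaining <- candidates
  trace <- list()
  level <- 0L
  while (length(remaining) > 0) {
    level <- level + 1L
    ne <- if (cfg$type == "BIC") metric_effective_n(current, cfg, corr)
    cur_score <- if (cfg$type != "LRT") score_with_ne(current, cfg, ne %||% NA)
    stat <- pval <- score <- rep(NA_real_, length(remaining))
    pass <- rep(FALSE, length(remaining))
    models <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      fit <- tryCatch(fitter(c(parents, remaining[j]), mixed),
                      error = function(e) {
        warning(sprintf("fit failed for candidate '%s': %s", remaining[j],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      models[[j]] <- fit
      if (is.null(fit)) next
      if (cfg$type == "LRT") {
        lr <- lrt_pvalue(fit, current, tol = 0.02)
        stat[j] <- lr$statistic
        pval[j] <- lr$p_value
        pass[j] <- lr$p_value < alpha_eff
      } else {
        score[j] <- score_with_ne(fit, cfg, ne)
        stat[j] <- 2 * (fit$loglik - current$loglik)
        pass[j] <- score[j] < cur_score
      }
    }
    pick <- if (cfg$type == "LRT") {
      if (any(pass)) which.min(replace(pval, !pass, Inf)) else NA_integer_
    } else {
      if (any(pass)) which.min(replace(score, !pass, Inf)) else NA_integer_
    }
    trace[[level]] <- data.frame(
      level = level, candidate = remaining,
      statistic = stat, p_value = pval, score = score, pass = pass,
      selected = !is.na(pick) & seq_along(remaining) == pick
    )
    if (is.na(pick)) break
    parents <- c(parents, remaining[pick])
    current <- models[[pick]]
    remaining <- remaining[-pick]
  }
  list(model = current, parents = parents,
       trace = if (length(trace) > 0) do.call(rbind, trace)
               else data.frame(level = integer(0), candidate = character(0),
                               statistic = numeric(0), p_value = numeric(0),
                               score = numeric(0), pass = logical(0),
                               selected = logical(0)))
}

#' Enumerate node orderings under root/sink constraints
#'
#' All permutations of the free (non-root, non-sink) nodes, with forced roots
#' first and forced sinks last, in deterministic (lexicographic-index) order.
#'
#' @param nodes list of [node_spec]s.
#' @param cap maximum number of free nodes to permute (default 8).
#' @return list of character vectors of node names.
#' @export
enumerate_orderings <- function(nodes, cap = 8L) {
  names <- vapply(nodes, `[[`, "", "name")
  roots <- names[vapply(nodes, `[[`, TRUE, "root")]
  sinks <- names[vapply(nodes, `[[`, TRUE, "sink")]
  free <- setdiff(names, c(roots, sinks))
  abort_if(length(free) > cap, sprintf(
    "%d free nodes exceed the ordering cap (%d); use a greedy single ordering",
    length(free), cap))
  if (length(free) == 0) return(list(c(roots, sinks)))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  lapply(perms(free), function(p) c(roots, p, sinks))
}

#' Learn Bayesian-network structures over orderings
#'
#' For each admissible node ordering, each node's candidate parents are its
#' predecessors in the ordering (forced roots receive none; forced sinks are
#' never parents), selected by [forward_select_node()] under the metric.
#' Structures are ranked by the global log-likelihood `sum_i loglik_i` of the
#' selected node models; duplicated edge sets are collapsed (all tied
#' structures are kept). Because a spurious extra edge can only increase the
#' raw likelihood, ranking uses a metric-consistent global score: the sum of
#' per-node penalized scores for BIC/AIC metrics, and for LRT metrics the
#' deviance plus the per-edge chi-square acceptance threshold; the raw global
#' log-likelihood is reported alongside.
#'
#' @param nodes list of [node_spec]s.
#' @param data data frame.
#' @param corr a [correlation_model].
#' @param cfg a [score_config] (or metric name).
#' @param top_k number of top-ranked structures to return.
#' @param ordering_cap passed to [enumerate_orderings()].
#' @return list of `network_structure` objects, ranked by decreasing global
#'   log-likelihood. Each has `order`, `edges` (data frame `from`, `to`),
#'   `parents` (named list), `models`, `loglik`, and `traces`.
#' @export
learn_network <- function(nodes, data, corr, cfg, top_k = 3L,
                          ordering_cap = 8L) {
  cfg <- as_score_config(cfg)
  names <- vapply(nodes, `[[`, "", "name")
  abort_if(anyDuplicated(names) > 0, "duplicate node names")
  specs <- stats::setNames(nodes, names)
  sinks <- names[vapply(nodes, `[[`, TRUE, "sink")]
  orderings <- enumerate_orderings(nodes, cap = ordering_cap)
  # shared memoized fitter per node across orderings
  fitters <- lapply(specs, function(nd) {
    allowed <- setdiff(nd$candidates %||% setdiff(names, nd$name),
                       c(nd$name, sinks))
    if (nd$root) allowed <- character(0)
    node_fitter(nd, data, corr, allowed)
  })
  results <- lapply(orderings, function(ord) {
    parents <- list(); models <- list(); traces <- list()
    ll <- 0; rank_score <- 0
    for (k in seq_along(ord)) {
      nd <- specs[[ord[k]]]
      cand <- if (nd$root) character(0) else {
        allow <- nd$candidates %||% setdiff(names, nd$name)
        setdiff(intersect(ord[seq_len(k - 1L)], allow), sinks)
      }
      sel <- forward_select_node(nd, data, corr, cfg, candidates = cand,
                                 fitter = fitters[[nd$name]])
      parents[[nd$name]] <- sel$parents
      models[[nd$name]] <- sel$model
      traces[[nd$name]] <- sel$trace
      ll <- ll + sel$model$loglik
      # global ranking must not reward spurious extra edges, which always
      # raise the raw likelihood: each node contributes its metric-consistent
      # penalized score (for LRT, every selected edge pays the chi-square
      # threshold it had to clear)
      rank_score <- rank_score + if (cfg$type == "LRT") {
        a_eff <- if (cfg$bonferroni && length(cand) > 0)
          cfg$alpha / length(cand) else cfg$alpha
        -2 * sel$model$loglik +
          stats::qchisq(1 - a_eff, df = 1) * length(sel$parents)
      } else {
        score_model(sel$model, cfg, corr)
      }
    }
    edges <- do.call(rbind, lapply(names, function(nm) {
      if (length(parents[[nm]]) == 0) NULL
      else data.frame(from = parents[[nm]], to = nm)
    })) %||% data.frame(from = character(0), to = character(0))
    structure(list(order = ord, edges = edges, parents = parents,
                   models = models, loglik = ll, score = rank_score,
                   traces = traces),
              class = "network_structure")
  })
  ord_ll <- order(vapply(results, `[[`, 0, "score"))
  results <- results[ord_ll]
  # collapse duplicate edge sets, keeping the highest-likelihood instance
  keys <- vapply(results, function(r)
    paste(sort(paste(r$edges$from, r$edges$to, sep = ">")), collapse = ";"),
    "")
  results <- results[!duplicated(keys)]
  results[seq_len(min(top_k, length(results)))]
}

#' @export
print.network_structure <- function(x, ...) {
  cat(sprintf("<network_structure> %d nodes, %d edges, loglik=%.3f\n",
              length(x$order), nrow(x$edges), x$loglik))
  if (nrow(x$edges) > 0)
    cat(paste(sprintf("  %s -> %s", x$edges$from, x$edges$to),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Markov blanket of a node
#'
#' Parents, children, and the children's other parents, excluding the node
#' itself.
#'
#' @param net a `network_structure`.
#' @param node node name.
#' @return Character vector of node names (possibly empty).
#' @export
markov_blanket <- function(net, node) {
  abort_if(!node %in% net$order, sprintf("unknown node '%s'", node))
  e <- net$edges
  parents <- e$from[e$to == node]
  children <- e$to[e$from == node]
  spouses <- e$from[e$to %in% children]
  setdiff(unique(c(parents, children, spouses)), node)
}

#' Markov-blanket table for a set of learned networks
#'
#' @param nets list of `network_structure`s (e.g. from [learn_network()]).
#' @return data frame with one row per node and one column per network.
#' @export
markov_blanket_table <- function(nets) {
  if (inherits(nets, "network_structure")) nets <- list(nets)
  nodes <- nets[[1L]]$order
  out <- data.frame(node = nodes)
  for (i in seq_along(nets)) {
    out[[sprintf("MB_in_M%d", i)]] <- vapply(nodes, function(nd)
      paste(markov_blanket(nets[[i]], nd), collapse = ", "), "")
  }
  out
}

#' Write a learned network as an edge-list TSV or DOT file
#'
#' @param net a `network_structure`.
#' @param path output path.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_dot <- function(net, path) {
  lines <- c("digraph bn {",
             sprintf("  \"%s\";", net$order),
             sprintf("  \"%s\" -> \"%s\";", net$edges$from, net$edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
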