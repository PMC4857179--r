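test_that("forward selection with no candidates returns the null model", {
  set.seed(71)
  dat <- data.frame(y = rnorm(50))
  corr <- correlation_model("iid", n = 50)
  sel <- forward_select_node(node_spec("y", "gaussian"), dat, corr, "LRT_F",
                             candidates = character(0))
  expect_equal(length(sel$parents), 0L)
  expect_equal(nrow(sel$trace), 0L)
  expect_equal(length(sel$model$beta), 1L) # intercept only
})

test_that("a strong true effect is selected first", {
  hits <- vapply(1:40, function(s) {
    set.seed(700 + s)
    n <- 150
    x <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
    dat <- data.frame(y = 1.2 * x[, 2] + rnorm(n), x)
    sel <- forward_select_node(node_spec("y", "gaussian"), dat,
                               correlation_model("iid", n = n), "LRT_F",
                               candidates = c("x1", "x2", "x3"))
    length(sel$parents) > 0 && sel$parents[1] == "x2"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("search trace counts follow the level accounting identity", {
  co <- small_cohort(25)
  sim <- mixbn:::simulate_replicate(
    simulation_scenario("gaussian", n_families = 25, reps = 1, seed = 5),
    co, 99)
  sel <- forward_select_node(node_spec("y", "gaussian"), sim$data, co$corr,
                             score_config("LRT_M", alpha = 0.4),
                             candidates = sim$null_cols)
  tr <- sel$trace
  for (l in unique(tr$level)) {
    expect_equal(sum(tr$level == l), 10 - l + 1)
    if (l > 1) expect_true(any(tr$selected[tr$level == l - 1]))
  }
})

test_that("ordering enumeration respects root and sink constraints", {
  mk <- function(name, ...) node_spec(name, "gaussian", ...)
  free3 <- list(mk("a"), mk("b"), mk("c"))
  expect_length(enumerate_orderings(free3), 6L)
  expect_length(enumerate_orderings(list(mk("r", root = TRUE))), 1L)
  nodes <- list(mk("r1", root = TRUE), mk("r2", root = TRUE),
                mk("f1"), mk("f2"), mk("s", sink = TRUE))
  ords <- enumerate_orderings(nodes)
  expect_length(ords, 2L)
  for (o in ords) {
    expect_equal(o[1:2], c("r1", "r2"))
    expect_equal(o[5], "s")
  }
  expect_error(enumerate_orderings(lapply(letters[1:9], mk), cap = 8), "cap")
})

test_that("a generating chain is recovered from strong-effect data", {
  # ranking is by raw global likelihood, so spurious extra edges (which always
  # raise the likelihood) must be kept rare by a strict per-node test
  hits <- vapply(1:30, function(s) {
    set.seed(800 + s)
    n <- 200
    y1 <- rnorm(n)
    y2 <- y1 + 0.7 * rnorm(n)
    y3 <- y2 + 0.7 * rnorm(n)
    dat <- data.frame(Y1 = y1, Y2 = y2, Y3 = y3)
    nodes <- list(node_spec("Y1", "gaussian"), node_spec("Y2", "gaussian"),
                  node_spec("Y3", "gaussian"))
    nets <- learn_network(nodes, dat, correlation_model("iid", n = n),
                          score_config("LRT_F", alpha = 0.01,
                                       bonferroni = TRUE), top_k = 1)
    e <- nets[[1]]$edges
    skel <- sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
    identical(skel, c("Y1 Y2", "Y2 Y3"))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("independent variables yield empty networks under BIC", {
  empty <- vapply(1:15, function(s) {
    set.seed(900 + s)
    n <- 100
    dat <- data.frame(Y1 = rnorm(n), Y2 = rnorm(n), Y3 = rnorm(n))
    nodes <- lapply(names(dat), node_spec, kind = "gaussian")
    nets <- learn_network(nodes, dat, correlation_model("iid", n = n),
                          score_config("BIC_F"), top_k = 1)
    nrow(nets[[1]]$edges) == 0
  }, TRUE)
  expect_gte(mean(empty), 0.8)
})

test_that("learned structures are acyclic and ordering-consistent", {
  set.seed(72)
  n <- 90
  dat <- data.frame(Y1 = rnorm(n))
  dat$Y2 <- dat$Y1 + rnorm(n)
  dat$Y3 <- dat$Y2 + rnorm(n)
  nodes <- lapply(names(dat), node_spec, kind = "gaussian")
  nets <- learn_network(nodes, dat, correlation_model("iid", n = n),
                        "LRT_F", top_k = 3)
  for (net in nets) {
    pos <- match(net$order, net$order)
    names(pos) <- net$order
    if (nrow(net$edges) > 0)
      expect_true(all(match(net$edges$from, net$order) <
                        match(net$edges$to, net$order)))
  }
})

test_that("Markov blankets include parents, children, and spouses", {
  chain <- structure(list(
    order = c("A", "B", "C"),
    edges = data.frame(from = c("A", "B"), to = c("B", "C"))),
    class = "network_structure")
  expect_setequal(markov_blanket(chain, "B"), c("A", "C"))
  collider <- structure(list(
    order = c("A", "B", "C"),
    edges = data.frame(from = c("A", "B"), to = c("C", "C"))),
    class = "network_structure")
  expect_setequal(markov_blanket(collider, "A"), c("B", "C"))
  isolated <- structure(list(
    order = "Z", edges = data.frame(from = character(0), to = character(0))),
    class = "network_structure")
  expect_length(markov_blanket(isolated, "Z"), 0L)
  expect_error(markov_blanket(chain, "nope"), "unknown node")
})

test_that("survival nodes can be sinks fed by mixed node kinds", {
  co <- small_cohort(20)
  n <- co$corr$n
  set.seed(73)
  g <- simulate_gaussian_trait(co$corr, 1, 1)
  sv <- simulate_survival_trait(co$corr, 1, beta = 0.8, X = matrix(g),
                                seed = 74)
  dat <- data.frame(bio = g, time = sv$time, status = sv$status)
  nodes <- list(node_spec("bio", "gaussian"),
                node_spec("surv", "survival", sink = TRUE,
                          time = "time", event = "status"))
  nets <- learn_network(nodes, dat, co$corr, score_config("LRT_M"),
                        top_k = 1)
  expect_s3_class(nets[[1]], "network_structure")
  expect_true(all(nets[[1]]$edges$from != "surv"))
})
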