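test_that("network statistics match hand evaluation on a labeled path", {
  net <- igraph::make_graph(~ n1 - n2, n2 - n3)
  net <- igraph::set_vertex_attr(net, "x",
    value = c(1, 1, 0)[match(igraph::V(net)$name, c("n1", "n2", "n3"))])
  net <- igraph::set_vertex_attr(net, "g",
    value = as.character(igraph::vertex_attr(net, "x")))
  stats <- network_statistics(net, list(
    term_edges(), term_nodefactor("g", levels = "1"),
    term_nodematch("g", diff = TRUE, levels = "1"),
    term_absdiff("x"), term_nodecov("x"), term_nodematch("g")))
  expect_equal(unname(stats), c(2, 3, 1, 1, 3, 1))
  # empty graph: all statistics zero
  e <- igraph::make_empty_graph(4, directed = FALSE)
  e <- igraph::set_vertex_attr(e, "x", value = runif(4))
  expect_equal(unname(network_statistics(e, list(term_edges(),
                                                 term_absdiff("x")))),
               c(0, 0))
  # K3 with one shared level: uniform match equals edge count
  k3 <- igraph::make_full_graph(3)
  k3 <- igraph::set_vertex_attr(k3, "g", value = rep("a", 3))
  expect_equal(unname(network_statistics(k3, list(term_nodematch("g")))), 3)
})

test_that("dyad design rows sum to the network statistics over edges", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(5:25, 1)
    net <- random_graph(n, runif(1, 0.1, 0.5))
    net <- igraph::set_vertex_attr(net, "x", value = runif(n))
    net <- igraph::set_vertex_attr(net, "g",
      value = sample(c("a", "b", "c"), n, TRUE))
    terms <- list(term_edges(), term_nodecov("x"), term_absdiff("x"),
                  term_nodefactor("g", ref = "a"), term_nodematch("g"),
                  term_nodematch("g", diff = TRUE))
    d <- dyad_design(net, terms)
    expect_equal(colSums(d$X * d$y),
                 network_statistics(net, terms))
    # and against the independent adjacency-loop oracle
    A <- graph_adjacency(net)
    x <- igraph::vertex_attr(net, "x")
    g <- igraph::vertex_attr(net, "g")
    specs <- list(list(kind = "edges"), list(kind = "nodecov", x = x),
                  list(kind = "absdiff", x = x),
                  list(kind = "nodefactor", x = g, level = "b"),
                  list(kind = "nodefactor", x = g, level = "c"),
                  list(kind = "nodematch_uniform", x = g),
                  list(kind = "nodematch_diff", x = g, level = "a"),
                  list(kind = "nodematch_diff", x = g, level = "b"),
                  list(kind = "nodematch_diff", x = g, level = "c"))
    expect_equal(unname(network_statistics(net, terms)),
                 unname(oracle_graph_stats(A, specs)))
  }
})

test_that("binary-attribute homophily designs are rank deficient by exactly one", {
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    b <- c("0", "1", sample(c("0", "1"), n - 2, TRUE))  # both levels present
    at <- data.frame(b = b)
    full <- list(term_edges(), term_nodefactor("b", ref = "0"),
                 term_nodematch("b", diff = TRUE))
    X <- dyad_change_stats(at, full)$X
    rep_full <- check_identifiability(X)
    expect_equal(rep_full$deficiency, 1L)
    expect_true(all(c("edges", "nodematch.b.0", "nodematch.b.1") %in%
                      rep_full$collinear_sets[[1]]))
    # dropping either differential term restores full rank
    for (lvl in c("0", "1")) {
      Xr <- dyad_change_stats(at, list(
        term_edges(), term_nodefactor("b", ref = "0"),
        term_nodematch("b", diff = TRUE, levels = lvl)))$X
      expect_equal(check_identifiability(Xr)$deficiency, 0L)
    }
    # uniform homophily with edges + nodefactor is identified
    Xu <- dyad_change_stats(at, list(
      term_edges(), term_nodefactor("b", ref = "0"), term_nodematch("b")))$X
    expect_equal(check_identifiability(Xu)$deficiency, 0L)
  }
})

test_that("edges-only fit equals logit of density; boundaries are flagged", {
  g <- igraph::make_graph(~ 1 - 2, 2 - 3, 3 - 4)  # 3 edges, 6 dyads
  f <- fit_ergm(g, list(term_edges()))
  expect_equal(unname(coef(f)), qlogis(0.5), tolerance = 1e-8)
  g2 <- igraph::sample_gnp(30, 0.2)
  f2 <- fit_ergm(g2, list(term_edges()))
  expect_equal(unname(coef(f2)), qlogis(igraph::edge_density(g2)),
               tolerance = 1e-6)
  # complete graph: MLE diverges to +infinity and is flagged
  fc <- fit_ergm(igraph::make_full_graph(5), list(term_edges()))
  expect_true(fc$coefficients$divergent)
  expect_gt(fc$coefficients$estimate, 10)
  # rank-deficient design is refused with the collinear set named
  k <- igraph::sample_gnp(10, 0.4)
  k <- igraph::set_vertex_attr(k, "b", value = rep(c("0", "1"), 5))
  expect_error(
    fit_ergm(k, list(term_edges(), term_nodefactor("b", ref = "0"),
                     term_nodematch("b", diff = TRUE))),
    "rank deficient")
  # unknown / dyad-dependent terms are rejected
  expect_error(fit_ergm(g, list(rxnet:::new_term("triangle"))),
               "dyad-dependent or unknown")
})

test_that("fit_ergm matches full-graph-enumeration MLE on small graphs", {
  set.seed(37)
  trials <- 0L
  compared <- 0L
  while (compared < 6L && trials < 30L) {
    trials <- trials + 1L
    n <- sample(3:5, 1)
    x <- runif(n)
    g <- sample(c("a", "b"), n, TRUE)
    net <- igraph::sample_gnp(n, 0.6)
    net <- igraph::set_vertex_attr(net, "x", value = x)
    net <- igraph::set_vertex_attr(net, "g", value = g)
    choice <- sample(1:3, 1)
    terms <- switch(choice,
      list(term_edges()),
      list(term_edges(), term_absdiff("x")),
      list(term_edges(), term_nodecov("x")))
    specs <- switch(choice,
      list(list(kind = "edges")),
      list(list(kind = "edges"), list(kind = "absdiff", x = x)),
      list(list(kind = "edges"), list(kind = "nodecov", x = x)))
    fit <- fit_ergm(net, terms)
    if (any(fit$coefficients$divergent) ||
        any(abs(fit$coefficients$estimate) > 8)) next
    mle <- oracle_enum_mle(specs, graph_adjacency(net),
                           eta0 = fit$coefficients$estimate * 0)
    expect_equal(unname(coef(fit)), mle, tolerance = 1e-6)
    compared <- compared + 1L
  }
  expect_gte(compared, 6L)
})

test_that("exact enumeration normalizes and factorizes", {
  at <- data.frame(x = c(0.1, 0.5, 0.9))
  terms <- list(term_edges(), term_absdiff("x"))
  # eta = 0: all 8 graphs equally likely
  en0 <- exact_small_graph_loglik(at, list(term_edges()), 0)
  expect_equal(exp(en0$logprob), rep(1 / 8, 8))
  # probabilities always sum to one
  en <- exact_small_graph_loglik(at, terms, c(0.7, -1.3))
  expect_equal(sum(exp(en$logprob)), 1, tolerance = 1e-12)
  # edges-only: probability depends only on edge count, with the
  # closed-form normalizer (1 + e^eta)^3 on 3 dyads
  en1 <- exact_small_graph_loglik(at, list(term_edges()), 1.2)
  expect_equal(en1$logprob,
               rowSums(en1$graphs) * 1.2 - 3 * log(1 + exp(1.2)))
  # enumeration equals the product of per-dyad logistic probabilities
  d <- dyad_change_stats(at, terms)
  p <- plogis(drop(d$X %*% c(0.7, -1.3)))
  fact <- apply(en$graphs, 1, function(a) prod(ifelse(a == 1, p, 1 - p)))
  expect_equal(exp(en$logprob), fact, tolerance = 1e-12)
  expect_error(exact_small_graph_loglik(data.frame(x = runif(6)),
                                        list(term_edges()), 0),
               "n <= 5")
})

test_that("simulated dyad-independent networks recover their coefficients", {
  # density: eta = 0 gives density 1/2 within binomial noise
  at <- data.frame(x = runif(46))  # 1035 dyads
  net <- generate_dyad_independent_network(at, list(term_edges()), 0,
                                           seed = 101)
  dens <- igraph::edge_density(net)
  expect_lt(abs(dens - 0.5), 3 * sqrt(0.25 / 1035))
  # strongly negative edges coefficient: empty graph
  net2 <- generate_dyad_independent_network(at, list(term_edges()), -30,
                                            seed = 102)
  expect_equal(igraph::ecount(net2), 0L)
  # negative absdiff coefficient is recovered with a negative estimate
  set.seed(41)
  ests <- replicate(10, {
    a <- data.frame(x = runif(120))
    g <- generate_dyad_independent_network(
      a, list(term_edges(), term_absdiff("x")), c(-1, -2))
    coef(fit_ergm(g, list(term_edges(), term_absdiff("x"))))["absdiff.x"]
  })
  expect_lt(mean(ests), 0)
  expect_lt(abs(mean(ests) - (-2)), 0.5)
})

test_that("reproducibility: same seed, same simulated network and fit", {
  at <- data.frame(x = runif(30), g = sample(c("a", "b"), 30, TRUE))
  terms <- list(term_edges(), term_absdiff("x"))
  n1 <- generate_dyad_independent_network(at, terms, c(-0.5, -1), seed = 5)
  n2 <- generate_dyad_independent_network(at, terms, c(-0.5, -1), seed = 5)
  expect_identical(igraph::as_edgelist(n1), igraph::as_edgelist(n2))
  expect_identical(coef(fit_ergm(n1, terms)), coef(fit_ergm(n2, terms)))
})
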