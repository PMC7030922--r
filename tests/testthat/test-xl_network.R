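test_that("the interaction graph aggregates unique links and honors exclusions", {
  df <- rbind(links_df("A", 1, "B", 5, sample = "s1"),
              links_df("A", 2, "B", 9, sample = "s2"),
              links_df("A", 3, "A", 8, sample = "s1"))
  g <- build_network(xl_dataset(df))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 2)
  expect_equal(igraph::E(g)$sample_count, 2)
  expect_equal(igraph::vcount(build_network(xl_dataset(df), exclude = "A")), 0)
  # ambiguous links dropped by default
  df$ambiguous <- c(TRUE, TRUE, FALSE)
  expect_equal(igraph::ecount(build_network(xl_dataset(df))), 0)
  expect_equal(igraph::ecount(build_network(xl_dataset(df),
                                            include_ambiguous = TRUE)), 1)
})

test_that("components split into core, side modules and remainder", {
  g <- igraph::make_graph(~ a - b - c - d - e)  # path of 5
  cp <- network_components(g)
  expect_equal(igraph::vcount(cp$core), 5)
  expect_length(cp$side_modules, 0)

  g2 <- igraph::graph_from_literal(k1:k2:k3:k4:k5 - k1:k2:k3:k4:k5,
                                   p1 - p2 - p3, q1 - q2)
  cp2 <- network_components(g2, k = 3)
  expect_equal(igraph::vcount(cp2$core), 5)
  expect_length(cp2$side_modules, 1)
  expect_equal(igraph::vcount(cp2$side_modules[[1]]), 3)
  expect_equal(cp2$remainder, c("q1", "q2"))

  # equal-size tie: the component holding the smallest name becomes core
  g3 <- igraph::make_graph(~ a - b - c, x - y - z)
  expect_message(cp3 <- network_components(g3), "tie")
  expect_true("a" %in% igraph::V(cp3$core)$name)
})

test_that("an exact power law fits with slope -2 and R-squared 1", {
  degs <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))  # f(d) = 64 d^-2
  g <- igraph::realize_degseq(degs)
  igraph::V(g)$name <- paste0("n", seq_along(degs))
  fit <- degree_powerlaw_fit(g)
  expect_equal(fit$slope, -2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(degree_powerlaw_fit(igraph::make_ring(10)), "degenerate")
})

test_that("the log-log fit equals a closed-form least-squares oracle", {
  net <- make_planted_network(4, 25, 0.3, 0.01, seed = 31)
  fit <- degree_powerlaw_fit(net$graph)
  x <- fit$points$log_degree; y <- fit$points$log_frequency
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$slope, slope, tolerance = 1e-9)
  expect_equal(fit$intercept, intercept, tolerance = 1e-9)
})

test_that("modularity matches closed forms and the matrix oracle", {
  net <- make_planted_network(3, 8, 0.5, 0.05, seed = 32)
  g <- net$graph
  one <- setNames(rep(1, igraph::vcount(g)), igraph::V(g)$name)
  expect_equal(newman_modularity(g, one), 0)

  tri2 <- igraph::graph_from_literal(a - b - c - a, d - e - f - d)
  memb <- setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "d", "e", "f"))
  expect_equal(newman_modularity(tri2, memb), 0.5)

  set.seed(33)
  for (i in 1:5) {
    rp <- setNames(sample(3, igraph::vcount(g), TRUE), igraph::V(g)$name)
    expect_equal(newman_modularity(g, rp), modularity_oracle(g, rp),
                 tolerance = 1e-12)
    expect_gte(newman_modularity(g, rp), -0.5)
    expect_lte(newman_modularity(g, rp), 1)
  }
  expect_error(newman_modularity(g, memb), "cover")
})

test_that("edge-betweenness clustering splits a barbell at the bridge", {
  g <- igraph::graph_from_literal(a1:a2:a3:a4 - a1:a2:a3:a4,
                                  b1:b2:b3:b4 - b1:b2:b3:b4, a1 - b1)
  part <- girvan_newman_cluster(g)
  expect_equal(part$n_clusters, 2)
  expect_equal(length(unique(part$membership[c("a1", "a2", "a3", "a4")])), 1)
  expect_equal(length(unique(part$membership[c("b1", "b2", "b3", "b4")])), 1)
  expect_true(part$membership["a1"] != part$membership["b1"])
})

test_that("a complete graph stays one community with Q = 0", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  part <- girvan_newman_cluster(k5)
  expect_equal(part$n_clusters, 1)
  expect_equal(part$modularity, 0)
})

test_that("clustering is deterministic and recovers planted modules", {
  net <- make_planted_network(4, 25, 0.3, 0.01, seed = 42)
  p1 <- girvan_newman_cluster(net$graph)
  p2 <- girvan_newman_cluster(net$graph)
  expect_identical(p1$membership, p2$membership)
  expect_gte(ari(p1$membership[names(net$membership)], net$membership), 0.9)
  # our Q of the chosen partition agrees with igraph's implementation
  expect_equal(p1$modularity,
               igraph::modularity(net$graph,
                                  p1$membership[igraph::V(net$graph)$name]),
               tolerance = 1e-12)
})

test_that("rewiring preserves degrees, fixes stars and moves cycles", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  ens <- rewire_null(star, n_iter = 5, seed = 1)
  el0 <- igraph::as_edgelist(star)
  for (g in ens$graphs)
    expect_equal(igraph::as_edgelist(g), el0)  # no legal swap exists

  net <- make_planted_network(3, 10, 0.5, 0.05, seed = 34)
  ens2 <- rewire_null(net$graph, n_iter = 20, seed = 2)
  d0 <- igraph::degree(net$graph)
  for (g in ens2$graphs)
    expect_identical(igraph::degree(g)[names(d0)], d0)

  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("r", 1:6)
  ens3 <- rewire_null(ring, n_iter = 10, seed = 3)
  key <- function(g) paste(sort(apply(igraph::as_edgelist(g), 1,
    function(e) paste(sort(e), collapse = "-"))), collapse = ";")
  expect_true(any(vapply(ens3$graphs, key, character(1)) != key(ring)))
})

test_that("co-annotation fractions behave on planted and saturated terms", {
  net <- make_planted_network(4, 25, 0.3, 0.01, seed = 35)
  ens <- rewire_null(net$graph, n_iter = 30, seed = 4)
  allterm <- annotation_set(data.frame(term = "ALL",
                                       accession = igraph::V(net$graph)$name))
  ca <- coannotation_statistic(net$graph, allterm, ens, min_proteins = 0)
  expect_equal(ca$per_term$observed, 1)

  ca2 <- coannotation_statistic(net$graph, net$annotation, ens,
                                min_proteins = 0)
  expect_true(all(ca2$per_term$observed > ca2$per_term$null_mean))
  expect_true(all(ca2$per_term$observed >= 0 & ca2$per_term$observed <= 1))

  expect_warning(
    coannotation_statistic(net$graph,
                           annotation_set(data.frame(term = c("ALL", "GHOST"),
                                                     accession = c(igraph::V(net$graph)$name[1],
                                                                   "NOBODY"))),
                           ens, terms = c("ALL", "GHOST"), min_proteins = 0),
    "skipped")
})

test_that("path distances separate annotated from non-annotated nodes", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("a", "b", "c", "d")
  ann <- annotation_set(data.frame(term = "T", accession = c("a", "b", "c", "d")))
  expect_equal(path_distance_statistic(k4, ann, "T")$mean_within, 1)

  pg <- igraph::make_graph(~ A - B - C - D)
  ann2 <- annotation_set(data.frame(term = "T", accession = c("A", "B")))
  ps <- path_distance_statistic(pg, ann2, "T")
  expect_equal(ps$mean_within, 1)
  expect_equal(ps$mean_between, 2)  # mean of d(A,C)=2 d(A,D)=3 d(B,C)=1 d(B,D)=2

  net <- make_planted_network(4, 25, 0.3, 0.01, seed = 36)
  for (t in unique(net$annotation$term)) {
    ps <- path_distance_statistic(net$graph, net$annotation, t)
    expect_lt(ps$mean_within, ps$mean_between)
  }
})

test_that("term enrichment ranks a perfectly matching term first", {
  cluster <- sprintf("c%02d", 1:10)
  bg <- c(cluster, sprintf("o%02d", 1:10))
  ann <- annotation_set(data.frame(
    term = c(rep("HIT", 10), rep("SPREAD", 10)),
    accession = c(cluster, bg[seq(1, 20, 2)])))
  enr <- term_enrichment(cluster, ann, bg)
  expect_equal(enr$term[1], "HIT")
  spread <- enr[enr$term == "SPREAD", ]
  expect_lte(spread$fold, 1 + 1e-9)
  expect_gte(spread$p, 0.5)
  expect_error(term_enrichment(cluster, ann, character(0)), "background")
  expect_error(term_enrichment(c(cluster, "zz"), ann, bg), "contain")
})

test_that("Fisher enrichment p equals the exhaustive hypergeometric tail", {
  # 2x2 table (8,2,2,8): 10-node cluster, term covers 8 inside + 2 outside
  cluster <- sprintf("c%02d", 1:10)
  outside <- sprintf("o%02d", 1:10)
  ann <- annotation_set(data.frame(term = "T",
                                   accession = c(cluster[1:8], outside[1:2])))
  enr <- term_enrichment(cluster, ann, c(cluster, outside))
  expect_equal(enr$p[1], hyper_tail_greater(8, 2, 2, 8), tolerance = 1e-12)
})
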