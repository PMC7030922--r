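test_that("tier rules reproduce every boundary of the classification scheme", {
  expect_equal(classify_tier("string", 399), "low")
  expect_equal(classify_tier("string", 400), "medium")
  expect_equal(classify_tier("string", 699.9), "medium")
  expect_equal(classify_tier("string", 700), "high")
  expect_equal(classify_tier("inweb", NA), "low")
  expect_equal(classify_tier("inweb", 0.19), "low")
  expect_equal(classify_tier("inweb", 0.2), "medium")
  expect_equal(classify_tier("inweb", 0.7), "high")
  expect_equal(classify_tier("biogrid", NA, TRUE), "high")
  expect_equal(classify_tier("biogrid", NA, FALSE), "low")
  expect_error(classify_tier("intact", 1), "unknown")
})

test_that("tier classification is total and deterministic over random scores", {
  set.seed(51)
  src <- sample(c("string", "inweb", "biogrid"), 500, TRUE)
  sc <- ifelse(runif(500) < 0.1, NA,
               ifelse(src == "string", runif(500, 0, 1200), runif(500)))
  lt <- sample(c(TRUE, FALSE, NA), 500, TRUE)
  t1 <- classify_tier(src, sc, lt)
  expect_true(all(t1 %in% c("low", "medium", "high")))
  expect_identical(t1, classify_tier(src, sc, lt))
})

test_that("pair overlap fractions follow the evidence exactly", {
  pairs <- data.frame(protein_a = c("A", "C"), protein_b = c("B", "D"))
  empty <- evidence_records(data.frame(protein_a = character(0),
                                       protein_b = character(0),
                                       source = character(0)))
  ov0 <- pair_overlap(pairs, empty)
  expect_equal(ov0$fraction_in_db, 0)
  expect_equal(ov0$fraction_high, 0)

  ev <- evidence_records(data.frame(protein_a = c("A", "C"),
                                    protein_b = c("B", "D"),
                                    source = "string", score = 800))
  ov1 <- pair_overlap(pairs, ev)
  expect_equal(ov1$fraction_in_db, 1)
  expect_equal(ov1$fraction_high, 1)
  # invariant chain: high <= in-db <= total
  expect_lte(ov1$n_high_confidence, ov1$n_in_any_db)
  expect_lte(ov1$n_in_any_db, ov1$n_pairs)

  # the max tier over records decides: low + high record -> high pair
  ev2 <- evidence_records(data.frame(protein_a = c("A", "A"),
                                     protein_b = c("B", "B"),
                                     source = c("string", "biogrid"),
                                     score = c(100, NA),
                                     low_throughput = c(NA, TRUE)))
  ov2 <- pair_overlap(pairs, ev2)
  expect_equal(ov2$per_pair$tier, c("high", NA))
  expect_equal(ov2$n_in_any_db, 1)
})

test_that("overlap fractions on a synthetic world equal the generator truth", {
  pairs <- data.frame(protein_a = sprintf("A%03d", 1:300),
                      protein_b = sprintf("B%03d", 1:300))
  ev <- make_evidence_db(pairs, c(low = 0.3, medium = 0.3, high = 0.4),
                         seed = 52)
  ov <- pair_overlap(pairs, ev)
  truth <- attr(ev, "truth")
  expect_equal(ov$fraction_in_db, 1)
  expect_equal(ov$fraction_high, mean(truth$tier == "high"))
})

test_that("replicate multiplicities count designed overlaps and ignore order", {
  # 5 pairs in all three, 3 in two, 7 in one
  all3 <- links_df(sprintf("T%02d", 1:5), 10, sprintf("U%02d", 1:5), 20)
  two <- links_df(sprintf("V%02d", 1:3), 10, sprintf("W%02d", 1:3), 20)
  one <- links_df(sprintf("X%02d", 1:7), 10, sprintf("Y%02d", 1:7), 20)
  d1 <- xl_dataset(rbind(all3, two, one[1:3, ]))
  d2 <- xl_dataset(rbind(all3, two, one[4:5, ]))
  d3 <- xl_dataset(rbind(all3, one[6:7, ]))
  ro <- replicate_overlap(list(d1, d2, d3))
  expect_equal(unname(ro$histogram), c(7, 3, 5))
  expect_equal(sum(ro$histogram), ro$n_pairs)
  ro2 <- replicate_overlap(list(d3, d1, d2))
  expect_identical(ro$multiplicity, ro2$multiplicity)

  same <- replicate_overlap(list(d1, d1, d1))
  expect_true(all(same$multiplicity == 3))
  expect_error(replicate_overlap(list(d1)), "at least 2")
})

test_that("neighbor agreement classifies edges and sums to one", {
  net <- function(df) build_network(xl_dataset(df))
  ga <- net(links_df("A", 1, "C", 2))
  gb_same <- net(links_df("A", 3, "C", 4))
  r <- neighbor_agreement(ga, gb_same)
  expect_equal(r$direct, 1)

  gb_path <- net(rbind(links_df("A", 1, "B", 2), links_df("B", 3, "C", 4)))
  r2 <- neighbor_agreement(ga, gb_path)
  expect_equal(r2$indirect, 1)
  expect_equal(r2$direct + r2$indirect + r2$unconnected, 1)

  expect_error(neighbor_agreement(ga, net(links_df("X", 1, "Y", 2))), "shared")
})

test_that("neighbor agreement equals an exhaustive per-edge oracle", {
  set.seed(53)
  mk_rand <- function(seed) {
    set.seed(seed)
    df <- links_df(sample(LETTERS[1:12], 40, TRUE), sample(9, 40, TRUE),
                   sample(LETTERS[1:12], 40, TRUE), sample(9, 40, TRUE) + 10)
    df <- df[df$protein_a != df$protein_b, ]
    build_network(xl_dataset(df))
  }
  ga <- mk_rand(54); gb <- mk_rand(55)
  r <- neighbor_agreement(ga, gb)
  shared <- intersect(igraph::V(ga)$name, igraph::V(gb)$name)
  eb <- igraph::as_edgelist(gb)
  bkey <- paste(pmin(eb[, 1], eb[, 2]), pmax(eb[, 1], eb[, 2]))
  adj <- function(v) unique(c(eb[eb[, 1] == v, 2], eb[eb[, 2] == v, 1]))
  ea <- igraph::as_edgelist(ga)
  ea <- ea[ea[, 1] %in% shared & ea[, 2] %in% shared, , drop = FALSE]
  cls <- vapply(seq_len(nrow(ea)), function(i) {
    a <- ea[i, 1]; b <- ea[i, 2]
    if (paste(min(a, b), max(a, b)) %in% bkey) "direct"
    else if (length(intersect(adj(a), adj(b))) > 0) "indirect"
    else "unconnected"
  }, character(1))
  expect_equal(r$direct, mean(cls == "direct"))
  expect_equal(r$indirect, mean(cls == "indirect"))
  expect_equal(r$unconnected, mean(cls == "unconnected"))
})

test_that("cluster consistency separates structured from shuffled labels", {
  net <- make_planted_network(4, 20, 0.35, 0.02, seed = 56)
  part <- setNames(net$membership, names(net$membership))
  ens <- rewire_null(net$graph, n_iter = 25, seed = 57)
  cc <- cluster_consistency(net$graph, part, ens)
  expect_gt(mean(cc$observed), mean(unlist(cc$null)))
  expect_lt(cc$ks$p.value, 0.01)

  # resampled graph from the same planted partition stays consistent
  net2 <- make_planted_network(4, 20, 0.35, 0.02, seed = 58)
  cc2 <- cluster_consistency(net2$graph, part, rewire_null(net2$graph, 25, 59))
  expect_lt(cc2$ks$p.value, 0.01)

  set.seed(60)
  shuf <- setNames(sample(part), names(part))
  cc3 <- cluster_consistency(net$graph, shuf, ens)
  expect_lt(abs(mean(cc3$observed) - mean(unlist(cc3$null))), 0.1)
})

test_that("lysine-corrected abundance correlation hits closed-form cases", {
  # exact linear relation on log scales -> R^2 = 1
  seqK <- paste(c(rep("K", 16), rep("A", 4)), collapse = "")
  rec <- protein_records(setNames(rep(seqK, 4), sprintf("P%d", 1:4)))
  n_linked <- c(1, 2, 4, 8)
  links <- do.call(rbind, lapply(1:4, function(i)
    links_df(sprintf("P%d", i), seq_len(n_linked[i]), "HUB", 100 + seq_len(n_linked[i]))))
  ds <- xl_dataset(links)
  ab <- setNames(16 * 10^(2 * log10(n_linked) + 1), sprintf("P%d", 1:4))
  r <- abundance_lysine_correlation(ds, ab, rec)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$n_proteins, 4)  # the hub has no abundance/sequence

  expect_error(abundance_lysine_correlation(
    ds, setNames(rep(1000, 4), sprintf("P%d", 1:4)), rec), "constant")

  # matches a direct Pearson oracle on uneven data
  ab2 <- setNames(c(2000, 31000, 170, 9000), sprintf("P%d", 1:4))
  r2 <- abundance_lysine_correlation(ds, ab2, rec)
  x <- log10(ab2 / 16); y <- log10(n_linked)
  expect_equal(r2$r_squared, cor(x, y)^2, tolerance = 1e-9)
})
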