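test_that("cross-species lysine mapping requires an identical prefix", {
  s <- "MAKRTKLLWKDE"
  expect_true(map_lysine_cross_species(s, s, 3)$confident)
  # mismatch immediately before the lysine breaks the mapping
  d <- s; substr(d, 5, 5) <- "A"
  expect_false(map_lysine_cross_species(s, d, 6)$confident)
  # mismatch after the lysine does not
  d2 <- s; substr(d2, 8, 8) <- "A"
  expect_true(map_lysine_cross_species(s, d2, 6)$confident)
  # short destination cannot host the position
  expect_false(map_lysine_cross_species(s, "MAK", 6)$confident)
  expect_error(map_lysine_cross_species(s, s, 99), "out of range")
  expect_error(map_lysine_cross_species(s, s, 2), "not lysine")
})

test_that("a mismatch leaves exactly the downstream lysines unmapped", {
  # 12 lysines every 5 residues; mismatch between lysine 9 and 10
  src <- paste(rep("AAAAK", 12), collapse = "")
  kpos <- seq(5, 60, by = 5)
  dst <- src
  substr(dst, 47, 47) <- "C"  # between K45 and K50
  conf <- vapply(kpos, function(p)
    map_lysine_cross_species(src, dst, p)$confident, logical(1))
  expect_equal(sum(conf), 9)
  expect_true(all(conf[kpos < 47]))
  expect_false(any(conf[kpos > 47]))
})

test_that("prefix mapping is transitive across three orthologs", {
  set.seed(61)
  for (i in 1:20) {
    base <- paste(sample(c("A", "K", "L", "S"), 40, TRUE), collapse = "")
    mutate <- function(s) {
      p <- sample(40, 1)
      substr(s, p, p) <- sample(c("A", "C", "L", "S"), 1)
      s
    }
    sb <- mutate(base); sc <- mutate(sb)
    kpos <- which(strsplit(base, "")[[1]] == "K")
    for (p in kpos) {
      ab <- map_lysine_cross_species(base, sb, p)$confident
      bc <- if (substr(sb, p, p) == "K")
        map_lysine_cross_species(sb, sc, p)$confident else FALSE
      if (ab && bc)
        expect_true(map_lysine_cross_species(base, sc, p)$confident)
    }
  }
})

test_that("interface enrichment covers the trivial and oracle cases", {
  bg <- sprintf("P:%d", 1:100)
  linked <- bg[1:50]
  r <- interface_enrichment(linked, linked, bg)
  expect_equal(r$fraction_linked_in_interface, 1)
  expect_lt(r$p, 1e-5)

  r0 <- interface_enrichment(linked, character(0), bg)
  expect_equal(r0$fraction_linked_in_interface, 0)
  expect_equal(r0$p, 1)

  # 2x2 table (40,60,20,80) against exhaustive two-sided enumeration
  bg2 <- sprintf("Q:%d", 1:200)
  linked2 <- bg2[1:100]
  iface <- c(bg2[1:40], bg2[101:120])
  r2 <- interface_enrichment(linked2, iface, bg2)
  expect_equal(unname(r2$table[1, ]), c(40, 20))
  expect_equal(r2$p, hyper_two_sided(40, 60, 20, 80), tolerance = 1e-12)
  expect_error(interface_enrichment("Z:1", iface, bg2), "subset")
  expect_error(interface_enrichment(character(0), iface, character(0)),
               "empty background")
})

simple_exp <- function(signal, bg = 0, pos = 100, neg = 0, n_rep = 1) {
  n <- length(signal)
  array_experiment(
    data.frame(spot = 1:n, peptide = strrep("A", 10),
               start = seq(1, by = 5, length.out = n),
               end = seq(1, by = 5, length.out = n) + 14),
    matrix(rep(signal, n_rep), ncol = n_rep),
    background = rep(bg, n_rep), positive = rep(pos, n_rep),
    negative = matrix(neg, 3, n_rep))
}

test_that("array quantification normalizes to the positive control", {
  q <- quantify_array(simple_exp(50))
  expect_equal(q[1], 0.5)
  # spot identical to the nonspecific control quantifies to zero
  e <- simple_exp(c(30, 80)); ctrl <- simple_exp(c(30, 10))
  q2 <- quantify_array(e, ctrl)
  expect_equal(q2[1], 0)
  expect_equal(q2[2], 0.7)
  expect_error(quantify_array(simple_exp(50, bg = 100, pos = 90)),
               "positive control")
})

test_that("quantification is linear in the raw signal before clipping", {
  set.seed(62)
  s1 <- runif(8, 0, 80); s2 <- runif(8, 0, 80)
  q <- function(s) quantify_array(simple_exp(s), clip = FALSE)
  expect_equal(q(0.3 * s1 + 0.7 * s2), 0.3 * q(s1) + 0.7 * q(s2),
               tolerance = 1e-12)
})

test_that("planted array amplitude is recovered within 5% at 5% noise", {
  sim <- simulate_array(amplitude = 1, noise_sd = 0.05, seed = 63)
  q <- quantify_array(sim$exp, sim$control)
  rec <- mean(q[sim$truth$in_region])
  expect_lt(abs(rec - sim$truth$amplitude), 0.05 * sim$truth$amplitude)
})

test_that("binding regions need two overlapping positive peptides", {
  tiling <- data.frame(start = c(1, 11, 41), end = c(20, 30, 60))
  # isolated single positive spot: no region
  r1 <- call_binding_regions(c(0, 0, 5), tiling, threshold = 1)
  expect_equal(nrow(r1), 0)
  # two overlapping positives merge into one region spanning their union
  r2 <- call_binding_regions(c(5, 5, 0), tiling, threshold = 1)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end, r2$n_peptides), c(1, 30, 2))
})

test_that("planted regions are recovered without spurious calls", {
  sim <- simulate_array(amplitude = 1, noise_sd = 0.05, seed = 64)
  q <- quantify_array(sim$exp, sim$control)
  thr <- array_signal_threshold(quantify_array(sim$control))
  regions <- call_binding_regions(q, sim$exp$peptides, thr)
  expect_equal(nrow(regions), length(sim$truth$regions))
  for (i in seq_along(sim$truth$regions)) {
    planted <- sim$truth$regions[[i]]
    hit <- regions$start <= planted[2] & regions$end >= planted[1]
    expect_true(any(hit))
  }
  # regions never overlap after union-merge
  if (nrow(regions) > 1)
    expect_true(all(regions$start[-1] > regions$end[-nrow(regions)]))
})

test_that("link-to-region distances match a brute-force scan", {
  regions <- structure(data.frame(start = c(65, 120), end = c(90, 140),
                                  n_peptides = 2L),
                       class = c("binding_regions", "data.frame"))
  ds <- xl_dataset(links_df(c("T", "T", "X"), c(70, 45, 5),
                            c("U", "V", "T"), c(9, 9, 130)))
  px <- region_link_proximity(regions, ds, "T")
  expect_equal(px$distance[px$position == 70], 0)
  expect_equal(px$distance[px$position == 45], 20)
  expect_equal(px$distance[px$position == 130], 0)
  # brute-force oracle over random positions
  set.seed(65)
  pos <- sample(200, 30)
  ds2 <- xl_dataset(links_df("T", pos, "U", 300 + seq_along(pos)))
  px2 <- region_link_proximity(regions, ds2, "T")
  oracle <- vapply(px2$position, function(p) {
    covered <- any(p >= regions$start & p <= regions$end)
    if (covered) 0 else min(abs(p - c(regions$start, regions$end)))
  }, numeric(1))
  expect_equal(px2$distance, oracle)
  # no regions: distances undefined
  none <- call_binding_regions(numeric(0), data.frame(start = integer(0),
                                                      end = integer(0)), 1)
  expect_true(all(is.na(region_link_proximity(none, ds, "T")$distance)))
})
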