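# Ground-truth synthetic worlds: toy structures, cross-link sets with a
# controlled violation rate, topology-labelled links with a controlled
# cross-side rate, abundance-driven replicate detection, planted-module
# networks with aligned annotations, scored mock evidence databases and
# planted peptide arrays. Every generator is deterministic given its seed.

#' Random-walk toy protein complex
#'
#' Each chain is a self-avoiding random walk with fixed 3.8 A steps
#' (consecutive Calpha spacing) and a minimum 4.0 A separation between
#' non-adjacent residues; chains are offset along x so the complex is
#' contiguous but never closer than the separation floor. About 15% of
#' residues are assigned lysine (typical lysine frequency), the rest drawn
#' from the remaining 19 letters.
#'
#' @param n_chains number of chains (>= 1); accessions `SYNP01`, ... map
#'   one-to-one onto chains `A`, `B`, ...
#' @param n_res residues per chain (>= 5).
#' @param seed RNG seed.
#' @param lysine_rate lysine assignment probability (default 0.15).
#' @param step Calpha step length in Angstrom (default 3.8).
#' @param min_sep minimum non-adjacent separation in Angstrom (default 4).
#' @return list with `model` ([structure_model()]), `records`
#'   (`AAStringSet`) and `maps` (identity [build_chain_map()] list).
#' @export
make_toy_complex <- function(n_chains, n_res, seed, lysine_rate = 0.15,
                             step = 3.8, min_sep = 4.0) {
  stopifnot(n_chains >= 1, n_res >= 5)
  aa20 <- strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]]  # 19 letters, K separate
  with_seed(seed, {
    chains <- list()
    seqs <- character(0)
    x_off <- 0
    for (ci in seq_len(n_chains)) {
      coords <- matrix(NA_real_, n_res, 3)
      coords[1, ] <- c(0, 0, 0)
      restarts <- 0
      i <- 2
      while (i <= n_res) {
        placed <- FALSE
        for (try in seq_len(200)) {
          dir <- rnorm(3)
          cand <- coords[i - 1, ] + step * dir / sqrt(sum(dir^2))
          if (i > 2) {
            prev <- coords[seq_len(i - 2), , drop = FALSE]
            d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
              (prev[, 3] - cand[3])^2
            if (min(d2) < min_sep^2) next
          }
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) {
          restarts <- restarts + 1
          if (restarts > 50)
            stop("self-avoiding walk failed repeatedly; try a smaller n_res")
          i <- 2
          next
        }
        i <- i + 1
      }
      # shift chain so its minimum x sits min_sep beyond everything placed
      coords[, 1] <- coords[, 1] - min(coords[, 1]) + x_off
      x_off <- max(coords[, 1]) + min_sep
      aa <- ifelse(runif(n_res) < lysine_rate, "K",
                   sample(aa20, n_res, replace = TRUE))
      ch <- LETTERS[ci]
      chains[[ch]] <- data.frame(auth_number = seq_len(n_res), aa = aa,
                                 x = coords[, 1], y = coords[, 2],
                                 z = coords[, 3], present = TRUE,
                                 stringsAsFactors = FALSE)
      seqs[sprintf("SYNP%02d", ci)] <- paste(aa, collapse = "")
    }
    model <- structure_model(chains, sprintf("toy%d", seed))
    records <- protein_records(seqs)
    maps <- lapply(seq_len(n_chains), function(ci)
      build_chain_map(records[ci], model, LETTERS[ci],
                      accession = names(records)[ci]))
    list(model = model, records = records, maps = maps)
  })
}

# lysine sites of a toy complex: accession, position, chain, residue index
lysine_sites <- function(model, maps) {
  rows <- lapply(maps, function(mp) {
    ch <- model$chains[[mp$chain_id]]
    pos <- as.integer(names(mp$mapping))
    idx <- unname(mp$mapping)
    k <- ch$aa[idx] == "K" & ch$present[idx]
    data.frame(accession = mp$accession, pos = pos[k],
               chain = mp$chain_id, idx = idx[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate cross-links from a structure with a known violation rate
#'
#' Enumerates all lysine pairs of the complex, splits them at the
#' restraint `threshold` and draws `round((1 - violation_rate) * n_links)`
#' unique links from the satisfied stratum and the rest from the violating
#' stratum, without replacement. The generating parameters are attached as
#' the `truth` attribute.
#'
#' @param model a [structure_model()].
#' @param maps chain maps covering the lysines.
#' @param n_links number of links to draw.
#' @param violation_rate fraction of links drawn beyond the threshold.
#' @param threshold restraint limit in Angstrom (default 33.4).
#' @param seed RNG seed.
#' @param fdr_threshold FDR cap for the simulated identifications.
#' @return an [xl_dataset()] with attribute `truth`.
#' @export
simulate_crosslinks <- function(model, maps, n_links, violation_rate,
                                threshold = XL_DEFAULT_THRESHOLD, seed = 1,
                                fdr_threshold = 0.02) {
  stopifnot(violation_rate >= 0, violation_rate <= 1)
  sites <- lysine_sites(model, maps)
  if (nrow(sites) < 2) stop("fewer than 2 lysines in the complex")
  pr <- utils::combn(nrow(sites), 2)
  d <- vapply(seq_len(ncol(pr)), function(j)
    ca_distance(model, sites$chain[pr[1, j]], sites$idx[pr[1, j]],
                sites$chain[pr[2, j]], sites$idx[pr[2, j]]), numeric(1))
  sat <- which(d <= threshold)
  viol <- which(d > threshold)
  n_viol <- round(violation_rate * n_links)
  n_sat <- n_links - n_viol
  if (n_sat > 0 && length(sat) == 0)
    stop("no lysine pair within the threshold: cannot draw satisfied links")
  if (n_viol > 0 && length(viol) == 0)
    stop("no lysine pair beyond the threshold: cannot draw violating links")
  if (n_sat > length(sat) || n_viol > length(viol))
    stop(sprintf("not enough unique lysine pairs (have %d satisfied / %d violating, need %d / %d)",
                 length(sat), length(viol), n_sat, n_viol))
  with_seed(seed, {
    pick <- c(if (n_sat > 0) sample(sat, n_sat),
              if (n_viol > 0) sample(viol, n_viol))
    df <- data.frame(
      protein_a = sites$accession[pr[1, pick]],
      pos_a = sites$pos[pr[1, pick]],
      protein_b = sites$accession[pr[2, pick]],
      pos_b = sites$pos[pr[2, pick]],
      fdr = runif(length(pick), 0, fdr_threshold),
      sample = "sim1", stringsAsFactors = FALSE)
    ds <- xl_dataset(df, name = "simulated_crosslinks",
                     fdr_threshold = fdr_threshold)
    attr(ds, "truth") <- list(violation_rate = violation_rate,
                              n_links = n_links, n_violating = n_viol,
                              threshold = threshold, seed = seed)
    ds
  })
}

#' Simulate topology-labelled cross-links with a known cross-side rate
#'
#' Builds membrane proteins with a fixed region layout (cytoplasmic
#' 1-100, transmembrane 101-120, extracellular 121-220) and draws
#' interprotein links whose endpoints fall on the same side with
#' probability `1 - cross_side_rate` and on opposite sides otherwise
#' (independent Bernoulli draws per link).
#'
#' @param n_links number of link draws (duplicates collapse on dedup).
#' @param cross_side_rate probability of a cytoplasmic-extracellular link.
#' @param n_proteins number of membrane proteins.
#' @param seed RNG seed.
#' @return list with `links` ([xl_dataset()]), `topology` (region
#'   data.frame) and `truth`.
#' @export
simulate_topology <- function(n_links, cross_side_rate, n_proteins = 40,
                              seed = 1) {
  stopifnot(cross_side_rate >= 0, cross_side_rate <= 1, n_proteins >= 2)
  accs <- sprintf("MEMP%03d", seq_len(n_proteins))
  topology <- do.call(rbind, lapply(accs, function(a)
    data.frame(accession = a,
               start = c(1, 101, 121), end = c(100, 120, 220),
               label = c("cytoplasmic", "transmembrane", "extracellular"),
               stringsAsFactors = FALSE)))
  draw_pos <- function(side, n)
    ifelse(side == "cytoplasmic", sample(100, n, replace = TRUE),
           sample(100, n, replace = TRUE) + 120)
  with_seed(seed, {
    ij <- t(vapply(seq_len(n_links), function(i) sample(n_proteins, 2),
                   integer(2)))
    cross <- runif(n_links) < cross_side_rate
    side_a <- sample(c("cytoplasmic", "extracellular"), n_links, replace = TRUE)
    side_b <- ifelse(cross,
                     ifelse(side_a == "cytoplasmic", "extracellular", "cytoplasmic"),
                     side_a)
    df <- data.frame(protein_a = accs[ij[, 1]],
                     pos_a = draw_pos(side_a, n_links),
                     protein_b = accs[ij[, 2]],
                     pos_b = draw_pos(side_b, n_links),
                     fdr = 0, sample = "sim1", stringsAsFactors = FALSE)
    links <- xl_dataset(df, name = "simulated_topology_links")
    attr(links, "truth") <- list(cross_side_rate = cross_side_rate,
                                 n_links = n_links,
                                 n_cross_drawn = sum(cross), seed = seed)
    list(links = links, topology = topology,
         truth = attr(links, "truth"))
  })
}

#' Log-normal protein abundances
#'
#' @param accessions protein names.
#' @param seed RNG seed.
#' @param meanlog10,sdlog10 location/scale of log10 abundance (defaults 6
#'   and 1, a typical dynamic range of label-free protein intensities).
#' @export
simulate_protein_abundances <- function(accessions, seed = 1,
                                        meanlog10 = 6, sdlog10 = 1) {
  with_seed(seed,
            setNames(10^rnorm(length(accessions), meanlog10, sdlog10),
                     accessions))
}

#' Simulate replicate detection driven by protein abundance
#'
#' Each protein pair is detected in each replicate independently with
#' probability `plogis(intercept + slope * log10(min abundance of the two
#' partners))`: detection of a pair is limited by its scarcer protein.
#' The logistic form is a modelling stand-in; the phenomenon it emulates
#' is that pairs found in more replicates have higher-abundance proteins.
#'
#' @param pairs data.frame with `protein_a`, `protein_b`.
#' @param abundances named positive abundance vector covering the pairs.
#' @param n_reps number of replicates (default 3).
#' @param slope,intercept logistic coefficients (defaults 1.5 and -9: a
#'   pair whose limiting protein sits at abundance 1e6 is detected with
#'   probability 0.5).
#' @param seed RNG seed.
#' @return list with `datasets` (list of [xl_dataset()], one per
#'   replicate) and `truth` (detection probabilities and matrix).
#' @export
simulate_replicates <- function(pairs, abundances, n_reps = 3, slope = 1.5,
                                intercept = -9, seed = 1) {
  if (any(abundances <= 0)) stop("abundances must be positive")
  ab_min <- pmin(abundances[pairs$protein_a], abundances[pairs$protein_b])
  p <- plogis(intercept + slope * log10(ab_min))
  n <- nrow(pairs)
  with_seed(seed, {
    det <- matrix(runif(n * n_reps) < rep(p, n_reps), nrow = n)
    datasets <- lapply(seq_len(n_reps), function(j) {
      hit <- which(det[, j])
      df <- data.frame(protein_a = pairs$protein_a[hit],
                       pos_a = rep(10L, length(hit)),
                       protein_b = pairs$protein_b[hit],
                       pos_b = rep(20L, length(hit)),
                       fdr = rep(0, length(hit)),
                       sample = rep(sprintf("rep%d", j), length(hit)),
                       stringsAsFactors = FALSE)
      xl_dataset(df, name = sprintf("replicate_%d", j))
    })
    list(datasets = datasets,
         truth = list(p = setNames(p, pair_key(pairs$protein_a, pairs$protein_b)),
                      detected = det, slope = slope, intercept = intercept,
                      seed = seed))
  })
}

#' Planted-partition network with module-aligned annotations
#'
#' Standard planted-partition (stochastic block) graph: edge probability
#' `p_in` within each of `k` modules of `size` nodes and `p_out` between
#' modules. One annotation term per module covers its members plus a
#' `spill` fraction of random outside nodes.
#'
#' @param k number of modules.
#' @param size nodes per module.
#' @param p_in,p_out within/between edge probabilities (`p_in > p_out`).
#' @param seed RNG seed.
#' @param spill spill-over fraction per term (default 0.1).
#' @return list with `graph` (igraph, named nodes), `edges` data.frame,
#'   `annotation` ([annotation_set()]), `membership` (planted truth).
#' @export
make_planted_network <- function(k, size, p_in, p_out, seed, spill = 0.1) {
  stopifnot(p_in > p_out)
  n <- k * size
  with_seed(seed, {
    pref <- matrix(p_out, k, k); diag(pref) <- p_in
    g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = rep(size, k))
    igraph::V(g)$name <- sprintf("NODE%03d", seq_len(n))
    membership <- setNames(rep(seq_len(k), each = size), igraph::V(g)$name)
    ann <- do.call(rbind, lapply(seq_len(k), function(ci) {
      members <- names(membership)[membership == ci]
      extra_n <- round(spill * size)
      outside <- setdiff(names(membership), members)
      extra <- if (extra_n > 0) sample(outside, extra_n) else character(0)
      data.frame(term = sprintf("MODTERM%d", ci),
                 accession = c(members, extra), stringsAsFactors = FALSE)
    }))
    e <- igraph::as_edgelist(g)
    list(graph = g,
         edges = data.frame(from = e[, 1], to = e[, 2],
                            stringsAsFactors = FALSE),
         annotation = annotation_set(ann),
         membership = membership,
         params = list(k = k, size = size, p_in = p_in, p_out = p_out,
                       spill = spill, seed = seed))
  })
}

#' Mock evidence database with known confidence tiers
#'
#' Assigns each pair a target tier drawn from `tier_mix`, picks a source
#' able to express that tier (BioGRID has no medium tier) and draws a
#' score inside the tier's range, so [classify_tier()] recovers the
#' sampled tier exactly.
#'
#' @param pairs data.frame with `protein_a`, `protein_b`.
#' @param tier_mix named fractions for `low`, `medium`, `high` (sum 1).
#' @param seed RNG seed.
#' @return evidence data.frame (see [evidence_records()]) with the
#'   sampled tiers as attribute `truth`.
#' @export
make_evidence_db <- function(pairs, tier_mix = c(low = 1/3, medium = 1/3,
                                                 high = 1/3), seed = 1) {
  if (abs(sum(tier_mix) - 1) > 1e-8) stop("tier fractions must sum to 1")
  n <- nrow(pairs)
  with_seed(seed, {
    tier <- sample(names(tier_mix), n, replace = TRUE, prob = tier_mix)
    source <- vapply(tier, function(t)
      if (t == "medium") sample(c("string", "inweb"), 1)
      else sample(c("string", "inweb", "biogrid"), 1), character(1))
    score <- rep(NA_real_, n)
    lt <- rep(NA, n)
    for (i in seq_len(n)) {
      if (source[i] == "string") {
        score[i] <- switch(tier[i], low = runif(1, 0, 399.99),
                           medium = runif(1, 400, 699.99),
                           high = runif(1, 700, 999))
      } else if (source[i] == "inweb") {
        score[i] <- switch(tier[i],
                           low = if (runif(1) < 0.5) NA_real_ else runif(1, 0, 0.199),
                           medium = runif(1, 0.2, 0.699),
                           high = runif(1, 0.7, 1))
      } else {
        lt[i] <- tier[i] == "high"
      }
    }
    ev <- evidence_records(data.frame(
      protein_a = pairs$protein_a, protein_b = pairs$protein_b,
      source = source, score = score, low_throughput = lt,
      stringsAsFactors = FALSE))
    attr(ev, "truth") <- list(tier = tier, tier_mix = tier_mix, seed = seed)
    ev
  })
}

#' Planted peptide tiling-array experiment
#'
#' Builds a tiled array over a target protein with binding regions of
#' known amplitude, a shared nonspecific component (also present in the
#' control experiment) and Gaussian noise, in raw fluorescence units
#' (background 10, positive control 110).
#'
#' @param protein_length residues of the target.
#' @param pep_len,offset peptide length and tiling offset (defaults 15/5,
#'   a typical CelluSpots layout).
#' @param regions list of `c(start, end)` planted binding regions.
#' @param amplitude normalized specific signal inside a region.
#' @param noise_sd Gaussian noise SD on the normalized scale.
#' @param nonspecific_max maximum of the per-spot uniform nonspecific
#'   component (default `0.2 * amplitude`).
#' @param n_reps technical replicates.
#' @param seed RNG seed.
#' @return list with `exp`, `control` ([array_experiment()]s) and `truth`
#'   (`in_region` spot flags, `amplitude`, `regions`).
#' @export
simulate_array <- function(protein_length = 120, pep_len = 15, offset = 5,
                           regions = list(c(30, 60), c(90, 110)),
                           amplitude = 1, noise_sd = 0.05,
                           nonspecific_max = 0.2 * amplitude,
                           n_reps = 2, seed = 1) {
  starts <- seq(1, protein_length - pep_len + 1, by = offset)
  peptides <- data.frame(spot = seq_along(starts), peptide = NA_character_,
                         start = starts, end = starts + pep_len - 1L)
  mid <- (peptides$start + peptides$end) / 2
  in_region <- vapply(mid, function(m)
    any(vapply(regions, function(r) m >= r[1] && m <= r[2], logical(1))),
    logical(1))
  bg <- 10; pos <- 110; denom <- pos - bg
  n_spots <- nrow(peptides)
  with_seed(seed, {
    aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    target_seq <- paste(sample(aa, protein_length, replace = TRUE),
                        collapse = "")
    peptides$peptide <- vapply(seq_len(n_spots), function(i)
      substr(target_seq, peptides$start[i], peptides$end[i]), character(1))
    nonspec <- runif(n_spots, 0, nonspecific_max)
    spec <- ifelse(in_region, amplitude, 0)
    raw <- function(level) bg + denom *
      pmax(matrix(level, n_spots, n_reps) +
             matrix(rnorm(n_spots * n_reps, 0, noise_sd), n_spots), 0)
    exp <- array_experiment(peptides, raw(spec + nonspec),
                            background = rep(bg, n_reps),
                            positive = rep(pos, n_reps),
                            negative = matrix(bg, 3, n_reps))
    control <- array_experiment(peptides, raw(nonspec),
                                background = rep(bg, n_reps),
                                positive = rep(pos, n_reps),
                                negative = matrix(bg, 3, n_reps))
    list(exp = exp, control = control,
         truth = list(in_region = in_region, amplitude = amplitude,
                      regions = regions, noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a complete synthetic world
#'
#' Bundles every generator with a single global seed fanned out to
#' per-generator streams by fixed offsets, so regenerating with the same
#' seed reproduces the world exactly while the generators stay decoupled.
#' Defaults define the reference study conditions used throughout the
#' package tests: an 8-chain, 100-residue toy complex (large enough that
#' both distance strata hold hundreds of unique lysine pairs) with 400
#' links at 10% violation rate, 2000 topology-labelled links at 2%
#' cross-side rate,
#' 500 abundance-driven replicate pairs over 3 replicates, a planted
#' 4 x 25 module network (p_in 0.3, p_out 0.01) and an evidence database
#' covering 51% of the network pairs such that 39% of all pairs carry a
#' high tier (the remaining covered pairs split evenly low/medium).
#'
#' @param seed global integer seed.
#' @param n_chains,n_res toy complex dimensions.
#' @param n_links,violation_rate cross-link simulation parameters.
#' @param n_topo_links,cross_side_rate topology simulation parameters.
#' @param n_pairs,n_reps replicate simulation parameters.
#' @param k,size,p_in,p_out planted network parameters.
#' @param evidence_coverage fraction of network pairs present in the
#'   evidence database.
#' @param tier_mix evidence tier fractions among covered pairs.
#' @return list of class `synthetic_world`.
#' @export
make_world <- function(seed = 1, n_chains = 8, n_res = 100, n_links = 400,
                       violation_rate = 0.1, n_topo_links = 2000,
                       cross_side_rate = 0.02, n_pairs = 500, n_reps = 3,
                       k = 4, size = 25, p_in = 0.3, p_out = 0.01,
                       evidence_coverage = 0.51,
                       tier_mix = c(low = 0.06, medium = 0.06, high = 0.39) / 0.51) {
  toy <- make_toy_complex(n_chains, n_res, seed = seed + 11L)
  links <- simulate_crosslinks(toy$model, toy$maps, n_links, violation_rate,
                               seed = seed + 13L)
  topo <- simulate_topology(n_topo_links, cross_side_rate, seed = seed + 23L)
  net <- make_planted_network(k, size, p_in, p_out, seed = seed + 41L)
  prot <- sprintf("RPRT%03d", seq_len(max(50, ceiling(n_pairs / 5))))
  pair_idx <- with_seed(seed + 31L,
                        t(vapply(seq_len(n_pairs), function(i)
                          sample(length(prot), 2), integer(2))))
  pairs <- unique(data.frame(protein_a = pmin(prot[pair_idx[, 1]], prot[pair_idx[, 2]]),
                             protein_b = pmax(prot[pair_idx[, 1]], prot[pair_idx[, 2]]),
                             stringsAsFactors = FALSE))
  abundances <- simulate_protein_abundances(prot, seed = seed + 29L)
  reps <- simulate_replicates(pairs, abundances, n_reps = n_reps,
                              seed = seed + 37L)
  net_pairs <- unique(data.frame(
    protein_a = pmin(net$edges$from, net$edges$to),
    protein_b = pmax(net$edges$from, net$edges$to),
    stringsAsFactors = FALSE))
  covered <- with_seed(seed + 47L,
                       net_pairs[runif(nrow(net_pairs)) < evidence_coverage, ,
                                 drop = FALSE])
  evidence <- make_evidence_db(covered, tier_mix, seed = seed + 53L)
  array_sim <- simulate_array(seed = seed + 67L)
  structure(list(
    seed = seed, model = toy$model, records = toy$records, maps = toy$maps,
    links = links, topology = topo$topology, topology_links = topo$links,
    pairs = pairs, abundances = abundances, replicates = reps$datasets,
    network = net, evidence = evidence, array = array_sim,
    truth = list(violation_rate = violation_rate,
                 cross_side_rate = cross_side_rate,
                 membership = net$membership,
                 detection = reps$truth,
                 evidence_tiers = attr(evidence, "truth"),
                 array = array_sim$truth)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world seed=%d> %d-chain complex, %d links, %d topology links, %d replicate pairs, %d-module network\n",
              x$seed, length(x$model$chains), nrow(x$links$links),
              nrow(x$topology_links$links), nrow(x$pairs),
              x$network$params$k))
  invisible(x)
}
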