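# Overlap of cross-linked protein pairs with external PPI evidence
# (STRING / InWEB / BioGRID style records with explicit confidence tiers),
# replicate-agreement summaries and abundance relations.

TIER_LEVELS <- c("low", "medium", "high")

#' Confidence tier of an external PPI evidence record
#'
#' STRING combined score: `< 400` low, `[400, 700)` medium, `>= 700` high.
#' InWEB final score: absent or `< 0.2` low, `[0.2, 0.7)` medium,
#' `>= 0.7` high. BioGRID: low-throughput experimental evidence high,
#' anything else low. Vectorized; total over the score domain.
#'
#' @param source `"string"`, `"inweb"` or `"biogrid"` (vectorized).
#' @param score numeric score, `NA` when the source provides none.
#' @param low_throughput logical, BioGRID only.
#' @return character vector of tiers (`low`/`medium`/`high`).
#' @export
classify_tier <- function(source, score = NA_real_, low_throughput = NA) {
  n <- length(source)
  score <- rep_len(as.numeric(score), n)
  low_throughput <- rep_len(as.logical(low_throughput), n)
  bad <- !(source %in% c("string", "inweb", "biogrid"))
  if (any(bad))
    stop("unknown evidence source: ", paste(unique(source[bad]), collapse = ", "))
  out <- character(n)
  i <- source == "string"
  out[i] <- ifelse(is.na(score[i]) | score[i] < 400, "low",
                   ifelse(score[i] < 700, "medium", "high"))
  i <- source == "inweb"
  out[i] <- ifelse(is.na(score[i]) | score[i] < 0.2, "low",
                   ifelse(score[i] < 0.7, "medium", "high"))
  i <- source == "biogrid"
  out[i] <- ifelse(!is.na(low_throughput[i]) & low_throughput[i], "high", "low")
  out
}

#' Overlap of cross-linked pairs with an evidence database
#'
#' A pair is "in a database" when any evidence record matches it, and
#' "high confidence" when the maximum tier over its records is high (the
#' convention of keeping only interactions with a high-confidence level in
#' at least one database). Optionally stratifies the cross-link-count
#' distribution by database presence and reports abundance medians (the
#' minimum of the two partners' abundances) for high-confidence vs absent
#' pairs.
#'
#' @param pairs data.frame with `protein_a`, `protein_b` (canonical
#'   order), e.g. from [network_pairs()].
#' @param evidence evidence data.frame from [read_evidence_table()] /
#'   [evidence_records()].
#' @param xl_counts optional named vector (pair key `A|B`) of unique
#'   cross-link counts per pair.
#' @param abundances optional named vector of protein abundances.
#' @return list of class `overlap_report`.
#' @export
pair_overlap <- function(pairs, evidence, xl_counts = NULL,
                         abundances = NULL) {
  pk <- pair_key(pairs$protein_a, pairs$protein_b)
  ek <- pair_key(evidence$protein_a, evidence$protein_b)
  tier_num <- match(evidence$tier, TIER_LEVELS)
  best <- tapply(tier_num, ek, max)
  tier <- rep(NA_character_, length(pk))
  hit <- pk %in% names(best)
  tier[hit] <- TIER_LEVELS[unlist(best[pk[hit]])]
  per_pair <- data.frame(
    protein_a = pmin(pairs$protein_a, pairs$protein_b),
    protein_b = pmax(pairs$protein_a, pairs$protein_b),
    in_db = pk %in% ek,
    tier = tier,
    stringsAsFactors = FALSE)
  if (!is.null(xl_counts)) per_pair$n_links <- unname(xl_counts[pk])
  n_pairs <- nrow(per_pair)
  n_in <- sum(per_pair$in_db)
  n_high <- sum(per_pair$tier == "high", na.rm = TRUE)
  out <- list(per_pair = per_pair, n_pairs = n_pairs,
              n_in_any_db = n_in, n_high_confidence = n_high,
              fraction_in_db = if (n_pairs > 0) n_in / n_pairs else NA_real_,
              fraction_high = if (n_pairs > 0) n_high / n_pairs else NA_real_)
  if (!is.null(xl_counts)) {
    out$xl_count_by_presence <- list(
      in_db = per_pair$n_links[per_pair$in_db],
      not_in_db = per_pair$n_links[!per_pair$in_db])
    out$median_links_in_db <- median(out$xl_count_by_presence$in_db)
    out$median_links_not_in_db <- median(out$xl_count_by_presence$not_in_db)
  }
  if (!is.null(abundances)) {
    ab_min <- pmin(abundances[per_pair$protein_a], abundances[per_pair$protein_b])
    hi <- !is.na(per_pair$tier) & per_pair$tier == "high"
    out$median_abundance_high <- median(ab_min[hi], na.rm = TRUE)
    out$median_abundance_absent <- median(ab_min[!per_pair$in_db], na.rm = TRUE)
  }
  structure(out, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d pairs: %d (%.0f%%) in a database, %d (%.0f%%) high confidence\n",
              x$n_pairs, x$n_in_any_db, 100 * x$fraction_in_db,
              x$n_high_confidence, 100 * x$fraction_high))
  invisible(x)
}

#' Protein pairs of a dataset (or network)
#'
#' Unique canonical interprotein pairs of a dataset with their unique
#' cross-link counts.
#' @param ds an [xl_dataset()].
#' @param include_ambiguous keep ambiguous links.
#' @export
network_pairs <- function(ds, include_ambiguous = FALSE) {
  lk <- ds$links[ds$links$link_class == "inter", , drop = FALSE]
  if (!include_ambiguous) lk <- lk[!lk$ambiguous, , drop = FALSE]
  key <- pair_key(lk$protein_a, lk$protein_b)
  idx <- split(seq_len(nrow(lk)), key)
  data.frame(
    protein_a = vapply(idx, function(i) lk$protein_a[i[1]], character(1)),
    protein_b = vapply(idx, function(i) lk$protein_b[i[1]], character(1)),
    n_links = vapply(idx, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Replicate agreement of interprotein pairs
#'
#' Counts, for each interprotein pair, the number of replicate datasets in
#' which it was detected, the histogram of those multiplicities and
#' optionally the median minimum-partner abundance per multiplicity class.
#'
#' @param datasets list of >= 2 [xl_dataset()] replicates.
#' @param abundances optional named abundance vector.
#' @param include_ambiguous keep ambiguous links.
#' @return list of class `replication_summary`: `multiplicity` (named
#'   integer vector per pair key), `histogram` (counts for 1..n_reps),
#'   `n_pairs`, optionally `median_abundance_by_multiplicity`.
#' @export
replicate_overlap <- function(datasets, abundances = NULL,
                              include_ambiguous = FALSE) {
  if (length(datasets) < 2) stop("need at least 2 replicate datasets")
  keys <- lapply(datasets, function(ds)
    unique(pair_key(network_pairs(ds, include_ambiguous)$protein_a,
                    network_pairs(ds, include_ambiguous)$protein_b)))
  tab <- table(unlist(keys))
  multiplicity <- setNames(as.integer(tab), names(tab))
  n_reps <- length(datasets)
  histogram <- vapply(seq_len(n_reps), function(k)
    sum(multiplicity == k), integer(1))
  names(histogram) <- as.character(seq_len(n_reps))
  out <- list(multiplicity = multiplicity, histogram = histogram,
              n_pairs = length(multiplicity), n_reps = n_reps)
  if (!is.null(abundances)) {
    parts <- strsplit(names(multiplicity), "|", fixed = TRUE)
    ab_min <- vapply(parts, function(p)
      min(abundances[p[1]], abundances[p[2]]), numeric(1))
    out$median_abundance_by_multiplicity <- vapply(seq_len(n_reps),
      function(k) median(ab_min[multiplicity == k], na.rm = TRUE), numeric(1))
    names(out$median_abundance_by_multiplicity) <- as.character(seq_len(n_reps))
  }
  structure(out, class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("<replication_summary> %d pairs over %d replicates; counts per multiplicity: %s\n",
              x$n_pairs, x$n_reps,
              paste(sprintf("%sx=%d", names(x$histogram), x$histogram),
                    collapse = ", ")))
  invisible(x)
}

#' Direct / indirect / unconnected agreement between two networks
#'
#' Restricting to proteins present in both networks, each edge of `net_a`
#' is `direct` when it is also an edge of `net_b`, `indirect` when its
#' endpoints share at least one common neighbor in `net_b`, else
#' `unconnected`. Evaluate the older network's edges against the newer
#' one to measure how well the new data recovers previous pairs.
#'
#' @param net_a,net_b igraphs from [build_network()].
#' @return list with the three fractions (summing to 1) and `n_edges`
#'   evaluated.
#' @export
neighbor_agreement <- function(net_a, net_b) {
  shared <- intersect(igraph::V(net_a)$name, igraph::V(net_b)$name)
  if (length(shared) == 0) stop("no protein shared between the two networks")
  e <- igraph::as_edgelist(net_a)
  e <- e[e[, 1] %in% shared & e[, 2] %in% shared, , drop = FALSE]
  if (nrow(e) == 0)
    return(list(direct = NA_real_, indirect = NA_real_,
                unconnected = NA_real_, n_edges = 0L))
  nb <- lapply(setNames(shared, shared), function(v)
    igraph::V(net_b)$name[igraph::neighbors(net_b, v)])
  status <- vapply(seq_len(nrow(e)), function(i) {
    a <- e[i, 1]; b <- e[i, 2]
    if (b %in% nb[[a]]) "direct"
    else if (length(intersect(nb[[a]], nb[[b]])) >= 1) "indirect"
    else "unconnected"
  }, character(1))
  n <- length(status)
  list(direct = sum(status == "direct") / n,
       indirect = sum(status == "indirect") / n,
       unconnected = sum(status == "unconnected") / n,
       n_edges = n)
}

#' Cluster consistency of a new network against an old partition
#'
#' For every node of `net_new` carrying an old cluster label and having at
#' least one labelled neighbor, the fraction of its labelled neighbors
#' assigned to the same old cluster; compared (two-sample KS) against the
#' same statistic on a degree-preserving rewired null of `net_new`.
#'
#' @param net_new igraph.
#' @param partition_old a [girvan_newman_cluster()] partition (or a named
#'   membership vector) from the reference network.
#' @param null a [rewire_null()] ensemble of `net_new`.
#' @return list of class `cluster_consistency`: `observed` (named
#'   fractions), `null` (list of numeric vectors), `ks`.
#' @export
cluster_consistency <- function(net_new, partition_old, null) {
  memb <- if (inherits(partition_old, "cluster_partition"))
    partition_old$membership else partition_old
  same_cluster_fractions <- function(g) {
    vn <- igraph::V(g)$name
    lab <- intersect(vn, names(memb))
    out <- c()
    for (v in lab) {
      nbv <- intersect(igraph::V(g)$name[igraph::neighbors(g, v)], lab)
      if (length(nbv) == 0) next
      out[v] <- mean(memb[nbv] == memb[v])
    }
    out
  }
  observed <- same_cluster_fractions(net_new)
  if (length(observed) == 0) stop("partition covers no connected node of net_new")
  null_fracs <- lapply(null$graphs, same_cluster_fractions)
  ks <- suppressWarnings(ks.test(observed, unlist(null_fracs)))
  structure(list(observed = observed, null = null_fracs, ks = ks),
            class = "cluster_consistency")
}

#' @export
print.cluster_consistency <- function(x, ...) {
  cat(sprintf("<cluster_consistency> %d nodes; mean same-cluster fraction %.2f (null %.2f); KS p = %.3g\n",
              length(x$observed), mean(x$observed), mean(unlist(x$null)),
              x$ks$p.value))
  invisible(x)
}

#' Correlation of cross-linked-lysine count with lysine-corrected abundance
#'
#' Per protein: the number of distinct cross-linked lysines, correlated
#' with abundance divided by the protein's total lysine count, both on
#' log10 scales. Pearson R-squared is reported; a weak value indicates
#' cross-link detection is not a simple function of abundance.
#'
#' @param ds an [xl_dataset()].
#' @param abundances named abundance vector.
#' @param records `AAStringSet` of protein sequences.
#' @return list with `r_squared`, `n_proteins` and the per-protein table.
#' @export
abundance_lysine_correlation <- function(ds, abundances, records) {
  lk <- ds$links
  pos_by_prot <- list()
  add <- function(acc, pos) {
    pos_by_prot[[acc]] <<- c(pos_by_prot[[acc]], pos)
  }
  for (i in seq_len(nrow(lk))) {
    add(lk$protein_a[i], lk$pos_a[i])
    add(lk$protein_b[i], lk$pos_b[i])
  }
  prots <- intersect(names(pos_by_prot), intersect(names(abundances),
                                                   names(records)))
  if (length(prots) < 3) stop("fewer than 3 proteins with abundance and sequence")
  n_linked <- vapply(prots, function(p) length(unique(pos_by_prot[[p]])),
                     integer(1))
  n_lys <- vapply(prots, function(p)
    sum(strsplit(as.character(records[[p]]), "")[[1]] == "K"), integer(1))
  keep <- n_lys > 0
  df <- data.frame(accession = prots[keep],
                   n_linked_lysines = n_linked[keep],
                   n_lysines = n_lys[keep],
                   abundance = unname(abundances[prots[keep]]))
  x <- log10(df$abundance / df$n_lysines)
  y <- log10(df$n_linked_lysines)
  if (isTRUE(all.equal(stats::var(x), 0)) || isTRUE(all.equal(stats::var(y), 0)))
    stop("undefined correlation: a variable is constant")
  r <- cor(x, y)
  list(r_squared = r^2, n_proteins = nrow(df), data = df)
}
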