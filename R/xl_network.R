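# Cross-link-derived protein-protein interaction network and its
# statistics: components, scale-free degree fit, Girvan-Newman
# edge-betweenness clustering scored by Newman modularity,
# degree-preserving rewired nulls, co-annotation / path-distance
# statistics and term enrichment.
#
# All topology statistics run on the unweighted graph; per-edge cross-link
# and sample counts are carried as metadata only.

#' Build the XL-based protein interaction graph
#'
#' Interprotein links only. Edge weight is the number of unique
#' residue-pair cross-links supporting the protein pair and
#' `sample_count` the number of distinct samples in which any of them was
#' seen. Ambiguous shared-peptide links are excluded unless opted in;
#' excluded accessions (e.g. sticky high-abundance proteins) are removed
#' together with their edges.
#'
#' @param ds an [xl_dataset()].
#' @param exclude character vector of accessions to drop.
#' @param include_ambiguous keep ambiguous links (default `FALSE`).
#' @return an undirected `igraph` with vertex names = accessions and edge
#'   attributes `weight`, `sample_count`.
#' @export
build_network <- function(ds, exclude = character(0),
                          include_ambiguous = FALSE) {
  stopifnot(inherits(ds, "xl_dataset"))
  lk <- ds$links[ds$links$link_class == "inter", , drop = FALSE]
  if (!include_ambiguous) lk <- lk[!lk$ambiguous, , drop = FALSE]
  lk <- lk[!(lk$protein_a %in% exclude) & !(lk$protein_b %in% exclude), ,
           drop = FALSE]
  if (nrow(lk) == 0)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  key <- pair_key(lk$protein_a, lk$protein_b)
  idx <- split(seq_len(nrow(lk)), key)
  edges <- data.frame(
    from = vapply(idx, function(i) lk$protein_a[i[1]], character(1)),
    to = vapply(idx, function(i) lk$protein_b[i[1]], character(1)),
    weight = vapply(idx, length, integer(1)),
    sample_count = vapply(idx, function(i)
      length(unique(unlist(split_samples(lk$samples[i])))), integer(1)),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Core component and side modules
#'
#' The core is the largest connected component (ties broken towards the
#' component containing the lexicographically smallest vertex name, and
#' logged); other components with at least `k` nodes are side modules;
#' remaining vertices are the remainder.
#'
#' @param graph igraph.
#' @param k minimum side-module size (default 3).
#' @export
network_components <- function(graph, k = 3) {
  stopifnot(k >= 1)
  comp <- igraph::components(graph)
  if (comp$no == 0)
    return(list(core = graph, side_modules = list(), remainder = character(0)))
  nm <- names(comp$membership)
  smallest <- vapply(seq_len(comp$no), function(ci)
    min(nm[comp$membership == ci]), character(1))
  top <- which(comp$csize == max(comp$csize))
  core_id <- top[order(smallest[top])][1]
  if (length(top) > 1)
    message("component size tie: core chosen as the component containing '",
            smallest[core_id], "'")
  sub <- function(ci) igraph::induced_subgraph(graph, nm[comp$membership == ci])
  side_ids <- setdiff(which(comp$csize >= k), core_id)
  side_ids <- side_ids[order(-comp$csize[side_ids], smallest[side_ids])]
  rest_ids <- setdiff(seq_len(comp$no), c(core_id, side_ids))
  list(core = sub(core_id),
       side_modules = lapply(side_ids, sub),
       remainder = sort(nm[comp$membership %in% rest_ids]))
}

#' Power-law fit of the degree distribution
#'
#' Least-squares line through (log10 degree, log10 frequency) over degrees
#' with nonzero frequency — the conventional log-log check for scale-free
#' topology.
#'
#' @param graph igraph with at least 3 distinct (positive) degrees.
#' @return list with `slope`, `intercept`, `r_squared` and the fitted
#'   points.
#' @export
degree_powerlaw_fit <- function(graph) {
  d <- igraph::degree(graph)
  d <- d[d > 0]
  tab <- table(d)
  if (length(tab) < 3)
    stop("degenerate fit: fewer than 3 distinct degrees")
  pts <- data.frame(log_degree = log10(as.numeric(names(tab))),
                    log_frequency = log10(as.numeric(tab)))
  fit <- lm(log_frequency ~ log_degree, data = pts)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared), points = pts)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` on the unweighted graph, where
#' `e_c` is the number of edges inside community `c`, `d_c` the total
#' degree of its members and `m` the edge count.
#'
#' @param graph igraph.
#' @param membership community labels named by vertex; every vertex of
#'   `graph` must be covered.
#' @export
newman_modularity <- function(graph, membership) {
  vn <- igraph::V(graph)$name
  if (!all(vn %in% names(membership)))
    stop("membership does not cover every node of the graph")
  memb <- membership[vn]
  m <- igraph::ecount(graph)
  if (m == 0) return(0)
  e <- igraph::as_edgelist(graph)
  deg <- igraph::degree(graph)
  comm <- unique(memb)
  e_c <- vapply(comm, function(cc)
    sum(memb[e[, 1]] == cc & memb[e[, 2]] == cc), numeric(1))
  d_c <- vapply(comm, function(cc) sum(deg[memb == cc]), numeric(1))
  sum(e_c / m - (d_c / (2 * m))^2)
}

edge_sort_key <- function(graph, eids) {
  e <- igraph::ends(graph, eids)
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|")
}

#' Girvan-Newman edge-betweenness clustering
#'
#' Iteratively removes the edge of highest (unweighted) edge betweenness,
#' breaking ties towards the lexicographically smallest edge so the
#' procedure is fully deterministic, and tracks the component partition
#' each time the graph splits. Returns the tracked partition maximizing
#' Newman modularity on the original graph; on graphs that never beat the
#' trivial single community (e.g. complete graphs) that single community
#' is returned with Q = 0.
#'
#' @param graph connected igraph (typically the core component).
#' @return list of class `cluster_partition`: `membership` (named integer
#'   vector), `modularity`, `n_clusters`.
#' @export
girvan_newman_cluster <- function(graph) {
  comp <- igraph::components(graph)
  if (comp$no != 1) stop("girvan_newman_cluster expects a connected graph")
  vn <- igraph::V(graph)$name
  best_memb <- setNames(rep(1L, length(vn)), vn)
  best_q <- 0
  work <- graph
  n_comm <- 1L
  while (igraph::ecount(work) > 0) {
    eb <- igraph::edge_betweenness(work, directed = FALSE)
    mx <- max(eb)
    cand <- which(eb >= mx - 1e-9 * max(1, mx))
    if (length(cand) > 1) cand <- cand[order(edge_sort_key(work, cand))][1]
    work <- igraph::delete_edges(work, cand[1])
    cm <- igraph::components(work)
    if (cm$no > n_comm) {
      n_comm <- cm$no
      memb <- cm$membership[vn]
      q <- newman_modularity(graph, memb)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_memb <- memb
      }
    }
  }
  structure(list(membership = best_memb, modularity = best_q,
                 n_clusters = length(unique(best_memb))),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d clusters over %d nodes, Q = %.3f\n",
              x$n_clusters, length(x$membership), x$modularity))
  invisible(x)
}

#' Degree-preserving rewired null ensemble
#'
#' Each permutation applies `10 * |E|` attempted double-edge swaps,
#' rejecting self-loops and multi-edges, so every rewired graph has
#' exactly the original degree sequence.
#'
#' @param graph igraph with at least 2 edges.
#' @param n_iter number of permutations (default 100).
#' @param seed RNG seed.
#' @return list of class `null_ensemble` with elements `graphs`,
#'   `n_iter`, `seed`.
#' @export
rewire_null <- function(graph, n_iter = 100, seed = 1) {
  if (igraph::ecount(graph) < 2) stop("rewiring needs at least 2 edges")
  graphs <- with_seed(seed, lapply(seq_len(n_iter), function(i)
    igraph::rewire(graph, igraph::keeping_degseq(
      loops = FALSE, niter = 10 * igraph::ecount(graph)))))
  structure(list(graphs = graphs, n_iter = n_iter, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d degree-preserving rewired graphs (seed %d)\n",
              x$n_iter, x$seed))
  invisible(x)
}

coannotated_edge_fraction <- function(graph, members) {
  m <- igraph::ecount(graph)
  if (m == 0) return(NA_real_)
  e <- igraph::as_edgelist(graph)
  mean(e[, 1] %in% members & e[, 2] %in% members)
}

#' Co-annotation statistic with a rewired null
#'
#' For each term, the observed fraction of network edges whose two
#' endpoints share the term, against the same fraction in each
#' degree-preserving rewired graph. A two-sided two-sample
#' Kolmogorov-Smirnov test compares the observed fractions across terms
#' with the pooled null fractions.
#'
#' @param graph igraph (typically the core component).
#' @param annot an [annotation_set()].
#' @param null a [rewire_null()] ensemble of `graph`.
#' @param terms terms to evaluate; default: all terms with more than
#'   `min_proteins` annotated proteins in `graph`.
#' @param min_proteins term-size floor (default 50, per the convention of
#'   restricting to cellular-component terms with > 50 proteins; set to 0
#'   for small synthetic worlds).
#' @return list of class `coannotation_stats`: `per_term` data.frame
#'   (term, n_annotated, observed, null mean and 2.5/97.5 percentiles),
#'   `null` matrix (terms x permutations), `ks` htest.
#' @export
coannotation_statistic <- function(graph, annot, null, terms = NULL,
                                   min_proteins = 50) {
  stopifnot(inherits(null, "null_ensemble"))
  nodes <- igraph::V(graph)$name
  all_terms <- unique(annot$term)
  sizes <- vapply(all_terms, function(t)
    length(intersect(term_members(annot, t), nodes)), integer(1))
  if (is.null(terms)) {
    terms <- all_terms[sizes > min_proteins]
  } else {
    empty <- terms[vapply(terms, function(t)
      length(intersect(term_members(annot, t), nodes)) == 0, logical(1))]
    if (length(empty) > 0) {
      warning("term(s) with no annotated node in the graph skipped: ",
              paste(empty, collapse = ", "))
      terms <- setdiff(terms, empty)
    }
  }
  if (length(terms) == 0) stop("no eligible term")
  members <- lapply(terms, function(t) intersect(term_members(annot, t), nodes))
  observed <- vapply(members, function(mm)
    coannotated_edge_fraction(graph, mm), numeric(1))
  null_mat <- vapply(null$graphs, function(g)
    vapply(members, function(mm) coannotated_edge_fraction(g, mm), numeric(1)),
    numeric(length(terms)))
  null_mat <- matrix(null_mat, nrow = length(terms),
                     dimnames = list(terms, NULL))
  per_term <- data.frame(
    term = terms,
    n_annotated = vapply(members, length, integer(1)),
    observed = observed,
    null_mean = rowMeans(null_mat),
    null_lo = apply(null_mat, 1, quantile, 0.025, names = FALSE),
    null_hi = apply(null_mat, 1, quantile, 0.975, names = FALSE),
    stringsAsFactors = FALSE)
  ks <- suppressWarnings(ks.test(observed, as.vector(null_mat)))
  structure(list(per_term = per_term, null = null_mat, ks = ks),
            class = "coannotation_stats")
}

#' @export
print.coannotation_stats <- function(x, ...) {
  cat(sprintf("<coannotation_stats> %d terms; KS D = %.3f, p = %.3g\n",
              nrow(x$per_term), unname(x$ks$statistic), x$ks$p.value))
  invisible(x)
}

#' Shortest-path distances within and out of an annotated set
#'
#' Mean unweighted shortest-path distance among the term's annotated
#' nodes, and from annotated to non-annotated nodes; unreachable pairs are
#' excluded from the means and counted.
#'
#' @param graph igraph.
#' @param annot an [annotation_set()].
#' @param term term with at least 2 annotated nodes in the graph.
#' @export
path_distance_statistic <- function(graph, annot, term) {
  nodes <- igraph::V(graph)$name
  A <- intersect(term_members(annot, term), nodes)
  if (length(A) < 2) stop("term needs >= 2 annotated nodes in the graph")
  N <- setdiff(nodes, A)
  D <- igraph::distances(graph)
  dw <- D[A, A, drop = FALSE][upper.tri(matrix(0, length(A), length(A)))]
  db <- as.vector(D[A, N, drop = FALSE])
  list(term = term,
       n_annotated = length(A),
       mean_within = mean(dw[is.finite(dw)]),
       mean_between = if (length(db) > 0) mean(db[is.finite(db)]) else NA_real_,
       n_unreachable_within = sum(!is.finite(dw)),
       n_unreachable_between = sum(!is.finite(db)))
}

#' Term enrichment of a cluster (one-sided Fisher + BH)
#'
#' One-sided Fisher's exact test on the 2x2 membership table (in cluster x
#' annotated with term) over the background, with Benjamini-Hochberg
#' adjustment across terms.
#'
#' @param cluster_nodes accessions of the cluster.
#' @param annot an [annotation_set()].
#' @param background_nodes background accessions (must contain the
#'   cluster; typically all identified proteins).
#' @return data.frame (term, counts, fold, p, q) ordered by p.
#' @export
term_enrichment <- function(cluster_nodes, annot, background_nodes) {
  if (length(background_nodes) == 0) stop("empty background")
  if (!all(cluster_nodes %in% background_nodes))
    stop("background must contain the cluster")
  cluster_nodes <- unique(cluster_nodes)
  background_nodes <- unique(background_nodes)
  terms <- unique(annot$term)
  rows <- lapply(terms, function(t) {
    tm <- intersect(term_members(annot, t), background_nodes)
    a <- length(intersect(cluster_nodes, tm))
    b <- length(cluster_nodes) - a
    cc <- length(tm) - a
    d <- length(background_nodes) - length(cluster_nodes) - cc
    p <- fisher.test(matrix(c(a, b, cc, d), nrow = 2),
                     alternative = "greater")$p.value
    fold <- if (length(tm) > 0)
      (a / length(cluster_nodes)) / (length(tm) / length(background_nodes))
    else NA_real_
    data.frame(term = t, n_cluster = a, n_term = length(tm),
               n_cluster_total = length(cluster_nodes),
               n_background = length(background_nodes),
               fold = fold, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), ]
}
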