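# Mapping cross-links onto structures and scoring them as Calpha-Calpha
# distance restraints. The default limit of 33.4 A is the DSSO spacer
# geometry (23.4 A) plus 10 A allowance for in-solution flexibility.

XL_DEFAULT_THRESHOLD <- 33.4

#' Calpha-Calpha Euclidean distance between two structure residues
#'
#' @param model a [structure_model()].
#' @param chain_a,chain_b chain ids.
#' @param idx_a,idx_b residue row indices within each chain.
#' @return distance in Angstrom, or `NA` when either residue lacks a
#'   Calpha (unmappable, never an error).
#' @export
ca_distance <- function(model, chain_a, idx_a, chain_b, idx_b) {
  ra <- model$chains[[chain_a]][idx_a, ]
  rb <- model$chains[[chain_b]][idx_b, ]
  if (!isTRUE(ra$present) || !isTRUE(rb$present)) return(NA_real_)
  sqrt((ra$x - rb$x)^2 + (ra$y - rb$y)^2 + (ra$z - rb$z)^2)
}

#' Evaluate one cross-link against a structure
#'
#' Enumerates every placement of the two link endpoints over the chain
#' maps sharing the link's accessions (all chain pairs, so homo-oligomer
#' copies are considered; intraprotein links may map within one chain or
#' across copies). The restraint distance is the minimum over placements:
#' a cross-link is explained if any copy pair satisfies it.
#'
#' @param model a [structure_model()].
#' @param chain_maps list of [build_chain_map()] results for this model.
#' @param link one-row data.frame with `protein_a`, `pos_a`, `protein_b`,
#'   `pos_b` (canonical cross-link row).
#' @param threshold restraint limit in Angstrom, default 33.4.
#' @return list of class `distance_result`: `distance` (min over
#'   placements), `placements` data.frame, `mappable`, `satisfied`,
#'   `threshold`.
#' @export
evaluate_link <- function(model, chain_maps, link,
                          threshold = XL_DEFAULT_THRESHOLD) {
  maps_a <- Filter(function(m) m$accession == link$protein_a, chain_maps)
  maps_b <- Filter(function(m) m$accession == link$protein_b, chain_maps)
  pl <- list()
  for (ma in maps_a) for (mb in maps_b) {
    ia <- ma$mapping[as.character(link$pos_a)]
    ib <- mb$mapping[as.character(link$pos_b)]
    if (is.na(ia) || is.na(ib)) next
    if (ma$chain_id == mb$chain_id && ia == ib) next  # same physical residue
    d <- ca_distance(model, ma$chain_id, ia, mb$chain_id, ib)
    if (is.na(d)) next
    pl[[length(pl) + 1]] <- data.frame(chain_a = ma$chain_id,
                                       chain_b = mb$chain_id,
                                       distance = d,
                                       stringsAsFactors = FALSE)
  }
  placements <- if (length(pl) > 0) do.call(rbind, pl) else
    data.frame(chain_a = character(0), chain_b = character(0),
               distance = numeric(0))
  mappable <- nrow(placements) > 0
  distance <- if (mappable) min(placements$distance) else NA_real_
  structure(list(distance = distance, placements = placements,
                 mappable = mappable,
                 satisfied = mappable && distance <= threshold,
                 threshold = threshold),
            class = "distance_result")
}

restraint_histogram <- function(distances, bin_width = 5) {
  if (length(distances) == 0)
    return(setNames(integer(0), character(0)))
  bin <- floor(distances / bin_width)  # right-open bins from 0
  nb <- max(bin) + 1
  counts <- tabulate(bin + 1, nbins = nb)
  lo <- (seq_len(nb) - 1) * bin_width
  setNames(counts, sprintf("[%g,%g)", lo, lo + bin_width))
}

#' Evaluate a dataset of cross-links against one or more structures
#'
#' Each link is evaluated against every structure whose chain maps cover
#' both endpoints; the pooled per-link distance is the minimum over
#' structures. Unmappable links are reported, never silently dropped.
#'
#' @param ds an [xl_dataset()].
#' @param structures list of `list(model = structure_model, maps = list of
#'   chain_map)` entries.
#' @param threshold restraint limit in Angstrom.
#' @param bin_width histogram bin width (A); bins are right-open from 0.
#' @param per_link_tsv optional path: write the per-link table as TSV.
#' @return list of class `restraint_summary`: `per_link` data.frame,
#'   `n_links`, `n_mappable`, `n_satisfied`, `fraction_satisfied`,
#'   `histogram`, `per_structure` (named list of the same counts per
#'   structure), `threshold`.
#' @export
evaluate_dataset <- function(ds, structures, threshold = XL_DEFAULT_THRESHOLD,
                             bin_width = 5, per_link_tsv = NULL) {
  stopifnot(inherits(ds, "xl_dataset"))
  if (inherits(structures, "structure_model") || !is.null(structures$model))
    structures <- list(structures)
  lk <- ds$links
  n <- nrow(lk)
  dist_pooled <- rep(NA_real_, n)
  per_structure <- list()
  per_struct_dist <- matrix(NA_real_, nrow = n, ncol = length(structures))
  sids <- vapply(seq_along(structures), function(i)
    structures[[i]]$model$structure_id %||% paste0("structure", i), character(1))
  for (si in seq_along(structures)) {
    st <- structures[[si]]
    for (i in seq_len(n)) {
      r <- evaluate_link(st$model, st$maps, lk[i, ], threshold)
      if (r$mappable) per_struct_dist[i, si] <- r$distance
    }
    d <- per_struct_dist[, si]
    m <- !is.na(d)
    per_structure[[sids[si]]] <- list(
      n_mappable = sum(m), n_satisfied = sum(d[m] <= threshold),
      fraction_satisfied = if (any(m)) mean(d[m] <= threshold) else NA_real_,
      histogram = restraint_histogram(d[m], bin_width))
  }
  if (length(structures) > 0 && n > 0)
    dist_pooled <- suppressWarnings(apply(per_struct_dist, 1, min, na.rm = TRUE))
  dist_pooled[!is.finite(dist_pooled)] <- NA_real_
  mappable <- !is.na(dist_pooled)
  per_link <- cbind(lk[, c("protein_a", "pos_a", "protein_b", "pos_b",
                           "link_class")],
                    data.frame(distance = dist_pooled, mappable = mappable,
                               satisfied = mappable & dist_pooled <= threshold))
  if (!is.null(per_link_tsv)) write_simple_tsv(per_link, per_link_tsv)
  structure(list(
    per_link = per_link,
    n_links = n,
    n_mappable = sum(mappable),
    n_satisfied = sum(per_link$satisfied),
    fraction_satisfied = if (any(mappable)) mean(dist_pooled[mappable] <= threshold) else NA_real_,
    histogram = restraint_histogram(dist_pooled[mappable], bin_width),
    per_structure = per_structure,
    threshold = threshold,
    bin_width = bin_width), class = "restraint_summary")
}

#' @export
print.restraint_summary <- function(x, ...) {
  cat(sprintf("<restraint_summary> %d links, %d mappable, %d satisfied (%.1f%%) at %.1f A\n",
              x$n_links, x$n_mappable, x$n_satisfied,
              100 * (x$fraction_satisfied %||% NA_real_), x$threshold))
  invisible(x)
}
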