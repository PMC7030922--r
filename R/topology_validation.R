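# Membrane-topology consistency of cross-links: a link joining a
# cytoplasmic and an extracellular residue cannot form in an intact
# membrane preparation, so the cross-side rate measures dataset quality.

topo_side <- function(pos, regions) {
  hit <- regions[regions$start <= pos & pos <= regions$end, , drop = FALSE]
  lab <- hit$label[hit$label %in% c("cytoplasmic", "extracellular")]
  if (length(lab) == 0) "unannotated" else lab[1]
}

#' Classify a cross-link against membrane-topology annotations
#'
#' Each endpoint takes the label of the region containing its position;
#' transmembrane/other regions and positions falling in no region count as
#' unannotated (UniProt topology is sparse; regions need not tile the
#' protein). The verdict is `violation` when one endpoint is cytoplasmic
#' and the other extracellular, `unmapped` when either endpoint is
#' unannotated, else `consistent`.
#'
#' @param link one-row data.frame (`protein_a`, `pos_a`, `protein_b`,
#'   `pos_b`).
#' @param topology data.frame of regions (`accession`, `start`, `end`,
#'   `label`), see [read_topology_table()].
#' @param records optional sequence records; when given, positions beyond
#'   the protein length raise a data error.
#' @return list with `side_a`, `side_b`, `verdict`.
#' @export
classify_link_topology <- function(link, topology, records = NULL) {
  if (!is.null(records)) {
    for (end in c("a", "b")) {
      acc <- link[[paste0("protein_", end)]]
      pos <- link[[paste0("pos_", end)]]
      if (acc %in% names(records) && pos > Biostrings::width(records[acc]))
        stop("data error: position ", pos, " beyond length of ", acc)
    }
  }
  side_a <- topo_side(link$pos_a,
                      topology[topology$accession == link$protein_a, , drop = FALSE])
  side_b <- topo_side(link$pos_b,
                      topology[topology$accession == link$protein_b, , drop = FALSE])
  verdict <- if (side_a == "unannotated" || side_b == "unannotated") "unmapped"
  else if (side_a != side_b) "violation"
  else "consistent"
  list(side_a = side_a, side_b = side_b, verdict = verdict)
}

#' Topology calls for every link of a dataset
#'
#' @param ds an [xl_dataset()].
#' @inheritParams classify_link_topology
#' @return the dataset's link table with `side_a`, `side_b`, `verdict`
#'   columns appended.
#' @export
classify_dataset_topology <- function(ds, topology, records = NULL) {
  stopifnot(inherits(ds, "xl_dataset"))
  lk <- ds$links
  calls <- lapply(seq_len(nrow(lk)), function(i)
    classify_link_topology(lk[i, ], topology, records))
  lk$side_a <- vapply(calls, `[[`, character(1), "side_a")
  lk$side_b <- vapply(calls, `[[`, character(1), "side_b")
  lk$verdict <- vapply(calls, `[[`, character(1), "verdict")
  lk
}

#' Cross-side (cytoplasmic/extracellular) violation rate
#'
#' The denominator counts links with both endpoints in annotated
#' cytoplasmic or extracellular regions; unmapped links are excluded.
#'
#' @inheritParams classify_dataset_topology
#' @return list of class `topology_rate`: `n_mapped`, `n_violation`,
#'   `rate` (fraction; `NA` with a warning when nothing is mapped) and
#'   `rate_pct` (percentage rounded to 2 decimals).
#' @export
violation_rate <- function(ds, topology, records = NULL) {
  calls <- classify_dataset_topology(ds, topology, records)
  n_mapped <- sum(calls$verdict != "unmapped")
  n_violation <- sum(calls$verdict == "violation")
  rate <- if (n_mapped > 0) n_violation / n_mapped else {
    warning("no link has both endpoints annotated: rate undefined")
    NA_real_
  }
  structure(list(n_mapped = n_mapped, n_violation = n_violation,
                 rate = rate, rate_pct = round(100 * rate, 2),
                 calls = calls),
            class = "topology_rate")
}

#' @export
print.topology_rate <- function(x, ...) {
  cat(sprintf("<topology_rate> %d of %d mapped links cross-side (%.2f%%)\n",
              x$n_violation, x$n_mapped, x$rate_pct))
  invisible(x)
}
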