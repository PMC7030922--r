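# Data model and IO for residue-level cross-link tables, sequences,
# structures and annotation/evidence tables.

SAMPLE_SEP <- ";"

split_samples <- function(x) strsplit(as.character(x), SAMPLE_SEP, fixed = TRUE)

join_samples <- function(x) paste(sort(unique(x)), collapse = SAMPLE_SEP)

# canonical residue-pair identity string
link_key <- function(links) {
  paste(links$protein_a, links$pos_a, links$protein_b, links$pos_b, sep = "|")
}

# unordered protein-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Construct a cross-link dataset
#'
#' A cross-link dataset is a deduplicated set of residue-to-residue links.
#' Link identity is the unordered residue pair (accession, position):
#' chemistry or charge-state variants of the same lysine pair collapse to one
#' link. Endpoints are stored in canonical order ((protein_a, pos_a) <=
#' (protein_b, pos_b) lexicographically), duplicate rows merge their sample
#' sets and keep the minimum FDR, and rows above `fdr_threshold` are dropped.
#'
#' @param links data.frame with columns `protein_a`, `pos_a`, `protein_b`,
#'   `pos_b` and optionally `fdr` (default 0), `sample` or `samples`
#'   (default `"s1"`), `ambiguous` (default `FALSE`; marks links inferred
#'   from a peptide shared by more than one protein).
#' @param name dataset label.
#' @param fdr_threshold per-identification FDR cutoff, default 0.02.
#' @param verbose log row counts before/after filtering and deduplication.
#' @return object of class `xl_dataset`: list with elements `links`
#'   (canonical data.frame with a `link_class` column, `intra` or `inter`),
#'   `name` and `fdr_threshold`.
#' @export
xl_dataset <- function(links, name = "dataset", fdr_threshold = 0.02,
                       verbose = FALSE) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  need <- c("protein_a", "pos_a", "protein_b", "pos_b")
  miss <- setdiff(need, names(links))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(links) > 0) {
    for (cl in c("pos_a", "pos_b")) {
      v <- suppressWarnings(as.numeric(links[[cl]]))
      bad <- which(is.na(v) & !is.na(links[[cl]]))
      if (length(bad) > 0)
        stop("non-numeric position in column '", cl, "' at row(s) ",
             paste(head(bad, 5), collapse = ", "))
      if (anyNA(v)) stop("missing position in column '", cl, "'")
      if (any(v < 1) || any(v != floor(v)))
        stop("positions must be integers >= 1 (1-based residue coordinates)")
      links[[cl]] <- as.integer(v)
    }
  } else {
    links$pos_a <- integer(0); links$pos_b <- integer(0)
  }
  links$protein_a <- as.character(links$protein_a)
  links$protein_b <- as.character(links$protein_b)
  nr <- nrow(links)
  if (is.null(links$fdr)) links$fdr <- rep(0, nr)
  links$fdr <- as.numeric(links$fdr)
  if (nr > 0 && (anyNA(links$fdr) || any(links$fdr < 0 | links$fdr > 1)))
    stop("fdr must be a fraction in [0, 1]")
  if (is.null(links$samples)) {
    links$samples <- if (!is.null(links$sample)) as.character(links$sample)
    else rep("s1", nr)
  }
  links$sample <- NULL
  if (is.null(links$ambiguous)) links$ambiguous <- rep(FALSE, nr)
  links$ambiguous <- as.logical(links$ambiguous)

  n0 <- nrow(links)
  links <- links[links$fdr <= fdr_threshold, , drop = FALSE]
  n1 <- nrow(links)

  # canonical endpoint order
  if (n1 > 0) {
    swap <- links$protein_a > links$protein_b |
      (links$protein_a == links$protein_b & links$pos_a > links$pos_b)
    if (any(swap)) {
      tmp_p <- links$protein_a[swap]; tmp_i <- links$pos_a[swap]
      links$protein_a[swap] <- links$protein_b[swap]
      links$pos_a[swap] <- links$pos_b[swap]
      links$protein_b[swap] <- tmp_p
      links$pos_b[swap] <- tmp_i
    }
  }

  # dedup: merge sample sets, keep min FDR; ambiguous only if every
  # supporting identification was ambiguous
  if (n1 > 0) {
    key <- link_key(links)
    idx <- split(seq_len(n1), key)
    keep <- vapply(idx, `[`, integer(1), 1L)
    out <- links[keep, , drop = FALSE]
    out$fdr <- vapply(idx, function(i) min(links$fdr[i]), numeric(1))
    out$samples <- vapply(idx, function(i)
      join_samples(unlist(split_samples(links$samples[i]))), character(1))
    out$ambiguous <- vapply(idx, function(i) all(links$ambiguous[i]), logical(1))
    links <- out[order(link_key(out)), , drop = FALSE]
    rownames(links) <- NULL
  }
  links$link_class <- if (nrow(links) > 0)
    ifelse(links$protein_a == links$protein_b, "intra", "inter")
  else character(0)
  links <- links[, c("protein_a", "pos_a", "protein_b", "pos_b", "link_class",
                     "fdr", "samples", "ambiguous")]
  if (verbose)
    message(sprintf("xl_dataset '%s': %d rows in, %d pass FDR <= %g, %d unique links",
                    name, n0, n1, fdr_threshold, nrow(links)))
  structure(list(links = links, name = name, fdr_threshold = fdr_threshold),
            class = "xl_dataset")
}

#' @export
print.xl_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf("<xl_dataset '%s'> %d unique links (%d inter / %d intra), %d proteins, FDR <= %g\n",
              x$name, s$n_links, s$n_inter, s$n_intra, s$n_proteins,
              x$fdr_threshold))
  invisible(x)
}

#' Read a cross-link table
#'
#' Reads a delimited text table of residue-level cross-links (one
#' identification per row) and returns a deduplicated, FDR-filtered
#' [xl_dataset()]. The field separator is taken from the file extension
#' (`.csv` is comma, anything else tab).
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical column names
#'   (`protein_a`, `pos_a`, `protein_b`, `pos_b`, `fdr`, `sample`, optionally
#'   `ambiguous`) to the column names used in the file. Defaults to the
#'   canonical names themselves.
#' @param name dataset label (default: file base name).
#' @inheritParams xl_dataset
#' @export
read_crosslink_table <- function(path, dialect = NULL, name = NULL,
                                 fdr_threshold = 0.02, verbose = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  canon <- c("protein_a", "pos_a", "protein_b", "pos_b", "fdr", "sample",
             "ambiguous")
  map <- setNames(canon, canon)
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  mandatory <- c("protein_a", "pos_a", "protein_b", "pos_b", "fdr", "sample")
  miss <- mandatory[!(map[mandatory] %in% names(raw))]
  if (length(miss) > 0)
    stop("format error: file lacks mandatory column(s): ",
         paste(map[miss], collapse = ", "))
  df <- data.frame(protein_a = raw[[map["protein_a"]]],
                   pos_a = raw[[map["pos_a"]]],
                   protein_b = raw[[map["protein_b"]]],
                   pos_b = raw[[map["pos_b"]]],
                   fdr = raw[[map["fdr"]]],
                   sample = raw[[map["sample"]]],
                   stringsAsFactors = FALSE)
  if (map["ambiguous"] %in% names(raw))
    df$ambiguous <- raw[[map["ambiguous"]]]
  xl_dataset(df, name = name %||% sub("\\.[^.]+$", "", basename(path)),
             fdr_threshold = fdr_threshold, verbose = verbose)
}

#' Write a cross-link dataset as TSV
#'
#' Emits the canonical columns; [read_crosslink_table()] on the result
#' round-trips to an identical dataset.
#' @param ds an [xl_dataset()].
#' @param path output file path.
#' @export
write_crosslink_table <- function(ds, path) {
  stopifnot(inherits(ds, "xl_dataset"))
  out <- ds$links
  names(out)[names(out) == "samples"] <- "sample"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a cross-link dataset
#'
#' Counts unique links, inter- and intraprotein links, unique interprotein
#' protein pairs (unordered), proteins carrying intraprotein links, distinct
#' proteins, and per-sample link counts. Ambiguous shared-peptide links are
#' excluded from the protein-pair count unless `include_ambiguous = TRUE`.
#'
#' @param ds an [xl_dataset()].
#' @param include_ambiguous count ambiguous links in the protein-pair tally.
#' @return list of class `xl_summary`.
#' @export
dataset_summary <- function(ds, include_ambiguous = FALSE) {
  stopifnot(inherits(ds, "xl_dataset"))
  lk <- ds$links
  inter <- lk[lk$link_class == "inter", , drop = FALSE]
  intra <- lk[lk$link_class == "intra", , drop = FALSE]
  pair_src <- if (include_ambiguous) inter else inter[!inter$ambiguous, , drop = FALSE]
  per_sample <- if (nrow(lk) > 0) {
    tab <- table(unlist(split_samples(lk$samples)))
    setNames(as.integer(tab), names(tab))
  } else integer(0)
  structure(list(
    name = ds$name,
    n_links = nrow(lk),
    n_inter = nrow(inter),
    n_intra = nrow(intra),
    n_inter_pairs = length(unique(pair_key(pair_src$protein_a, pair_src$protein_b))),
    n_proteins_intra = length(unique(intra$protein_a)),
    n_proteins = length(unique(c(lk$protein_a, lk$protein_b))),
    per_sample = per_sample
  ), class = "xl_summary")
}

#' @export
print.xl_summary <- function(x, ...) {
  cat(sprintf(paste0("Cross-link summary '%s':\n",
                     "  unique links     %6d\n",
                     "  interprotein     %6d (%d protein pairs)\n",
                     "  intraprotein     %6d (within %d proteins)\n",
                     "  proteins total   %6d\n"),
              x$name, x$n_links, x$n_inter, x$n_inter_pairs,
              x$n_intra, x$n_proteins_intra, x$n_proteins))
  if (length(x$per_sample) > 0)
    cat("  per sample:", paste(sprintf("%s=%d", names(x$per_sample),
                                       x$per_sample), collapse = ", "), "\n")
  invisible(x)
}

## ---- sequences --------------------------------------------------------

#' Protein sequence records
#'
#' Thin wrappers around Biostrings for FASTA IO. Records are an
#' `AAStringSet` named by accession; sequences use the 20-letter alphabet
#' plus X.
#' @param seqs named character vector of sequences.
#' @export
protein_records <- function(seqs) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(seqs))))
    stop("sequences must use the 20 amino-acid letters plus X")
  Biostrings::AAStringSet(toupper(seqs))
}

#' @rdname protein_records
#' @param path FASTA file path.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname protein_records
#' @param records an `AAStringSet`.
#' @export
write_protein_fasta <- function(records, path) {
  Biostrings::writeXStringSet(records, path)
  invisible(path)
}

## ---- generic TSV tables ----------------------------------------------

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (cl in intersect(numeric_cols, names(df)))
    df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Read and validate a membrane-topology table
#'
#' Expects TSV columns `accession`, `start`, `end`, `label` with 1-based
#' inclusive regions labelled `cytoplasmic`, `extracellular`,
#' `transmembrane` or `other` (UniProt-style). Overlapping regions with
#' different labels are rejected.
#' @param path TSV path.
#' @export
read_topology_table <- function(path) {
  df <- read_tsv_checked(path, c("accession", "start", "end", "label"),
                         c("start", "end"))
  validate_topology(df)
}

#' @rdname read_topology_table
#' @param topology data.frame of regions to validate.
#' @export
validate_topology <- function(topology) {
  ok_labels <- c("cytoplasmic", "extracellular", "transmembrane", "other")
  if (!all(topology$label %in% ok_labels))
    stop("topology labels must be one of: ", paste(ok_labels, collapse = ", "))
  if (any(topology$start < 1) || any(topology$end < topology$start))
    stop("topology regions need 1 <= start <= end")
  for (acc in unique(topology$accession)) {
    r <- topology[topology$accession == acc, , drop = FALSE]
    if (nrow(r) < 2) next
    r <- r[order(r$start), , drop = FALSE]
    for (i in seq_len(nrow(r) - 1)) {
      ov <- which(r$start[(i + 1):nrow(r)] <= r$end[i]) + i
      if (any(r$label[ov] != r$label[i]))
        stop("overlapping regions with different labels for ", acc)
    }
  }
  topology
}

#' Read an external PPI evidence table
#'
#' TSV columns: `protein_a`, `protein_b`, `source` (one of `string`,
#' `inweb`, `biogrid`), `score` (may be empty), `low_throughput`
#' (logical; BioGRID only). Pairs are canonicalized and a confidence
#' `tier` column is derived via [classify_tier()].
#' @param path TSV path.
#' @export
read_evidence_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_a", "protein_b", "source"))
  if (is.null(df$score)) df$score <- NA_real_
  df$score <- suppressWarnings(as.numeric(df$score))
  if (is.null(df$low_throughput)) df$low_throughput <- NA
  df$low_throughput <- as.logical(df$low_throughput)
  evidence_records(df)
}

#' @rdname read_evidence_table
#' @param df data.frame of evidence rows.
#' @export
evidence_records <- function(df) {
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  df$protein_a <- a; df$protein_b <- b
  if (is.null(df$score)) df$score <- rep(NA_real_, nrow(df))
  if (is.null(df$low_throughput)) df$low_throughput <- rep(NA, nrow(df))
  df$tier <- classify_tier(df$source, df$score, df$low_throughput)
  df
}

#' Read a protein abundance table
#'
#' TSV columns `accession`, `abundance`; returns a named numeric vector.
#' @param path TSV path.
#' @export
read_abundance_table <- function(path) {
  df <- read_tsv_checked(path, c("accession", "abundance"), "abundance")
  if (any(df$abundance <= 0)) stop("abundances must be positive")
  setNames(df$abundance, df$accession)
}

#' Read a term-annotation table
#'
#' Long-format TSV with columns `term`, `accession` and optional `name`,
#' `namespace` metadata; returns a data.frame of class `annotation_set`.
#' @param path TSV path.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_checked(path, c("term", "accession"))
  annotation_set(df)
}

#' @rdname read_annotation_table
#' @param df long data.frame (`term`, `accession`).
#' @export
annotation_set <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "accession") %in% names(df)))
  df <- unique(df[!is.na(df$accession) & nzchar(df$accession), , drop = FALSE])
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' @rdname read_annotation_table
#' @param annot an `annotation_set`.
#' @param term term identifier.
#' @export
term_members <- function(annot, term) {
  unique(annot$accession[annot$term == term])
}

write_simple_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- structures -------------------------------------------------------

#' Construct a Calpha-only structure model
#'
#' @param chains named list (by chain id); each element a data.frame with
#'   columns `auth_number`, `aa` (one-letter), `x`, `y`, `z`, `present`.
#' @param structure_id identifier.
#' @export
structure_model <- function(chains, structure_id = "model") {
  stopifnot(is.list(chains), length(chains) > 0, !is.null(names(chains)))
  for (ch in names(chains)) {
    df <- chains[[ch]]
    stopifnot(all(c("auth_number", "aa", "x", "y", "z", "present") %in% names(df)))
    if (any(df$present & !(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))))
      stop("present residues must have finite coordinates (chain ", ch, ")")
    chains[[ch]] <- as.data.frame(df, stringsAsFactors = FALSE)
  }
  structure(list(structure_id = structure_id, chains = chains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model '%s'> %d chain(s): %s\n", x$structure_id,
              length(x$chains),
              paste(sprintf("%s (%d res, %d with CA)", names(x$chains),
                            vapply(x$chains, nrow, integer(1)),
                            vapply(x$chains, function(d) sum(d$present),
                                   integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Read a structure (PDB or mmCIF) as a Calpha-only model
#'
#' Residues are taken in file order per chain; residues without a Calpha
#' atom are kept but marked absent. Alternate locations resolve to the
#' highest occupancy (ties: first in file).
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param structure_id identifier, default: file base name.
#' @export
read_structure <- function(path, structure_id = NULL) {
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("format error: cannot parse structure file '",
                             path, "': ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty model: no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  if (!("o" %in% names(at)) || all(is.na(at$o))) at$o <- 1
  chains <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    rid <- paste(ca$resno, ca$insert)
    ord <- unique(rid)
    rows <- lapply(ord, function(r) {
      res <- ca[rid == r, , drop = FALSE]
      cas <- res[res$elety == "CA", , drop = FALSE]
      aa <- bio3d::aa321(res$resid[1])
      if (nrow(cas) == 0) {
        data.frame(auth_number = res$resno[1], aa = aa,
                   x = NA_real_, y = NA_real_, z = NA_real_,
                   present = FALSE, stringsAsFactors = FALSE)
      } else {
        best <- cas[order(-cas$o)[1], , drop = FALSE]  # altloc: top occupancy
        data.frame(auth_number = best$resno, aa = aa,
                   x = best$x, y = best$y, z = best$z,
                   present = TRUE, stringsAsFactors = FALSE)
      }
    })
    chains[[ch]] <- do.call(rbind, rows)
  }
  structure_model(chains, structure_id %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Write a Calpha-only model as a PDB file
#'
#' Emits one CA ATOM record per present residue (absent residues are
#' skipped; they reappear as gaps in numbering on read-back).
#' @param model a [structure_model()].
#' @param path output path.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in names(model$chains)) {
    df <- model$chains[[ch]]
    for (i in seq_len(nrow(df))) {
      if (!df$present[i]) next
      serial <- serial + 1L
      res3 <- bio3d::aa123(df$aa[i])
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, res3, ch, df$auth_number[i], df$x[i], df$y[i], df$z[i]), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- chain maps -------------------------------------------------------

#' Map UniProt sequence positions to structure residues
#'
#' Globally aligns the protein record sequence to the one-letter sequence
#' of a structure chain (match +1, mismatch -1, gap -2) and keeps only
#' aligned, identical residues. Positions of residues missing from the
#' chain stay unmapped. An alignment identity below `min_identity` over the
#' aligned columns aborts: the chain most likely belongs to a different
#' protein.
#'
#' @param record sequence: single `AAString`/`AAStringSet` element or
#'   character string.
#' @param model a [structure_model()].
#' @param chain_id chain to align against.
#' @param accession accession recorded in the map (default: name of
#'   `record` if any).
#' @param min_identity refusal floor, default 0.30.
#' @return object of class `chain_map`: `accession`, `chain_id`, `mapping`
#'   (integer vector, names = sequence positions, values = row index into
#'   the chain's residue table) and `identity`.
#' @export
build_chain_map <- function(record, model, chain_id, accession = NULL,
                            min_identity = 0.30) {
  stopifnot(inherits(model, "structure_model"))
  if (!(chain_id %in% names(model$chains)))
    stop("chain '", chain_id, "' not in model '", model$structure_id, "'")
  if (is.null(accession)) accession <- names(record) %||% "protein"
  seq_chr <- toupper(as.character(record)[1])
  chain <- model$chains[[chain_id]]
  chain_chr <- paste(chain$aa, collapse = "")
  ab <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  sm <- matrix(-1, length(ab), length(ab), dimnames = list(ab, ab))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_chr), Biostrings::AAString(chain_chr),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ip <- 0L; is_ <- 0L
  map <- integer(0); n_col <- 0L; n_id <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") ip <- ip + 1L
    if (s[k] != "-") is_ <- is_ + 1L
    if (p[k] != "-" && s[k] != "-") {
      n_col <- n_col + 1L
      if (p[k] == s[k]) {
        n_id <- n_id + 1L
        map[as.character(ip)] <- is_
      }
    }
  }
  identity <- if (n_col > 0) n_id / n_col else 0
  if (identity < min_identity)
    stop(sprintf("alignment identity %.1f%% below %.0f%%: chain '%s' likely does not match '%s'",
                 100 * identity, 100 * min_identity, chain_id, accession))
  structure(list(accession = accession, chain_id = chain_id,
                 structure_id = model$structure_id,
                 mapping = map, identity = identity),
            class = "chain_map")
}

#' @export
print.chain_map <- function(x, ...) {
  cat(sprintf("<chain_map %s -> %s:%s> %d positions mapped, identity %.1f%%\n",
              x$accession, x$structure_id, x$chain_id, length(x$mapping),
              100 * x$identity))
  invisible(x)
}
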