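#' Read a compound table from CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a mandatory header and "."
#' decimals.  Required columns are `id` and `inhib_10uM`; all others
#' (`smiles`, `inhib_1uM`, QC metadata `tail_nA`/`seal_MOhm`/`drop_pct`,
#' descriptors, `label`, `cluster`, `plate`, `fingerprint`) are optional
#' and kept absent (`NA`) when missing — never silently zeroed.
#' Fingerprints are serialized as `"<n_bits>:<bit;bit;...>"` (sorted,
#' zero-based) for exact round-trips.
#'
#' @param path CSV file path.
#' @return a `compound_library` data frame.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("id", "inhib_10uM")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop2("missing required column(s): %s",
                          paste(miss, collapse = ", "))
  dup <- unique(raw$id[duplicated(raw$id)])
  if (length(dup)) stop2("duplicate compound id(s): %s",
                         paste(dup, collapse = ", "))
  num_cols <- intersect(c("inhib_1uM", "inhib_10uM", "tail_nA", "seal_MOhm",
                          "drop_pct", "logP", "max_basic_pKa",
                          "min_acidic_pKa", "wiener_index"), names(raw))
  int_cols <- intersect(c("cluster", "plate"), names(raw))
  lib <- raw
  for (cn in c(num_cols, int_cols)) {
    v <- raw[[cn]]
    blank <- is.na(v) | v == "" | v == "NA"
    conv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(conv) & !blank)
    if (length(bad))
      stop2("unparseable numeric value in column '%s' at row(s) %s", cn,
            paste(bad, collapse = ", "))
    lib[[cn]] <- if (cn %in% int_cols) as.integer(conv) else conv
  }
  if ("fingerprint" %in% names(raw)) {
    lib$fingerprint <- lapply(raw$fingerprint, fp_from_string)
  }
  class(lib) <- c("compound_library", "data.frame")
  lib
}

#' Write a compound table to CSV
#'
#' Inverse of [read_library()]; `write_library()` followed by
#' [read_library()] is an identity on every carried field.
#'
#' @param lib a `compound_library` (or plain data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  out <- as.data.frame(lib)
  if ("fingerprint" %in% names(out))
    out$fingerprint <- vapply(lib$fingerprint, function(f)
      if (is.null(f)) NA_character_ else fp_to_string(f), character(1))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE, na = "")
  invisible(path)
}

#' Filter records on patch-clamp well quality control
#'
#' Retains a record iff all three QC criteria hold, with strict
#' inequalities: pre-compound peak tail current > 0.2 nA, seal resistance
#' > 30 MOhm, and seal-resistance drop rate < 25%.  Every rejected record
#' is annotated with all criteria it failed.
#'
#' @param lib a `compound_library` with complete `tail_nA`, `seal_MOhm`
#'   and `drop_pct` columns; missing metadata is an error, never silent
#'   retention.
#' @return a list with elements `retained` (library) and `rejected`
#'   (library with a `qc_reasons` column).
#' @export
qc_filter <- function(lib) {
  need <- c("tail_nA", "seal_MOhm", "drop_pct")
  miss <- setdiff(need, names(lib))
  if (length(miss)) stop2("missing QC metadata column(s): %s",
                          paste(miss, collapse = ", "))
  nas <- lib$id[!stats::complete.cases(lib[need])]
  if (length(nas)) stop2("missing QC metadata for id(s): %s",
                         paste(utils::head(nas, 10L), collapse = ", "))
  fail_tail <- !(lib$tail_nA > 0.2)
  fail_seal <- !(lib$seal_MOhm > 30)
  fail_drop <- !(lib$drop_pct < 25)
  keep <- !(fail_tail | fail_seal | fail_drop)
  rejected <- lib[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    reasons <- mapply(function(a, b, c) paste(
      c(if (a) "tail-current", if (b) "seal-resistance", if (c) "drop-rate"),
      collapse = ","),
      fail_tail[!keep], fail_seal[!keep], fail_drop[!keep])
    rejected$qc_reasons <- as.character(reasons)
  } else rejected$qc_reasons <- character(0)
  retained <- lib[keep, , drop = FALSE]
  class(retained) <- class(rejected) <- c("compound_library", "data.frame")
  list(retained = retained, rejected = rejected)
}

#' Binarize percent inhibition into blocker/nonblocker labels
#'
#' A compound is a blocker iff its 10 uM percent inhibition is strictly
#' greater than the threshold (default 50).  Exactly-threshold values are
#' nonblockers: blockers are defined strictly as ">50% inhibition", which
#' leaves the boundary to the nonblocker class.  Idempotent.
#'
#' @param lib a `compound_library` with `inhib_10uM`.
#' @param threshold percent-inhibition cutoff, default 50.
#' @return the library with a `label` column (`"blocker"`/`"nonblocker"`).
#' @export
binarize_labels <- function(lib, threshold = 50) {
  if (!"inhib_10uM" %in% names(lib)) stop2("inhib_10uM column required")
  if (anyNA(lib$inhib_10uM))
    stop2("missing inhib_10uM for id(s): %s",
          paste(utils::head(lib$id[is.na(lib$inhib_10uM)], 10L), collapse = ", "))
  lib$label <- ifelse(lib$inhib_10uM > threshold, "blocker", "nonblocker")
  lib
}

#' Read an edge list as a structure network
#'
#' Tab-separated id pairs, one edge per line, optional third similarity
#' column, no header.  Edges are undirected and deduplicated; self-loops
#' are dropped with a warning.  When `nodes` is supplied, edges referencing
#' unknown ids are an error and the node universe is `nodes`; otherwise the
#' universe is the set of endpoint ids.
#'
#' @param path TSV file path.
#' @param nodes optional character vector of node ids.
#' @param metric similarity metric tag, default `"3D"` (the usual carrier
#'   for precomputed conformer-overlap neighbour relations).
#' @return a `structure_network`.
#' @export
read_edge_list <- function(path, nodes = NULL, metric = "3D") {
  if (!file.exists(path)) stop2("file not found: %s", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop2("edge list must have at least two columns")
  if (!is.null(nodes)) {
    unknown <- setdiff(unique(c(raw[[1]], raw[[2]])), nodes)
    if (length(unknown)) stop2("edge references unknown id(s): %s",
                               paste(utils::head(unknown, 10L), collapse = ", "))
  }
  ids <- nodes %||% unique(c(raw[[1]], raw[[2]]))
  structure_network(ids, cbind(raw[[1]], raw[[2]]), metric = metric)
}

#' Write a structure network as a TSV edge list
#'
#' @param network a `structure_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "structure_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
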