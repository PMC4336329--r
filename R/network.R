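#' Construct a compound similarity network
#'
#' An undirected graph on compound ids: no self-loops, symmetric
#' deduplicated edges, every edge endpoint a known node.  Edges are stored
#' as a two-column character matrix with lexicographically ordered pairs.
#'
#' @param node_ids character vector of unique node ids.
#' @param edges two-column matrix (or data frame) of id pairs; may be empty.
#' @param metric similarity metric tag: `"2D"`, `"3D"`, `"scaffold"` or
#'   `"merged"`.
#' @return an object of class `structure_network`.
#' @export
structure_network <- function(node_ids, edges = NULL, metric = "2D") {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop2("node ids must be unique")
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    loops <- em[, 1] == em[, 2]
    if (any(loops)) {
      warn2("dropping %d self-loop(s)", sum(loops))
      em <- em[!loops, , drop = FALSE]
    }
    unknown <- setdiff(unique(c(em)), node_ids)
    if (length(unknown)) stop2("edge references unknown node(s): %s",
                               paste(utils::head(unknown, 10L), collapse = ", "))
    swap <- em[, 1] > em[, 2]
    em[swap, ] <- em[swap, c(2, 1), drop = FALSE]
    em <- em[!duplicated(paste(em[, 1], em[, 2], sep = "\r")), , drop = FALSE]
  }
  dimnames(em) <- NULL
  structure(list(node_ids = node_ids, edges = em, metric = metric),
            class = "structure_network")
}

#' @export
print.structure_network <- function(x, ...) {
  cat(sprintf("structure network (%s): %d nodes, %d edges\n",
              x$metric, length(x$node_ids), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(network) nrow(network$edges)

#' Node degrees of a structure network
#'
#' @param network a `structure_network`.
#' @return named integer vector over all nodes (isolated nodes have 0).
#' @export
network_degree <- function(network) {
  f <- factor(c(network$edges[, 1], network$edges[, 2]),
              levels = network$node_ids)
  stats::setNames(as.integer(table(f)), network$node_ids)
}

#' Build the 2D Tanimoto similarity network of a library
#'
#' Connects two compounds iff the Tanimoto coefficient of their
#' fingerprints is strictly greater than `threshold` (default 0.7, the
#' conventional cutoff for declaring two structures similar).  All pairs
#' are compared exactly, in row blocks of the bit matrix; no approximate
#' bucketing is used, so the edge set equals a brute-force scan.
#'
#' @param lib a `compound_library` with a complete `fingerprint` column.
#' @param threshold similarity cutoff; edges require `TC > threshold`.
#' @param block_size rows per block in the blocked all-pairs computation.
#' @return a `structure_network` with metric `"2D"`.
#' @export
build_similarity_network <- function(lib, threshold = 0.7, block_size = 1000L) {
  fps <- lib$fingerprint
  if (is.null(fps)) stop2("library has no fingerprint column")
  missing <- vapply(fps, is.null, logical(1))
  if (any(missing))
    stop2("missing fingerprint for id(s): %s",
          paste(utils::head(lib$id[missing], 10L), collapse = ", "))
  n <- nrow(lib)
  if (n < 2L) return(structure_network(lib$id, NULL, metric = "2D"))
  x <- fp_matrix(fps)
  r <- rowSums(x)
  if (any(r == 0L)) warn2("%d empty fingerprint(s); their similarities are 0",
                          sum(r == 0L))
  from <- integer(0); to <- integer(0)
  storage.mode(x) <- "double"
  for (start in seq(1L, n, by = block_size)) {
    end <- min(start + block_size - 1L, n)
    inter <- tcrossprod(x[start:end, , drop = FALSE], x)
    uni <- outer(r[start:end], r, "+") - inter
    sim <- ifelse(uni == 0, 0, inter / uni)
    hit <- which(sim > threshold, arr.ind = TRUE)
    gi <- hit[, 1] + start - 1L
    gj <- hit[, 2]
    keep <- gi < gj
    from <- c(from, gi[keep]); to <- c(to, gj[keep])
  }
  structure_network(lib$id, cbind(lib$id[from], lib$id[to]), metric = "2D")
}

#' Merge two structure networks by edge-set union
#'
#' Combines similarity criteria (e.g. 2D fingerprints with imported 3D
#' neighbour relations) by taking the union of their edge sets over a
#' shared node universe.
#'
#' @param a,b `structure_network` objects.
#' @param mode `"strict"` requires identical node universes; `"intersect"`
#'   restricts both to the common nodes first.
#' @return a `structure_network` with metric `"merged"`.
#' @export
merge_networks <- function(a, b, mode = c("strict", "intersect")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "structure_network"), inherits(b, "structure_network"))
  if (mode == "strict") {
    if (!setequal(a$node_ids, b$node_ids))
      stop2("node universes differ; use mode = \"intersect\" for partial overlap")
    ids <- a$node_ids
    ea <- a$edges; eb <- b$edges
  } else {
    ids <- intersect(a$node_ids, b$node_ids)
    ea <- a$edges[a$edges[, 1] %in% ids & a$edges[, 2] %in% ids, , drop = FALSE]
    eb <- b$edges[b$edges[, 1] %in% ids & b$edges[, 2] %in% ids, , drop = FALSE]
  }
  structure_network(ids, rbind(ea, eb), metric = "merged")
}

#' Neighbourhood phenotype grid
#'
#' For every labelled compound, counts its blocker and nonblocker
#' neighbours in the network and tallies compounds per
#' `(n_blocker_neighbors, n_nonblocker_neighbors)` cell.  The `(0, 0)` cell
#' counts singletons; cells along the axes are pure-blocker or
#' pure-nonblocker neighbourhoods and the diagonal region is the mixed
#' "transition zone".
#'
#' @param network a `structure_network`.
#' @param lib a labelled `compound_library` covering all nodes.
#' @return a `phenotype_grid` data frame with columns
#'   `n_blocker_neighbors`, `n_nonblocker_neighbors`, `count`.
#' @export
neighbor_phenotype_grid <- function(network, lib) {
  if (!"label" %in% names(lib)) stop2("library has no label column; run binarize_labels()")
  lab <- stats::setNames(lib$label, lib$id)
  if (anyNA(lab[network$node_ids]))
    stop2("node(s) without label: %s",
          paste(utils::head(network$node_ids[is.na(lab[network$node_ids])], 10L),
                collapse = ", "))
  ids <- network$node_ids
  nb <- stats::setNames(integer(length(ids)), ids)
  nn <- nb
  if (n_edges(network)) {
    e1 <- network$edges[, 1]; e2 <- network$edges[, 2]
    add <- function(cnt, ends, other_lab, want) {
      t1 <- table(factor(ends[other_lab == want], levels = ids))
      cnt + as.integer(t1)
    }
    nb <- add(nb, e1, lab[e2], "blocker");   nb <- add(nb, e2, lab[e1], "blocker")
    nn <- add(nn, e1, lab[e2], "nonblocker"); nn <- add(nn, e2, lab[e1], "nonblocker")
  }
  tab <- as.data.frame(table(n_blocker_neighbors = nb,
                             n_nonblocker_neighbors = nn),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  grid <- data.frame(
    n_blocker_neighbors = as.integer(tab$n_blocker_neighbors),
    n_nonblocker_neighbors = as.integer(tab$n_nonblocker_neighbors),
    count = as.integer(tab$Freq))
  grid <- grid[order(grid$n_blocker_neighbors, grid$n_nonblocker_neighbors), ]
  rownames(grid) <- NULL
  class(grid) <- c("phenotype_grid", "data.frame")
  attr(grid, "n_compounds") <- length(ids)
  grid
}

#' Correlation between network degree and activity
#'
#' Pearson product-moment correlation between a compound's number of
#' structural neighbours and its percent inhibition.  Near-zero values
#' indicate that activity enrichment in the network is not a frequency
#' artefact of heavily represented scaffolds.
#'
#' @param network a `structure_network`.
#' @param lib a `compound_library` covering all nodes.
#' @param activity activity column name, default `"inhib_10uM"`.
#' @return Pearson r in `[-1, 1]`, or `NA` (with a warning) when either
#'   variable has zero variance.
#' @export
degree_activity_correlation <- function(network, lib, activity = "inhib_10uM") {
  deg <- network_degree(network)
  act <- stats::setNames(lib[[activity]], lib$id)[names(deg)]
  if (length(deg) < 3L) stop2("need at least 3 nodes")
  if (anyNA(act)) stop2("missing activity for some network nodes")
  if (stats::sd(deg) == 0 || stats::sd(act) == 0) {
    warn2("zero variance in degree or activity; correlation undefined")
    return(NA_real_)
  }
  stats::cor(deg, act)
}
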