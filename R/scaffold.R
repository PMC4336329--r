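# Molecular graphs for scaffold work are parsed through ChemmineR/ChemmineOB
# (SMILES <-> SDF <-> canonical SMILES); the Murcko pruning and the
# ring-removal hierarchy themselves are implemented here on the heavy-atom
# graph, since no installed package provides them.

# SMILES -> list(atoms = element vector, bonds = data.frame(from, to, order),
# sdf = ChemmineR SDF).  Hydrogens are implicit in SMILES-derived SDFs.
mol_graph <- function(smiles) {
  sdf <- parse_smiles(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- sub("_.*$", "", rownames(ab))
  bonds <- if (NROW(bb) && NCOL(bb) >= 3L)
    data.frame(from = as.integer(bb[, 1]),
                                    to = as.integer(bb[, 2]),
                                    order = as.integer(bb[, 3]))
           else data.frame(from = integer(0), to = integer(0), order = integer(0))
  list(atoms = atoms, bonds = bonds, sdf = sdf)
}

# Subset a molecular graph to `keep` atom indices and emit a canonical
# SMILES via the toolkit.  NULL when nothing is kept.
subgraph_smiles <- function(g, keep) {
  keep <- sort(keep)
  if (!length(keep)) return(NULL)
  ab <- ChemmineR::atomblock(g$sdf)[keep, , drop = FALSE]
  bb <- ChemmineR::bondblock(g$sdf)
  sel <- bb[, 1] %in% keep & bb[, 2] %in% keep
  bb <- bb[sel, , drop = FALSE]
  remap <- stats::setNames(seq_along(keep), keep)
  bb[, 1] <- remap[as.character(bb[, 1])]
  bb[, 2] <- remap[as.character(bb[, 2])]
  h <- ChemmineR::header(g$sdf)
  h["Counts_Line"] <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                              nrow(ab), nrow(bb))
  sdf <- methods::new("SDF", header = h, atomblock = ab, bondblock = bb)
  smi <- ChemmineR::sdf2smiles(methods::new("SDFset", SDF = list(sdf), ID = "s"))
  canonical_smiles(as.character(smi))
}

# Toolkit canonical form (round-trip through the parser so any two
# representations of the same structure compare equal).
canonical_smiles <- function(smiles) {
  out <- ChemmineR::sdf2smiles(parse_smiles(smiles))
  unname(as.character(out))
}

adjacency_list <- function(n_atoms, bonds) {
  adj <- rep(list(integer(0)), n_atoms)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$from[b]]] <- c(adj[[bonds$from[b]]], bonds$to[b])
    adj[[bonds$to[b]]] <- c(adj[[bonds$to[b]]], bonds$from[b])
  }
  adj
}

n_components <- function(atom_idx, bonds) {
  if (!length(atom_idx)) return(0L)
  gr <- igraph::graph_from_data_frame(
    bonds[bonds$from %in% atom_idx & bonds$to %in% atom_idx, 1:2],
    directed = FALSE,
    vertices = data.frame(name = as.character(atom_idx)))
  igraph::count_components(gr)
}

# Smallest set of smallest rings, greedily assembled from the toolkit's
# exhaustive ring perception: rings are added smallest-first while they
# contribute at least one new bond, until the cyclomatic number is reached.
sssr <- function(g) {
  n_atoms <- length(g$atoms)
  if (!nrow(g$bonds)) return(list())
  ncomp <- n_components(seq_len(n_atoms), g$bonds)
  cyclomatic <- nrow(g$bonds) - n_atoms + ncomp
  if (cyclomatic <= 0L) return(list())
  rings_raw <- ChemmineR::rings(g$sdf, type = "all")
  if (!length(rings_raw)) return(list())
  ring_atoms <- lapply(rings_raw, function(r) as.integer(sub("^.*_", "", r)))
  ring_atoms <- ring_atoms[order(lengths(ring_atoms))]
  bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ring_bonds <- lapply(ring_atoms, function(r) {
    k <- length(r)
    bond_key(r, r[c(2:k, 1)])
  })
  chosen <- list(); covered <- character(0)
  for (i in seq_along(ring_atoms)) {
    if (length(chosen) >= cyclomatic) break
    new_bonds <- setdiff(ring_bonds[[i]], covered)
    if (length(new_bonds)) {
      chosen[[length(chosen) + 1L]] <- ring_atoms[[i]]
      covered <- c(covered, new_bonds)
    }
  }
  chosen
}

# Murcko pruning on atom indices: iteratively strip all terminal atoms,
# leaving ring systems plus the linkers between them (rings are safe: every
# ring atom keeps degree >= 2), then re-attach atoms joined to the kept core
# by a double or triple bond (exocyclic =O and friends travel with their
# ring or linker).
murcko_prune <- function(keep, bonds) {
  start <- keep
  repeat {
    if (!length(keep)) break
    sel <- bonds$from %in% keep & bonds$to %in% keep
    bsub <- bonds[sel, , drop = FALSE]
    deg <- table(factor(c(bsub$from, bsub$to), levels = keep))
    drop <- as.integer(names(deg)[deg <= 1L])
    if (!length(drop)) break
    keep <- setdiff(keep, drop)
  }
  if (length(keep)) {
    removed <- setdiff(start, keep)
    multi <- bonds$order >= 2L
    back <- bonds$from[multi & bonds$from %in% removed & bonds$to %in% keep]
    back <- c(back, bonds$to[multi & bonds$to %in% removed & bonds$from %in% keep])
    keep <- sort(unique(c(keep, back)))
  }
  keep
}

#' Murcko scaffold of a molecule
#'
#' The molecular framework: ring systems plus the linkers connecting them,
#' with side chains removed.  Terminal atoms are stripped iteratively (ring
#' atoms always survive), after which atoms joined to the framework by a
#' double or triple bond are re-attached, so exocyclic carbonyls and the
#' like travel with their ring or linker.  Acyclic molecules have no
#' scaffold.
#'
#' @param smiles a single SMILES string.
#' @return the canonical scaffold SMILES, or `NA_character_` for acyclic
#'   molecules.
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- mol_graph(smiles)
  if (!length(sssr(g))) return(NA_character_)
  keep <- murcko_prune(seq_along(g$atoms), g$bonds)
  if (!length(keep)) return(NA_character_)
  subgraph_smiles(g, keep)
}

#' Enumerate the child scaffolds of a scaffold
#'
#' Every ring of the scaffold is tried for removal (exhaustively, not along
#' one canonical path): a child is generated by deleting the ring's atoms
#' that are exclusive to it (atoms shared with other rings stay, so fused
#' neighbours survive), discarding the candidate when the remnant is
#' disconnected, then re-pruning dangling linkers.  A two-ring scaffold
#' thus yields one child per removable ring (deduplicated on canonical
#' form); one-ring scaffolds yield the empty set.
#'
#' @param scaffold a scaffold SMILES (as from [murcko_scaffold()]).
#' @return character vector of distinct canonical child scaffold SMILES
#'   (possibly empty).
#' @export
enumerate_scaffold_children <- function(scaffold) {
  stopifnot(is.character(scaffold), length(scaffold) == 1L)
  g <- mol_graph(scaffold)
  rings <- sssr(g)
  if (length(rings) <= 1L) return(character(0))
  children <- character(0)
  all_atoms <- seq_along(g$atoms)
  for (i in seq_along(rings)) {
    shared <- unique(unlist(rings[-i]))
    exclusive <- setdiff(rings[[i]], shared)
    if (!length(exclusive)) next  # ring fully absorbed by its neighbours
    keep <- setdiff(all_atoms, exclusive)
    # drop atoms isolated by the removal (e.g. exocyclic substituents of
    # the removed ring)
    sel <- g$bonds$from %in% keep & g$bonds$to %in% keep
    deg <- table(factor(c(g$bonds$from[sel], g$bonds$to[sel]), levels = keep))
    keep <- keep[deg > 0L]
    if (!length(keep)) next
    if (n_components(keep, g$bonds) != 1L) next  # disconnected remnant
    keep <- murcko_prune(keep, g$bonds)
    if (!length(keep)) next
    sub_bonds <- g$bonds[g$bonds$from %in% keep & g$bonds$to %in% keep, ,
                         drop = FALSE]
    if (nrow(sub_bonds) - length(keep) + 1L <= 0L) next  # no ring left
    children <- c(children, subgraph_smiles(g, keep))
  }
  unique(children)
}

#' Build the Murcko scaffold hierarchy of a library
#'
#' Computes every compound's Murcko scaffold and closes the scaffold set
#' under [enumerate_scaffold_children()], adding a directed parent-to-child
#' edge for each single-ring removal, down to one-ring scaffolds.
#' Intermediate scaffolds not realised by any compound are included as
#' virtual nodes and flagged.  Ring-free compounds are excluded and
#' counted.
#'
#' @param lib a `compound_library` with a `smiles` column, or a character
#'   vector of SMILES (optionally named by compound id).
#' @return a `scaffold_network`: list with `scaffolds` (data frame:
#'   `scaffold`, `ring_count`, `virtual`), `edges` (data frame `parent`,
#'   `child`), `membership` (data frame `id`, `scaffold`) and
#'   `n_acyclic`.
#' @export
build_scaffold_network <- function(lib) {
  if (inherits(lib, "data.frame")) {
    if (!"smiles" %in% names(lib)) stop2("library has no smiles column")
    smiles <- stats::setNames(lib$smiles, lib$id)
  } else {
    smiles <- lib
    if (is.null(names(smiles))) names(smiles) <- paste0("CMP", seq_along(smiles))
  }
  scaff <- vapply(smiles, murcko_scaffold, character(1))
  acyclic <- is.na(scaff)
  membership <- data.frame(id = names(smiles)[!acyclic],
                           scaffold = unname(scaff[!acyclic]),
                           stringsAsFactors = FALSE)
  realized <- unique(membership$scaffold)
  seen <- character(0)
  edges_p <- character(0); edges_c <- character(0)
  queue <- realized
  while (length(queue)) {
    s <- queue[[1]]; queue <- queue[-1]
    if (s %in% seen) next
    seen <- c(seen, s)
    kids <- enumerate_scaffold_children(s)
    for (k in kids) {
      edges_p <- c(edges_p, s); edges_c <- c(edges_c, k)
      if (!(k %in% seen)) queue <- c(queue, k)
    }
  }
  ring_count <- vapply(seen, function(s) length(sssr(mol_graph(s))), integer(1))
  scaffolds <- data.frame(scaffold = seen,
                          ring_count = unname(ring_count),
                          virtual = !(seen %in% realized),
                          stringsAsFactors = FALSE)
  out <- list(scaffolds = scaffolds,
              edges = data.frame(parent = edges_p, child = edges_c,
                                 stringsAsFactors = FALSE),
              membership = membership,
              n_acyclic = sum(acyclic))
  class(out) <- "scaffold_network"
  out
}

#' @export
print.scaffold_network <- function(x, ...) {
  cat(sprintf(paste0("scaffold network: %d scaffolds (%d virtual), %d ",
                     "parent-child edges,\n  %d member compounds, %d acyclic ",
                     "compounds excluded\n"),
              nrow(x$scaffolds), sum(x$scaffolds$virtual), nrow(x$edges),
              nrow(x$membership), x$n_acyclic))
  invisible(x)
}

#' Activity-annotated compound network from a scaffold hierarchy
#'
#' For club analysis on the scaffold level, each scaffold's activity is the
#' best (maximum) inhibition among its member compounds, and scaffolds are
#' linked when they share a parent-child relation.  Returns the undirected
#' scaffold graph plus the max-member activity vector.
#'
#' @param scaffnet a `scaffold_network`.
#' @param lib the labelled/annotated `compound_library` the hierarchy was
#'   built from.
#' @param activity activity column, default `"inhib_10uM"`.
#' @return list with `network` (a `structure_network`, metric
#'   `"scaffold"`) and `activities` (named vector over realised
#'   scaffolds; virtual scaffolds are excluded).
#' @export
scaffold_club_input <- function(scaffnet, lib, activity = "inhib_10uM") {
  stopifnot(inherits(scaffnet, "scaffold_network"))
  act <- stats::setNames(lib[[activity]], lib$id)
  mem <- scaffnet$membership
  realized <- unique(mem$scaffold)
  sc_act <- vapply(realized, function(s)
    max(act[mem$id[mem$scaffold == s]]), numeric(1))
  e <- scaffnet$edges
  keep <- e$parent %in% realized & e$child %in% realized
  net <- structure_network(realized,
                           cbind(e$parent[keep], e$child[keep]),
                           metric = "scaffold")
  list(network = net, activities = sc_act)
}
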