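#' Construct a folded bit-set fingerprint
#'
#' A fingerprint is represented as the sorted set of on-bit indices
#' (zero-based, the usual cheminformatics convention) together with the
#' folded length `n_bits`.  This is the exact object the Tanimoto
#' coefficient is defined on: for fingerprints \eqn{F_i, F_j},
#' \eqn{TC_{i,j} = |F_i \cap F_j| / |F_i \cup F_j|}.
#'
#' @param on_bits integer vector of on-bit indices in `[0, n_bits)`;
#'   duplicates are collapsed.
#' @param n_bits folded fingerprint length in bits.
#' @return an object of class `chemfp`.
#' @examples
#' a <- chemfp(c(1, 2, 3), 16)
#' b <- chemfp(c(2, 3, 4), 16)
#' tanimoto(a, b) # 0.5
#' @export
chemfp <- function(on_bits, n_bits) {
  if (!is_count(n_bits, min = 1L)) stop2("n_bits must be a positive integer")
  on_bits <- as.integer(on_bits)
  if (anyNA(on_bits)) stop2("on_bits must not contain NA")
  if (length(on_bits) && (min(on_bits) < 0L || max(on_bits) >= n_bits))
    stop2("on_bits indices must lie in [0, n_bits)")
  structure(list(on_bits = sort(unique(on_bits)), n_bits = as.integer(n_bits)),
            class = "chemfp")
}

#' @export
print.chemfp <- function(x, ...) {
  cat(sprintf("<chemfp: %d/%d bits on>\n", length(x$on_bits), x$n_bits))
  invisible(x)
}

is_chemfp <- function(x) inherits(x, "chemfp")

#' Tanimoto coefficient between two fingerprints
#'
#' \eqn{TC = |F_a \cap F_b| / |F_a \cup F_b|} on the on-bit sets.  Two empty
#' fingerprints have an undefined ratio; it is defined here as 0 (with a
#' warning) so featureless records never generate spurious similarity edges.
#'
#' @param a,b `chemfp` objects of equal folded length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!is_chemfp(a) || !is_chemfp(b)) stop2("tanimoto expects chemfp objects")
  if (a$n_bits != b$n_bits)
    stop2("fingerprints have different lengths (%d vs %d)", a$n_bits, b$n_bits)
  na <- length(a$on_bits); nb <- length(b$on_bits)
  if (na == 0L && nb == 0L) {
    warn2("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  inter <- length(intersect(a$on_bits, b$on_bits))
  inter / (na + nb - inter)
}

# Dense 0/1 matrix (rows = compounds, cols = bits 0..n_bits-1) from a list of
# chemfp.  Used by the blocked all-pairs similarity scan and the classifiers.
fp_matrix <- function(fps) {
  if (!length(fps)) stop2("no fingerprints supplied")
  nb <- unique(vapply(fps, function(f) f$n_bits, integer(1)))
  if (length(nb) != 1L) stop2("fingerprints have mixed lengths")
  x <- matrix(0L, nrow = length(fps), ncol = nb)
  for (i in seq_along(fps)) {
    ob <- fps[[i]]$on_bits
    if (length(ob)) x[i, ob + 1L] <- 1L
  }
  x
}

# Serialization used by the CSV dialect: "<n_bits>:<bit;bit;...>", sorted,
# zero-based; empty fingerprint -> "<n_bits>:".
fp_to_string <- function(fp) {
  if (is.null(fp) || (length(fp) == 1L && is.na(fp)[1])) return(NA_character_)
  sprintf("%d:%s", fp$n_bits, paste(fp$on_bits, collapse = ";"))
}

fp_from_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) < 1L || is.na(suppressWarnings(as.integer(parts[1]))))
    stop2("malformed fingerprint string: %s", s)
  nb <- as.integer(parts[1])
  bits <- if (length(parts) > 1L && nzchar(parts[2]))
    as.integer(strsplit(parts[2], ";", fixed = TRUE)[[1]]) else integer(0)
  chemfp(bits, nb)
}

#' Compute a circular fingerprint from a SMILES string
#'
#' Delegates to the OpenBabel toolkit (through ChemmineR/ChemmineOB) and
#' folds the toolkit's bit indices to `n_bits` by modular folding.  Kind
#' `"fcfp6"` requests a diameter-6 (radius 3) circular fingerprint and
#' `"ecfp4"` a diameter-4 (radius 2) one.  OpenBabel implements circular
#' fingerprints with standard (ECFP-style) atom invariants only, so the
#' functional-class variant is served by the same radius-3 fingerprint; the
#' radius is honoured exactly, the atom typing is the toolkit's.
#'
#' @param smiles character vector of SMILES strings.
#' @param kind `"fcfp6"` (radius 3) or `"ecfp4"` (radius 2).
#' @param n_bits folded length, default 1024.
#' @return a list of `chemfp` (a single `chemfp` for one input).
#' @export
compute_fingerprint <- function(smiles, kind = c("fcfp6", "ecfp4"),
                                n_bits = 1024L) {
  kind <- match.arg(kind)
  if (!is_count(n_bits, 1L)) stop2("n_bits must be a positive integer")
  sdf <- parse_smiles(smiles)
  ob_kind <- if (kind == "fcfp6") "ECFP6" else "ECFP4"
  fpset <- ChemmineR::fingerprintOB(sdf, ob_kind)
  m <- methods::slot(fpset, "fpma")
  out <- lapply(seq_len(nrow(m)), function(i) {
    on <- which(m[i, ] != 0) - 1L
    chemfp(unique(on %% as.integer(n_bits)), n_bits)
  })
  if (length(smiles) == 1L) out[[1]] else out
}

# Parse SMILES into a ChemmineR SDFset, with per-string error reporting.
parse_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop2("ChemmineR/ChemmineOB are required for structure handling")
  if (!is.character(smiles) || !length(smiles) || anyNA(smiles))
    stop2("smiles must be a non-empty character vector without NA")
  nm <- names(smiles) %||% paste0("mol", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, nm))),
    error = function(e) stop2("failed to parse SMILES [%s]: %s",
                              paste(smiles, collapse = ", "), conditionMessage(e)))
  # validSDF() would also reject legitimate single-atom molecules (no bond
  # block), so validity here is a nonempty atom block
  ok <- vapply(ChemmineR::SDFset2SDF(sdf), function(s)
    nrow(ChemmineR::atomblock(s)) >= 1L, logical(1))
  if (!all(ok))
    stop2("invalid SMILES: %s", paste(smiles[!ok], collapse = ", "))
  sdf
}
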