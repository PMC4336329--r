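count_internal_edges <- function(network, members) {
  inset <- stats::setNames(network$node_ids %in% members, network$node_ids)
  if (!n_edges(network)) return(0L)
  sum(inset[network$edges[, 1]] & inset[network$edges[, 2]])
}

count_cross_edges <- function(network, g1, g2) {
  if (!n_edges(network)) return(0L)
  e1 <- network$edges[, 1]; e2 <- network$edges[, 2]
  sum((e1 %in% g1 & e2 %in% g2) | (e1 %in% g2 & e2 %in% g1))
}

#' Within-group connection density
#'
#' For a group of `V` compounds with `E` internal similarity edges, the
#' density is `E / (V (V - 1))` under the `"as-printed"` convention — the
#' form the summary-network statistic is defined with, which is half the
#' usual undirected graph density.  `convention = "undirected"` gives the
#' standard `2E / (V (V - 1))` instead.  Undefined (`NA`) for groups
#' smaller than 2.
#'
#' @param network a `structure_network`.
#' @param members character vector of member compound ids.
#' @param convention `"as-printed"` (default) or `"undirected"`.
#' @return the density, or `NA_real_` when `V < 2`.
#' @export
within_density <- function(network, members,
                           convention = c("as-printed", "undirected")) {
  convention <- match.arg(convention)
  v <- length(members)
  if (v < 2L) return(NA_real_)
  e <- count_internal_edges(network, members)
  dens <- e / (v * (v - 1))
  if (convention == "undirected") 2 * dens else dens
}

#' Between-group connection density
#'
#' `E / (V1 V2)` where `E` counts edges with one endpoint in each of two
#' disjoint groups.
#'
#' @param network a `structure_network`.
#' @param g1,g2 disjoint character vectors of compound ids.
#' @return the density in `[0, 1]`.
#' @export
between_density <- function(network, g1, g2) {
  if (!length(g1) || !length(g2)) stop2("both groups must be nonempty")
  if (length(intersect(g1, g2))) stop2("groups overlap")
  count_cross_edges(network, g1, g2) / (length(g1) * length(g2))
}

six_classes <- c("P-B", "I-B", "U-B", "P-NB", "I-NB", "U-NB")

#' Blocker/nonblocker enrichment of the six activity-predictability classes
#'
#' Each hBS level pairs one blocker class with one nonblocker class
#' (consistent votes: P-B with U-NB; intermediate: I-B with I-NB;
#' low votes: U-B with P-NB).  The enrichment of a class is its share of
#' its hBS level divided by the library-wide share of its activity class,
#' e.g. \deqn{E_{P\text{-}B} = \frac{P_B / (P_B + U_{NB})}{B / (B + NB)}.}
#' Values near 1 mean the level's composition mirrors the library; values
#' much greater than 1 mark levels that concentrate blockers (or
#' nonblockers).
#'
#' @param counts named numeric vector of class sizes over
#'   `c("P-B","I-B","U-B","P-NB","I-NB","U-NB")` (missing names count 0).
#' @param B,NB library-wide blocker and nonblocker totals; both must be
#'   positive.
#' @return named numeric vector of the six enrichments `E_P-B` ...
#'   `E_U-NB`; an enrichment is `NA` when its hBS level is empty.
#' @examples
#' enrichment_scores(c("P-B" = 90, "U-NB" = 10), B = 100, NB = 900)[["E_P-B"]]
#' # (90/100) / (100/1000) = 9
#' @export
enrichment_scores <- function(counts, B, NB) {
  if (!is_count(B, 0L) && !is.numeric(B)) stop2("B must be numeric")
  if (B <= 0) stop2("empty class: no blockers (B = 0)")
  if (NB <= 0) stop2("empty class: no nonblockers (NB = 0)")
  cnt <- stats::setNames(numeric(6), six_classes)
  known <- intersect(names(counts), six_classes)
  cnt[known] <- counts[known]
  b_frac <- B / (B + NB)
  nb_frac <- NB / (B + NB)
  pair_ratio <- function(num, den) {
    tot <- cnt[num] + cnt[den]
    if (tot == 0) NA_real_ else unname(cnt[num] / tot)
  }
  out <- c(
    "E_P-B"  = pair_ratio("P-B", "U-NB") / b_frac,
    "E_I-B"  = pair_ratio("I-B", "I-NB") / b_frac,
    "E_U-B"  = pair_ratio("U-B", "P-NB") / b_frac,
    "E_P-NB" = pair_ratio("P-NB", "U-B") / nb_frac,
    "E_I-NB" = pair_ratio("I-NB", "I-B") / nb_frac,
    "E_U-NB" = pair_ratio("U-NB", "P-B") / nb_frac)
  out
}

#' Build the six-class activity-predictability summary network
#'
#' Collapses a fitted ensemble onto six group nodes (P-B, I-B, U-B, P-NB,
#' I-NB, U-NB), with within-group and pairwise between-group connection
#' densities measured on the compound structure network, and per-class
#' blocker/nonblocker enrichments.  Raw densities are accompanied by a
#' max-normalized column (relative density), the quantity edge widths
#' encode in summary-network figures.
#'
#' @param ensemble a [herg_ensemble()] fit (or its `results` data frame
#'   with `id` and `combined` columns).
#' @param network the `structure_network` over the same compounds.
#' @param convention within-group density convention, see
#'   [within_density()].
#' @return a `summary_network`: `groups` (class, V, within_cd,
#'   relative_within_cd, enrichment), `between` (pairwise density matrix
#'   as a data frame), `B`, `NB`.
#' @export
build_summary_network <- function(ensemble, network,
                                  convention = c("as-printed", "undirected")) {
  convention <- match.arg(convention)
  res <- if (inherits(ensemble, "herg_ensemble")) ensemble$results else ensemble
  if (!all(c("id", "combined") %in% names(res)))
    stop2("ensemble results must carry id and combined class columns")
  members <- split(res$id, factor(res$combined, levels = six_classes))
  v <- lengths(members)
  if (sum(v) != nrow(res))
    stop2("unknown combined class value(s): %s",
          paste(setdiff(unique(res$combined), six_classes), collapse = ", "))
  wd <- vapply(members, function(m) within_density(network, m, convention),
               numeric(1))
  btw <- matrix(NA_real_, 6, 6, dimnames = list(six_classes, six_classes))
  for (i in 1:5) for (j in (i + 1):6) {
    g1 <- members[[i]]; g2 <- members[[j]]
    if (length(g1) && length(g2)) {
      d <- between_density(network, g1, g2)
      btw[i, j] <- d; btw[j, i] <- d
    }
  }
  act <- sub("^[PIU]-", "", res$combined)
  B <- sum(act == "B"); NB <- sum(act == "NB")
  enr <- tryCatch(enrichment_scores(v, B, NB), error = function(e) {
    warn2("enrichments unavailable: %s", conditionMessage(e))
    stats::setNames(rep(NA_real_, 6), paste0("E_", six_classes))
  })
  all_d <- c(wd, btw[upper.tri(btw)])
  dmax <- suppressWarnings(max(all_d, na.rm = TRUE))
  rel <- if (is.finite(dmax) && dmax > 0) wd / dmax else wd * NA_real_
  groups <- data.frame(class = six_classes, V = as.integer(v),
                       within_cd = unname(wd),
                       relative_within_cd = unname(rel),
                       enrichment = unname(enr[paste0("E_", six_classes)]),
                       stringsAsFactors = FALSE)
  structure(list(groups = groups, between = as.data.frame(btw),
                 B = B, NB = NB, convention = convention,
                 density_max = dmax),
            class = "summary_network")
}

#' @export
print.summary_network <- function(x, ...) {
  cat(sprintf("summary network over %d blockers / %d nonblockers (%s density)\n",
              x$B, x$NB, x$convention))
  print(x$groups, digits = 4)
  cat("between-group connection densities:\n")
  print(round(as.matrix(x$between), 6))
  invisible(x)
}
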