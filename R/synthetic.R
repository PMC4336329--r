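#' Configuration for the synthetic screening-library generator
#'
#' Describes a synthetic compound library with the statistical structure a
#' diverse high-throughput hERG screen is assumed to have: a small fraction
#' (default 5%) of blockers concentrated in a few structurally tight
#' "potent" fingerprint clusters, moderate inhibitors spread over
#' structurally heterogeneous clusters, and per-well patch-clamp QC
#' metadata of which a small fraction fails.
#'
#' Fingerprints are generated directly as bit sets: each cluster owns a
#' marker-bit template; a compound switches on its cluster template (potent
#' clusters keep the full template, moderate clusters retain each template
#' bit with probability `moderate_retention`, making them heterogeneous),
#' adds `background_bits` random bits, and finally every one of the
#' `n_bits` positions is flipped independently with probability
#' `bit_flip_prob`.  10 uM percent inhibition is drawn from a Normal with
#' the cluster's potency mean, truncated to `[-20, 100]`; 1 uM inhibition
#' is a monotone shrinkage of the 10 uM value.
#'
#' @param n_compounds library size.
#' @param n_bits fingerprint length in bits.
#' @param n_clusters number of structural communities.
#' @param blocker_fraction target proportion of blockers (>50% inhibition
#'   at 10 uM) in `[0, 1]`.
#' @param cluster_potency_mean optional numeric vector of length
#'   `n_clusters` giving each cluster's mean percent inhibition; by default
#'   potent clusters sit at 85 and moderate clusters span 5--45.
#' @param potency_sd percent-inhibition noise around the cluster mean.
#' @param bit_flip_prob per-bit corruption probability in `[0, 0.5)`.
#' @param marker_bits_per_cluster template size per cluster.
#' @param background_bits random extra on-bits per compound.
#' @param moderate_retention probability a moderate-cluster compound keeps
#'   each template bit (structural heterogeneity of weak inhibitors).
#' @param qc_fail_rate fraction of wells drawn from the failing QC mixture.
#' @param descriptors if `TRUE`, physicochemical descriptor columns (logP,
#'   basic/acidic pKa, Wiener index) are simulated for the Winnow learner.
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 5000L, n_bits = 1024L,
                             n_clusters = 20L, blocker_fraction = 0.05,
                             cluster_potency_mean = NULL, potency_sd = 8,
                             bit_flip_prob = 0.02,
                             marker_bits_per_cluster = 200L,
                             background_bits = 8L,
                             moderate_retention = 0.7,
                             qc_fail_rate = 0.04,
                             descriptors = TRUE, seed = 1L) {
  if (!is_count(n_compounds)) stop2("n_compounds must be a non-negative integer")
  if (!is_count(n_bits, 1L)) stop2("n_bits must be a positive integer")
  if (!is_count(n_clusters, 1L)) stop2("n_clusters must be >= 1")
  if (!is_prob(blocker_fraction)) stop2("blocker_fraction must be in [0, 1]")
  if (!is.numeric(bit_flip_prob) || bit_flip_prob < 0 || bit_flip_prob >= 0.5)
    stop2("bit_flip_prob must be in [0, 0.5)")
  if (!is_count(marker_bits_per_cluster, 1L) ||
      marker_bits_per_cluster > n_bits)
    stop2("marker_bits_per_cluster must be in [1, n_bits]")
  if (!is_count(background_bits)) stop2("background_bits must be >= 0")
  if (!is_prob(moderate_retention)) stop2("moderate_retention must be in [0, 1]")
  if (!is_prob(qc_fail_rate)) stop2("qc_fail_rate must be in [0, 1]")
  if (!is.null(cluster_potency_mean)) {
    if (length(cluster_potency_mean) != n_clusters)
      stop2("cluster_potency_mean must have length n_clusters")
    if (blocker_fraction > 0 && !any(cluster_potency_mean > 50))
      stop2("blocker_fraction > 0 infeasible: no cluster potency mean > 50")
  }
  structure(list(
    n_compounds = as.integer(n_compounds), n_bits = as.integer(n_bits),
    n_clusters = as.integer(n_clusters),
    blocker_fraction = blocker_fraction,
    cluster_potency_mean = cluster_potency_mean,
    potency_sd = potency_sd, bit_flip_prob = bit_flip_prob,
    marker_bits_per_cluster = as.integer(marker_bits_per_cluster),
    background_bits = as.integer(background_bits),
    moderate_retention = moderate_retention,
    qc_fail_rate = qc_fail_rate, descriptors = isTRUE(descriptors),
    seed = as.integer(seed)), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic library config: n=%d, %d clusters, %d-bit ",
                     "fingerprints,\n  blocker fraction %.3f, bit flip %.3f, ",
                     "seed %d\n"),
              x$n_compounds, x$n_clusters, x$n_bits, x$blocker_fraction,
              x$bit_flip_prob, x$seed))
  invisible(x)
}

# Truncated-normal draw on [lo, hi] by inverse-CDF (exact truncation, no
# boundary atoms from clamping).
rtruncnorm <- function(n, mean, sd, lo = -20, hi = 100) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Resolve the cluster design implied by a config: which clusters are potent,
# their potency means, and their marker templates.
cluster_design <- function(config) {
  k <- config$n_clusters
  means <- config$cluster_potency_mean
  if (is.null(means)) {
    k_pot <- if (config$blocker_fraction > 0) max(1L, round(config$blocker_fraction * k)) else 0L
    k_pot <- min(k_pot, k)
    means <- numeric(k)
    if (k_pot > 0L) means[seq_len(k_pot)] <- 85
    # moderate means capped at 35 so their Normal(., potency_sd) tails above
    # the 50% blocker threshold stay negligible and the realized blocker
    # fraction tracks blocker_fraction
    if (k > k_pot)
      means[(k_pot + 1L):k] <- seq(5, 35, length.out = k - k_pot)
  }
  potent <- means > 50
  if (config$blocker_fraction > 0 && !any(potent))
    stop2("blocker_fraction > 0 infeasible: no potent cluster in design")
  templates <- lapply(seq_len(k), function(i)
    sort(sample.int(config$n_bits, config$marker_bits_per_cluster) - 1L))
  list(means = means, potent = potent, templates = templates)
}

# Draw one library body (fingerprints, activities, descriptors) given a
# design and cluster assignment.  All randomness comes from the current
# RNG stream (callers seed it).
draw_compounds <- function(config, design, cluster, id_prefix = "CMP") {
  n <- length(cluster)
  nb <- config$n_bits
  fps <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- cluster[i]
    tmpl <- design$templates[[cl]]
    if (!design$potent[cl] && config$moderate_retention < 1)
      tmpl <- tmpl[stats::runif(length(tmpl)) < config$moderate_retention]
    on <- logical(nb)
    on[tmpl + 1L] <- TRUE
    if (config$background_bits > 0L)
      on[sample.int(nb, config$background_bits)] <- TRUE
    if (config$bit_flip_prob > 0) {
      flip <- stats::runif(nb) < config$bit_flip_prob
      on <- xor(on, flip)
    }
    fps[[i]] <- chemfp(which(on) - 1L, nb)
  }
  inhib10 <- rtruncnorm(n, design$means[cluster], config$potency_sd)
  shrink <- stats::rbeta(n, 5, 2)
  inhib1 <- ifelse(inhib10 >= 0, inhib10 * shrink,
                   pmax(inhib10 / shrink, -20))
  # per-well QC metadata: mixture of passing and failing wells
  fail <- stats::runif(n) < config$qc_fail_rate
  tail_nA <- 0.25 + stats::rgamma(n, shape = 4, rate = 10)
  seal_MOhm <- stats::runif(n, 35, 120)
  drop_pct <- stats::runif(n, 0, 20)
  if (any(fail)) {
    mode <- sample(3L, sum(fail), replace = TRUE)
    idx <- which(fail)
    tail_nA[idx[mode == 1L]] <- stats::runif(sum(mode == 1L), 0, 0.2)
    seal_MOhm[idx[mode == 2L]] <- stats::runif(sum(mode == 2L), 5, 30)
    drop_pct[idx[mode == 3L]] <- stats::runif(sum(mode == 3L), 25, 60)
  }
  lib <- data.frame(
    id = sprintf("%s%06d", id_prefix, seq_len(n)),
    cluster = cluster,
    inhib_1uM = inhib1, inhib_10uM = inhib10,
    tail_nA = tail_nA, seal_MOhm = seal_MOhm, drop_pct = drop_pct,
    source = rep("synthetic", n),
    stringsAsFactors = FALSE)
  if (config$descriptors) {
    lib$logP <- stats::rnorm(n, 2.5 + 1.5 * design$potent[cluster], 1.2)
    lib$max_basic_pKa <- ifelse(stats::runif(n) < 0.5,
                                stats::rnorm(n, 8, 1.5), NA_real_)
    lib$min_acidic_pKa <- ifelse(stats::runif(n) < 0.4,
                                 stats::rnorm(n, 5, 2), NA_real_)
    lib$wiener_index <- round(stats::rlnorm(n, log(800), 0.5))
  }
  lib$fingerprint <- fps
  class(lib) <- c("compound_library", "data.frame")
  lib
}

#' Generate a synthetic screening library
#'
#' Draws a library under a [synthetic_config()]: compounds are assigned to
#' structural clusters, potent clusters (potency mean > 50) hold
#' approximately `blocker_fraction` of the library, and fingerprints are
#' cluster templates plus bit noise.  The output is the common currency of
#' the package: a `compound_library` data frame with a `fingerprint` list
#' column, activity columns, QC metadata, and optional descriptors.
#'
#' @param config a [synthetic_config()].
#' @return a `compound_library` data frame; the cluster design is attached
#'   as attributes `design` and `config`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    design <- cluster_design(config)
    n <- config$n_compounds
    if (n == 0L) {
      lib <- draw_compounds(config, design, integer(0))
    } else {
      potent_ids <- which(design$potent)
      moderate_ids <- which(!design$potent)
      is_blk <- stats::runif(n) < config$blocker_fraction
      cluster <- integer(n)
      if (length(potent_ids) == 0L) is_blk[] <- FALSE
      if (length(moderate_ids) == 0L) is_blk[] <- TRUE
      cluster[is_blk] <- potent_ids[sample.int(length(potent_ids),
                                               sum(is_blk), replace = TRUE)]
      cluster[!is_blk] <- moderate_ids[sample.int(length(moderate_ids),
                                                  sum(!is_blk), replace = TRUE)]
      lib <- draw_compounds(config, design, cluster)
    }
    attr(lib, "design") <- design
    attr(lib, "config") <- config
    lib
  })
}

#' Generate a structure-free null library
#'
#' Same structural clusters as [generate_library()], but the activity
#' annotations (1 uM and 10 uM inhibition, jointly) are randomly permuted
#' across compounds, so the joint distribution of (fingerprint, activity)
#' factorizes.  Used to check calibration of the chemical-club permutation
#' test.
#'
#' @param config a [synthetic_config()].
#' @return a `compound_library` data frame.
#' @export
generate_null_library <- function(config) {
  lib <- generate_library(config)
  n <- nrow(lib)
  if (n > 1L) {
    perm <- with_seed((config$seed %% 1000000000L) + 1000003L, sample.int(n))
    lib$inhib_1uM <- lib$inhib_1uM[perm]
    lib$inhib_10uM <- lib$inhib_10uM[perm]
    if ("label" %in% names(lib)) lib$label <- lib$label[perm]
  }
  lib
}

#' Generate an external library partitioned into assay plates
#'
#' Emulates an unseen screening collection (the role the DIVERSet plays for
#' a reference screen): a configurable fraction of its structural clusters
#' reuse marker templates (and potency means) from a reference library, the
#' rest are novel moderate clusters, and compounds are grouped into
#' 384-well plates.  Per-plate cluster mixtures are Dirichlet-distributed,
#' so plate-level blocker counts vary — the quantity plate-level risk
#' ranking is evaluated on.
#'
#' @param config a [synthetic_config()] describing the external collection.
#' @param reference a library produced by [generate_library()] (its cluster
#'   design is read from attributes).
#' @param overlap_fraction fraction of the external clusters that reuse
#'   reference templates, in `[0, 1]`.
#' @param plate_size compounds per plate (default 384).
#' @return a `compound_library` with a `plate` column.
#' @export
generate_external_library <- function(config, reference, overlap_fraction = 0.5,
                                      plate_size = 384L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is_prob(overlap_fraction)) stop2("overlap_fraction must be in [0, 1]")
  ref_design <- attr(reference, "design")
  if (is.null(ref_design) || nrow(reference) == 0L)
    stop2("reference must be a nonempty library from generate_library()")
  ref_config <- attr(reference, "config")
  if (!is.null(ref_config) && ref_config$n_bits != config$n_bits)
    stop2("reference and external fingerprint lengths differ")
  with_seed(config$seed, {
    k <- config$n_clusters
    n_overlap <- round(overlap_fraction * k)
    k_ref <- length(ref_design$templates)
    # reuse reference clusters, potent ones first so shared chemotypes
    # include the high-risk neighbourhoods
    ref_order <- order(!ref_design$potent)
    take <- ref_order[seq_len(min(n_overlap, k_ref))]
    n_new <- k - length(take)
    means <- c(ref_design$means[take],
               if (n_new > 0) seq(5, 35, length.out = n_new))
    templates <- c(ref_design$templates[take],
                   lapply(seq_len(n_new), function(i)
                     sort(sample.int(config$n_bits,
                                     config$marker_bits_per_cluster) - 1L)))
    design <- list(means = means, potent = means > 50, templates = templates)
    n <- config$n_compounds
    n_plates <- if (n > 0L) ceiling(n / plate_size) else 0L
    plate <- rep(seq_len(n_plates), each = plate_size)[seq_len(n)]
    cluster <- integer(n)
    for (p in seq_len(n_plates)) {
      idx <- which(plate == p)
      w <- stats::rgamma(k, shape = 0.5)  # Dirichlet(0.5) plate mixture
      cluster[idx] <- sample.int(k, length(idx), replace = TRUE, prob = w / sum(w))
    }
    lib <- draw_compounds(config, design, cluster, id_prefix = "EXT")
    lib$plate <- plate
    attr(lib, "design") <- design
    attr(lib, "config") <- config
    attr(lib, "overlap_clusters") <- length(take)
    lib
  })
}

#' @export
print.compound_library <- function(x, ...) {
  nb <- if (nrow(x) && !is.null(x$fingerprint[[1]])) x$fingerprint[[1]]$n_bits else NA
  cat(sprintf("compound library: %d compounds (%s-bit fingerprints)\n",
              nrow(x), nb))
  if ("label" %in% names(x)) {
    tb <- table(x$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}
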