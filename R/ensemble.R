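#' Random k-fold plan over a library
#'
#' Seeded near-equal partition: folds are disjoint, cover the library, and
#' differ in size by at most one.
#'
#' @param n library size (or a `compound_library`).
#' @param k number of folds, default 5.
#' @param seed RNG seed.
#' @return integer fold ids of length `n`, with attributes `k` and `seed`.
#' @export
make_folds <- function(n, k = 5L, seed = NULL) {
  if (inherits(n, "data.frame")) n <- nrow(n)
  if (!is_count(k, 2L)) stop2("k must be an integer >= 2")
  if (k > n) stop2("k = %d exceeds library size %d", k, n)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  attr(fold, "k") <- as.integer(k)
  attr(fold, "seed") <- seed
  fold
}

#' Balanced training batches for an imbalanced screen
#'
#' Corrects the class imbalance of a naive screening library (about 5%
#' blockers) by building `floor(NB/B)` batches, each containing all `B`
#' training blockers plus an equally sized random sample of nonblockers
#' drawn without replacement within a batch and independently across
#' batches.
#'
#' @param labels training labels (`"blocker"`/`"nonblocker"`, logical or
#'   0/1).
#' @param seed RNG seed.
#' @return list of integer index vectors (one per batch, ascending order).
#' @export
balanced_batches <- function(labels, seed = NULL) {
  blk <- as_blocker(labels)
  b_idx <- which(blk); nb_idx <- which(!blk)
  if (!length(b_idx)) stop2("no blockers in the training data")
  if (!length(nb_idx)) stop2("no nonblockers in the training data")
  n_batches <- length(nb_idx) %/% length(b_idx)
  if (n_batches < 1L)
    stop2("fewer nonblockers than blockers; balanced batching undefined")
  with_seed(seed, {
    lapply(seq_len(n_batches), function(i)
      sort(c(b_idx, sample(nb_idx, length(b_idx)))))
  })
}

#' Discretize a predictability score
#'
#' Predictable (P) for `PS >= 0.95`, unpredictable (U) for `PS <= 0.05`,
#' inconsistent (I) otherwise.  Both boundaries are closed, mirroring the
#' definitions of the P and U classes.
#'
#' @param ps predictability scores in `[0, 1]`.
#' @return character vector of `"P"`, `"I"`, `"U"`.
#' @export
assign_predictability <- function(ps) {
  stopifnot(all(ps >= 0 & ps <= 1, na.rm = TRUE))
  ifelse(ps >= 0.95, "P", ifelse(ps <= 0.05, "U", "I"))
}

#' Consensus predictability of two classifier families
#'
#' P iff both families call P, U iff both call U, otherwise I.
#'
#' @param a,b per-family predictability classes (`"P"`, `"I"`, `"U"`).
#' @return consensus classes.
#' @export
consensus_class <- function(a, b) {
  ifelse(a == "P" & b == "P", "P", ifelse(a == "U" & b == "U", "U", "I"))
}

#' Bin a hERG Blocker Score
#'
#' High for `hBS > 0.95`, low for `hBS < 0.05`, intermediate otherwise;
#' both boundaries are open (strict), so 0.95 and 0.05 fall in the
#' intermediate bin.  Note the deliberate asymmetry with
#' [assign_predictability()], whose boundaries are closed.
#'
#' @param hbs scores in `[0, 1]`.
#' @return character vector of `"high"`, `"intermediate"`, `"low"`.
#' @export
hbs_bin <- function(hbs) {
  stopifnot(all(hbs >= 0 & hbs <= 1, na.rm = TRUE))
  ifelse(hbs > 0.95, "high", ifelse(hbs < 0.05, "low", "intermediate"))
}

descriptor_columns <- function(lib) {
  intersect(c("logP", "max_basic_pKa", "min_acidic_pKa", "wiener_index"),
            names(lib))
}

# Train one family's models on each balanced batch and accumulate blocker
# votes on the target rows.  Returns votes matrix (targets x batches).
vote_matrix <- function(family, x_train_fun, y, batches, x_target,
                        alpha, theta, n_epochs, C, gamma) {
  votes <- matrix(NA, nrow = nrow(x_target), ncol = length(batches))
  for (b in seq_along(batches)) {
    idx <- batches[[b]]
    xb <- x_train_fun(idx)
    if (family == "winnow") {
      m <- winnow_train(xb, y[idx], alpha = alpha, theta = theta,
                        n_epochs = n_epochs)
      votes[, b] <- predict(m, x_target) == "blocker"
    } else {
      m <- kernel_train(xb, y[idx], C = C, gamma = gamma)
      votes[, b] <- predict(m, x_target) == "blocker"
    }
  }
  votes
}

#' Fit the balanced-batch hERG ensemble classifier
#'
#' The central fitting function of the package.  The library is split into
#' `k` seeded folds; for each fold, an ensemble of Winnow and RBF-kernel
#' classifiers is trained on balanced batches of the remaining folds (each
#' batch: all training blockers plus an equal random draw of nonblockers),
#' and every held-out compound receives one binary blocker vote per model.
#' Averaging the votes of both families gives the hERG Blocker Score
#' (hBS); the fraction of votes matching the true label is the
#' Predictability Score (PS), so `PS = hBS` for blockers and `1 - hBS` for
#' nonblockers, exactly.  Per-family PS classes (P/I/U) are intersected
#' into a consensus, and each compound lands in one of the six
#' activity-predictability classes (P-B ... U-NB).
#'
#' Winnow sees fingerprint bits plus quantile-binned physicochemical
#' descriptors (binned on the training folds only); the kernel family sees
#' the raw fingerprint bits.  Kernel hyperparameters are grid-searched
#' once, on the first balanced batch of fold 1, then frozen for every
#' batch.
#'
#' @param lib a `compound_library` with fingerprints; labels are derived
#'   with [binarize_labels()] if absent.
#' @param k folds (default 5).
#' @param seed master seed; fold, grid-search and batch seeds are derived
#'   from it.
#' @param families subset of `c("winnow", "svm")`.
#' @param alpha,theta,n_epochs Winnow hyperparameters (see
#'   [winnow_train()]).
#' @param C,gamma kernel hyperparameters; `NULL` (default) triggers the
#'   one-off grid search.
#' @param n_bins descriptor quantile bins for Winnow.
#' @param threshold blocker threshold for label derivation.
#' @return a `herg_ensemble` object: `results` (per-compound data frame),
#'   `folds`, `kernel_params`, `batch_counts`, and the call parameters.
#' @seealso [predict_external()] for scoring an unseen library.
#' @export
herg_ensemble <- function(lib, k = 5L, seed = 1L,
                          families = c("winnow", "svm"),
                          alpha = 2, theta = NULL, n_epochs = 1L,
                          C = NULL, gamma = NULL, n_bins = 10L,
                          threshold = 50) {
  families <- match.arg(families, c("winnow", "svm"), several.ok = TRUE)
  if (!"label" %in% names(lib)) lib <- binarize_labels(lib, threshold)
  n <- nrow(lib)
  blk <- as_blocker(lib$label)
  x_fp <- fp_matrix(lib$fingerprint)
  desc <- descriptor_columns(lib)
  seeds <- derive_seeds(seed, k + 2L)
  folds <- make_folds(n, k, seed = seeds[[1]])

  kernel_params <- list(C = C, gamma = gamma)
  if ("svm" %in% families && (is.null(C) || is.null(gamma))) {
    tr1 <- which(folds != 1L)
    b1 <- balanced_batches(blk[tr1], seed = seeds[[3]])[[1]]
    gs <- kernel_grid_search(x_fp[tr1[b1], , drop = FALSE], blk[tr1[b1]],
                             seed = seeds[[2]])
    kernel_params <- list(C = gs$C, gamma = gs$gamma)
  }

  vote_sum <- stats::setNames(
    rep(list(numeric(n)), length(families)), families)
  vote_n <- stats::setNames(
    rep(list(integer(n)), length(families)), families)
  batch_counts <- integer(k)

  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    batches_local <- balanced_batches(blk[train], seed = seeds[[2L + f]])
    batches <- lapply(batches_local, function(b) train[b])
    batch_counts[f] <- length(batches)
    if ("winnow" %in% families) {
      if (length(desc)) {
        bins <- fit_descriptor_bins(lib[train, desc, drop = FALSE], n_bins)
        ind_all <- apply_descriptor_bins(bins, lib[, desc, drop = FALSE])
        xw <- cbind(x_fp, ind_all)
      } else xw <- x_fp
      v <- vote_matrix("winnow", function(idx) xw[idx, , drop = FALSE],
                       blk, batches, xw[test, , drop = FALSE],
                       alpha, theta, n_epochs, NULL, NULL)
      vote_sum$winnow[test] <- rowSums(v)
      vote_n$winnow[test] <- ncol(v)
    }
    if ("svm" %in% families) {
      v <- vote_matrix("svm", function(idx) x_fp[idx, , drop = FALSE],
                       blk, batches, x_fp[test, , drop = FALSE],
                       alpha, theta, n_epochs,
                       kernel_params$C, kernel_params$gamma)
      vote_sum$svm[test] <- rowSums(v)
      vote_n$svm[test] <- ncol(v)
    }
  }

  tot_sum <- Reduce(`+`, vote_sum)
  tot_n <- Reduce(`+`, vote_n)
  hbs <- tot_sum / tot_n
  ps <- ifelse(blk, hbs, 1 - hbs)
  res <- data.frame(id = lib$id, label = lib$label,
                    activity_class = ifelse(blk, "B", "NB"),
                    fold = folds, hBS = hbs, PS = ps,
                    stringsAsFactors = FALSE)
  fam_class <- list()
  for (fam in families) {
    h <- vote_sum[[fam]] / vote_n[[fam]]
    p <- ifelse(blk, h, 1 - h)
    res[[paste0("hBS_", fam)]] <- h
    res[[paste0("PS_", fam)]] <- p
    fam_class[[fam]] <- assign_predictability(p)
    res[[paste0("class_", fam)]] <- fam_class[[fam]]
  }
  res$predictability <- if (length(families) == 2L)
    consensus_class(fam_class[[1]], fam_class[[2]]) else fam_class[[1]]
  res$combined <- paste(res$predictability, res$activity_class, sep = "-")
  structure(list(results = res, folds = folds, k = as.integer(k),
                 seed = seed, families = families,
                 kernel_params = kernel_params,
                 batch_counts = batch_counts,
                 alpha = alpha, theta = theta, n_epochs = n_epochs,
                 n_bins = n_bins, threshold = threshold,
                 call = match.call()),
            class = "herg_ensemble")
}

#' @export
print.herg_ensemble <- function(x, ...) {
  cat(sprintf(paste0("hERG balanced-batch ensemble: %d compounds, %d folds, ",
                     "families: %s\n"),
              nrow(x$results), x$k, paste(x$families, collapse = "+")))
  if (!is.null(x$kernel_params$C))
    cat(sprintf("  kernel: C=%g, gamma=%g\n",
                x$kernel_params$C, x$kernel_params$gamma))
  cat(sprintf("  votes per family per fold: %s\n",
              paste(x$batch_counts, collapse = ", ")))
  tb <- table(x$results$combined)
  cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.herg_ensemble <- function(object, ...) {
  res <- object$results
  out <- list(
    n = nrow(res),
    class_counts = table(res$combined),
    hbs_bins = table(hbs_bin(res$hBS)),
    blocker_fraction = mean(res$activity_class == "B"),
    mean_hbs_blockers = mean(res$hBS[res$activity_class == "B"]),
    mean_hbs_nonblockers = mean(res$hBS[res$activity_class == "NB"]))
  class(out) <- "summary.herg_ensemble"
  out
}

#' @export
print.summary.herg_ensemble <- function(x, ...) {
  cat(sprintf("ensemble of %d compounds (%.1f%% blockers)\n",
              x$n, 100 * x$blocker_fraction))
  cat(sprintf("  mean hBS: blockers %.3f, nonblockers %.3f\n",
              x$mean_hbs_blockers, x$mean_hbs_nonblockers))
  cat("  hBS bins: ",
      paste(sprintf("%s=%d", names(x$hbs_bins), x$hbs_bins), collapse = ", "),
      "\n")
  cat("  activity-predictability classes:\n")
  print(x$class_counts)
  invisible(x)
}

#' Histogram of hERG Blocker Scores
#'
#' @param x a `herg_ensemble`.
#' @param breaks histogram breaks (default 40 equal bins on `[0, 1]`).
#' @param ... passed to [graphics::hist()].
#' @export
plot.herg_ensemble <- function(x, breaks = seq(0, 1, length.out = 41), ...) {
  graphics::hist(x$results$hBS, breaks = breaks, xlab = "hERG Blocker Score",
                 main = "hBS distribution", ...)
  invisible(x)
}

#' Score an external library with a reference-trained ensemble
#'
#' Trains the balanced-batch ensemble on the full reference library (no
#' folds) and applies it to an unseen collection partitioned into assay
#' plates.  External compounds already present in the reference (matched
#' by id, and by identical canonical structure when both sides carry
#' SMILES) are excluded from evaluation and listed in the dedup report.
#' A compound is a predicted blocker iff its average hBS over both
#' families strictly exceeds `hbs_cutoff` (default 0.9).  When the
#' external library carries inhibition measurements, per-plate recall and
#' the least-squares R-squared of predicted on observed per-plate blocker
#' counts are reported, along with the Spearman rank correlation of the
#' plate ranking.
#'
#' @param reference labelled, fingerprinted `compound_library` to train
#'   on.
#' @param external `compound_library` to score; a `plate` column groups
#'   compounds into plates.
#' @param hbs_cutoff predicted-blocker cutoff on hBS (strict), default
#'   0.9.
#' @param seed master seed.
#' @inheritParams herg_ensemble
#' @return a `herg_prediction`: `compounds` (id, plate, hBS, predicted),
#'   `plates` (per-plate counts and recall), `recall`, `r_squared`,
#'   `rank_correlation`, `dedup`.
#' @export
predict_external <- function(reference, external, hbs_cutoff = 0.9,
                             seed = 1L, families = c("winnow", "svm"),
                             alpha = 2, theta = NULL, n_epochs = 1L,
                             C = NULL, gamma = NULL, n_bins = 10L,
                             threshold = 50) {
  families <- match.arg(families, c("winnow", "svm"), several.ok = TRUE)
  if (!nrow(external)) stop2("empty external set")
  if (!"label" %in% names(reference))
    reference <- binarize_labels(reference, threshold)
  dup <- external$id %in% reference$id
  if ("smiles" %in% names(external) && "smiles" %in% names(reference))
    dup <- dup | (!is.na(external$smiles) &
                    external$smiles %in% stats::na.omit(reference$smiles))
  dedup <- list(n_removed = sum(dup), ids = external$id[dup])
  external <- external[!dup, , drop = FALSE]
  if (!nrow(external)) stop2("no external compounds left after deduplication")

  blk <- as_blocker(reference$label)
  x_fp <- fp_matrix(reference$fingerprint)
  x_ext <- fp_matrix(external$fingerprint)
  if (ncol(x_ext) != ncol(x_fp))
    stop2("reference and external fingerprint lengths differ")
  desc <- descriptor_columns(reference)
  desc <- intersect(desc, descriptor_columns(external))
  seeds <- derive_seeds(seed, 3L)
  batches <- balanced_batches(blk, seed = seeds[[1]])

  kernel_params <- list(C = C, gamma = gamma)
  if ("svm" %in% families && (is.null(C) || is.null(gamma))) {
    b1 <- batches[[1]]
    gs <- kernel_grid_search(x_fp[b1, , drop = FALSE], blk[b1],
                             seed = seeds[[2]])
    kernel_params <- list(C = gs$C, gamma = gs$gamma)
  }

  vote_sum <- numeric(nrow(external)); vote_n <- 0L
  if ("winnow" %in% families) {
    if (length(desc)) {
      bins <- fit_descriptor_bins(reference[, desc, drop = FALSE], n_bins)
      xw <- cbind(x_fp, apply_descriptor_bins(bins, reference[, desc, drop = FALSE]))
      xw_ext <- cbind(x_ext, apply_descriptor_bins(bins, external[, desc, drop = FALSE]))
    } else { xw <- x_fp; xw_ext <- x_ext }
    v <- vote_matrix("winnow", function(idx) xw[idx, , drop = FALSE],
                     blk, batches, xw_ext, alpha, theta, n_epochs, NULL, NULL)
    vote_sum <- vote_sum + rowSums(v); vote_n <- vote_n + ncol(v)
  }
  if ("svm" %in% families) {
    v <- vote_matrix("svm", function(idx) x_fp[idx, , drop = FALSE],
                     blk, batches, x_ext, alpha, theta, n_epochs,
                     kernel_params$C, kernel_params$gamma)
    vote_sum <- vote_sum + rowSums(v); vote_n <- vote_n + ncol(v)
  }
  hbs <- vote_sum / vote_n
  predicted <- hbs > hbs_cutoff
  compounds <- data.frame(id = external$id,
                          plate = external$plate %||% rep(1L, nrow(external)),
                          hBS = hbs, predicted_blocker = predicted,
                          stringsAsFactors = FALSE)
  has_labels <- "inhib_10uM" %in% names(external) &&
    !anyNA(external$inhib_10uM)
  plates <- NULL; recall <- NA_real_; r2 <- NA_real_; rank_cor <- NA_real_
  if (has_labels) {
    obs_blk <- external$inhib_10uM > threshold
    pl <- sort(unique(compounds$plate))
    plates <- data.frame(plate = pl)
    plates$n <- vapply(pl, function(p) sum(compounds$plate == p), integer(1))
    plates$predicted_blockers <- vapply(pl, function(p)
      sum(predicted[compounds$plate == p]), integer(1))
    plates$observed_blockers <- vapply(pl, function(p)
      sum(obs_blk[compounds$plate == p]), integer(1))
    plates$recall <- vapply(pl, function(p) {
      sel <- compounds$plate == p & obs_blk
      if (!any(sel)) NA_real_ else mean(predicted[sel])
    }, numeric(1))
    recall <- if (any(obs_blk)) mean(predicted[obs_blk]) else NA_real_
    if (nrow(plates) >= 3L && stats::sd(plates$observed_blockers) > 0) {
      fit <- stats::lm(predicted_blockers ~ observed_blockers, data = plates)
      r2 <- summary(fit)$r.squared
      rank_cor <- stats::cor(plates$predicted_blockers,
                             plates$observed_blockers, method = "spearman")
    }
  } else {
    pl <- sort(unique(compounds$plate))
    plates <- data.frame(plate = pl)
    plates$n <- vapply(pl, function(p) sum(compounds$plate == p), integer(1))
    plates$predicted_blockers <- vapply(pl, function(p)
      sum(predicted[compounds$plate == p]), integer(1))
  }
  structure(list(compounds = compounds, plates = plates, recall = recall,
                 r_squared = r2, rank_correlation = rank_cor,
                 dedup = dedup, hbs_cutoff = hbs_cutoff,
                 kernel_params = kernel_params, seed = seed,
                 n_votes = vote_n),
            class = "herg_prediction")
}

#' @export
print.herg_prediction <- function(x, ...) {
  cat(sprintf(paste0("external prediction: %d compounds on %d plates ",
                     "(cutoff hBS > %g, %d votes)\n"),
              nrow(x$compounds), nrow(x$plates), x$hbs_cutoff, x$n_votes))
  if (x$dedup$n_removed)
    cat(sprintf("  %d duplicate(s) of the reference excluded\n",
                x$dedup$n_removed))
  cat(sprintf("  predicted blockers: %d\n", sum(x$compounds$predicted_blocker)))
  if (!is.na(x$recall))
    cat(sprintf("  recall %.3f, plate R^2 %.3f, rank correlation %.3f\n",
                x$recall, x$r_squared, x$rank_correlation))
  invisible(x)
}
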