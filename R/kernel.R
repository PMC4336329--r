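#' Train a soft-margin RBF-kernel classifier
#'
#' Thin, contract-stable wrapper around [e1071::svm()] with a radial basis
#' kernel on (typically 1024-bit) fingerprint vectors.  Features are not
#' rescaled: bits are already on a common 0/1 scale.
#'
#' @param x 0/1 feature matrix.
#' @param y labels (`"blocker"`/`"nonblocker"`, logical or 0/1).
#' @param C soft-margin cost.
#' @param gamma RBF kernel width.
#' @return a `kernel_model`.
#' @export
kernel_train <- function(x, y, C = 1, gamma = 1 / ncol(x)) {
  x <- as.matrix(x)
  yy <- factor(ifelse(as_blocker(y), "blocker", "nonblocker"),
               levels = c("nonblocker", "blocker"))
  if (length(unique(yy)) < 2L)
    stop2("degenerate single-class training batch")
  fit <- e1071::svm(x, yy, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, C = C, gamma = gamma), class = "kernel_model")
}

#' @export
predict.kernel_model <- function(object, newdata, ...) {
  as.character(predict(object$fit, as.matrix(newdata)))
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf("RBF-kernel classifier: C=%g, gamma=%g, %d support vectors\n",
              x$C, x$gamma, x$fit$tot.nSV))
  invisible(x)
}

#' Grid search for RBF cost and kernel width
#'
#' Exhaustive search over a `(C, gamma)` grid, scoring each pair by mean
#' balanced accuracy (average of sensitivity and specificity) under
#' k-fold cross-validation with seeded fold assignment; ties resolve to
#' the first grid member in row-major order, so the result is
#' deterministic given the seed.
#'
#' @param x 0/1 feature matrix.
#' @param y labels.
#' @param C_grid cost grid (default powers of 4 from 2^-5 to 2^15).
#' @param gamma_grid width grid (default powers of 4 from 2^-15 to 2^3).
#' @param k folds, default 5.
#' @param seed fold-assignment seed.
#' @return list with `C`, `gamma` (members of the grids) and `scores`
#'   (the CV table).
#' @export
kernel_grid_search <- function(x, y, C_grid = 2^seq(-5, 15, by = 4),
                               gamma_grid = 2^seq(-15, 3, by = 4),
                               k = 5L, seed = NULL) {
  x <- as.matrix(x)
  yy <- as_blocker(y)
  n <- nrow(x)
  if (!is_count(k, 2L) || k > n) stop2("k must be in [2, n]")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  grid <- expand.grid(C = C_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$balanced_accuracy <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    accs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(yy[tr])) < 2L) return(NA_real_)
      m <- kernel_train(x[tr, , drop = FALSE], yy[tr],
                        C = grid$C[gi], gamma = grid$gamma[gi])
      p <- predict(m, x[!tr, , drop = FALSE]) == "blocker"
      truth <- yy[!tr]
      sens <- if (any(truth)) mean(p[truth]) else NA_real_
      spec <- if (any(!truth)) mean(!p[!truth]) else NA_real_
      mean(c(sens, spec), na.rm = TRUE)
    }, numeric(1))
    grid$balanced_accuracy[gi] <- mean(accs, na.rm = TRUE)
  }
  best <- which.max(grid$balanced_accuracy)
  list(C = grid$C[best], gamma = grid$gamma[best], scores = grid)
}
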