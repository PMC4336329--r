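#' Wiener index of a molecular graph
#'
#' Sum of shortest-path lengths over all unordered heavy-atom pairs; a
#' classical topological descriptor of molecular size and branching.  The
#' graph must be connected (largest-fragment selection belongs upstream);
#' a single-atom graph has index 0.
#'
#' @param x a SMILES string, an [igraph::graph] or a square adjacency
#'   matrix.
#' @param ... unused.
#' @return the exact integer index.
#' @export
wiener_index <- function(x, ...) UseMethod("wiener_index")

#' @export
wiener_index.character <- function(x, ...) {
  stopifnot(length(x) == 1L)
  g <- mol_graph(x)
  n <- length(g$atoms)
  if (n == 1L) return(0L)
  gr <- igraph::graph_from_data_frame(g$bonds[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = as.character(seq_len(n))))
  wiener_index(gr)
}

#' @export
wiener_index.igraph <- function(x, ...) {
  if (igraph::vcount(x) == 1L) return(0L)
  if (igraph::count_components(x) != 1L)
    stop2("molecular graph is disconnected; Wiener index undefined")
  d <- igraph::distances(x, weights = NA)
  as.integer(round(sum(d) / 2))
}

#' @export
wiener_index.matrix <- function(x, ...) {
  stopifnot(nrow(x) == ncol(x))
  wiener_index(igraph::graph_from_adjacency_matrix(x != 0, mode = "undirected"))
}

#' Fit quantile bins for physicochemical descriptors
#'
#' Discretizes numeric descriptors into `n_bins` quantile bins whose edges
#' are fit on training data only, so test values can never alter the
#' binning (values outside the training range clamp into the extreme
#' bins).  Descriptors undefined for some compounds (acid/base pKa of
#' molecules without the matching group) get a dedicated "absent" bin.
#' Constant descriptors collapse to a single bin with a warning.
#'
#' @param data data frame of numeric descriptor columns (training set).
#' @param n_bins bins per descriptor, at least 2 (default 10).
#' @return a `descriptor_bins` object for [apply_descriptor_bins()].
#' @export
fit_descriptor_bins <- function(data, n_bins = 10L) {
  if (!is_count(n_bins, 2L)) stop2("n_bins must be an integer >= 2")
  data <- as.data.frame(data)
  if (!ncol(data)) stop2("no descriptor columns supplied")
  edges <- lapply(names(data), function(cn) {
    x <- data[[cn]]
    if (!is.numeric(x)) stop2("descriptor '%s' is not numeric", cn)
    x <- x[!is.na(x)]
    if (!length(x)) return(numeric(0))
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE))
    inner <- qs[-c(1L, length(qs))]
    if (!length(inner))
      warn2("descriptor '%s' is constant on the training data; single bin", cn)
    inner
  })
  names(edges) <- names(data)
  structure(list(edges = edges, n_bins = as.integer(n_bins)),
            class = "descriptor_bins")
}

#' Expand descriptors into one-hot bin indicator features
#'
#' Each compound contributes exactly one indicator per descriptor: its
#' quantile bin, or the descriptor's "absent" bin when the value is
#' missing.
#'
#' @param bins a fitted `descriptor_bins`.
#' @param data data frame with the same descriptor columns.
#' @return a 0/1 integer matrix with named columns
#'   (`<descriptor>.bin<k>`, `<descriptor>.absent`).
#' @export
apply_descriptor_bins <- function(bins, data) {
  stopifnot(inherits(bins, "descriptor_bins"))
  data <- as.data.frame(data)
  miss <- setdiff(names(bins$edges), names(data))
  if (length(miss)) stop2("missing descriptor column(s): %s",
                          paste(miss, collapse = ", "))
  blocks <- lapply(names(bins$edges), function(cn) {
    e <- bins$edges[[cn]]
    nb <- length(e) + 1L
    x <- data[[cn]]
    idx <- findInterval(x, e) + 1L           # clamps below/above into end bins
    idx[is.na(x)] <- nb + 1L                 # absent bin
    m <- matrix(0L, nrow = length(x), ncol = nb + 1L,
                dimnames = list(NULL, c(paste0(cn, ".bin", seq_len(nb)),
                                        paste0(cn, ".absent"))))
    m[cbind(seq_along(x), idx)] <- 1L
    m
  })
  do.call(cbind, blocks)
}

#' Train a Winnow2 multiplicative-update linear classifier
#'
#' The classical online mistake-driven learner for sparse binary features:
#' all weights start at 1; an example is predicted a blocker iff the sum of
#' weights over its active features strictly exceeds the threshold `theta`.
#' On a false negative the active weights are multiplied by `alpha`; on a
#' false positive they are divided by `alpha`; correct predictions change
#' nothing.  Weights therefore stay strictly positive, and for a target
#' concept that is a k-literal disjunction over d features the number of
#' training mistakes is O(k log d).
#'
#' @param x 0/1 feature matrix, or a list of active-feature index vectors
#'   (1-based; supply `n_features`).
#' @param y labels: `"blocker"`/`"nonblocker"`, logical, or 0/1.
#' @param alpha promotion/demotion factor, > 1 (default 2).
#' @param theta decision threshold; default `n_features / 2`.
#' @param n_epochs passes over the examples in the given order (default 1).
#' @param n_features feature-space size when `x` is a list.
#' @return a `winnow_model` with elements `weights`, `alpha`, `theta`,
#'   `n_features`, `mistakes`.
#' @export
winnow_train <- function(x, y, alpha = 2, theta = NULL, n_epochs = 1L,
                         n_features = NULL) {
  feats <- as_active_features(x, n_features)
  d <- feats$n_features
  if (d < 1L) stop2("empty feature space")
  if (!is.numeric(alpha) || alpha <= 1) stop2("alpha must be > 1")
  if (!is_count(n_epochs, 1L)) stop2("n_epochs must be >= 1")
  yy <- as_blocker(y)
  if (length(yy) != length(feats$active)) stop2("x and y lengths differ")
  theta <- theta %||% (d / 2)
  w <- rep(1, d)
  mistakes <- 0L
  for (ep in seq_len(n_epochs)) {
    for (i in seq_along(feats$active)) {
      f <- feats$active[[i]]
      pred <- sum(w[f]) > theta
      if (pred == yy[i]) next
      mistakes <- mistakes + 1L
      w[f] <- if (yy[i]) w[f] * alpha else w[f] / alpha
    }
  }
  structure(list(weights = w, alpha = alpha, theta = theta,
                 n_features = d, n_epochs = as.integer(n_epochs),
                 mistakes = mistakes,
                 feature_names = feats$names),
            class = "winnow_model")
}

as_active_features <- function(x, n_features = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(n_features)) stop2("n_features required for list input")
    list(active = lapply(x, as.integer), n_features = as.integer(n_features),
         names = NULL)
  } else {
    x <- as.matrix(x)
    list(active = lapply(seq_len(nrow(x)), function(i) which(x[i, ] != 0)),
         n_features = ncol(x), names = colnames(x))
  }
}

as_blocker <- function(y) {
  if (is.character(y) || is.factor(y)) as.character(y) == "blocker"
  else as.logical(y)
}

#' Predict with a Winnow model
#'
#' Score = sum of weights over active features; class is `"blocker"` iff
#' the score strictly exceeds `theta` (ties go to nonblocker).
#'
#' @param object a `winnow_model`.
#' @param newdata features as in [winnow_train()].
#' @param type `"class"` or `"score"`.
#' @param ... unused.
#' @export
predict.winnow_model <- function(object, newdata,
                                 type = c("class", "score"), ...) {
  type <- match.arg(type)
  feats <- as_active_features(newdata, object$n_features)
  score <- vapply(feats$active, function(f) sum(object$weights[f]), numeric(1))
  if (type == "score") return(score)
  ifelse(score > object$theta, "blocker", "nonblocker")
}

#' @rdname predict.winnow_model
#' @param model a `winnow_model`.
#' @param x features.
#' @export
winnow_predict <- function(model, x) predict(model, x, type = "class")

#' @export
print.winnow_model <- function(x, ...) {
  cat(sprintf(paste0("Winnow2 model: %d features, alpha=%g, theta=%g, ",
                     "%d training mistakes\n"),
              x$n_features, x$alpha, x$theta, x$mistakes))
  invisible(x)
}
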