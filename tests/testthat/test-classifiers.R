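test_that("wiener index matches hand values and a BFS oracle", {
  expect_equal(wiener_index("C"), 0L)        # single heavy atom
  expect_equal(wiener_index("CCC"), 4L)      # propane path: 1+1+2
  expect_equal(wiener_index("c1ccccc1"), 27L)  # benzene 6-cycle
  # independent BFS oracle on random connected graphs
  bfs_wiener <- function(adj) {
    n <- length(adj); tot <- 0
    for (s in seq_len(n)) {
      dist <- rep(NA_integer_, n); dist[s] <- 0L; q <- s
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        for (w in adj[[v]]) if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; q <- c(q, w)
        }
      }
      tot <- tot + sum(dist)
    }
    as.integer(tot / 2)
  }
  withr::with_seed(10, {
    for (rep in 1:50) {
      n <- sample(2:20, 1)
      g <- igraph::sample_gnp(n, min(1, 3 / n))
      # force connectivity with a random spanning path
      ord <- sample(n)
      g <- igraph::add_edges(g, as.vector(rbind(ord[-n], ord[-1])))
      g <- igraph::simplify(g)
      adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
      expect_equal(wiener_index(g), bfs_wiener(adj))
    }
  })
  g2 <- igraph::make_empty_graph(4, directed = FALSE)
  expect_error(wiener_index(g2), "disconnected")
})

test_that("descriptor binning is train-fit, clamped, and leakage-free", {
  train <- data.frame(x = 1:1000 / 10, y = rep(5, 1000))
  expect_warning(bins <- fit_descriptor_bins(train, n_bins = 10), "constant")
  expect_error(fit_descriptor_bins(train, n_bins = 1), "n_bins")
  m <- apply_descriptor_bins(bins, data.frame(x = c(-100, 50, 1e6, NA), y = 1:4))
  expect_equal(unname(m[1, "x.bin1"]), 1L)     # below training range clamps low
  expect_equal(unname(m[3, "x.bin10"]), 1L)    # above range clamps high
  expect_equal(unname(m[4, "x.absent"]), 1L)   # missing -> absent bin
  expect_true(all(rowSums(m[, startsWith(colnames(m), "x.")]) == 1))
  # exactly one indicator per descriptor per compound
  expect_true(all(rowSums(m[, startsWith(colnames(m), "y.")]) == 1))
  # applying to new data never changes the fitted edges
  before <- bins$edges
  invisible(apply_descriptor_bins(bins, data.frame(x = runif(50, -5, 500), y = 0)))
  expect_identical(bins$edges, before)
  # deciles of 1000 uniform draws give ~100 per bin
  u <- data.frame(x = withr::with_seed(3, runif(1000)))
  b <- fit_descriptor_bins(u, 10)
  counts <- colSums(apply_descriptor_bins(b, u))
  expect_true(all(abs(counts[paste0("x.bin", 1:10)] - 100) <= 1))
})

test_that("winnow reproduces the hand trace and leaves mistake-free streams alone", {
  # 2-feature trace: theta = 1, alpha = 2, weights start (1, 1)
  x <- list(1L, 1L)                      # feature f1 active in both examples
  y <- c("nonblocker", "blocker")
  m <- winnow_train(x, y, alpha = 2, theta = 1, n_features = 2)
  # step 1: score 1 is not > 1 -> nonblocker, correct, no update
  # step 2: score 1 -> nonblocker, wrong -> w_f1 doubled
  expect_equal(m$weights, c(2, 1))
  expect_equal(m$mistakes, 1L)
  # zero-mistake stream: weights stay at the all-ones initialisation
  m0 <- winnow_train(list(1L, 2L), c("nonblocker", "nonblocker"),
                     theta = 5, n_features = 4)
  expect_equal(m0$weights, rep(1, 4))
  expect_equal(m0$mistakes, 0L)
  # ties predict nonblocker; empty feature vector scores 0
  expect_equal(predict(m, list(integer(0))), "nonblocker")
  expect_equal(predict(m, list(1L), type = "score"), 2)
  expect_error(winnow_train(list(), character(0), n_features = 0), "empty feature")
})

test_that("winnow stays positive and learns disjunctions within the mistake bound", {
  k <- 3; d <- 64
  markers <- 1:3
  withr::with_seed(8, {
    x <- matrix(rbinom(200 * d, 1, 0.15), nrow = 200)
    y <- ifelse(rowSums(x[, markers, drop = FALSE]) > 0, "blocker", "nonblocker")
    m <- winnow_train(x, y, alpha = 2, n_epochs = 10)
    expect_true(all(m$weights > 0))
    # converged: zero errors on the training stream
    expect_equal(unname(predict(m, x)), unname(y))
    # classical Winnow bound for a k-literal disjunction over d features
    expect_lt(m$mistakes, 8 * k^2 + 5 * k + 14 * k * log(d))
    # random update sequences keep weights strictly positive
    yr <- sample(c("blocker", "nonblocker"), 200, replace = TRUE)
    mr <- winnow_train(x, yr, n_epochs = 3)
    expect_true(all(mr$weights > 0))
  })
})

test_that("kernel classifier separates toy data and grid search is well-behaved", {
  x <- rbind(matrix(c(1, 0), 20, 2, byrow = TRUE),
             matrix(c(0, 1), 20, 2, byrow = TRUE))
  y <- rep(c("blocker", "nonblocker"), each = 20)
  m <- kernel_train(x, y, C = 10, gamma = 1)
  expect_equal(predict(m, x), y)
  expect_error(kernel_train(x, rep("blocker", 40)), "single-class")
  gs <- kernel_grid_search(x, y, C_grid = c(1, 10), gamma_grid = c(0.1, 1),
                           k = 5, seed = 1)
  expect_true(gs$C %in% c(1, 10) && gs$gamma %in% c(0.1, 1))
  # swapping class labels swaps predictions on the symmetric toy set
  m2 <- kernel_train(x, ifelse(y == "blocker", "nonblocker", "blocker"),
                     C = 10, gamma = 1)
  p2 <- predict(m2, x)
  expect_equal(p2, ifelse(y == "blocker", "nonblocker", "blocker"))
})
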