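test_that("chc matches hand-computed and degenerate cases", {
  ids <- letters[1:6]
  act <- setNames(c(90, 80, 70, 60, 10, 5), ids)
  complete5 <- t(combn(ids[1:5], 2))
  net <- structure_network(ids, complete5)
  expect_equal(chc(net, act, 50), 1.0)            # 5 above-threshold, K5
  net2 <- structure_network(ids, rbind(c("a", "b"), c("c", "d")))
  expect_equal(chc(net2, act, 50), 1 / 3)         # 4 nodes, 2 edges
  net3 <- structure_network(ids)
  expect_equal(chc(net3, act, 50), 0)             # no edges
  expect_true(is.na(chc(net, act, 85)))           # N_t = 1: absent
  expect_true(is.na(chc(net, act, 1000)))         # empty support: absent
})

test_that("chc equals a brute-force pair count on random graphs", {
  for (s in 1:25) {
    n <- sample(5:40, 1)
    net <- random_network(n, p = runif(1, 0.05, 0.4), seed = s)
    act <- setNames(runif(n, 0, 100), net$node_ids)
    for (t in c(10, 50, 90))
      expect_equal(chc(net, act, t), chc_oracle(net, act, t))
  }
})

test_that("chc is invariant under node relabeling", {
  net <- random_network(15, p = 0.3, seed = 7)
  act <- setNames(runif(15, 0, 100), net$node_ids)
  new_ids <- setNames(sprintf("Z%02d", sample(15)), net$node_ids)
  net2 <- structure_network(unname(new_ids[net$node_ids]),
                            cbind(new_ids[net$edges[, 1]],
                                  new_ids[net$edges[, 2]]))
  act2 <- setNames(as.numeric(act), new_ids[names(act)])
  expect_equal(chc(net2, act2, 40), chc(net, act, 40))
})

test_that("adding an above-threshold edge strictly increases ChC", {
  net <- structure_network(letters[1:5], rbind(c("a", "b")))
  act <- setNames(rep(90, 5), letters[1:5])
  base <- chc(net, act, 50)
  net2 <- structure_network(letters[1:5], rbind(c("a", "b"), c("c", "d")))
  expect_gt(chc(net2, act, 50), base)
})

test_that("profile agrees with chc and has non-increasing club sizes", {
  net <- random_network(30, p = 0.2, seed = 9)
  act <- setNames(runif(30, 0, 100), net$node_ids)
  prof1 <- chc_profile(net, act, thresholds = 42)
  expect_equal(prof1$ChC, chc(net, act, 42))
  prof <- chc_profile(net, act)
  expect_true(all(diff(prof$N_t) <= 0))
  expect_true(all(prof$ChC >= 0 & prof$ChC <= 1, na.rm = TRUE))
  for (i in sample(nrow(prof), 5))
    expect_equal(prof$ChC[i], chc(net, act, prof$t[i]))
  expect_error(chc_profile(net, act, thresholds = numeric(0)), "empty")
  expect_error(chc_profile(net, act, thresholds = c(2, 1)), "increasing")
})

test_that("planted potent clusters raise ChC at high thresholds", {
  cfg <- synthetic_config(n_compounds = 500, n_clusters = 10, seed = 31)
  lib <- generate_library(cfg)
  net <- build_similarity_network(lib)
  act <- setNames(lib$inhib_10uM, lib$id)
  prof <- chc_profile(net, act, thresholds = c(10, 70))
  expect_gt(prof$ChC[2], prof$ChC[1])
  # and the peak disappears in the permuted-activity null library
  nul <- generate_null_library(cfg)
  netn <- build_similarity_network(nul)
  actn <- setNames(nul$inhib_10uM, nul$id)
  pn <- permutation_null(netn, actn, thresholds = c(70), n_perm = 200, seed = 1)
  po <- permutation_null(net, act, thresholds = c(70), n_perm = 200, seed = 1)
  expect_lte(po$empirical_p, 1 / 201 + 1e-12)
  expect_gt(pn$empirical_p, 0.01)
})

test_that("permutation p-values behave under exchangeability", {
  net <- random_network(12, p = 0.3, seed = 5)
  act <- setNames(rep(60, 12), net$node_ids)
  pr <- permutation_null(net, act, thresholds = 50, n_perm = 100, seed = 2)
  expect_equal(pr$empirical_p, 1.0)   # all permutations identical to observed
  # minimum attainable p with 1000 permutations is below 1e-3
  expect_lt(1 / 1001, 0.001)
})

test_that("Monte-Carlo p matches exhaustive enumeration on a 6-node toy", {
  ids <- letters[1:6]
  net <- structure_network(ids, rbind(c("a", "b"), c("b", "c"), c("d", "e")))
  act <- setNames(c(90, 85, 80, 20, 15, 10), ids)
  t0 <- 50
  obs <- chc(net, act, t0)
  # full enumeration of all 720 label permutations
  perm_idx <- expand.grid(rep(list(1:6), 6))
  perm_idx <- perm_idx[apply(perm_idx, 1, function(r) length(unique(r)) == 6), ]
  vals <- apply(perm_idx, 1, function(r)
    chc(net, setNames(as.numeric(act)[as.integer(r)], ids), t0))
  p_exact <- mean(vals >= obs - 1e-12)
  pr <- permutation_null(net, act, thresholds = t0, n_perm = 2000, seed = 77)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(pr$empirical_p - p_exact), 3 * se + 1 / 2001)
})

test_that("two-clique bound matches closed form and construction", {
  expect_equal(two_clique_upper_bound(2), 1.0)
  expect_equal(round(log10(two_clique_upper_bound(197)), 2), -2.29)
  expect_error(two_clique_upper_bound(1), ">= 2")
  n <- 10
  ids <- sprintf("P%02d", 1:n)
  pairs <- cbind(ids[seq(1, n, 2)], ids[seq(2, n, 2)])
  net <- structure_network(ids, pairs)
  act <- setNames(rep(99, n), ids)
  expect_equal(chc(net, act, 50), two_clique_upper_bound(n))
})
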