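test_that("tanimoto matches hand values and is a bounded symmetric similarity", {
  expect_equal(tanimoto(chemfp(c(1, 2, 3), 16), chemfp(c(2, 3, 4), 16)), 0.5)
  expect_equal(tanimoto(chemfp(1:5, 16), chemfp(1:5, 16)), 1.0)
  expect_equal(tanimoto(chemfp(1:3, 16), chemfp(8:10, 16)), 0.0)
  expect_warning(v <- tanimoto(chemfp(integer(0), 16), chemfp(integer(0), 16)),
                 "empty")
  expect_equal(v, 0)
  expect_error(tanimoto(chemfp(1, 16), chemfp(1, 32)), "different lengths")
  fps <- random_fps(20, seed = 6)
  for (i in 1:19) {
    s <- tanimoto(fps[[i]], fps[[i + 1]])
    expect_equal(s, tanimoto(fps[[i + 1]], fps[[i]]))
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("similarity network uses a strict threshold and matches brute force", {
  # TC exactly 0.7: |intersection| = 7, |union| = 10
  a <- chemfp(1:9, 32); b <- chemfp(c(1:7, 10), 32)
  expect_equal(tanimoto(a, b), 0.7)
  lib <- data.frame(id = c("x", "y"), inhib_10uM = c(1, 2))
  lib$fingerprint <- list(a, b)
  expect_equal(nrow(build_similarity_network(lib, 0.7)$edges), 0L)
  # brute-force oracle on 100 random fingerprints
  lib <- random_fp_library(100, seed = 13)
  net <- build_similarity_network(lib, threshold = 0.3)
  pairs <- t(combn(100, 2))
  want <- apply(pairs, 1, function(p)
    tanimoto(lib$fingerprint[[p[1]]], lib$fingerprint[[p[2]]]) > 0.3)
  oracle <- sort(paste(pmin(lib$id[pairs[want, 1]], lib$id[pairs[want, 2]]),
                       pmax(lib$id[pairs[want, 1]], lib$id[pairs[want, 2]])))
  got <- sort(paste(net$edges[, 1], net$edges[, 2]))
  expect_equal(got, oracle)
  expect_error(build_similarity_network(data.frame(id = "a", inhib_10uM = 1)),
               "fingerprint")
})

test_that("zero-noise synthetic clusters become cliques", {
  cfg <- synthetic_config(n_compounds = 30, n_clusters = 2,
                          blocker_fraction = 0.5, bit_flip_prob = 0,
                          background_bits = 0, moderate_retention = 1, seed = 4)
  lib <- generate_library(cfg)
  net <- build_similarity_network(lib)
  for (cl in unique(lib$cluster)) {
    m <- sum(lib$cluster == cl)
    ids <- lib$id[lib$cluster == cl]
    internal <- sum(net$edges[, 1] %in% ids & net$edges[, 2] %in% ids)
    expect_equal(internal, m * (m - 1) / 2)
  }
})

test_that("merge_networks is a guarded edge-set union", {
  n1 <- random_network(20, p = 0.2, seed = 1)
  n2 <- random_network(20, p = 0.2, seed = 2)
  expect_equal(merge_networks(n1, n1)$edges, n1$edges)
  empty <- structure_network(n1$node_ids)
  expect_equal(merge_networks(n1, empty)$edges, n1$edges)
  m <- merge_networks(n1, n2)
  expect_lte(nrow(m$edges), nrow(n1$edges) + nrow(n2$edges))
  expect_equal(m$metric, "merged")
  n3 <- random_network(10, p = 0.2, seed = 3)
  expect_error(merge_networks(n1, n3), "universes differ")
  mi <- merge_networks(n1, n3, mode = "intersect")
  expect_setequal(mi$node_ids, intersect(n1$node_ids, n3$node_ids))
})

test_that("phenotype grid matches hand counts and conserves compounds", {
  lib <- data.frame(id = c("A", "B", "C"), inhib_10uM = c(80, 10, 20))
  lib <- binarize_labels(lib)
  net <- structure_network(lib$id, cbind("A", "B"))
  grid <- neighbor_phenotype_grid(net, lib)
  want <- data.frame(n_blocker_neighbors = c(0L, 0L, 1L),
                     n_nonblocker_neighbors = c(0L, 1L, 0L),
                     count = c(1L, 1L, 1L))
  expect_equal(as.data.frame(grid), want, ignore_attr = TRUE)
  expect_equal(sum(grid$count), nrow(lib))
  # oracle recount on a random 200-node network
  lib2 <- binarize_labels(random_fp_library(200, seed = 21))
  net2 <- random_network(200, p = 0.02, seed = 22)
  net2$node_ids <- lib2$id
  net2$edges[] <- lib2$id[as.integer(sub("N", "", net2$edges))]
  grid2 <- neighbor_phenotype_grid(net2, lib2)
  expect_equal(sum(grid2$count), 200L)
  lab <- setNames(lib2$label, lib2$id)
  for (k in sample(200, 10)) {
    id <- lib2$id[k]
    nbrs <- c(net2$edges[net2$edges[, 1] == id, 2],
              net2$edges[net2$edges[, 2] == id, 1])
    cell <- grid2[grid2$n_blocker_neighbors == sum(lab[nbrs] == "blocker") &
                  grid2$n_nonblocker_neighbors == sum(lab[nbrs] == "nonblocker"), ]
    expect_gte(cell$count, 1L)
  }
  expect_error(neighbor_phenotype_grid(net2, lib2[-1, ]), "label")
})

test_that("degree-activity correlation handles degenerate inputs", {
  lib <- data.frame(id = c("a", "b", "c", "d"), inhib_10uM = c(1, 2, 3, 4))
  iso <- structure_network(lib$id)
  expect_warning(r <- degree_activity_correlation(iso, lib), "zero variance")
  expect_true(is.na(r))
  # perfectly degree-sorted activities
  net <- structure_network(lib$id, rbind(c("b", "c"), c("c", "d"), c("b", "d"),
                                         c("a", "d")))
  deg <- network_degree(net)
  lib$inhib_10uM <- as.numeric(deg[lib$id])
  expect_equal(degree_activity_correlation(net, lib), 1.0)
})
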