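test_that("connection densities match hand counts on small graphs", {
  ids <- letters[1:5]
  net <- structure_network(ids, rbind(c("a", "b"), c("b", "c"), c("a", "d"),
                                      c("b", "d"), c("c", "e")))
  # group {a,b,c}: edges a-b, b-c -> E=2, V=3 -> 2/6 under the as-printed form
  expect_equal(within_density(net, c("a", "b", "c")), 1 / 3)
  expect_equal(within_density(net, c("a", "b", "c"), "undirected"), 2 / 3)
  expect_equal(within_density(net, c("a", "e")), 0)
  expect_true(is.na(within_density(net, "a")))
  # complete group under the as-printed formula caps at 1/2
  k4 <- structure_network(letters[1:4], t(combn(letters[1:4], 2)))
  expect_equal(within_density(k4, letters[1:4]), 1 / 2)
  expect_equal(within_density(k4, letters[1:4], "undirected"), 1)
  # between-groups: V1=2, V2=3, E=3 -> 0.5
  expect_equal(between_density(net, c("a", "b"), c("c", "d", "e")), 0.5)
  expect_equal(between_density(net, c("a", "b"), "e"), 0)
  bip <- structure_network(letters[1:4],
                           rbind(c("a", "c"), c("a", "d"), c("b", "c"), c("b", "d")))
  expect_equal(between_density(bip, c("a", "b"), c("c", "d")), 1.0)
  expect_error(between_density(net, c("a", "b"), c("b", "c")), "overlap")
  expect_error(between_density(net, character(0), "a"), "nonempty")
})

test_that("densities equal brute-force pair enumeration on random fixtures", {
  for (s in 1:10) {
    net <- random_network(30, p = 0.2, seed = 100 + s)
    g1 <- net$node_ids[1:10]; g2 <- net$node_ids[11:25]
    pair_in <- function(a, b) any((net$edges[, 1] == a & net$edges[, 2] == b) |
                                    (net$edges[, 1] == b & net$edges[, 2] == a))
    e_in <- sum(apply(t(combn(g1, 2)), 1, function(p) pair_in(p[1], p[2])))
    e_cross <- sum(outer(g1, g2, Vectorize(pair_in)))
    expect_equal(within_density(net, g1), e_in / (10 * 9))
    expect_equal(between_density(net, g1, g2), e_cross / (10 * 15))
  }
})

test_that("enrichment follows the printed six-ratio scheme", {
  e <- enrichment_scores(c("P-B" = 90, "U-NB" = 10), B = 100, NB = 900)
  expect_equal(unname(e["E_P-B"]), 9.0)
  expect_equal(unname(e["E_U-NB"]), (10 / 100) / (900 / 1000))
  expect_true(is.na(e["E_I-B"]))  # empty intermediate level
  expect_error(enrichment_scores(c("P-B" = 1), B = 0, NB = 10), "no blockers")
  expect_error(enrichment_scores(c("P-B" = 1), B = 10, NB = 0), "no nonblockers")
  # mixture identity per hBS level: blocker and nonblocker shares sum to 1
  cnt <- c("P-B" = 40, "I-B" = 25, "U-B" = 10, "P-NB" = 500, "I-NB" = 300,
           "U-NB" = 60)
  B <- 75; NB <- 860
  e <- enrichment_scores(cnt, B, NB)
  bf <- B / (B + NB); nf <- NB / (B + NB)
  expect_equal(e[["E_P-B"]] * bf + e[["E_U-NB"]] * nf, 1)
  expect_equal(e[["E_I-B"]] * bf + e[["E_I-NB"]] * nf, 1)
  expect_equal(e[["E_U-B"]] * bf + e[["E_P-NB"]] * nf, 1)
})

test_that("random labels concentrate all six enrichments near 1", {
  withr::with_seed(17, {
    n <- 5000
    blk <- runif(n) < 0.1
    pred <- sample(c("P", "I", "U"), n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    combined <- paste(pred, ifelse(blk, "B", "NB"), sep = "-")
    e <- enrichment_scores(table(combined), sum(blk), sum(!blk))
    expect_true(all(abs(e - 1) < 0.15))
  })
})

test_that("summary network assembles the six-class table", {
  # 12-compound hand fixture
  ids <- sprintf("c%02d", 1:12)
  combined <- c("P-B", "P-B", "P-B", "U-NB", "U-NB", "I-B", "I-NB", "I-NB",
                "P-NB", "P-NB", "P-NB", "U-B")
  res <- data.frame(id = ids, combined = combined, stringsAsFactors = FALSE)
  net <- structure_network(ids, rbind(
    c("c01", "c02"), c("c01", "c03"), c("c02", "c03"),   # P-B triangle
    c("c01", "c04"),                                     # P-B to U-NB
    c("c09", "c10"),                                     # P-NB pair
    c("c07", "c08")))                                    # I-NB pair
  sn <- build_summary_network(res, net)
  g <- sn$groups
  expect_equal(sum(g$V), 12L)
  expect_equal(g$V[g$class == "P-B"], 3L)
  expect_equal(g$within_cd[g$class == "P-B"], 3 / 6)        # triangle, as-printed
  expect_equal(g$within_cd[g$class == "P-NB"], 1 / 6)
  expect_equal(sn$between["P-B", "U-NB"], 1 / 6)            # 1 edge / (3*2)
  expect_equal(sn$B, 5L); expect_equal(sn$NB, 7L)
  # enrichment of P-B: (3/5) / (5/12)
  expect_equal(g$enrichment[g$class == "P-B"], (3 / 5) / (5 / 12))
  expect_equal(max(g$relative_within_cd, na.rm = TRUE), 1)
  # all compounds in one class: five empty groups, one density
  res1 <- data.frame(id = ids, combined = "P-B", stringsAsFactors = FALSE)
  expect_warning(sn1 <- build_summary_network(res1, net), "enrichments unavailable")
  expect_equal(sn1$groups$V[sn1$groups$class == "P-B"], 12L)
  expect_equal(sum(sn1$groups$V), 12L)
  expect_false(is.na(sn1$groups$within_cd[1]))
  expect_true(all(is.na(sn1$groups$within_cd[-1])))
})
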