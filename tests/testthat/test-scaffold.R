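# Scaffold and fingerprint chemistry: small fixed SMILES fixtures, built in
# code.  Canonical forms are compared through the package's own
# canonicalisation path so string representation never matters.
canon <- function(s) chemclub:::canonical_smiles(s)

test_that("murcko_scaffold strips side chains and rejects acyclic molecules", {
  expect_true(is.na(murcko_scaffold("CCCCCC")))                 # hexane
  expect_equal(murcko_scaffold("Cc1ccccc1"), canon("c1ccccc1")) # toluene
  # two decorated variants of one ring system share a scaffold
  s1 <- murcko_scaffold("CCc1ccc(O)cc1")
  s2 <- murcko_scaffold("NCc1ccc(Cl)cc1")
  expect_equal(s1, s2)
  expect_equal(s1, canon("c1ccccc1"))
  # linker survives, exocyclic decoration goes
  expect_equal(murcko_scaffold("OCc1ccc(CCc2ccccc2)cc1"),
               canon("c1ccc(CCc2ccccc2)cc1"))
  expect_error(murcko_scaffold("not_a_smiles("))
})

test_that("scaffold children enumerate single-ring removals exhaustively", {
  expect_equal(enumerate_scaffold_children(canon("c1ccccc1")), character(0))
  # biphenyl: two removals, both give benzene, deduplicated to one child
  kids <- enumerate_scaffold_children(canon("c1ccc(-c2ccccc2)cc1"))
  expect_equal(kids, canon("c1ccccc1"))
  # asymmetric linear three-ring: middle removal disconnects (excluded),
  # the two end removals give two distinct children
  tri <- canon("c1ccc(-c2ccc(-c3ccccn3)cc2)cc1")
  kids3 <- enumerate_scaffold_children(tri)
  expect_length(kids3, 2L)
  expect_setequal(kids3, c(canon("c1ccc(-c2ccccc2)cc1"),
                           canon("c1ccc(-c2ccccn2)cc1")))
  # fused pair: removing either ring leaves the other
  expect_equal(enumerate_scaffold_children(canon("c1ccc2ccccc2c1")),
               canon("c1ccccc1"))
})

test_that("scaffold network closes the hierarchy with ring-count monotone edges", {
  smiles <- c(mono = "Cc1ccncc1",
              tri = "c1ccc(-c2ccc(-c3ccccn3)cc2)cc1",
              open = "CCCC")
  sn <- build_scaffold_network(smiles)
  expect_equal(sn$n_acyclic, 1L)
  expect_equal(nrow(sn$membership), 2L)
  rc <- setNames(sn$scaffolds$ring_count, sn$scaffolds$scaffold)
  # every parent-child edge removes exactly one ring
  expect_true(all(rc[sn$edges$parent] - rc[sn$edges$child] == 1L))
  # closure reaches the 1-ring level and marks unrealised scaffolds virtual
  expect_true(any(sn$scaffolds$ring_count == 1L))
  expect_true(any(sn$scaffolds$virtual))
  expect_false(all(sn$scaffolds$virtual))
  # acyclic: ring counts strictly decrease along edges, so no cycles
  g <- igraph::graph_from_data_frame(sn$edges)
  expect_true(igraph::is_dag(g))
  # single-ring library -> edgeless hierarchy
  sn1 <- build_scaffold_network(c(a = "c1ccccc1", b = "Cc1ccncc1"))
  expect_equal(nrow(sn1$edges), 0L)
})

test_that("scaffold club input uses max-member activity", {
  lib <- data.frame(id = c("a", "b", "c"),
                    smiles = c("Cc1ccccc1", "CCc1ccccc1", "Cc1ccncc1"),
                    inhib_10uM = c(30, 70, 50), stringsAsFactors = FALSE)
  sn <- build_scaffold_network(lib)
  inp <- scaffold_club_input(sn, lib)
  benzene <- canon("c1ccccc1")
  expect_equal(unname(inp$activities[benzene]), 70)
  expect_equal(inp$network$metric, "scaffold")
})

test_that("toolkit fingerprints are canonical and deterministic", {
  f1 <- compute_fingerprint("c1ccccc1", "fcfp6")
  f2 <- compute_fingerprint("C1=CC=CC=C1", "fcfp6")  # kekulized form
  expect_identical(f1$on_bits, f2$on_bits)
  expect_identical(compute_fingerprint("CCO", "ecfp4"),
                   compute_fingerprint("CCO", "ecfp4"))
  expect_lt(tanimoto(compute_fingerprint("CC", "ecfp4"),
                     compute_fingerprint("c1ccccc1", "ecfp4")), 1)
  expect_error(compute_fingerprint("xyz((", "ecfp4"))
})

test_that("the packaged toy structure set builds a consistent hierarchy", {
  path <- system.file("extdata", "toy_smiles.smi", package = "chemclub")
  tab <- read.table(path, col.names = c("id", "smiles"),
                    stringsAsFactors = FALSE)
  sn <- build_scaffold_network(setNames(tab$smiles, tab$id))
  expect_equal(sn$n_acyclic, 2L)                       # hexane, ethanol
  expect_equal(nrow(sn$membership), nrow(tab) - 2L)
  rc <- setNames(sn$scaffolds$ring_count, sn$scaffolds$scaffold)
  expect_true(all(rc[sn$edges$parent] - rc[sn$edges$child] == 1L))
  expect_true(igraph::is_dag(igraph::graph_from_data_frame(sn$edges)))
  # decorated single-ring drugs collapse onto the benzene scaffold
  benzene <- chemclub:::canonical_smiles("c1ccccc1")
  mem <- setNames(sn$membership$scaffold, sn$membership$id)
  expect_equal(unname(mem[c("toluene", "phenol", "paracetamol", "ibuprofen")]),
               rep(benzene, 4))
  # Wiener index grows with molecular size on the fixture set
  w <- vapply(setNames(tab$smiles, tab$id), wiener_index, integer(1))
  expect_equal(unname(w[["ethanol"]]), 4L)
  expect_gt(w[["caffeine"]], w[["benzene"]])
})
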