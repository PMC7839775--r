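test_that("read_tree loads topologies and validates tips", {
  t1 <- read_tree("((A,B),C);")
  expect_s3_class(t1, "phylo")
  expect_equal(sort(t1$tip.label), c("A", "B", "C"))
  expect_null(t1$edge.length)

  t2 <- read_tree("((A:1,B:1):1,C:2);")
  expect_equal(sort(t2$edge.length), c(1, 1, 1, 2))

  expect_error(read_tree("((A,A),C);"), "duplicate")
  f <- tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", f)
  expect_equal(sort(read_tree(f)$tip.label), c("A", "B", "C"))
})

test_that("grafen_tree assigns the expected heights", {
  # ((A,B),C): root at 1, inner node at (2-1)/(3-1) = 0.5
  t <- grafen_tree(read_tree("((A,B),C);"))
  d <- ape::node.depth.edgelength(t)
  expect_equal(unname(d[1:3]), c(1, 1, 1))      # ultrametric, depth 1
  ab <- ape::getMRCA(t, c("A", "B"))
  expect_equal(unname(d[ab]), 0.5)
  expect_equal(t$edge.length[t$edge[, 2] == which(t$tip.label == "A")], 0.5)

  # star tree: root is the only internal node, all tip edges length 1
  st <- grafen_tree(read_tree("(A,B,C);"))
  expect_equal(st$edge.length, rep(1, 3))

  # balanced 4-tip tree: both inner nodes at height (2-1)/(4-1) = 1/3
  # above the tips, i.e. at depth 2/3 below the root
  t4 <- grafen_tree(read_tree("((A,B),(C,D));"))
  d4 <- ape::node.depth.edgelength(t4)
  expect_equal(1 - unname(d4[ape::getMRCA(t4, c("A", "B"))]), 1 / 3)
  expect_equal(1 - unname(d4[ape::getMRCA(t4, c("C", "D"))]), 1 / 3)
})

test_that("phylo_cor builds the shared-depth correlation matrix", {
  A <- phylo_cor(grafen_tree(read_tree("((A,B),C);")))
  expect_equal(unname(diag(A)), rep(1, 3))
  expect_equal(A["A", "B"], 0.5)
  expect_equal(A["A", "C"], 0)
  expect_equal(A["B", "C"], 0)

  expect_equal(unname(phylo_cor(grafen_tree(read_tree("(A,B,C);")))),
               diag(3))
  # two-tip tree: off-diagonal 0
  expect_equal(phylo_cor(grafen_tree(read_tree("(A,B);")))["A", "B"], 0)

  expect_error(phylo_cor(read_tree("((A:1,B:1):1,C:5);")), "ultrametric")
  expect_error(phylo_cor(read_tree("((A,B),C);")), "branch lengths")
})

test_that("phylo_cor is PSD and invariant to child rotation", {
  set.seed(31)
  for (n in c(4, 9, 17)) {
    A <- phylo_cor(sim_tree(n))
    expect_true(isSymmetric(A))
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  a <- phylo_cor(grafen_tree(read_tree("((A,B),C);")))
  b <- phylo_cor(grafen_tree(read_tree("(C,(B,A));")))
  nm <- rownames(a)
  expect_equal(a, b[nm, nm])
})

test_that("tip deletion commutes with matrix construction when lengths are kept", {
  set.seed(32)
  t <- sim_tree(8)
  A <- phylo_cor(t)
  drop <- "Species_03"
  keep <- setdiff(rownames(A), drop)
  A_sub <- phylo_cor(ape::drop.tip(t, drop))
  expect_equal(A_sub[keep, keep], A[keep, keep])
  # ... but not when Grafen heights are recomputed on the pruned topology:
  # clade sizes change, so the package's convention is to recompute
  A_regraf <- phylo_cor(grafen_tree(ape::drop.tip(t, drop)))
  expect_false(isTRUE(all.equal(A_regraf[keep, keep], A[keep, keep])))
})

test_that("align_phylo restricts, reorders and normalizes labels", {
  A <- phylo_cor(grafen_tree(read_tree("((Parus_major,Turdus_merula),Rana_pipiens);")))
  sp <- c("parus major", "Rana pipiens", "Parus_major")
  al <- align_phylo(A, sp)
  expect_equal(rownames(al$A), c("parus major", "Rana pipiens"))
  expect_equal(al$index, c(1, 2, 1))
  expect_equal(al$A[1, 2], A["Parus_major", "Rana_pipiens"])

  expect_error(align_phylo(A, c("Parus major", "Missing species")),
               "Missing species")
})

test_that("correlation matrices round-trip through the CSV writer", {
  A <- phylo_cor(sim_tree(5, seed = 33))
  f <- tempfile(fileext = ".csv")
  write_phylo_cor(A, f)
  back <- as.matrix(read.csv(f, row.names = 1))
  dimnames(back) <- dimnames(A)
  expect_equal(back, A, tolerance = 1e-12)
})
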