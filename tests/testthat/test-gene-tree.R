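test_that("NHX reader builds the annotated model and separates parsing from validation", {
  gt <- readGeneTree("((a[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S]);")
  expect_equal(unname(eventsOf(gt)[treeRoot(geneTreeOf(gt))]), "S")
  expect_setequal(speciesImage(gt), c("A", "B"))

  tt <- transferToy()
  expect_equal(nrow(transferEdgesOf(tt)), 1)
  expect_equal(unname(sigmaOf(tt)[transferEdgesOf(tt)[, "head"]]), "C")

  # a transfer vertex with no flagged out-edge parses fine but fails O2
  gt2 <- readGeneTree("((a[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S],c[&&NHX:S=C])[&&NHX:ev=T];")
  v <- validateObservability(gt2)
  expect_true("O2" %in% v$axiom)

  expect_error(readGeneTree("((a[&&NHX:S=A],b[&&NHX:S=B]));"), "lacks an ev= tag")
  expect_error(
    readGeneTree("((a[&&NHX:S=A],b[&&NHX:S=B:xfer=1])[&&NHX:ev=S]);"),
    "not a transfer vertex")
  expect_error(readGeneTree("((a[&&NHX:S=A],b)[&&NHX:ev=S]);"),
               "leaf without species")
})

test_that("species can come from a side table instead of S= tags", {
  gt <- readGeneTree("((a,b)[&&NHX:ev=S]);",
                     speciesMap = data.frame(gene = c("a", "b"),
                                             species = c("A", "B")))
  expect_setequal(speciesImage(gt), c("A", "B"))
})

test_that("gene tree writer round-trips through the reader", {
  for (gt in list(transferToy(), incompatibleToy(), exampleGtcInstance()$geneTree)) {
    back <- readGeneTree(writeGeneTree(gt))
    expect_true(treesIsomorphic(geneTreeOf(gt), geneTreeOf(back)))
    expect_equal(nrow(transferEdgesOf(back)), nrow(transferEdgesOf(gt)))
    expect_true(sameTripletSet(informativeTriplets(back), informativeTriplets(gt)))
  }
})

test_that("observability axioms are diagnosed with the offending location", {
  # O1: unary internal vertex
  tr <- newRootedTree("r", list(r = c("u", "b"), u = "a"),
                      c(a = "a", b = "b"))
  gt <- newGeneTree(tr, c(r = "S", u = "D"), NULL, c(a = "A", b = "B"))
  v <- validateObservability(gt)
  expect_true(any(v$axiom == "O1" & v$where == "u"))

  # O3a: speciation children sharing a species
  gt3 <- readGeneTree(
    "((a1[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S],a2[&&NHX:S=A])[&&NHX:ev=S];")
  expect_true("O3a" %in% validateObservability(gt3)$axiom)

  # O3b: transfer into a subtree with a shared species
  gt4 <- readGeneTree(
    "((a1[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S],a2[&&NHX:S=A:xfer=1])[&&NHX:ev=T];")
  expect_true("O3b" %in% validateObservability(gt4)$axiom)

  expect_equal(nrow(validateObservability(exampleGtcInstance()$geneTree)), 0)
})

test_that("transfer-free forest partitions the leaves into k+1 components", {
  tt <- transferToy()
  tf <- transferForest(tt)
  expect_length(tf$components, 2)
  leafSets <- lapply(tf$components, treeLeafLabels)
  expect_setequal(unlist(leafSets), treeLeafLabels(geneTreeOf(tt)))
  expect_setequal(sort(vapply(leafSets, length, integer(1))), c(1, 2))

  # no transfers: a single component equal to the tree
  gt <- readGeneTree("((a[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S],c[&&NHX:S=C])[&&NHX:ev=S];")
  tf2 <- transferForest(gt)
  expect_length(tf2$components, 1)
  expect_true(treesIsomorphic(tf2$components[[1]], geneTreeOf(gt)))

  set.seed(5)
  for (i in 1:30) {
    sim <- simulateInstance(sample(4:12, 1), 0.4, 0.5, 0.3, seed = 500 + i)
    tf <- transferForest(sim$geneTree)
    expect_length(tf$components, nrow(transferEdgesOf(sim$geneTree)) + 1)
    expect_setequal(unlist(lapply(tf$components, treeLeafLabels)),
                    treeLeafLabels(geneTreeOf(sim$geneTree)))
  }
})

test_that("per-vertex forest species sets recurse over non-transfer children", {
  ex <- exampleGtcInstance()$geneTree
  tree <- geneTreeOf(ex)
  xferHeads <- transferEdgesOf(ex)[, "head"]
  for (v in tree@vertices) {
    expect_gt(length(sigmaForest(ex, v)), 0)  # never empty
    ch <- setdiff(treeChildren(tree, v), xferHeads)
    if (length(ch)) {
      expect_setequal(sigmaForest(ex, v),
                      unique(unlist(lapply(ch, sigmaForest, gt = ex))))
    }
  }
  # transfer toy: the root's component excludes the transferred leaf
  tt <- transferToy()
  expect_setequal(sigmaForest(tt, treeRoot(geneTreeOf(tt))), c("A", "B"))
  lf <- treeLeaves(geneTreeOf(tt))[1]
  expect_equal(sigmaForest(tt, lf), unname(sigmaOf(tt)[lf]))
  expect_error(sigmaForest(tt, "zz"), "unknown vertex")
})
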