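test_that("worked example: full run matches the expected refinement sequence", {
  ex <- exampleGtcInstance()
  gt <- ex$geneTree
  expect_false(verifySolution(gt, ex$leastResolvedTree))  # displays R, cyclic
  expect_true(displaysTriplets(ex$leastResolvedTree, informativeTriplets(gt)))
  expect_true(verifySolution(gt, ex$resolvedTree))
  res <- solveGtc(gt)
  expect_equal(res$status, "solved")
  expect_true(isBinaryTree(res$speciesTree))
  expect_true(verifySolution(gt, res$speciesTree))
  expect_true(treesIsomorphic(res$speciesTree, ex$resolvedTree))
  # trace: star -> split off D -> resolve the {A,B,C} cherry
  expect_equal(nrow(res$trace), 2)
  expect_equal(res$trace$sideB[1], "D")
  expect_setequal(strsplit(res$trace$sideA[1], ",")[[1]], c("A", "B", "C"))
})

test_that("verify rejects trees missing a triplet and trees missing species", {
  gt <- transferToy()
  expect_true(verifySolution(gt, readNewick("((A,B),C);")))
  expect_false(verifySolution(gt, readNewick("((A,C),B);")))  # AB|C not displayed
  expect_error(verifySolution(gt, readNewick("(A,B);")), "missing")
})

test_that("crafted instances: incompatible triplets fail, single transfer solves", {
  res <- solveGtc(incompatibleToy())
  expect_equal(res$status, "no_solution")
  expect_null(res$speciesTree)
  # oracle: none of the 3 binary trees on {A,B,C} works
  expect_false(oraBruteSolvable(incompatibleToy()))

  res2 <- solveGtc(transferToy())
  expect_equal(res2$status, "solved")
  expect_true(treesIsomorphic(res2$speciesTree, readNewick("((A,B),C);")))
  # oracle: exactly one of the 3 binary trees verifies
  trees <- allBinarySpeciesTrees(c("A", "B", "C"))
  ok <- vapply(trees, function(S) verifySolution(transferToy(), S), logical(1))
  expect_equal(sum(ok), 1)
})

test_that("invalid instances and malformed species trees are usage errors", {
  bad <- readGeneTree(
    "((a1[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S],a2[&&NHX:S=A])[&&NHX:ev=S];")
  expect_error(solveGtc(bad), "observability")
  gt <- transferToy()
  expect_error(solveGtc(gt, readNewick("((A,B),(C,D));")), "must equal")
  gt5 <- readGeneTree(paste0(
    "(a[&&NHX:S=A],b[&&NHX:S=B],c[&&NHX:S=C],d[&&NHX:S=D],e[&&NHX:S=E])",
    "[&&NHX:ev=S];"))
  expect_error(solveGtc(gt5, readNewick("((A,B,(C,D),E));")), "almost binary")
})

test_that("a user-supplied species tree disagreeing with the triplets is refused", {
  gt <- transferToy()  # R = {AB|C}
  res <- solveGtc(gt, readNewick("((A,C),B);"))
  expect_equal(res$status, "no_solution")
  expect_match(res$reason, "contradicts informative triplet A,B|C", fixed = TRUE)
})

test_that("degenerate instances with one or two species solve trivially", {
  gt <- readGeneTree("((a1[&&NHX:S=A],a2[&&NHX:S=A])[&&NHX:ev=D],b[&&NHX:S=B])[&&NHX:ev=S];")
  res <- solveGtc(gt)
  expect_equal(res$status, "solved")
  expect_setequal(treeLeafLabels(res$speciesTree), c("A", "B"))
  expect_equal(nrow(res$trace), 0)
})

test_that("verdicts agree with brute force over all binary species trees", {
  set.seed(61)
  n <- 0; nNeg <- 0
  for (i in 1:60) {
    sim <- simulateInstance(sample(3:5, 1), 0.5, 0.6, 0.4, seed = 5000 + i)
    gt <- sim$geneTree
    if (i %% 2 == 0) gt <- perturbEvents(gt)
    verdict <- solveGtc(gt)$status == "solved"
    expect_equal(verdict, oraBruteSolvable(gt))
    if (!verdict) nNeg <- nNeg + 1
    n <- n + 1
  }
  expect_equal(n, 60)
})

test_that("transfer-free instances reduce to BUILD triplet compatibility", {
  set.seed(67)
  for (i in 1:25) {
    sim <- simulateInstance(sample(4:10, 1), 0.6, 0, 0.4, seed = 6000 + i)
    gt <- sim$geneTree
    expect_equal(nrow(transferEdgesOf(gt)), 0)
    built <- ahoBuild(informativeTriplets(gt), speciesImage(gt))
    res <- solveGtc(gt)
    expect_equal(res$status == "solved", !is.null(built))
  }
  # and a crafted incompatible transfer-free instance
  gtInc <- readGeneTree(paste0(
    "(((a1[&&NHX:S=A],b1[&&NHX:S=B])[&&NHX:ev=S],c1[&&NHX:S=C])[&&NHX:ev=S],",
    "((b2[&&NHX:S=B],c2[&&NHX:S=C])[&&NHX:ev=S],a2[&&NHX:S=A])[&&NHX:ev=S])",
    "[&&NHX:ev=D];"))
  expect_null(ahoBuild(informativeTriplets(gtInc), c("A", "B", "C")))
  expect_equal(solveGtc(gtInc)$status, "no_solution")
})

test_that("each iteration adds one binary vertex; loop length <= |Sigma|-2", {
  set.seed(71)
  for (i in 1:10) {
    sim <- simulateInstance(sample(5:12, 1), 0.4, 0.5, 0.3, seed = 7000 + i)
    res <- solveGtc(sim$geneTree)
    expect_equal(res$status, "solved")
    k <- length(speciesImage(sim$geneTree))
    # each split refinement resolves one cherry (adding one or two internal
    # vertices, one when a side is a singleton), so the loop is bounded by
    # the number of internal vertices a binary tree can gain over the star
    expect_lte(nrow(res$trace), max(0, k - 2))
    expect_gte(nrow(res$trace), if (k > 2) 1 else 0)
  }
})
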