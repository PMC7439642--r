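# literal re-check of a good-split-graph edge against the four defining
# conditions, independent of the incremental construction
recheckEdge <- function(gt, S, Q, x, a, b, conds) {
  R <- informativeTriplets(gt)
  V <- sort(unname(S@labels[treeChildren(S, x)]))
  idx <- gtctree:::gtIndex(gt)
  mu <- lcaMap(gt, S)
  ev <- eventsOf(gt)
  pm <- parentMap(geneTreeOf(gt))
  members <- Q$members
  got <- character(0)
  if (any((R$a == a & R$b == b) | (R$a == b & R$b == a))) {
    cs <- R$c[(R$a == pmin(a, b) & R$b == pmax(a, b))]
    if (any(cs %in% V)) got <- c(got, "C1")
  }
  for (v in geneTreeOf(gt)@vertices) {
    u <- pm[[v]]
    if (is.na(u)) next
    if (ev[[u]] %in% c("D", "T") && !(paste0("G:", u) %in% members) &&
        ev[[v]] == "S" && all(c(a, b) %in% idx$sigmaComp[[v]])) got <- c(got, "C2")
    if (ev[[u]] == "S" && ev[[v]] == "S" && mu[[u]] == x &&
        all(c(a, b) %in% idx$sigmaComp[[v]])) got <- c(got, "C3")
  }
  for (u in geneTreeOf(gt)@vertices) {
    if (ev[[u]] %in% c("D", "T") && !(paste0("G:", u) %in% members) &&
        all(c(a, b) %in% idx$sigmaComp[[u]])) got <- c(got, "C4")
  }
  identical(sort(unique(got)), sort(strsplit(conds, ",")[[1]]))
}

test_that("worked example: star-phase graph has 4 vertices and 2 edges", {
  ex <- exampleGtcInstance()$geneTree
  S1 <- starTree(speciesImage(ex))
  Q1 <- maximalTopologicalSort(buildAuxGraph(ex, S1))
  g <- goodSplitGraph(ex, S1, Q1, treeRoot(S1))
  expect_setequal(g$vertices, c("A", "B", "C", "D"))
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$a, g$edges$b), c("A B", "A C"))
  bp <- disconnectedBipartition(g)
  expect_setequal(bp$A, c("A", "B", "C"))
  expect_setequal(bp$B, "D")
  for (i in seq_len(nrow(g$edges))) {
    expect_true(recheckEdge(ex, S1, Q1, treeRoot(S1),
                            g$edges$a[i], g$edges$b[i], g$edges$conds[i]))
  }
  expect_error(goodSplitGraph(ex, S1, Q1, "nope"), "not a cherry")
})

test_that("worked example: second-phase graph resolves the ABC cherry", {
  ex <- exampleGtcInstance()$geneTree
  S2 <- readNewick("((A,B,C),D);")
  Q2 <- maximalTopologicalSort(buildAuxGraph(ex, S2))
  ch <- cherries(S2)
  x <- ch[lengths(S2@children[ch]) == 3]
  g <- goodSplitGraph(ex, S2, Q2, x)
  expect_setequal(g$vertices, c("A", "B", "C"))
  expect_equal(paste(g$edges$a, g$edges$b), "A B")
  bp <- disconnectedBipartition(g)
  expect_setequal(bp$A, c("A", "B"))
  expect_setequal(bp$B, "C")
})

test_that("connected graphs admit no bipartition; edgeless ones split apart", {
  inc <- incompatibleToy()
  S <- starTree(c("A", "B", "C"))
  Q <- maximalTopologicalSort(buildAuxGraph(inc, S))
  g <- goodSplitGraph(inc, S, Q, treeRoot(S))
  # C1 from AB|C and BC|A joins A-B and B-C: connected
  expect_true(all(c("A B", "B C") %in% paste(g$edges$a, g$edges$b)))
  expect_null(disconnectedBipartition(g))
  expect_null(findGoodSplit(inc, S))
  expect_null(disconnectedBipartition(list(vertices = c("A", "B"),
    edges = data.frame(a = "A", b = "B", conds = "C1"))))
  bp <- disconnectedBipartition(list(vertices = c("A", "B"),
    edges = data.frame(a = character(0), b = character(0), conds = character(0))))
  expect_equal(bp, list(A = "A", B = "B"))
})

test_that("a speciation-only tree over distinct species constrains nothing", {
  gt <- readGeneTree(
    "(a[&&NHX:S=A],b[&&NHX:S=B],c[&&NHX:S=C])[&&NHX:ev=S];")
  S <- starTree(c("A", "B", "C"))
  Q <- maximalTopologicalSort(buildAuxGraph(gt, S))
  g <- goodSplitGraph(gt, S, Q, treeRoot(S))
  expect_equal(nrow(g$edges), 0)
})

test_that("split refinement adds exactly one binary vertex and keeps shape", {
  st <- starTree(c("A", "B", "C", "D"))
  r <- treeRoot(st)
  ch <- treeChildren(st, r)
  A <- ch[st@labels[ch] %in% c("A", "B", "C")]
  B <- setdiff(ch, A)
  S2 <- applySplitRefinement(st, r, A, B)
  expect_true(treesIsomorphic(S2, readNewick("((A,B,C),D);")))
  expect_true(isAlmostBinaryTree(S2))
  nbin <- function(S) sum(lengths(S@children) == 2)
  expect_equal(nbin(S2), nbin(st) + 1)
  expect_error(applySplitRefinement(st, r, ch, character(0)), "empty side")
  expect_error(applySplitRefinement(st, r, ch[1:2], ch[2:4]), "partition")
})

test_that("good splits keep agreement and strictly extend the sort", {
  set.seed(53)
  for (i in 1:15) {
    sim <- simulateInstance(sample(4:9, 1), 0.4, 0.5, 0.3, seed = 4000 + i)
    gt <- sim$geneTree
    R <- informativeTriplets(gt)
    S <- starTree(speciesImage(gt))
    repeat {
      if (isBinaryTree(S)) break
      Q <- maximalTopologicalSort(buildAuxGraph(gt, S))
      step <- findGoodSplit(gt, S, R)
      expect_false(is.null(step))
      S2 <- applySplitRefinement(S, step$cherry, step$A, step$B)
      expect_true(agreesWith(S2, R))
      Q2 <- maximalTopologicalSort(buildAuxGraph(gt, S2))
      expect_true(all(Q$members %in% Q2$members))
      expect_gt(length(Q2$members), length(Q$members))
      # every in-neighbor of the refined cherry already belongs to M(Q)
      G2 <- buildAuxGraph(gt, S2)
      inN <- G2@edges$tail[G2@edges$head == paste0("S:", step$cherry)]
      expect_true(all(inN %in% Q$members))
      S <- S2
    }
  }
})
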