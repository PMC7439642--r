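test_that("Newick parsing handles basic shapes and rejects malformed input", {
  star <- readNewick("(A,B,C);")
  expect_length(treeLeaves(star), 3)
  expect_length(setdiff(star@vertices, treeLeaves(star)), 1)
  expect_equal(nrow(displayedTriplets(star)), 0)

  t2 <- readNewick("((A,B),C);")
  expect_true(sameTripletSet(displayedTriplets(t2), tripletSet("A", "B", "C")))

  ab <- readNewick("((A,B,C),D);")
  expect_true(isAlmostBinaryTree(ab))
  expect_false(isBinaryTree(ab))

  expect_error(readNewick("((A,B),C)"), "missing ';'")
  expect_error(readNewick("((A,B,C);"), "parse error")
  expect_error(readNewick("((A,A),B);"), "duplicate leaf labels")
  expect_error(readNewick(";"), "parse error")
  # branch lengths and comments are tolerated and ignored
  expect_equal(writeNewick(readNewick("((A:0.1,B:0.2):0.3,C:1e-2);")),
               "((A,B),C);")
})

test_that("Newick write/read round-trip is the identity on random trees", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    labs <- paste0("t", seq_len(n))
    tr <- randomTree(labs)
    back <- readNewick(writeNewick(tr))
    expect_true(treesIsomorphic(tr, back))
  }
})

test_that("lca answers identity, pair and whole-leaf-set queries", {
  tr <- readNewick("((A,B),C);")
  idA <- names(tr@labels)[match("A", tr@labels)]
  idB <- names(tr@labels)[match("B", tr@labels)]
  expect_equal(lca(tr, idA), idA)
  expect_equal(lca(tr, c(idA, idB)), parentMap(tr)[[idA]])
  expect_equal(lca(tr, treeLeaves(tr)), treeRoot(tr))
  expect_equal(lcaOfLabels(tr, c("A", "B", "C")), treeRoot(tr))
  expect_error(lca(tr, character(0)), "non-empty")
  expect_error(lca(tr, "nope"), "unknown vertex")
  expect_error(lcaOfLabels(tr, "Z"), "not in tree")
})

test_that("displayed triplets match brute-force enumeration on small trees", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    tr <- randomTree(paste0("x", seq_len(n)))
    expect_true(sameTripletSet(displayedTriplets(tr), oraDisplayedTriplets(tr)))
  }
  # a binary tree on n leaves displays exactly choose(n,3) triplets
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- randomTree(paste0("x", seq_len(n)), pMultifurcate = 0)
    expect_equal(nrow(displayedTriplets(tr)), choose(n, 3))
  }
})

test_that("agreement is weaker than display", {
  star <- readNewick("(A,B,C);")
  R <- tripletSet(c("A", "B"), c("B", "C"), c("C", "A"))
  expect_true(agreesWith(star, R))        # star agrees with anything
  expect_false(displaysTriplets(star, R))
  t2 <- readNewick("((A,B),C);")
  expect_false(agreesWith(t2, tripletSet("A", "C", "B")))
  expect_true(agreesWith(t2, tripletSet()))
  expect_true(displaysTriplets(t2, tripletSet("A", "B", "C")))
  expect_error(agreesWith(t2, tripletSet("A", "Z", "B")), "not in tree")
})

test_that("extension moves preserve leaves and add one vertex", {
  st <- starTree(c("A", "B", "C", "D"))
  r <- treeRoot(st)
  idA <- names(st@labels)[match("A", st@labels)]
  idB <- names(st@labels)[match("B", st@labels)]
  expect_true(treesIsomorphic(applyExtension(st, r, idA), st))  # |X'| <= 1
  ext <- applyExtension(st, r, c(idA, idB))
  expect_true(treesIsomorphic(ext, readNewick("((A,B),C,D);")))
  expect_setequal(treeLeafLabels(ext), treeLeafLabels(st))
  expect_equal(length(ext@vertices), length(st@vertices) + 1)
  expect_error(applyExtension(st, r, treeChildren(st, r)), "strict subset")
  expect_error(applyExtension(st, r, "bogus"), "children of x")
})

test_that("restriction keeps exactly the induced triplets", {
  tr <- readNewick("((A,B),(C,D));")
  expect_true(treesIsomorphic(restrictTree(tr, c("A", "C")), readNewick("(A,C);")))
  tr2 <- readNewick("(((A,B),C),D);")
  expect_true(treesIsomorphic(restrictTree(tr2, c("A", "B", "D")),
                              readNewick("((A,B),D);")))
  expect_true(treesIsomorphic(restrictTree(tr2, treeLeafLabels(tr2)), tr2))
  expect_error(restrictTree(tr2, "Q"), "unknown label")
  set.seed(11)
  for (i in 1:25) {
    tr <- randomTree(paste0("x", 1:7))
    keep <- sample(paste0("x", 1:7), sample(2:6, 1))
    res <- restrictTree(tr, keep)
    expect_setequal(treeLeafLabels(res), keep)
    full <- oraDisplayedTriplets(tr)
    induced <- full[full$a %in% keep & full$b %in% keep & full$c %in% keep, ]
    expect_true(sameTripletSet(oraDisplayedTriplets(res), tripletSet(
      induced$a, induced$b, induced$c)))
  }
})
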