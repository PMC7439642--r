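# Good split refinements: resolving one cherry of an almost binary species
# tree so that triplet agreement is kept and the refinement unlocks at
# least one new vertex of the auxiliary graph's maximal topological sort.
# The candidate splits at a cherry are read off the connected components of
# an Aho-style constraint graph on the cherry's leaves.

#' Constraint graph at a cherry (good-split graph)
#'
#' Undirected graph on the leaves below cherry \code{x}.  Two species are
#' joined (must stay together under any split) when separating them would
#' either contradict an informative triplet (C1) or create an edge into
#' \code{x} in the refined auxiliary graph from a vertex outside the
#' current maximal topological sort, or a self-loop at \code{x} (C2-C4).
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param S an almost binary species tree.
#' @param Q maximal topological sort of the auxiliary graph of (gt, S), as
#'   returned by \code{\link{maximalTopologicalSort}}.
#' @param x a cherry of \code{S}.
#' @param R informative triplets (recomputed when NULL).
#' @return list with \code{vertices} (species labels under \code{x}) and
#'   \code{edges}, a data.frame with columns \code{a}, \code{b},
#'   \code{conds} (comma-joined subset of C1..C4 justifying the edge).
#' @export
goodSplitGraph <- function(gt, S, Q, x, R = NULL) {
  lv <- treeLeaves(S)
  ch <- treeChildren(S, x)
  if (length(ch) == 0 || !all(ch %in% lv)) {
    stop("goodSplitGraph: '", x, "' is not a cherry of S")
  }
  V <- sort(unname(S@labels[ch]))
  if (is.null(R)) R <- informativeTriplets(gt)
  idx <- gtIndex(gt)
  mu <- lcaMap(gt, S)
  ev <- gt@events
  members <- Q$members
  pm <- parentMap(gt@tree)

  ea <- character(0); eb <- character(0); ec <- character(0)
  addPairs <- function(P, cond) {
    P <- intersect(P, V)
    if (length(P) < 2) return(invisible())
    prs <- utils::combn(sort(P), 2)
    ea <<- c(ea, prs[1, ]); eb <<- c(eb, prs[2, ])
    ec <<- c(ec, rep(cond, ncol(prs)))
  }

  # C1: a triplet ab|c with all three species below x
  if (nrow(R)) {
    inV <- R$a %in% V & R$b %in% V & R$c %in% V
    for (i in which(inV)) addPairs(c(R$a[i], R$b[i]), "C1")
  }
  # C2/C3 range over all gene-tree edges (transfer edges included)
  for (v in gt@tree@vertices) {
    u <- pm[[v]]
    if (is.na(u)) next
    if (ev[[u]] %in% c("D", "T") && !(gv(u) %in% members) && ev[[v]] == "S") {
      addPairs(idx$sigmaComp[[v]], "C2")
    }
    if (ev[[u]] == "S" && ev[[v]] == "S" && mu[[u]] == x) {
      addPairs(idx$sigmaComp[[v]], "C3")
    }
  }
  # C4: duplication/transfer vertices not yet in the sort
  for (u in gt@tree@vertices) {
    if (ev[[u]] %in% c("D", "T") && !(gv(u) %in% members)) {
      addPairs(idx$sigmaComp[[u]], "C4")
    }
  }

  if (length(ea)) {
    key <- paste(ea, eb, sep = "\r")
    conds <- vapply(split(ec, key), function(z)
      paste(sort(unique(z)), collapse = ","), character(1))
    uq <- !duplicated(key)
    edges <- data.frame(a = ea[uq], b = eb[uq],
                        conds = unname(conds[key[uq]]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        conds = character(0), stringsAsFactors = FALSE)
  }
  list(vertices = V, edges = edges, cherry = x)
}

#' Disconnected bipartition of an undirected graph
#'
#' NULL when the graph is connected; otherwise the bipartition (A, B)
#' where A is the connected component containing the lexicographically
#' smallest vertex and B the rest.  No edge crosses (A, B).
#'
#' @param g a graph as returned by \code{\link{goodSplitGraph}}.
#' @return NULL, or list with character vectors \code{A} and \code{B}.
#' @export
disconnectedBipartition <- function(g) {
  V <- sort(g$vertices)
  if (length(V) < 2) return(NULL)
  comp <- stats::setNames(seq_along(V), V)
  for (i in seq_len(nrow(g$edges))) {
    ca <- comp[[g$edges$a[i]]]; cb <- comp[[g$edges$b[i]]]
    if (ca != cb) comp[comp == cb] <- ca
  }
  first <- comp[[V[[1]]]]
  A <- V[comp == first]
  B <- setdiff(V, A)
  if (length(B) == 0) return(NULL)
  list(A = A, B = B)
}

#' Split refinement at a cherry
#'
#' Partitions the children of cherry \code{x} into two non-empty groups
#' and inserts a new parent above each group of size two or more: an
#' almost binary tree becomes an almost binary tree with exactly one more
#' binary internal vertex.
#'
#' @param S an almost binary species tree.
#' @param x a cherry of \code{S}.
#' @param A,B child vertex ids of \code{x}, partitioning them, both
#'   non-empty.
#' @return the refined \linkS4class{RootedTree}.
#' @export
applySplitRefinement <- function(S, x, A, B) {
  ch <- treeChildren(S, x)
  if (length(A) == 0 || length(B) == 0) stop("applySplitRefinement: empty side")
  if (!setequal(c(A, B), ch) || length(intersect(A, B))) {
    stop("applySplitRefinement: (A,B) must partition the children of x")
  }
  children <- S@children
  ids <- freshIds(S, 2)
  newch <- character(0)
  if (length(A) >= 2) { children[[ids[1]]] <- A; newch <- c(newch, ids[1]) }
  else newch <- c(newch, A)
  if (length(B) >= 2) { children[[ids[2]]] <- B; newch <- c(newch, ids[2]) }
  else newch <- c(newch, B)
  children[[x]] <- newch
  newRootedTree(S@root, children, S@labels)
}

#' Search for a good split refinement
#'
#' Scans the cherries of \code{S} (ordered by smallest descendant species
#' label).  A cherry qualifies when every strict ancestor of it already
#' belongs to the maximal topological sort and its constraint graph is
#' disconnected; any disconnected bipartition then yields a good split
#' refinement.  Returns NULL when no cherry qualifies, in which case the
#' instance has no solution.
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param S an almost binary species tree that agrees with the informative
#'   triplets (checked; a disagreement is a usage error).
#' @param R informative triplets (recomputed when NULL).
#' @return NULL or list with \code{cherry}, child-id vectors \code{A},
#'   \code{B}, and the constraint \code{graph}.
#' @export
findGoodSplit <- function(gt, S, R = NULL) {
  if (is.null(R)) R <- informativeTriplets(gt)
  if (!agreesWith(S, R)) {
    stop("findGoodSplit: species tree does not agree with the informative triplets")
  }
  G <- buildAuxGraph(gt, S)
  Q <- maximalTopologicalSort(G)
  pm <- parentMap(S)
  minlab <- minLabelBelow(S)
  # only multifurcating cherries can contribute a refinement; a split at a
  # binary cherry is the identity
  chs <- cherries(S)
  chs <- chs[lengths(S@children[chs]) >= 3]
  chs <- chs[order(minlab[chs])]
  for (x in chs) {
    anc <- setdiff(ancestorsOf(S, x, pm), x)
    if (!all(sv(anc) %in% Q$members)) next
    g <- goodSplitGraph(gt, S, Q, x, R)
    bp <- disconnectedBipartition(g)
    if (!is.null(bp)) {
      ch <- treeChildren(S, x)
      labs <- S@labels[ch]
      return(list(cherry = x,
                  A = ch[labs %in% bp$A],
                  B = ch[labs %in% bp$B],
                  graph = g))
    }
  }
  NULL
}

#' Dump a good-split graph in DOT format
#'
#' @param g as returned by \code{\link{goodSplitGraph}}.
#' @param file path; "" prints to the console.
#' @export
goodSplitGraphToDot <- function(g, file = "") {
  lines <- c("graph goodsplit {",
             sprintf('  "%s";', g$vertices),
             sprintf('  "%s" -- "%s" [label="%s"];',
                     g$edges$a, g$edges$b, g$edges$conds),
             "}")
  writeLines(lines, con = file)
  invisible(lines)
}
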