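# Rooted-tree construction, queries and the two tree surgeries (restriction
# and extension) everything else builds on.  Trees here are small (tens of
# vertices), so queries recompute indexes on demand instead of caching.

#' Construct a RootedTree from its parts
#'
#' Children are brought into canonical order (by smallest descendant leaf
#' label), which makes written Newick and all tie-breaking deterministic.
#'
#' @param root root vertex id.
#' @param children named list mapping each internal vertex to the character
#'   vector of its children.
#' @param labels named character mapping leaf vertex ids to labels.
#' @return a validated \linkS4class{RootedTree}.
#' @export
newRootedTree <- function(root, children, labels) {
  children <- children[lengths(children) > 0]
  vertices <- unique(c(root, names(children), unlist(children, use.names = FALSE),
                       names(labels)))
  tr <- new("RootedTree", vertices = vertices, root = root,
            children = children, labels = labels)
  validObject(tr)
  canonicalizeTree(tr)
}

# order every children vector by the smallest leaf label below each child
canonicalizeTree <- function(tree) {
  if (length(tree@children) == 0) return(tree)
  minlab <- minLabelBelow(tree)
  tree@children <- lapply(tree@children, function(ch) ch[order(minlab[ch])])
  tree
}

minLabelBelow <- function(tree) {
  out <- character(length(tree@vertices))
  names(out) <- tree@vertices
  for (v in rev(dfsOrder(tree))) {
    ch <- tree@children[[v]]
    out[v] <- if (is.null(ch)) tree@labels[[v]] else min(out[ch])
  }
  out
}

#' @rdname treeAccessors
#' @export
treeRoot <- function(tree) tree@root

#' Tree accessors
#'
#' Small accessors for \linkS4class{RootedTree} objects: the root id, the
#' leaf vertex ids, the leaf labels, the children of a vertex, and the
#' parent map (named character; the root maps to \code{NA}).
#'
#' @param tree a \linkS4class{RootedTree}.
#' @param v a vertex id.
#' @name treeAccessors
#' @export
treeLeaves <- function(tree) names(tree@labels)

#' @rdname treeAccessors
#' @export
treeLeafLabels <- function(tree) unname(tree@labels)

#' @rdname treeAccessors
#' @export
treeChildren <- function(tree, v) {
  ch <- tree@children[[v]]
  if (is.null(ch)) character(0) else ch
}

#' @rdname treeAccessors
#' @export
parentMap <- function(tree) {
  pm <- rep(NA_character_, length(tree@vertices))
  names(pm) <- tree@vertices
  for (v in names(tree@children)) pm[tree@children[[v]]] <- v
  pm
}

# root-first depth-first order of all vertices
dfsOrder <- function(tree) {
  out <- character(length(tree@vertices))
  stack <- tree@root
  i <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    i <- i + 1L
    out[i] <- v
    ch <- tree@children[[v]]
    if (!is.null(ch)) stack <- c(stack, rev(ch))
  }
  out
}

# per-vertex leaf-label sets (list named by vertex), computed bottom-up
leavesBelow <- function(tree) {
  out <- vector("list", length(tree@vertices))
  names(out) <- tree@vertices
  for (v in rev(dfsOrder(tree))) {
    ch <- tree@children[[v]]
    out[[v]] <- if (is.null(ch)) unname(tree@labels[[v]]) else
      unlist(out[ch], use.names = FALSE)
  }
  out
}

# chain of ancestors of v, from v itself up to the root
ancestorsOf <- function(tree, v, pm = parentMap(tree)) {
  out <- v
  while (!is.na(pm[[v]])) {
    v <- pm[[v]]
    out <- c(out, v)
  }
  out
}

#' Lowest common ancestor
#'
#' The unique minimal vertex that is an ancestor of every vertex in
#' \code{X}; \code{lca} of a single vertex is that vertex itself, and the
#' lca of all leaves is the root.
#'
#' @param tree a \linkS4class{RootedTree}.
#' @param X non-empty character vector of vertex ids.
#' @return a vertex id.
#' @export
lca <- function(tree, X) {
  X <- unique(X)
  if (length(X) == 0) stop("lca: X must be non-empty")
  if (!all(X %in% tree@vertices)) {
    stop("lca: unknown vertex id(s): ", paste(setdiff(X, tree@vertices), collapse = ", "))
  }
  pm <- parentMap(tree)
  common <- ancestorsOf(tree, X[[1]], pm)
  for (v in X[-1]) {
    common <- common[common %in% ancestorsOf(tree, v, pm)]
  }
  common[[1]]
}

#' @rdname lca
#' @param labels leaf labels (rather than vertex ids).
#' @export
lcaOfLabels <- function(tree, labels) {
  ids <- names(tree@labels)[match(labels, tree@labels)]
  if (anyNA(ids)) {
    stop("lcaOfLabels: label(s) not in tree: ",
         paste(setdiff(labels, tree@labels), collapse = ", "))
  }
  lca(tree, ids)
}

#' Shape predicates and cherries
#'
#' A vertex is binary if it has two children; a tree is binary if all its
#' internal vertices are.  A cherry is an internal vertex all of whose
#' children are leaves (possibly more than two).  A tree is almost binary
#' if its only non-binary vertices are cherries.  Trees with one or two
#' leaves count as binary.
#'
#' @param tree a \linkS4class{RootedTree}.
#' @name treeShape
#' @export
isBinaryTree <- function(tree) {
  all(lengths(tree@children) == 2L)
}

#' @rdname treeShape
#' @export
isAlmostBinaryTree <- function(tree) {
  lv <- treeLeaves(tree)
  for (v in names(tree@children)) {
    if (length(tree@children[[v]]) > 2L && !all(tree@children[[v]] %in% lv)) {
      return(FALSE)
    }
  }
  TRUE
}

#' @rdname treeShape
#' @export
cherries <- function(tree) {
  lv <- treeLeaves(tree)
  int <- names(tree@children)
  int[vapply(int, function(v) all(tree@children[[v]] %in% lv), logical(1))]
}

#' Star tree over a label set
#'
#' @param labels leaf labels (at least one).
#' @return a \linkS4class{RootedTree}; with a single label, the one-vertex
#'   tree whose root is the leaf.
#' @export
starTree <- function(labels) {
  labels <- sort(unique(labels))
  if (length(labels) == 0) stop("starTree: empty label set")
  ids <- paste0("v", seq_along(labels))
  names(labels) <- NULL
  if (length(labels) == 1) {
    return(newRootedTree("v1", list(), stats::setNames(labels, "v1")))
  }
  newRootedTree("v0", list(v0 = ids), stats::setNames(labels, ids))
}

# fresh vertex ids not colliding with existing ones
freshIds <- function(tree, n, prefix = "x") {
  out <- character(0)
  i <- 1L
  while (length(out) < n) {
    cand <- paste0(prefix, i)
    if (!(cand %in% tree@vertices)) out <- c(out, cand)
    i <- i + 1L
  }
  out
}

#' Extension move at a multifurcation
#'
#' Groups a strict subset \code{Xp} of the children of \code{x} under a new
#' vertex inserted below \code{x}.  With \code{length(Xp) <= 1} the tree is
#' returned unchanged.  The leaf set is preserved and exactly one internal
#' vertex is added when \code{length(Xp) >= 2}.
#'
#' @param tree a \linkS4class{RootedTree}.
#' @param x an internal vertex with at least three children.
#' @param Xp strict subset of the children of \code{x}.
#' @return the extended \linkS4class{RootedTree}.
#' @export
applyExtension <- function(tree, x, Xp) {
  ch <- treeChildren(tree, x)
  if (length(ch) < 3) stop("applyExtension: vertex has fewer than three children")
  if (!all(Xp %in% ch)) stop("applyExtension: Xp must be children of x")
  if (length(Xp) >= length(ch)) stop("applyExtension: Xp must be a strict subset")
  if (length(Xp) <= 1) return(tree)
  y <- freshIds(tree, 1)
  children <- tree@children
  children[[x]] <- c(setdiff(ch, Xp), y)
  children[[y]] <- Xp
  newRootedTree(tree@root, children, tree@labels)
}

#' Restriction of a tree to a leaf subset
#'
#' Takes the minimal subtree spanning the given leaves and suppresses all
#' resulting degree-two vertices (except the new root).  The restricted
#' tree displays exactly the triplets of the original tree over the kept
#' labels.
#'
#' @param tree a \linkS4class{RootedTree}.
#' @param keep leaf labels to keep (non-empty).
#' @return a \linkS4class{RootedTree} with leaf set \code{keep}.
#' @export
restrictTree <- function(tree, keep) {
  keep <- unique(keep)
  if (length(keep) == 0) stop("restrictTree: empty label set")
  if (!all(keep %in% tree@labels)) {
    stop("restrictTree: unknown label(s): ",
         paste(setdiff(keep, tree@labels), collapse = ", "))
  }
  ids <- names(tree@labels)[match(keep, tree@labels)]
  if (length(ids) == 1) {
    return(newRootedTree(ids, list(), tree@labels[ids]))
  }
  lb <- leavesBelow(tree)
  nkeep <- vapply(tree@vertices, function(v) sum(lb[[v]] %in% keep), integer(1))
  names(nkeep) <- tree@vertices
  # recursive rebuild from the lca of the kept leaves, skipping pass-through
  # vertices (those with exactly one child subtree containing kept leaves)
  children <- list()
  build <- function(v) {
    while (!(v %in% ids)) {
      ch <- tree@children[[v]]
      live <- ch[nkeep[ch] > 0]
      if (length(live) > 1) {
        children[[v]] <<- vapply(live, build, character(1))
        return(v)
      }
      v <- live
    }
    v
  }
  root <- lca(tree, ids)
  root <- build(root)
  newRootedTree(root, children, tree@labels[ids])
}

#' Canonical Newick equality (label-preserving isomorphism)
#'
#' Two rooted trees are isomorphic as leaf-labeled trees iff their canonical
#' Newick strings coincide.
#'
#' @param t1,t2 \linkS4class{RootedTree} objects.
#' @export
treesIsomorphic <- function(t1, t2) {
  identical(writeNewick(canonicalizeTree(t1)), writeNewick(canonicalizeTree(t2)))
}
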