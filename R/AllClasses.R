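#' @import methods
NULL

#' Rooted phylogenetic tree
#'
#' A rooted tree with opaque character vertex ids and edges implicitly
#' directed away from the root.  Internal structure is kept minimal: the set
#' of vertices, the root id, an ordered children map for internal vertices,
#' and a leaf-label map.  Leaf labels are unique within a tree; children are
#' stored in canonical order (sorted by smallest descendant leaf label) so
#' that all outputs and tie-breaks are deterministic.
#'
#' @slot vertices character vector of all vertex ids.
#' @slot root id of the root vertex.
#' @slot children named list; for each internal vertex, the ordered character
#'   vector of its children.  Leaves do not appear as names.
#' @slot labels named character; for each leaf vertex id, its label.
#'
#' @examples
#' tr <- readNewick("((A,B),C);")
#' treeLeafLabels(tr)
#' @export
setClass("RootedTree",
  representation(
    vertices = "character",
    root = "character",
    children = "list",
    labels = "character"
  )
)

setValidity("RootedTree", function(object) {
  msg <- character(0)
  vs <- object@vertices
  if (length(vs) == 0) return("tree has no vertices")
  if (anyDuplicated(vs)) msg <- c(msg, "duplicate vertex ids")
  if (!(object@root %in% vs)) msg <- c(msg, "root is not a vertex")
  kids <- unlist(object@children, use.names = FALSE)
  if (anyDuplicated(kids)) msg <- c(msg, "a vertex has two parents")
  if (object@root %in% kids) msg <- c(msg, "root has a parent")
  if (!all(kids %in% vs)) msg <- c(msg, "child id not in vertex set")
  if (!all(names(object@children) %in% vs)) {
    msg <- c(msg, "internal vertex id not in vertex set")
  }
  nonroot <- setdiff(vs, object@root)
  if (!setequal(nonroot, kids)) {
    msg <- c(msg, "vertices other than the root must have exactly one parent")
  }
  leaves <- setdiff(vs, names(object@children)[lengths(object@children) > 0])
  if (!setequal(names(object@labels), leaves)) {
    msg <- c(msg, "labels must be given for exactly the leaves")
  }
  if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate leaf labels")
  if (length(msg)) msg else TRUE
})

#' Event-labeled gene tree
#'
#' A rooted gene tree together with the vertex event labeling (leaf,
#' speciation, duplication or transfer origin), the set of transfer edges,
#' and the gene-to-species assignment of its leaves.  Transfer edges always
#' start at transfer vertices; removing them yields the transfer-free forest
#' whose components carry the vertical part of the history.
#'
#' Event codes used throughout: \code{"L"} leaf, \code{"S"} speciation,
#' \code{"D"} duplication, \code{"T"} transfer origin.
#'
#' @slot tree a \linkS4class{RootedTree} whose leaves are genes.
#' @slot events named character; event code per vertex id.
#' @slot transferEdges two-column character matrix (tail, head) of transfer
#'   edges; possibly zero rows.
#' @slot sigma named character; species per leaf vertex id.
#'
#' @export
setClass("GeneTree",
  representation(
    tree = "RootedTree",
    events = "character",
    transferEdges = "matrix",
    sigma = "character"
  )
)

setValidity("GeneTree", function(object) {
  msg <- character(0)
  tr <- object@tree
  vs <- tr@vertices
  lv <- treeLeaves(tr)
  ev <- object@events
  if (!setequal(names(ev), vs)) msg <- c(msg, "events must cover all vertices")
  if (!all(ev %in% c("L", "S", "D", "T"))) {
    msg <- c(msg, "unknown event code (expected L, S, D or T)")
  }
  if (!all(ev[lv] == "L") || any(ev[setdiff(vs, lv)] == "L")) {
    msg <- c(msg, "event is 'L' exactly for leaves")
  }
  te <- object@transferEdges
  if (ncol(te) != 2) msg <- c(msg, "transferEdges must have two columns")
  if (nrow(te) > 0) {
    pm <- parentMap(tr)
    ok <- pm[te[, 2]] == te[, 1]
    if (any(is.na(ok)) || !all(ok)) {
      msg <- c(msg, "transfer edge is not an edge of the tree")
    }
    if (!all(ev[te[, 1]] == "T")) {
      msg <- c(msg, "transfer edge starting at a non-transfer vertex")
    }
  }
  if (!setequal(names(object@sigma), lv)) {
    msg <- c(msg, "sigma must map exactly the leaves")
  }
  if (length(msg)) msg else TRUE
})

#' Auxiliary timing digraph
#'
#' The directed graph on the union of gene-tree and species-tree vertices
#' whose edges encode "must predate" constraints between genes and species
#' (classes A1 to A4; self-loops permitted).  A time-consistent
#' reconciliation exists precisely when the species tree displays all
#' informative triplets and this graph is acyclic.  Vertex ids are
#' namespaced: gene vertices as \code{"G:<id>"}, species vertices as
#' \code{"S:<id>"}.
#'
#' @slot vertices all namespaced vertex ids.
#' @slot edges data.frame with columns \code{tail}, \code{head},
#'   \code{class} (one of "A1".."A4"); parallel edges of different classes
#'   are retained.
#'
#' @export
setClass("AuxGraph",
  representation(vertices = "character", edges = "data.frame")
)

#' @export
setMethod("show", "RootedTree", function(object) {
  cat(sprintf(
    "RootedTree: %d leaves, %d vertices\n  %s\n",
    length(treeLeaves(object)), length(object@vertices),
    writeNewick(object)
  ))
})

#' @export
setMethod("show", "GeneTree", function(object) {
  ev <- object@events
  cat(sprintf(
    "GeneTree: %d genes over %d species; %d speciations, %d duplications, %d transfer vertices, %d transfer edges\n",
    length(object@sigma), length(unique(object@sigma)),
    sum(ev == "S"), sum(ev == "D"), sum(ev == "T"), nrow(object@transferEdges)
  ))
  cat("  ", writeGeneTree(object), "\n", sep = "")
})

#' @export
setMethod("show", "AuxGraph", function(object) {
  tab <- table(factor(object@edges$class, levels = c("A1", "A2", "A3", "A4")))
  cat(sprintf(
    "AuxGraph: %d vertices, %d edges (A1 %d, A2 %d, A3 %d, A4 %d)\n",
    length(object@vertices), nrow(object@edges),
    tab[["A1"]], tab[["A2"]], tab[["A3"]], tab[["A4"]]
  ))
})
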