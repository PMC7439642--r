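# The event-labeled gene tree: NHX input, observability validation, the
# transfer-free forest and the per-vertex species sets it induces.

#' Construct a GeneTree
#'
#' @param tree a \linkS4class{RootedTree} over genes.
#' @param events named character, event code per vertex ("S", "D", "T";
#'   leaves may be omitted and are filled with "L").
#' @param transferEdges two-column character matrix (tail, head); may have
#'   zero rows.
#' @param sigma named character mapping each leaf vertex id (or,
#'   equivalently, each leaf label) to a species.
#' @return a validated \linkS4class{GeneTree}.  Validation here is purely
#'   syntactic; the observability axioms are checked separately by
#'   \code{\link{validateObservability}} so that invalid instances can be
#'   loaded and reported on.
#' @export
newGeneTree <- function(tree, events, transferEdges = NULL, sigma) {
  lv <- treeLeaves(tree)
  ev <- rep(NA_character_, length(tree@vertices))
  names(ev) <- tree@vertices
  ev[lv] <- "L"
  ev[names(events)] <- events
  if (anyNA(ev)) {
    stop("newGeneTree: missing event for vertex(es): ",
         paste(names(ev)[is.na(ev)], collapse = ", "))
  }
  if (is.null(transferEdges)) {
    transferEdges <- matrix(character(0), ncol = 2)
  }
  colnames(transferEdges) <- c("tail", "head")
  if (!all(names(sigma) %in% lv) && all(names(sigma) %in% tree@labels)) {
    sigma <- stats::setNames(unname(sigma),
                             names(tree@labels)[match(names(sigma), tree@labels)])
  }
  gt <- new("GeneTree", tree = tree, events = ev,
            transferEdges = transferEdges, sigma = sigma)
  validObject(gt)
  gt
}

#' @rdname geneTreeAccessors
#' @export
geneTreeOf <- function(gt) gt@tree

#' GeneTree accessors
#'
#' @param gt a \linkS4class{GeneTree}.
#' @name geneTreeAccessors
#' @export
eventsOf <- function(gt) gt@events

#' @rdname geneTreeAccessors
#' @export
transferEdgesOf <- function(gt) gt@transferEdges

#' @rdname geneTreeAccessors
#' @export
sigmaOf <- function(gt) gt@sigma

#' @rdname geneTreeAccessors
#' @export
speciesImage <- function(gt) sort(unique(unname(gt@sigma)))

#' Read an event-annotated gene tree
#'
#' Parses the NHX dialect used throughout the package: internal vertices
#' carry \code{[&&NHX:ev=S|D|T]}; a transfer edge is flagged on the child
#' end of the edge with \code{xfer=1}; leaf species come either from
#' \code{S=<name>} tags or from a two-column table (gene, species).
#'
#' @param text NHX-annotated Newick string.
#' @param speciesMap optional data.frame or two-column matrix mapping gene
#'   labels to species; overrides/complements \code{S=} tags.
#' @return a syntactically valid \linkS4class{GeneTree}; observability
#'   axioms are not enforced here.
#' @examples
#' gt <- readGeneTree("((a[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S]);")
#' @export
readGeneTree <- function(text, speciesMap = NULL) {
  p <- parseNewick(text)
  tree <- p$tree
  ann <- p$annots
  # an unannotated unary wrapper around the true root (e.g. "((...)[tags]);")
  # is collapsed away
  while (length(treeChildren(tree, tree@root)) == 1 &&
         length(ann[[tree@root]]) == 0) {
    child <- treeChildren(tree, tree@root)[[1]]
    kids <- tree@children
    kids[[tree@root]] <- NULL
    tree <- newRootedTree(child, kids, tree@labels)
  }
  lv <- treeLeaves(tree)
  internal <- setdiff(tree@vertices, lv)
  tag <- function(v, key) {
    a <- ann[[v]]
    if (!is.null(a) && key %in% names(a)) a[[key]] else NULL
  }

  events <- character(0)
  for (v in internal) {
    evtag <- tag(v, "ev")
    if (is.null(evtag) || is.na(evtag)) {
      stop(sprintf("gene tree format error: internal vertex '%s' lacks an ev= tag", v))
    }
    code <- c(S = "S", D = "D", T = "T")[evtag]
    if (is.na(code)) {
      stop(sprintf("gene tree format error: vertex '%s' has unknown event '%s'", v, evtag))
    }
    events[v] <- code
  }

  pm <- parentMap(tree)
  xfer <- character(0)
  for (v in tree@vertices) {
    xtag <- tag(v, "xfer")
    if (!is.null(xtag) && !is.na(xtag) && xtag == "1") {
      if (is.na(pm[[v]])) {
        stop("gene tree format error: xfer=1 on the root (no incoming edge)")
      }
      if (events[[pm[[v]]]] != "T") {
        stop(sprintf(
          "gene tree format error: transfer flag on edge (%s,%s) whose tail is not a transfer vertex",
          pm[[v]], v))
      }
      xfer <- c(xfer, v)
    }
  }
  transferEdges <- cbind(tail = pm[xfer], head = xfer)

  sigma <- character(0)
  for (v in lv) {
    stag <- tag(v, "S")
    if (!is.null(stag) && !is.na(stag)) sigma[v] <- stag
  }
  if (!is.null(speciesMap)) {
    sm <- as.data.frame(speciesMap, stringsAsFactors = FALSE)
    ids <- names(tree@labels)[match(sm[[1]], tree@labels)]
    keep <- !is.na(ids)
    sigma[ids[keep]] <- sm[[2]][keep]
  }
  missing <- setdiff(lv, names(sigma))
  if (length(missing)) {
    stop("gene tree format error: leaf without species: ",
         paste(tree@labels[missing], collapse = ", "))
  }
  newGeneTree(tree, events, transferEdges, sigma[lv])
}

#' Write a gene tree in the package's NHX dialect
#'
#' @param gt a \linkS4class{GeneTree}.
#' @return a character scalar; \code{readGeneTree} of it reproduces the
#'   gene tree up to vertex ids.
#' @export
writeGeneTree <- function(gt) {
  tree <- gt@tree
  xferHeads <- gt@transferEdges[, "head"]
  rec <- function(v) {
    tag <- if (v %in% xferHeads) ":xfer=1" else ""
    ch <- tree@children[[v]]
    if (is.null(ch)) {
      sp <- gt@sigma[[v]]
      return(sprintf("%s[&&NHX:S=%s%s]", tree@labels[[v]], sp, tag))
    }
    sprintf("(%s)[&&NHX:ev=%s%s]",
            paste(vapply(ch, rec, character(1)), collapse = ","),
            gt@events[[v]], tag)
  }
  paste0(rec(tree@root), ";")
}

#' Observability-axiom validation
#'
#' Checks the three observability axioms on a syntactically valid gene
#' tree: (O1) every internal vertex has out-degree at least two; (O2) every
#' transfer vertex has at least one transfer and one non-transfer out-edge;
#' (O3a) the children of a speciation have pairwise disjoint species sets
#' in the transfer-free forest; (O3b) the two endpoints of a transfer edge
#' have disjoint species sets in the transfer-free forest.
#'
#' @param gt a \linkS4class{GeneTree}.
#' @return data.frame of violations with columns \code{axiom},
#'   \code{where}, \code{message}; zero rows iff the instance is valid.
#' @export
validateObservability <- function(gt) {
  tree <- gt@tree
  ev <- gt@events
  viol <- list()
  add <- function(axiom, where, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      axiom = axiom, where = where, message = message, stringsAsFactors = FALSE)
  }
  internal <- names(tree@children)
  for (v in internal) {
    if (length(tree@children[[v]]) < 2) {
      add("O1", v, sprintf("internal vertex '%s' has out-degree %d",
                           v, length(tree@children[[v]])))
    }
  }
  xferHeads <- gt@transferEdges[, "head"]
  for (v in internal[ev[internal] == "T"]) {
    ch <- tree@children[[v]]
    nx <- sum(ch %in% xferHeads)
    if (nx == 0) add("O2", v, sprintf("transfer vertex '%s' has no transfer out-edge", v))
    if (nx == length(ch)) {
      add("O2", v, sprintf("transfer vertex '%s' has no non-transfer out-edge", v))
    }
  }
  idx <- gtIndex(gt)
  for (v in internal[ev[internal] == "S"]) {
    ch <- tree@children[[v]]
    ch <- ch[!(ch %in% xferHeads)]  # transfer children leave the component
    if (length(ch) < 2) next
    for (i in seq_len(length(ch) - 1)) {
      for (j in seq(i + 1, length(ch))) {
        ov <- intersect(idx$sigmaComp[[ch[i]]], idx$sigmaComp[[ch[j]]])
        if (length(ov)) {
          add("O3a", v, sprintf(
            "speciation '%s': children '%s' and '%s' share species %s",
            v, ch[i], ch[j], paste(ov, collapse = ",")))
        }
      }
    }
  }
  te <- gt@transferEdges
  for (k in seq_len(nrow(te))) {
    ov <- intersect(idx$sigmaComp[[te[k, 1]]], idx$sigmaComp[[te[k, 2]]])
    if (length(ov)) {
      add("O3b", paste0(te[k, 1], "->", te[k, 2]), sprintf(
        "transfer edge (%s,%s): endpoint species sets share %s",
        te[k, 1], te[k, 2], paste(ov, collapse = ",")))
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(axiom = character(0), where = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

# Per-gene-tree precomputation shared by the triplet extractor, the
# auxiliary graph and the solver: component membership in the transfer-free
# forest, leaves reachable without crossing a transfer edge, and the
# corresponding species sets.
gtIndex <- function(gt) {
  tree <- gt@tree
  xferHeads <- gt@transferEdges[, "head"]
  ord <- dfsOrder(tree)
  compOf <- character(length(tree@vertices))
  names(compOf) <- tree@vertices
  pm <- parentMap(tree)
  for (v in ord) {
    compOf[v] <- if (is.na(pm[[v]]) || v %in% xferHeads) v else compOf[[pm[[v]]]]
  }
  compLeaves <- vector("list", length(tree@vertices))  # L_{T_E-bar}(v)
  names(compLeaves) <- tree@vertices
  sigmaComp <- vector("list", length(tree@vertices))
  names(sigmaComp) <- tree@vertices
  for (v in rev(ord)) {
    ch <- tree@children[[v]]
    if (is.null(ch)) {
      compLeaves[[v]] <- v
    } else {
      keep <- ch[!(ch %in% xferHeads)]
      compLeaves[[v]] <- unlist(compLeaves[keep], use.names = FALSE)
    }
    sigmaComp[[v]] <- sort(unique(unname(gt@sigma[compLeaves[[v]]])))
  }
  list(order = ord, parent = pm, compOf = compOf,
       compLeaves = compLeaves, sigmaComp = sigmaComp)
}

#' Transfer-free forest
#'
#' The forest obtained from the gene tree by deleting its transfer edges.
#' Its component leaf sets partition the gene set; removing k transfer
#' edges yields exactly k+1 components.
#'
#' @param gt a \linkS4class{GeneTree}.
#' @return list with \code{components} (list of \linkS4class{RootedTree}),
#'   \code{componentOf} (named character: vertex id to component root id)
#'   and \code{componentRoots}.
#' @export
transferForest <- function(gt) {
  idx <- gtIndex(gt)
  roots <- unique(unname(idx$compOf))
  tree <- gt@tree
  xferHeads <- gt@transferEdges[, "head"]
  comps <- lapply(roots, function(r) {
    vs <- names(idx$compOf)[idx$compOf == r]
    children <- lapply(tree@children[intersect(names(tree@children), vs)],
                       function(ch) ch[!(ch %in% xferHeads)])
    children <- children[lengths(children) > 0]
    labels <- tree@labels[intersect(names(tree@labels), vs)]
    if (length(labels) == 0) stop("internal error: component without leaves")
    # a component root may have become out-degree <2 only through transfer
    # removal; the component is kept as-is (orders are preserved, not suppressed)
    newRootedTree(r, children, labels)
  })
  names(comps) <- roots
  list(components = comps, componentOf = idx$compOf, componentRoots = roots)
}

#' Species set of a vertex in the transfer-free forest
#'
#' The species of the leaves reachable from \code{v} without crossing a
#' transfer edge.  Never empty.
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param v a vertex id of the gene tree.
#' @return character vector of species.
#' @export
sigmaForest <- function(gt, v) {
  if (!(v %in% gt@tree@vertices)) stop("sigmaForest: unknown vertex: ", v)
  gtIndex(gt)$sigmaComp[[v]]
}
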