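# The LCA-map and the auxiliary timing digraph A(T,S), plus the maximal
# topological sort used to measure how much of it is already forced to be
# acyclic.  Gene vertices are namespaced "G:", species vertices "S:".

gv <- function(v) if (length(v)) paste0("G:", v) else character(0)
sv <- function(v) if (length(v)) paste0("S:", v) else character(0)

# ancestor chains for every vertex of S, root-last; reused for lca queries
speciesIndex <- function(S) {
  pm <- parentMap(S)
  ord <- dfsOrder(S)
  depth <- integer(length(ord)); names(depth) <- ord
  for (v in ord) depth[v] <- if (is.na(pm[[v]])) 0L else depth[[pm[[v]]]] + 1L
  anc <- lapply(ord, function(v) ancestorsOf(S, v, pm))
  names(anc) <- ord
  leafOf <- stats::setNames(names(S@labels), S@labels)  # species label -> leaf id
  list(parent = pm, order = ord, depth = depth, anc = anc, leafOf = leafOf)
}

# lca in S of a set of species labels, via ancestor-chain intersection
lcaSpecies <- function(sidx, speciesLabels) {
  ids <- sidx$leafOf[speciesLabels]
  if (anyNA(ids)) {
    stop("species not in species tree: ",
         paste(speciesLabels[is.na(ids)], collapse = ", "))
  }
  common <- sidx$anc[[ids[[1]]]]
  for (v in ids[-1]) common <- common[common %in% sidx$anc[[v]]]
  common[[1]]
}

#' LCA-map from gene-tree vertices to species-tree vertices
#'
#' Maps every gene-tree vertex to the lowest common ancestor in S of the
#' species reachable from it in the transfer-free forest.  Always exists
#' and is unique, whether or not any reconciliation exists; gene leaves map
#' to their own species.
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param S a \linkS4class{RootedTree} whose leaf labels include the
#'   species image of \code{gt}.
#' @return named character: gene vertex id to species vertex id.
#' @export
lcaMap <- function(gt, S) {
  missing <- setdiff(speciesImage(gt), S@labels)
  if (length(missing)) {
    stop("lcaMap: species missing from species tree: ",
         paste(missing, collapse = ", "))
  }
  idx <- gtIndex(gt)
  sidx <- speciesIndex(S)
  vapply(gt@tree@vertices, function(v) lcaSpecies(sidx, idx$sigmaComp[[v]]),
         character(1))
}

#' Build the auxiliary timing digraph
#'
#' Four edge classes: (A1) every gene-tree edge, with each endpoint
#' replaced by its LCA-map image when it is a leaf or speciation; (A2)
#' every species-tree edge; (A3) an edge from each duplication/transfer
#' vertex to its LCA-map image; (A4) for each transfer edge, an edge from
#' the lca of the two endpoint images down to the transfer vertex.
#' Parallel edges of different classes are retained; self-loops may arise.
#'
#' @inheritParams lcaMap
#' @return an \linkS4class{AuxGraph}.
#' @export
buildAuxGraph <- function(gt, S) {
  mu <- lcaMap(gt, S)
  sidx <- speciesIndex(S)
  ev <- gt@events
  pm <- parentMap(gt@tree)
  subst <- function(v) if (ev[[v]] %in% c("L", "S")) sv(mu[[v]]) else gv(v)

  tails <- character(0); heads <- character(0); cls <- character(0)
  # A1
  for (v in gt@tree@vertices) {
    p <- pm[[v]]
    if (is.na(p)) next
    tails <- c(tails, subst(p)); heads <- c(heads, subst(v)); cls <- c(cls, "A1")
  }
  # A2
  for (x in names(S@children)) {
    for (y in S@children[[x]]) {
      tails <- c(tails, sv(x)); heads <- c(heads, sv(y)); cls <- c(cls, "A2")
    }
  }
  # A3
  for (v in gt@tree@vertices[ev == "D" | ev == "T"]) {
    tails <- c(tails, gv(v)); heads <- c(heads, sv(mu[[v]])); cls <- c(cls, "A3")
  }
  # A4
  te <- gt@transferEdges
  for (k in seq_len(nrow(te))) {
    u <- te[k, 1]; v <- te[k, 2]
    top <- lcaSpecies2(sidx, mu[[u]], mu[[v]])
    tails <- c(tails, sv(top)); heads <- c(heads, gv(u)); cls <- c(cls, "A4")
  }
  vertices <- c(gv(gt@tree@vertices), sv(S@vertices))
  new("AuxGraph", vertices = vertices,
      edges = data.frame(tail = tails, head = heads, class = cls,
                         stringsAsFactors = FALSE))
}

# lca of two vertices of S (ids, not labels)
lcaSpecies2 <- function(sidx, x, y) {
  common <- sidx$anc[[x]][sidx$anc[[x]] %in% sidx$anc[[y]]]
  common[[1]]
}

#' Maximal topological sort
#'
#' Kahn-style peeling of in-degree-zero vertices.  Vertices carrying
#' self-loops never enter the sort.  The produced vertex set M(Q) does not
#' depend on tie-breaking; the sequence is made deterministic by peeling
#' species vertices before gene vertices and lexicographically within each
#' group.  The graph is acyclic iff every vertex is listed.
#'
#' @param G an \linkS4class{AuxGraph}.
#' @param order optional character vector giving a priority order over
#'   vertex ids (used by tests to show tie-break invariance).
#' @return list with \code{sequence} (character vector) and \code{members}
#'   (the set M(Q), equal to the sequence).
#' @export
maximalTopologicalSort <- function(G, order = NULL) {
  vs <- G@vertices
  if (is.null(order)) {
    grp <- ifelse(startsWith(vs, "S:"), 0L, 1L)
    order <- vs[base::order(grp, vs)]
  }
  e <- G@edges[G@edges$tail != G@edges$head, , drop = FALSE]  # self-loops block forever
  selfloop <- unique(G@edges$tail[G@edges$tail == G@edges$head])
  indeg <- table(factor(e$head, levels = vs))
  indeg <- stats::setNames(as.integer(indeg), vs)
  indeg[selfloop] <- indeg[selfloop] + 1L  # never reaches zero
  outAdj <- split(e$head, factor(e$tail, levels = vs))
  seqn <- character(0)
  avail <- order[indeg[order] == 0L]
  while (length(avail)) {
    v <- avail[[1]]
    avail <- avail[-1]
    seqn <- c(seqn, v)
    for (h in outAdj[[v]]) {
      indeg[h] <- indeg[h] - 1L
      if (indeg[h] == 0L) {
        # insert keeping priority order
        pos <- match(h, order)
        before <- vapply(avail, function(a) match(a, order) < pos, logical(1))
        avail <- append(avail, h, after = sum(before))
      }
    }
  }
  list(sequence = seqn, members = seqn)
}

#' @rdname maximalTopologicalSort
#' @export
isAcyclicAux <- function(G, Q = maximalTopologicalSort(G)) {
  length(Q$members) == length(G@vertices)
}

#' Species-leaf self-loop screen
#'
#' If a leaf of the species tree carries a self-loop in the auxiliary
#' graph, no refinement of S can remove it, so the instance can be
#' discarded immediately.  Returns TRUE when no species leaf has a
#' self-loop (i.e. the run may proceed).
#'
#' @inheritParams lcaMap
#' @export
leafSelfLoopScreen <- function(gt, S) {
  G <- buildAuxGraph(gt, S)
  loops <- G@edges$tail[G@edges$tail == G@edges$head]
  !any(loops %in% sv(treeLeaves(S)))
}

#' Dump an auxiliary graph in DOT format
#'
#' @param G an \linkS4class{AuxGraph}.
#' @param file path; "" prints to the console.
#' @export
auxGraphToDot <- function(G, file = "") {
  col <- c(A1 = "black", A2 = "steelblue", A3 = "darkorange", A4 = "firebrick")
  lines <- c("digraph aux {",
             sprintf('  "%s" -> "%s" [color=%s, label="%s"];',
                     G@edges$tail, G@edges$head, col[G@edges$class], G@edges$class),
             "}")
  writeLines(lines, con = file)
  invisible(lines)
}
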