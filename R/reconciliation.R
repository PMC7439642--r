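# Reconciliation maps and time maps.  Leaves and speciations map to species
# vertices; duplications and transfer origins map to species edges (the
# edge entering the image of their species set, or the conceptual planted
# edge above the root).  Time maps realize the embedding with explicit
# (purely ordinal, exact) time values; both objects come with independent
# checkers that re-verify every axiom literally.

#' Construct a reconciliation map
#'
#' Gene leaves map to their species and speciations to the lowest common
#' ancestor of their transfer-free species set.  A duplication or transfer
#' origin maps to a species edge on the root path above that lca: when the
#' auxiliary graph is acyclic, the edge whose topological-rank time
#' interval contains the vertex's own rank (this makes the map
#' time-consistent, and is the topological-order replacement for an
#' incremental construction); when it is cyclic, no time-consistent map
#' exists and the vertex is placed on the edge directly entering its lca,
#' which still yields a valid plain reconciliation whenever the species
#' tree displays the informative triplets.  The planted edge above the
#' species root is encoded with tail NA.
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param S a species tree; the caller should have established that S
#'   displays the informative triplets (e.g. via
#'   \code{\link{verifySolution}}).
#' @return data.frame with one row per gene vertex: \code{vertex},
#'   \code{event}, \code{type} ("vertex" or "edge"), \code{head} (species
#'   vertex; for an edge, its child endpoint) and \code{tail} (edge parent
#'   endpoint, NA for vertex images and for the planted edge).
#' @export
constructReconciliation <- function(gt, S) {
  mu <- lcaMap(gt, S)
  pmS <- parentMap(S)
  ev <- gt@events
  vs <- gt@tree@vertices
  G <- buildAuxGraph(gt, S)
  Q <- maximalTopologicalSort(G)
  acyclic <- length(Q$members) == length(G@vertices)
  rank <- stats::setNames(seq_along(Q$sequence), Q$sequence)

  type <- ifelse(ev[vs] %in% c("D", "T"), "edge", "vertex")
  head <- unname(mu[vs])
  tail <- rep(NA_character_, length(vs))
  for (i in which(type == "edge")) {
    z <- head[i]
    if (acyclic) {
      # climb while the vertex's time (rank) predates the parent end
      while (!is.na(pmS[[z]]) && rank[[gv(vs[i])]] < rank[[sv(pmS[[z]])]]) {
        z <- pmS[[z]]
      }
    }
    head[i] <- z
    tail[i] <- pmS[[z]]
  }
  data.frame(vertex = vs, event = unname(ev[vs]), type = type,
             head = head, tail = tail, stringsAsFactors = FALSE)
}

# --- image comparability helpers -------------------------------------------
# an image is a row of the reconciliation data.frame; the ancestor order of
# S is extended to edges: for an edge e=(u,v) and vertex x, x < e iff
# x <= v, and e < x iff u <= x; for edges e=(u,v), f=(a,b): e <= f iff v <= b.

leqS <- function(sidx, x, y) y %in% sidx$anc[[x]]

imgLt <- function(sidx, X, Y) {
  if (X$type == "vertex" && Y$type == "vertex") {
    return(X$head != Y$head && leqS(sidx, X$head, Y$head))
  }
  if (X$type == "vertex" && Y$type == "edge") {
    return(leqS(sidx, X$head, Y$head))
  }
  if (X$type == "edge" && Y$type == "vertex") {
    if (is.na(X$tail)) return(FALSE)  # planted edge lies above everything
    return(leqS(sidx, X$tail, Y$head))
  }
  X$head != Y$head && leqS(sidx, X$head, Y$head)
}

imgLeq <- function(sidx, X, Y) {
  if (X$type == Y$type && identical(X$head, Y$head)) return(TRUE)
  imgLt(sidx, X, Y)
}

imgComparable <- function(sidx, X, Y) {
  imgLeq(sidx, X, Y) || imgLeq(sidx, Y, X)
}

#' Check a reconciliation map against the axioms
#'
#' Re-verifies, literally and independently of the construction: the leaf
#' constraint (M1); the event constraints (M2): speciations at the lca of
#' their species set, duplications/transfers on edges, transfer-edge
#' endpoints incomparable, speciation children pairwise incomparable; and
#' the ancestor constraints (M3) along transfer-free paths.
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param S the species tree.
#' @param mu a reconciliation data.frame as returned by
#'   \code{\link{constructReconciliation}}.
#' @return data.frame of violations (\code{constraint}, \code{where},
#'   \code{message}); zero rows iff the map is valid.
#' @export
checkReconciliation <- function(gt, S, mu) {
  sidx <- speciesIndex(S)
  idx <- gtIndex(gt)
  ev <- gt@events
  rows <- split(mu, mu$vertex)
  img <- function(v) rows[[v]][1, , drop = FALSE]
  viol <- list()
  add <- function(constraint, where, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      constraint = constraint, where = where, message = message,
      stringsAsFactors = FALSE)
  }

  for (v in treeLeaves(gt@tree)) {
    X <- img(v)
    want <- sidx$leafOf[[gt@sigma[[v]]]]
    if (X$type != "vertex" || X$head != want) {
      add("M1", v, sprintf("leaf '%s' must map to species leaf '%s'",
                           gt@tree@labels[[v]], gt@sigma[[v]]))
    }
  }
  for (v in gt@tree@vertices) {
    X <- img(v)
    if (ev[[v]] == "S") {
      want <- lcaSpecies(sidx, idx$sigmaComp[[v]])
      if (X$type != "vertex" || X$head != want) {
        add("M2.i", v, sprintf("speciation '%s' must map to lca '%s'", v, want))
      }
    }
    if (ev[[v]] %in% c("D", "T") && X$type != "edge") {
      add("M2.ii", v, sprintf("'%s' (%s) must map to a species edge", v, ev[[v]]))
    }
  }
  te <- gt@transferEdges
  for (k in seq_len(nrow(te))) {
    if (imgComparable(sidx, img(te[k, 1]), img(te[k, 2]))) {
      add("M2.iii", paste0(te[k, 1], "->", te[k, 2]),
          "transfer edge endpoints map to comparable locations")
    }
  }
  for (v in gt@tree@vertices[ev == "S"]) {
    ch <- treeChildren(gt@tree, v)
    for (i in seq_len(length(ch) - 1)) {
      for (j in seq(i + 1, length(ch))) {
        if (imgComparable(sidx, img(ch[i]), img(ch[j]))) {
          add("M2.iv", v, sprintf(
            "children '%s','%s' of speciation '%s' map to comparable locations",
            ch[i], ch[j], v))
        }
      }
    }
  }
  # M3 over all strict ancestor pairs inside one component
  pm <- idx$parent
  for (x in gt@tree@vertices) {
    y <- pm[[x]]
    while (!is.na(y) && idx$compOf[[y]] == idx$compOf[[x]]) {
      both <- ev[[x]] %in% c("D", "T") && ev[[y]] %in% c("D", "T")
      ok <- if (both) imgLeq(sidx, img(x), img(y)) else imgLt(sidx, img(x), img(y))
      if (!ok) {
        add(if (both) "M3.i" else "M3.ii", paste0(x, "<", y),
            sprintf("ancestor constraint fails for '%s' below '%s'", x, y))
      }
      y <- pm[[y]]
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(constraint = character(0), where = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Construct time maps realizing a reconciliation
#'
#' Assigns exact integer time values, the topological ranks of the
#' auxiliary graph: every species vertex gets its own rank, every
#' duplication/transfer vertex gets its own rank, and every
#' leaf/speciation gets the rank of its species image.  Descendants then
#' carry strictly larger values along every gene-tree edge (transfer edges
#' included), and each edge-mapped vertex falls strictly inside the time
#' interval of the species edge chosen by
#' \code{\link{constructReconciliation}}.  Requires an acyclic auxiliary
#' graph; the result is re-verified with
#' \code{\link{checkTimeAssignment}} and any failure is reported as an
#' internal error.
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param S the species tree (auxiliary graph must be acyclic and S must
#'   display the informative triplets).
#' @param mu reconciliation as returned by
#'   \code{\link{constructReconciliation}}.
#' @return list with named numeric vectors \code{tauT} (gene vertices) and
#'   \code{tauS} (species vertices); larger = later (closer to the leaves).
#' @export
constructTimeAssignment <- function(gt, S, mu) {
  G <- buildAuxGraph(gt, S)
  Q <- maximalTopologicalSort(G)
  if (length(Q$members) != length(G@vertices)) {
    stop("constructTimeAssignment: auxiliary graph is cyclic; no time-consistent map exists")
  }
  ev <- gt@events
  lmap <- lcaMap(gt, S)
  rank <- stats::setNames(seq_along(Q$sequence), Q$sequence)
  tauS <- rank[sv(S@vertices)]
  names(tauS) <- S@vertices
  tauT <- vapply(gt@tree@vertices, function(v) {
    if (ev[[v]] %in% c("D", "T")) rank[[gv(v)]] else rank[[sv(lmap[[v]])]]
  }, numeric(1))
  tau <- list(tauT = tauT, tauS = tauS)
  bad <- checkTimeAssignment(gt, S, mu, tau)
  if (nrow(bad)) {
    stop("constructTimeAssignment: internal error: constructed assignment fails: ",
         paste(unique(bad$constraint), collapse = ", "))
  }
  tau
}

#' Check a time assignment
#'
#' Verifies that both maps are time maps (strict increase toward the
#' leaves, over all edges of the gene tree, transfer edges included) and
#' that the boundary conditions hold: leaves/speciations carry the time of
#' their species image (B1) and edge-mapped vertices lie strictly inside
#' their species edge's interval (B2).
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param S the species tree.
#' @param mu reconciliation data.frame.
#' @param tau list with \code{tauT}, \code{tauS} as returned by
#'   \code{\link{constructTimeAssignment}}.
#' @return data.frame of violations; zero rows iff valid.
#' @export
checkTimeAssignment <- function(gt, S, mu, tau) {
  viol <- list()
  add <- function(constraint, where, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      constraint = constraint, where = where, message = message,
      stringsAsFactors = FALSE)
  }
  tauT <- tau$tauT; tauS <- tau$tauS
  pmT <- parentMap(gt@tree)
  for (v in gt@tree@vertices) {
    p <- pmT[[v]]
    if (!is.na(p) && !(tauT[[v]] > tauT[[p]])) {
      add("timeMapT", paste0(p, "->", v), "gene time must increase toward the leaves")
    }
  }
  pmS <- parentMap(S)
  for (v in S@vertices) {
    p <- pmS[[v]]
    if (!is.na(p) && !(tauS[[v]] > tauS[[p]])) {
      add("timeMapS", paste0(p, "->", v), "species time must increase toward the leaves")
    }
  }
  ev <- gt@events
  for (i in seq_len(nrow(mu))) {
    v <- mu$vertex[i]
    if (mu$type[i] == "vertex") {
      if (ev[[v]] %in% c("L", "S") && tauT[[v]] != tauS[[mu$head[i]]]) {
        add("B1", v, "leaf/speciation time must equal its species image time")
      }
    } else {
      if (!(tauS[[mu$head[i]]] > tauT[[v]])) {
        add("B2", v, "edge-mapped vertex must predate the edge's child end")
      }
      if (!is.na(mu$tail[i]) && !(tauT[[v]] > tauS[[mu$tail[i]]])) {
        add("B2", v, "edge-mapped vertex must postdate the edge's parent end")
      }
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(constraint = character(0), where = character(0),
               message = character(0), stringsAsFactors = FALSE)
}
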