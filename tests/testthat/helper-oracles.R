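# Independent oracle implementations used to cross-check the package.  They
# deliberately share no code with the implementation beyond basic accessors:
# ancestor chains are recomputed from the parent map, triplet extraction is a
# literal scan over leaf triples and transfer edges, and acyclicity is
# delegated to igraph.

# ancestor chain (vertex to root) from a raw parent map
oraAncestors <- function(pm, v) {
  out <- v
  while (!is.na(pm[[v]])) {
    v <- pm[[v]]
    out <- c(out, v)
  }
  out
}

oraLca <- function(pm, vs) {
  common <- oraAncestors(pm, vs[[1]])
  for (v in vs[-1]) common <- common[common %in% oraAncestors(pm, v)]
  common[[1]]
}

# all triplets displayed by a rooted tree, by scanning every leaf triple
oraDisplayedTriplets <- function(tree) {
  pm <- parentMap(tree)
  ids <- treeLeaves(tree)
  out <- list()
  if (length(ids) >= 3) {
    for (tri in utils::combn(ids, 3, simplify = FALSE)) {
      for (k in 1:3) {
        pair <- tri[-k]
        if (oraLca(pm, pair) != oraLca(pm, tri)) {
          out[[length(out) + 1L]] <- c(tree@labels[[pair[1]]],
                                       tree@labels[[pair[2]]],
                                       tree@labels[[tri[k]]])
        }
      }
    }
  }
  if (length(out)) {
    m <- do.call(rbind, out)
    tripletSet(m[, 1], m[, 2], m[, 3])
  } else tripletSet()
}

# literal implementation of the informative-triplet definition: iterate over
# all leaf triples of each transfer-free component (clause 1) and over all
# transfer edges with all cross pairs of leaves (clause 2)
oraInformativeTriplets <- function(gt) {
  tree <- geneTreeOf(gt)
  sigma <- sigmaOf(gt)
  xferHeads <- transferEdgesOf(gt)[, "head"]
  pmFull <- parentMap(tree)
  # component membership: cut at transfer heads
  compOf <- vapply(tree@vertices, function(v) {
    chain <- oraAncestors(pmFull, v)
    cut <- which(chain %in% xferHeads)
    if (length(cut)) chain[[min(cut)]] else chain[[length(chain)]]
  }, character(1))
  # forest parent map: transfer heads become roots
  pmF <- pmFull
  pmF[xferHeads] <- NA
  out <- list()
  # clause 1
  for (r in unique(compOf)) {
    ids <- intersect(treeLeaves(tree), names(compOf)[compOf == r])
    if (length(ids) < 3) next
    for (tri in utils::combn(ids, 3, simplify = FALSE)) {
      sps <- unname(sigma[tri])
      if (anyDuplicated(sps)) next
      top <- oraLca(pmF, tri)
      if (eventsOf(gt)[[top]] != "S") next
      for (k in 1:3) {
        pair <- tri[-k]
        if (oraLca(pmF, pair) != top) {
          out[[length(out) + 1L]] <- c(sigma[[pair[1]]], sigma[[pair[2]]],
                                       sigma[[tri[k]]])
        }
      }
    }
  }
  # clause 2: leaves reachable below a vertex without crossing transfer edges
  below <- function(x) {
    lv <- treeLeaves(tree)
    lv[vapply(lv, function(l) {
      chain <- oraAncestors(pmF, l)
      x %in% chain
    }, logical(1))]
  }
  te <- transferEdgesOf(gt)
  for (k in seq_len(nrow(te))) {
    for (ori in 1:2) {
      X <- below(te[k, ori]); Y <- below(te[k, 3 - ori])
      if (length(X) < 2 || length(Y) < 1) next
      for (pr in utils::combn(X, 2, simplify = FALSE)) {
        for (y in Y) {
          sps <- c(sigma[[pr[1]]], sigma[[pr[2]]], sigma[[y]])
          if (anyDuplicated(sps)) next
          out[[length(out) + 1L]] <- sps
        }
      }
    }
  }
  if (length(out)) {
    m <- do.call(rbind, out)
    tripletSet(m[, 1], m[, 2], m[, 3])
  } else tripletSet()
}

# acyclicity of an AuxGraph through igraph (self-loops make it cyclic)
oraAcyclic <- function(G) {
  e <- G@edges
  if (any(e$tail == e$head)) return(FALSE)
  ig <- igraph::graph_from_data_frame(e[, c("tail", "head")], directed = TRUE,
                                      vertices = data.frame(name = G@vertices))
  igraph::is_dag(ig)
}

# brute-force GTC verdict: scan every binary species tree on the image
oraBruteSolvable <- function(gt) {
  R <- informativeTriplets(gt)
  trees <- allBinarySpeciesTrees(speciesImage(gt))
  any(vapply(trees, function(S) verifySolution(gt, S, R), logical(1)))
}

# random leaf-labeled tree (possibly multifurcating) over given labels
randomTree <- function(labels, pMultifurcate = 0.2) {
  labels <- sample(labels)
  nodes <- as.list(labels)
  while (length(nodes) > 1) {
    k <- if (length(nodes) > 2 && stats::runif(1) < pMultifurcate) 3 else 2
    pick <- sample(seq_along(nodes), k)
    merged <- list(nodes[pick])
    nodes <- c(nodes[-pick], merged)
  }
  flat <- function(x) if (!is.list(x)) x else
    paste0("(", paste(vapply(x, flat, character(1)), collapse = ","), ")")
  readNewick(paste0(flat(nodes[[1]]), ";"))
}

# small crafted gene trees used across test files
incompatibleToy <- function() {
  readGeneTree(paste0(
    "(((a1[&&NHX:S=A],b1[&&NHX:S=B])[&&NHX:ev=S],c1[&&NHX:S=C])[&&NHX:ev=S],",
    "((b2[&&NHX:S=B],c2[&&NHX:S=C])[&&NHX:ev=S],a2[&&NHX:S=A])[&&NHX:ev=S])",
    "[&&NHX:ev=D];"))
}

transferToy <- function() {
  readGeneTree(
    "((a[&&NHX:S=A],b[&&NHX:S=B])[&&NHX:ev=S],c[&&NHX:S=C:xfer=1])[&&NHX:ev=T];")
}

# a perturbed copy of a simulated instance: re-label one speciation as a
# duplication when this keeps the instance valid
perturbEvents <- function(gt) {
  ev <- eventsOf(gt)
  sp <- names(ev)[ev == "S"]
  if (length(sp) == 0) return(gt)
  ev[sample(sp, 1)] <- "D"
  cand <- tryCatch(
    newGeneTree(geneTreeOf(gt), ev[ev != "L"], transferEdgesOf(gt), sigmaOf(gt)),
    error = function(e) NULL)
  if (!is.null(cand) && nrow(validateObservability(cand)) == 0) cand else gt
}
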