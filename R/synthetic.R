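# Instance generation: a duplication-transfer-loss simulator along a known
# timed species tree (every output admits a time-consistent reconciliation
# by construction), a worked example instance, an exhaustive enumerator of
# binary species trees for brute-force validation, and a classic BUILD
# implementation for rooted-triplet compatibility.

#' Simulate a solvable gene-tree instance
#'
#' Draws an ultrametric binary species tree with strictly ordered
#' speciation times, then grows a gene tree inside it: along each branch,
#' duplications, transfers and losses occur at exponential waiting times;
#' a transfer copies the gene into a branch alive at the transfer time
#' (so a time-consistent embedding exists by construction), and losses
#' prune lineages.  The observable gene tree keeps a vertex only when at
#' least two of its descendant lines survive; a transfer contributes only
#' when both its vertical and its horizontal line leave sampled
#' descendants, otherwise the horizontal copy is treated as unsampled.
#' The output always satisfies the observability axioms, and the true
#' species tree (restricted to observed species) verifies as a solution.
#'
#' @param nSpecies number of species in the true tree (>= 2).
#' @param dupRate,transferRate,lossRate non-negative event rates per
#'   lineage per unit time (total tree height is 1).
#' @param seed integer seed; fixed seed gives a bit-identical instance.
#' @param maxTries resample attempts when all genes die out.
#' @return list with \code{geneTree} (a \linkS4class{GeneTree}),
#'   \code{speciesTree} (true tree restricted to the observed species) and
#'   \code{fullSpeciesTree}.
#' @examples
#' sim <- simulateInstance(6, dupRate = 0.3, transferRate = 0.3,
#'                         lossRate = 0.3, seed = 7)
#' nrow(validateObservability(sim$geneTree))
#' @export
simulateInstance <- function(nSpecies, dupRate = 0.3, transferRate = 0.3,
                             lossRate = 0.2, seed = 1, maxTries = 50) {
  stopifnot(nSpecies >= 2, dupRate >= 0, transferRate >= 0, lossRate >= 0)
  set.seed(seed)
  for (try in seq_len(maxTries)) {
    sp <- randomTimedSpeciesTree(nSpecies)
    sim <- tryCatch(growGeneTree(sp, dupRate, transferRate, lossRate),
                    simError = function(e) NULL)
    if (is.null(sim)) next
    obs <- observableTree(sim)
    if (is.null(obs)) next
    gt <- buildObservableGeneTree(obs, sp)
    if (is.null(gt)) next
    observed <- speciesImage(gt)
    st <- if (length(observed) >= 2) restrictTree(sp$tree, observed) else
      starTree(observed)
    return(list(geneTree = gt, speciesTree = st, fullSpeciesTree = sp$tree))
  }
  stop("simulateInstance: all lineages lost in every attempt; lower lossRate")
}

# ultrametric species tree: leaves at time 1, internal vertices at distinct
# times in (0,1); returns list(tree, time (named), parent)
randomTimedSpeciesTree <- function(n) {
  labels <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("S%03d", seq_len(n))
  ids <- paste0("s", seq_len(2 * n - 1))
  leafIds <- ids[seq_len(n)]
  time <- stats::setNames(rep(1, n), leafIds)
  mergeTimes <- sort(stats::runif(n - 1), decreasing = TRUE)
  active <- leafIds
  children <- list()
  for (k in seq_len(n - 1)) {
    pick <- sample(seq_along(active), 2)
    par <- ids[n + k]
    children[[par]] <- active[pick]
    time[par] <- mergeTimes[k]
    active <- c(active[-pick], par)
  }
  tree <- newRootedTree(active, children, stats::setNames(labels, leafIds))
  list(tree = tree, time = time, parent = parentMap(tree))
}

# Grow the full (unpruned) gene history.  Nodes are nested lists with
# fields kind ("leaf","loss","S","D","T"), species (branch end vertex),
# time, and children (for "T": children[[1]] vertical, children[[2]]
# horizontal).  Event budget guards against explosion.
growGeneTree <- function(sp, dupRate, transferRate, lossRate, budget = 4000) {
  count <- 0L
  tick <- function() {
    count <<- count + 1L
    if (count > budget) {
      stop(structure(class = c("simError", "error", "condition"),
                     list(message = "event budget exceeded", call = NULL)))
    }
  }
  total <- dupRate + transferRate + lossRate
  branchesAlive <- function(t) {
    vs <- sp$tree@vertices
    vs[!is.na(sp$parent[vs]) & sp$time[sp$parent[vs]] < t & t < sp$time[vs]]
  }
  lineage <- function(v, t0) {
    tick()
    tEnd <- sp$time[[v]]
    te <- if (total > 0) t0 + stats::rexp(1, total) else Inf
    if (te >= tEnd) {
      if (v %in% treeLeaves(sp$tree)) {
        return(list(kind = "leaf", species = v, time = tEnd))
      }
      kids <- lapply(treeChildren(sp$tree, v), lineage, t0 = tEnd)
      return(list(kind = "S", species = v, time = tEnd, children = kids))
    }
    what <- sample(c("D", "T", "loss"), 1,
                   prob = c(dupRate, transferRate, lossRate))
    if (what == "loss") return(list(kind = "loss", species = v, time = te))
    if (what == "D") {
      return(list(kind = "D", species = v, time = te,
                  children = list(lineage(v, te), lineage(v, te))))
    }
    recip <- setdiff(branchesAlive(te), v)
    if (length(recip) == 0) return(lineage(v, te))  # no coexisting branch
    r <- recip[[sample.int(length(recip), 1)]]
    list(kind = "T", species = v, time = te,
         children = list(lineage(v, te), lineage(r, te)))
  }
  root <- sp$tree@root
  list(kind = "S", species = root, time = sp$time[[root]],
       children = lapply(treeChildren(sp$tree, root), lineage,
                         t0 = sp$time[[root]]))
}

# Observability projection: NULL for extinct subtrees; suppresses
# single-descendant vertices; keeps a transfer vertex only when both sides
# survive (otherwise the horizontal copy is treated as unsampled).
observableTree <- function(node) {
  switch(node$kind,
    leaf = node,
    loss = NULL,
    S = ,
    D = {
      kids <- Filter(Negate(is.null), lapply(node$children, observableTree))
      if (length(kids) == 0) return(NULL)
      if (length(kids) == 1) return(kids[[1]])
      list(kind = node$kind, species = node$species, time = node$time,
           children = kids)
    },
    T = {
      vert <- observableTree(node$children[[1]])
      if (is.null(vert)) return(NULL)
      horiz <- observableTree(node$children[[2]])
      if (is.null(horiz)) return(vert)
      list(kind = "T", species = node$species, time = node$time,
           children = list(vert, horiz))
    })
}

# convert an observable simulation tree into a GeneTree
buildObservableGeneTree <- function(obs, sp) {
  counter <- 0L
  leafCount <- new.env(parent = emptyenv())
  children <- list(); events <- character(0)
  sigma <- character(0); xferHeads <- character(0)
  speciesLabel <- sp$tree@labels
  build <- function(node) {
    counter <<- counter + 1L
    id <- paste0("g", counter)
    if (node$kind == "leaf") {
      spl <- speciesLabel[[node$species]]
      k <- (get0(spl, envir = leafCount, ifnotfound = 0L)) + 1L
      assign(spl, k, envir = leafCount)
      sigma[id] <<- spl
      events[id] <<- "L"
      labels[id] <<- sprintf("%s_%d", spl, k)
      return(id)
    }
    events[id] <<- node$kind
    kids <- vapply(node$children, build, character(1))
    children[[id]] <<- kids
    if (node$kind == "T") xferHeads <<- c(xferHeads, kids[[2]])
    id
  }
  labels <- character(0)
  if (obs$kind == "leaf") return(NULL)  # single surviving gene: no instance
  root <- build(obs)
  tree <- newRootedTree(root, children, labels)
  pm <- parentMap(tree)
  newGeneTree(tree, events[setdiff(names(events), names(labels))],
              cbind(tail = pm[xferHeads], head = xferHeads), sigma)
}

#' Worked example instance
#'
#' A small gene tree over species A-D with three nested transfers, built so
#' that its informative triplets are exactly \{AB|D, AC|D\}.  The least
#' resolved species tree displaying them, ((A,B,C),D), admits a (unique)
#' reconciliation that is not time-consistent, while the binary refinement
#' (((A,B),C),D) is time-consistent; the solver reaches it from the star
#' tree in two good split refinements.  The fixture is stored as an NHX
#' file under \code{inst/extdata} (a synthetic construction, checked by the
#' test suite against all the properties above).
#'
#' @return list with \code{geneTree}, \code{leastResolvedTree} and
#'   \code{resolvedTree}.
#' @export
exampleGtcInstance <- function() {
  path <- system.file("extdata", "example-gene-tree.nhx", package = "gtctree")
  gt <- readGeneTree(paste(readLines(path), collapse = ""))
  list(geneTree = gt,
       leastResolvedTree = readNewick("((A,B,C),D);"),
       resolvedTree = readNewick("(((A,B),C),D);"))
}

#' Enumerate all rooted binary trees over a label set
#'
#' Every leaf-labeled rooted binary shape exactly once; there are
#' (2n-3)!! of them, so the label set is capped at seven.
#'
#' @param species character vector of 1 to 7 distinct labels.
#' @return list of \linkS4class{RootedTree}.
#' @export
allBinarySpeciesTrees <- function(species) {
  species <- sort(unique(species))
  n <- length(species)
  if (n < 1 || n > 7) stop("allBinarySpeciesTrees: need between 1 and 7 species")
  shapes <- list(species[[1]])
  for (k in seq_len(n)[-1]) {
    x <- species[[k]]
    insertAll <- function(t) {
      res <- list(list(t, x))
      if (is.list(t)) {
        res <- c(res,
                 lapply(insertAll(t[[1]]), function(l) list(l, t[[2]])),
                 lapply(insertAll(t[[2]]), function(r) list(t[[1]], r)))
      }
      res
    }
    shapes <- do.call(c, lapply(shapes, insertAll))
  }
  toNewick <- function(t) {
    if (!is.list(t)) return(t)
    paste0("(", toNewick(t[[1]]), ",", toNewick(t[[2]]), ")")
  }
  lapply(shapes, function(t) readNewick(paste0(toNewick(t), ";")))
}

#' BUILD compatibility test for rooted triplets
#'
#' The classic recursive construction: on each label set, connect the
#' cherry pair of every triplet whose three labels are all present, and
#' recurse into the connected components; a non-trivial label set whose
#' graph is connected makes the triplet set incompatible.
#'
#' @param R a triplet set (see \code{\link{tripletSet}}).
#' @param labels the label universe.
#' @return a \linkS4class{RootedTree} displaying \code{R}, or NULL when
#'   \code{R} is incompatible.
#' @export
ahoBuild <- function(R, labels) {
  labels <- sort(unique(labels))
  rec <- function(labs, R) {
    if (length(labs) == 1) return(labs)
    sub <- R[R$a %in% labs & R$b %in% labs & R$c %in% labs, , drop = FALSE]
    comp <- stats::setNames(seq_along(labs), labs)
    for (i in seq_len(nrow(sub))) {
      ca <- comp[[sub$a[i]]]; cb <- comp[[sub$b[i]]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    parts <- split(labs, comp[labs])
    if (length(parts) == 1) return(NULL)
    subtrees <- character(0)
    for (p in parts) {
      s <- rec(p, sub)
      if (is.null(s)) return(NULL)
      subtrees <- c(subtrees, s)
    }
    paste0("(", paste(subtrees, collapse = ","), ")")
  }
  out <- rec(labels, R)
  if (is.null(out)) return(NULL)
  readNewick(paste0(out, ";"))
}
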