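# The gene tree consistency (GTC) solver: starting from a star (or a given
# almost binary) species tree, apply good split refinements until the tree
# is binary, then verify.  Each iteration adds exactly one binary internal
# vertex, so the loop runs at most |Sigma| - 2 times.

#' Verify a candidate species tree
#'
#' A species tree is a solution for the gene tree precisely when it
#' displays every informative triplet and the auxiliary timing digraph is
#' acyclic (then, and only then, a time-consistent reconciliation exists).
#'
#' @param gt a \linkS4class{GeneTree}.
#' @param S a \linkS4class{RootedTree} whose leaves include the species
#'   image of \code{gt}.
#' @param R informative triplets, recomputed when NULL (pass them when
#'   verifying many candidate trees for one gene tree).
#' @return TRUE or FALSE.
#' @export
verifySolution <- function(gt, S, R = NULL) {
  missing <- setdiff(speciesImage(gt), S@labels)
  if (length(missing)) {
    stop("verifySolution: species missing from species tree: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(R)) R <- informativeTriplets(gt)
  if (!displaysTriplets(S, R)) return(FALSE)
  isAcyclicAux(buildAuxGraph(gt, S))
}

#' Solve the gene tree consistency problem
#'
#' Decides whether some refinement of the given almost binary species tree
#' (default: the star tree over the observed species) displays all
#' informative triplets of the gene tree and admits an acyclic auxiliary
#' graph, i.e. whether a time-consistent species tree exists; constructs a
#' binary one in the affirmative case by iterated good split refinements.
#'
#' @param gt a \linkS4class{GeneTree} satisfying the observability axioms
#'   (violations are a usage error).
#' @param S optional almost binary species tree over exactly the species
#'   image of \code{gt}; defaults to the star tree.
#' @return list with elements \code{status} ("solved" or "no_solution"),
#'   \code{speciesTree} (binary \linkS4class{RootedTree} or NULL),
#'   \code{triplets} (the informative triplets used), \code{trace} (one
#'   row per applied refinement: cherry and the two species groups) and
#'   \code{reason} (diagnostic string for "no_solution").
#' @examples
#' ex <- exampleGtcInstance()
#' res <- solveGtc(ex$geneTree)
#' res$status
#' writeNewick(res$speciesTree)
#' @export
solveGtc <- function(gt, S = NULL) {
  viol <- validateObservability(gt)
  if (nrow(viol)) {
    stop("solveGtc: gene tree violates observability axioms: ",
         paste(viol$axiom, collapse = ", "))
  }
  sp <- speciesImage(gt)
  if (is.null(S)) S <- starTree(sp)
  if (!setequal(S@labels, sp)) {
    stop("solveGtc: species tree leaves must equal the species image of the gene tree")
  }
  if (!isAlmostBinaryTree(S)) {
    stop("solveGtc: species tree must be almost binary")
  }
  R <- informativeTriplets(gt)
  trace <- list()
  fail <- function(reason) list(status = "no_solution", speciesTree = NULL,
                                triplets = R, trace = trace, reason = reason)

  # Screen: a self-loop at a species leaf survives every refinement.
  if (!leafSelfLoopScreen(gt, S)) {
    return(fail("self-loop at a species leaf in the auxiliary graph"))
  }
  # Running hypothesis for the good-split search: S agrees with R.
  dis <- firstDisagreement(S, R)
  if (!is.null(dis)) {
    return(fail(sprintf("species tree contradicts informative triplet %s,%s|%s",
                        dis$a, dis$b, dis$c)))
  }

  iter <- 0L
  maxIter <- max(0L, length(sp) - 2L)
  while (!isBinaryTree(S)) {
    step <- findGoodSplit(gt, S, R)
    if (is.null(step)) {
      return(fail("no good split refinement exists"))
    }
    S2 <- applySplitRefinement(S, step$cherry, step$A, step$B)
    trace[[length(trace) + 1L]] <- data.frame(
      cherry = step$cherry,
      sideA = paste(sort(unname(S@labels[step$A])), collapse = ","),
      sideB = paste(sort(unname(S@labels[step$B])), collapse = ","),
      stringsAsFactors = FALSE)
    S <- S2
    iter <- iter + 1L
    if (iter > maxIter) stop("solveGtc: internal error: refinement loop overran")
  }
  if (!verifySolution(gt, S, R)) {
    return(fail("binary refinement reached but not time-consistent"))
  }
  list(status = "solved", speciesTree = S, triplets = R,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(cherry = character(0), sideA = character(0),
                    sideB = character(0), stringsAsFactors = FALSE),
       reason = NULL)
}
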