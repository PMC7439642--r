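# Informative species triplets: the necessary-and-sufficient data a species
# tree must display for the gene tree to be reconcilable at all.  Two
# sources: speciation vertices of the transfer-free forest, and the two
# sides of each transfer edge.  Extraction works at species-set level per
# vertex, which enumerates exactly the same set as a literal scan over leaf
# triples (tests check this against a brute-force oracle).

# all ordered (pair, outgroup) species triplets from pair-species set P and
# outgroup set C
crossTriplets <- function(P, C) {
  if (length(P) < 2 || length(C) == 0) {
    return(tripletSet())
  }
  prs <- utils::combn(sort(P), 2)
  k <- ncol(prs); m <- length(C)
  a <- rep(prs[1, ], times = m)
  b <- rep(prs[2, ], times = m)
  c <- rep(C, each = k)
  keep <- c != a & c != b
  tripletSet(a[keep], b[keep], c[keep])
}

#' Informative species triplets
#'
#' \code{speciationTriplets} collects the triplets
#' \eqn{\sigma(a)\sigma(b)|\sigma(c)} (species pairwise distinct) where
#' ab|c is displayed by one component of the transfer-free forest and the
#' component-lca of a, b, c is a speciation.  \code{transferTriplets}
#' collects those where a, b sit below one endpoint of a transfer edge and
#' c below the other (either orientation), inside the transfer-free forest.
#' \code{informativeTriplets} is their deduplicated union.
#'
#' @param gt a \linkS4class{GeneTree} that passes
#'   \code{\link{validateObservability}}.
#' @return a triplet set over species labels (see \code{\link{tripletSet}}).
#' @export
speciationTriplets <- function(gt) {
  idx <- gtIndex(gt)
  xferHeads <- gt@transferEdges[, "head"]
  out <- list(tripletSet())
  ev <- gt@events
  for (v in names(gt@tree@children)) {
    if (ev[[v]] != "S") next
    ch <- gt@tree@children[[v]]
    ch <- ch[!(ch %in% xferHeads)]  # stay inside v's component
    if (length(ch) < 2) next
    for (i in seq_along(ch)) {
      P <- idx$sigmaComp[[ch[i]]]
      if (length(P) < 2) next
      C <- unique(unlist(idx$sigmaComp[ch[-i]], use.names = FALSE))
      out[[length(out) + 1L]] <- crossTriplets(P, C)
    }
  }
  Reduce(tripletUnion, out)
}

#' @rdname speciationTriplets
#' @export
transferTriplets <- function(gt) {
  te <- gt@transferEdges
  idx <- gtIndex(gt)
  out <- list(tripletSet())
  for (k in seq_len(nrow(te))) {
    Sx <- idx$sigmaComp[[te[k, 1]]]
    Sy <- idx$sigmaComp[[te[k, 2]]]
    out[[length(out) + 1L]] <- crossTriplets(Sx, Sy)
    out[[length(out) + 1L]] <- crossTriplets(Sy, Sx)
  }
  Reduce(tripletUnion, out)
}

#' @rdname speciationTriplets
#' @export
informativeTriplets <- function(gt) {
  tripletUnion(speciationTriplets(gt), transferTriplets(gt))
}

#' Format / parse triplets as text lines
#'
#' One triplet per line in the form \code{"A,B|C"}.
#'
#' @param R a triplet set.
#' @export
formatTriplets <- function(R) {
  sprintf("%s,%s|%s", R$a, R$b, R$c)
}
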