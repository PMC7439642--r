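# Rooted triplets ab|c as a plain data.frame with columns a, b, c, where
# {a,b} is the cherry pair (stored with a < b) and c the outgroup.  Set
# semantics throughout: ab|c and ba|c are the same triplet.

#' Build a normalized triplet set
#'
#' @param a,b,c equal-length character vectors; row i encodes the triplet
#'   \code{a[i] b[i] | c[i]}.
#' @return data.frame with columns \code{a}, \code{b}, \code{c}; pair
#'   normalized lexicographically, duplicates removed.
#' @export
tripletSet <- function(a = character(0), b = character(0), c = character(0)) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  df <- unique(data.frame(a = lo, b = hi, c = c, stringsAsFactors = FALSE))
  df <- df[order(df$a, df$b, df$c), , drop = FALSE]
  rownames(df) <- NULL
  df
}

tripletKeys <- function(R) paste(R$a, R$b, R$c, sep = "\r")

#' @rdname tripletSet
#' @param R1,R2 triplet sets.
#' @export
tripletUnion <- function(R1, R2) {
  tripletSet(c(R1$a, R2$a), c(R1$b, R2$b), c(R1$c, R2$c))
}

#' @rdname tripletSet
#' @export
sameTripletSet <- function(R1, R2) {
  setequal(tripletKeys(R1), tripletKeys(R2))
}

#' Triplets displayed by a tree or forest
#'
#' A tree displays ab|c when the lowest common ancestor of a and b lies
#' strictly below that of a, b and c.  For a forest (list of trees), a
#' triplet must be displayed inside a single component.  A star tree
#' displays no triplet.
#'
#' @param x a \linkS4class{RootedTree} or a list of them.
#' @return a triplet set (see \code{\link{tripletSet}}) over leaf labels.
#' @export
displayedTriplets <- function(x) {
  if (is(x, "RootedTree")) x <- list(x)
  A <- character(0); B <- character(0); C <- character(0)
  for (tree in x) {
    lb <- leavesBelow(tree)
    for (v in names(tree@children)) {
      ch <- tree@children[[v]]
      if (length(ch) < 2) next
      for (i in seq_along(ch)) {
        Pi <- lb[[ch[i]]]
        if (length(Pi) < 2) next
        prs <- utils::combn(Pi, 2)
        rest <- unlist(lb[ch[-i]], use.names = FALSE)
        k <- ncol(prs); m <- length(rest)
        A <- c(A, rep(prs[1, ], times = m))
        B <- c(B, rep(prs[2, ], times = m))
        C <- c(C, rep(rest, each = k))
      }
    }
  }
  tripletSet(A, B, C)
}

# is ab|c displayed? (labels; all three must be in the tree)
displaysOne <- function(tree, a, b, c, pm = parentMap(tree)) {
  ia <- names(tree@labels)[match(a, tree@labels)]
  ib <- names(tree@labels)[match(b, tree@labels)]
  ic <- names(tree@labels)[match(c, tree@labels)]
  anc_a <- ancestorsOf(tree, ia, pm)
  anc_b <- ancestorsOf(tree, ib, pm)
  anc_c <- ancestorsOf(tree, ic, pm)
  lab_ab <- (anc_a[anc_a %in% anc_b])[1]
  lab_abc <- (anc_a[anc_a %in% anc_b & anc_a %in% anc_c])[1]
  lab_ab != lab_abc
}

#' Does a tree display / agree with a triplet set?
#'
#' \code{displaysTriplets} checks that every triplet of \code{R} is
#' displayed.  \code{agreesWith} is weaker: for every ab|c in \code{R},
#' neither of the contradicting triplets ac|b, bc|a may be displayed (a
#' star tree therefore agrees with any triplet set over its leaves).
#'
#' @param tree a \linkS4class{RootedTree} containing all labels of \code{R}.
#' @param R a triplet set.
#' @export
displaysTriplets <- function(tree, R) {
  checkTripletLabels(tree, R)
  pm <- parentMap(tree)
  if (nrow(R) == 0) return(TRUE)
  all(vapply(seq_len(nrow(R)), function(i) {
    displaysOne(tree, R$a[i], R$b[i], R$c[i], pm)
  }, logical(1)))
}

#' @rdname displaysTriplets
#' @export
agreesWith <- function(tree, R) {
  checkTripletLabels(tree, R)
  is.null(firstDisagreement(tree, R))
}

# first triplet of R contradicted by the tree, or NULL; used for reporting
firstDisagreement <- function(tree, R) {
  pm <- parentMap(tree)
  for (i in seq_len(nrow(R))) {
    a <- R$a[i]; b <- R$b[i]; c <- R$c[i]
    if (displaysOne(tree, a, c, b, pm) || displaysOne(tree, b, c, a, pm)) {
      return(R[i, , drop = FALSE])
    }
  }
  NULL
}

checkTripletLabels <- function(tree, R) {
  labs <- unique(c(R$a, R$b, R$c))
  missing <- setdiff(labs, tree@labels)
  if (length(missing)) {
    stop("triplet label(s) not in tree: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
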