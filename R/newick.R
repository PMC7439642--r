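# Newick reading/writing.  The reader handles plain Newick plus NHX-style
# square-bracket annotations ("[&&NHX:key=value:...]"), which are attached
# to the preceding vertex and returned alongside the tree; branch lengths
# are parsed and discarded.  Hand-rolled because no installed reader keeps
# NHX tags.

# tokenizing parser; returns list(tree = RootedTree, annots = named list of
# named character vectors, one per vertex id)
parseNewick <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("Newick parse error: empty input")
  if (substring(s, nchar(s)) != ";") stop("Newick parse error: missing ';'")
  s <- substring(s, 1, nchar(s) - 1L)
  n <- nchar(s)
  pos <- 1L
  counter <- 0L
  children <- list()
  labels <- character(0)
  annots <- list()

  peek <- function() if (pos <= n) substring(s, pos, pos) else ""
  fail <- function(why) stop(sprintf("Newick parse error at position %d: %s", pos, why))

  readName <- function() {
    start <- pos
    while (pos <= n && !(substring(s, pos, pos) %in% c("(", ")", ",", ":", "[", ";"))) {
      pos <<- pos + 1L
    }
    substring(s, start, pos - 1L)
  }

  readAnnot <- function() {
    # one or more [...] blocks; only NHX blocks are interpreted
    out <- character(0)
    while (peek() == "[") {
      close <- regexpr("]", substring(s, pos), fixed = TRUE)
      if (close < 0) fail("unterminated '['")
      block <- substring(s, pos + 1L, pos + close - 2L)
      pos <<- pos + close
      if (startsWith(block, "&&NHX")) {
        body <- sub("^&&NHX:?", "", block)
        if (nzchar(body)) {
          for (kv in strsplit(body, ":", fixed = TRUE)[[1]]) {
            eq <- regexpr("=", kv, fixed = TRUE)
            if (eq < 0) fail(sprintf("malformed NHX tag '%s'", kv))
            out[substring(kv, 1, eq - 1L)] <- substring(kv, eq + 1L)
          }
        }
      }
    }
    out
  }

  skipLength <- function() {
    if (peek() == ":") {
      pos <<- pos + 1L
      start <- pos
      while (pos <= n && grepl("[0-9eE.+-]", substring(s, pos, pos))) pos <<- pos + 1L
      if (pos == start) fail("expected branch length after ':'")
    }
  }

  node <- function() {
    counter <<- counter + 1L
    id <- paste0("v", counter - 1L)
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- character(0)
      repeat {
        kids <- c(kids, node())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      children[[id]] <<- kids
      readName()  # internal vertex names are accepted and ignored
      a <- readAnnot()
      skipLength()
      a2 <- readAnnot()
      annots[[id]] <<- c(a, a2)
      id
    } else {
      nm <- readName()
      if (!nzchar(nm)) fail("leaf without a label")
      labels[id] <<- nm
      a <- readAnnot()
      skipLength()
      a2 <- readAnnot()
      annots[[id]] <<- c(a, a2)
      id
    }
  }

  root <- node()
  if (pos <= n) fail("trailing characters")
  if (anyDuplicated(labels)) {
    stop("Newick parse error: duplicate leaf labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  tree <- newRootedTree(root, children, labels)
  list(tree = tree, annots = annots)
}

#' Read and write plain Newick
#'
#' \code{readNewick} parses a single rooted Newick string (branch lengths
#' and square-bracket comments are accepted and ignored); internal vertex
#' ids are assigned deterministically in depth-first file order.
#' \code{writeNewick} emits canonical Newick (children sorted by smallest
#' descendant label), so \code{readNewick(writeNewick(t))} is isomorphic to
#' \code{t}.
#'
#' @param text a Newick string ending in ";".
#' @param tree a \linkS4class{RootedTree}.
#' @return \code{readNewick}: a \linkS4class{RootedTree};
#'   \code{writeNewick}: a character scalar.
#' @examples
#' writeNewick(readNewick("((A,B),C);"))
#' @export
readNewick <- function(text) parseNewick(text)$tree

#' @rdname readNewick
#' @export
writeNewick <- function(tree) {
  rec <- function(v) {
    ch <- tree@children[[v]]
    if (is.null(ch)) return(tree@labels[[v]])
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")")
  }
  paste0(rec(tree@root), ";")
}
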