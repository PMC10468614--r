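#' Parse a Newick phylogeny with mandatory branch lengths
#'
#' Reads a Newick string into an \pkg{ape} \code{phylo} object and validates
#' the invariants the Brownian-motion machinery relies on: a single root,
#' branch lengths on every edge (the BM fit needs elapsed time), nonnegative
#' lengths, and unique tip labels.
#'
#' @param text A Newick string (may contain a trailing newline).
#' @return A rooted \code{phylo} object.
#' @examples
#' tr <- parse_phylogeny("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_phylogeny <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("malformed Newick: parser returned no tree", call. = FALSE)
  validate_phylogeny(tr)
  tr
}

#' Validate a phylogeny for rate fitting
#'
#' @param tr A \code{phylo} object.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths; BM rate estimation needs elapsed time on every edge",
         call. = FALSE)
  }
  if (anyNA(tr$edge.length)) stop("tree has NA branch lengths", call. = FALSE)
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(tr)
}

#' Prune a tree to a set of tips
#'
#' Thin wrapper over \code{ape::keep.tip} that keeps original branch lengths
#' and errors when fewer than two of the requested tips are present.
#'
#' @param tr A \code{phylo} object.
#' @param tips Character vector of tip labels to keep.
#' @return The induced subtree rooted at the MRCA of \code{tips}.
#' @export
prune_to_tips <- function(tr, tips) {
  keep <- intersect(tr$tip.label, tips)
  if (length(keep) < 2L) {
    stop("fewer than 2 requested tips present in tree", call. = FALSE)
  }
  ape::keep.tip(tr, keep)
}
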