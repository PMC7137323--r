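#' Protein identifiers of an object
#'
#' @param x a \linkS4class{PpiNetwork}, \linkS4class{AnnotationTable},
#'   \linkS4class{RelationTensor}, \linkS4class{JumpVector} or
#'   \linkS4class{HeptResult}.
#' @return character vector of protein identifiers (for annotation tables,
#'   the distinct proteins occurring in the pair set).
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' Number of proteins in an object's index
#'
#' @param x an object with a protein index.
#' @return integer scalar n.
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname proteinIds
#' @export
setMethod("proteinIds", "PpiNetwork", function(x) x@proteins)
#' @rdname proteinIds
#' @export
setMethod("proteinIds", "RelationTensor", function(x) x@proteins)
#' @rdname proteinIds
#' @export
setMethod("proteinIds", "JumpVector", function(x) x@proteins)
#' @rdname proteinIds
#' @export
setMethod("proteinIds", "HeptResult", function(x) x@proteins)
#' @rdname proteinIds
#' @export
setMethod("proteinIds", "AnnotationTable",
  function(x) unique(x@pairs$protein))

#' @rdname nProteins
#' @export
setMethod("nProteins", "PpiNetwork", function(x) length(x@proteins))
#' @rdname nProteins
#' @export
setMethod("nProteins", "RelationTensor", function(x) length(x@proteins))
#' @rdname nProteins
#' @export
setMethod("nProteins", "JumpVector", function(x) length(x@proteins))
#' @rdname nProteins
#' @export
setMethod("nProteins", "HeptResult", function(x) length(x@proteins))

#' Edge set of a PPI network
#'
#' @param x a \linkS4class{PpiNetwork}.
#' @param ids logical; if \code{TRUE} return a two-column character matrix of
#'   identifiers, otherwise the integer index matrix.
#' @return two-column matrix, one undirected edge per row (i < j).
#' @export
networkEdges <- function(x, ids = FALSE) {
  stopifnot(is(x, "PpiNetwork"))
  if (!ids) return(x@edges)
  cbind(x@proteins[x@edges[, 1L]], x@proteins[x@edges[, 2L]])
}

#' Sparse adjacency matrix of a PPI network
#'
#' @param x a \linkS4class{PpiNetwork}.
#' @return symmetric n x n \code{dgCMatrix} of 0/1 weights with empty
#'   diagonal, rows/columns named by protein identifier.
#' @export
adjacencyMatrix <- function(x) {
  stopifnot(is(x, "PpiNetwork"))
  n <- length(x@proteins)
  e <- x@edges
  A <- Matrix::sparseMatrix(
    i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
    x = rep.int(1, 2L * nrow(e)), dims = c(n, n),
    dimnames = list(x@proteins, x@proteins))
  methods::as(A, "CsparseMatrix")
}

#' Annotation pair set and term universe
#'
#' \code{annotationPairs} returns the deduplicated (protein, term) pairs;
#' \code{termUniverse} the distinct term identifiers;
#' \code{annotationKind} the table's kind.
#'
#' @param x an \linkS4class{AnnotationTable}.
#' @return \code{annotationPairs}: data.frame with columns \code{protein},
#'   \code{term}; \code{termUniverse}: character vector;
#'   \code{annotationKind}: character scalar.
#' @export
annotationPairs <- function(x) {
  stopifnot(is(x, "AnnotationTable"))
  x@pairs
}

#' @rdname annotationPairs
#' @export
termUniverse <- function(x) {
  stopifnot(is(x, "AnnotationTable"))
  unique(x@pairs$term)
}

#' @rdname annotationPairs
#' @export
annotationKind <- function(x) {
  stopifnot(is(x, "AnnotationTable"))
  x@kind
}

#' Relation slices of a tensor
#'
#' @param x a \linkS4class{RelationTensor}.
#' @return named list of sparse symmetric n x n slice matrices, in the fixed
#'   slice order used by the edge-type importance vector VE.
#' @export
tensorSlices <- function(x) {
  stopifnot(is(x, "RelationTensor"))
  x@slices
}

#' @rdname tensorSlices
#' @export
sliceNames <- function(x) {
  stopifnot(is(x, "RelationTensor"))
  names(x@slices)
}

#' Number of relation slices (m)
#'
#' @param x a \linkS4class{RelationTensor}.
#' @return integer scalar m.
#' @export
nSlices <- function(x) {
  stopifnot(is(x, "RelationTensor"))
  length(x@slices)
}

#' Restart weights of a jump vector
#'
#' @param x a \linkS4class{JumpVector}.
#' @return named numeric vector d of length n.
#' @export
jumpWeights <- function(x) {
  stopifnot(is(x, "JumpVector"))
  stats::setNames(x@d, x@proteins)
}

#' Score vectors of a HEPT result
#'
#' \code{authorityScores} returns VA (the ranking score),
#' \code{hubScores} VH, and \code{edgeTypeScores} VE (one importance weight
#' per relation slice).
#'
#' @param x a \linkS4class{HeptResult}.
#' @return named numeric vector.
#' @export
authorityScores <- function(x) {
  stopifnot(is(x, "HeptResult"))
  stats::setNames(x@VA, x@proteins)
}

#' @rdname authorityScores
#' @export
hubScores <- function(x) {
  stopifnot(is(x, "HeptResult"))
  stats::setNames(x@VH, x@proteins)
}

#' @rdname authorityScores
#' @export
edgeTypeScores <- function(x) {
  stopifnot(is(x, "HeptResult"))
  x@VE
}

setMethod("show", "PpiNetwork", function(object) {
  cat(sprintf("PpiNetwork with %d proteins and %d undirected edges\n",
    length(object@proteins), nrow(object@edges)))
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable (kind = %s): %d pairs, %d proteins, %d terms\n",
    object@kind, nrow(object@pairs), length(unique(object@pairs$protein)),
    length(unique(object@pairs$term))))
})

setMethod("show", "RelationTensor", function(object) {
  n <- length(object@proteins)
  cat(sprintf("RelationTensor: %d proteins, %d slices\n", n,
    length(object@slices)))
  for (k in seq_along(object@slices)) {
    s <- object@slices[[k]]
    cat(sprintf("  [%d] %-14s %d nonzero pairs\n", k,
      names(object@slices)[k], length(s@x) %/% 2L))
  }
})

setMethod("show", "JumpVector", function(object) {
  cat(sprintf(
    "JumpVector over %d proteins (%s; %d proteins with positive weight)\n",
    length(object@proteins),
    if (object@normalized) "L1-normalized" else "unnormalized",
    sum(object@d > 0)))
})

setMethod("show", "HeptResult", function(object) {
  cat(sprintf("HeptResult: %d proteins, %d edge types\n",
    length(object@proteins), length(object@VE)))
  cat(sprintf("  %s after %d iterations (final L1 change %.3g)\n",
    if (object@converged) "converged" else "NOT converged",
    object@iterations, object@finalChange))
  cat(sprintf("  alpha = %.3g, epsilon = %.3g\n", object@alpha,
    object@epsilon))
  ve <- format(signif(object@VE, 4))
  cat("  edge-type importance:",
    paste(sprintf("%s = %s", names(object@VE), ve), collapse = ", "), "\n")
})
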