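#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Undirected protein-protein interaction network
#'
#' Holds the protein index (an ordered vector of unique identifiers defining
#' the dense integer indexing used throughout the package) together with the
#' deduplicated, self-loop-free undirected edge set.
#'
#' @slot proteins character vector of unique, non-empty protein identifiers;
#'   protein \code{i} of every vector/matrix in the package refers to
#'   \code{proteins[i]}.
#' @slot edges two-column integer matrix of undirected edges, stored with
#'   \code{edges[, 1] < edges[, 2]}; no self-loops, no duplicates.
#'
#' @seealso [readPpiEdges()], [adjacencyMatrix()], [degreeCentralityBaseline()]
#' @export
setClass("PpiNetwork",
  representation(proteins = "character", edges = "matrix"))

setValidity("PpiNetwork", function(object) {
  p <- object@proteins
  e <- object@edges
  msg <- character()
  if (length(p) < 1L) msg <- c(msg, "at least one protein is required")
  if (anyDuplicated(p)) msg <- c(msg, "protein identifiers must be unique")
  if (any(!nzchar(p))) msg <- c(msg, "protein identifiers must be non-empty")
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (!is.numeric(e)) msg <- c(msg, "edges must be integer indices")
    else {
      if (any(e < 1L) || any(e > length(p)))
        msg <- c(msg, "edge indices out of range")
      if (any(e[, 1L] >= e[, 2L]))
        msg <- c(msg, "edges must satisfy i < j (no self-loops, canonical order)")
      if (anyDuplicated(e))
        msg <- c(msg, "duplicate edges are not allowed")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Protein annotation table
#'
#' A deduplicated set of (protein, term) pairs of a single annotation kind:
#' protein domains (Pfam-style), GO terms, or subcellular compartments.
#' Proteins absent from a PPI network may be present; downstream computations
#' restrict to the network's protein index.
#'
#' @slot kind one of \code{"domain"}, \code{"go"}, \code{"subcellular"}.
#' @slot pairs data.frame with character columns \code{protein} and
#'   \code{term}; no duplicated rows.
#'
#' @seealso [readAnnotations()], [filterGoTerms()], [termUniverse()]
#' @export
setClass("AnnotationTable",
  representation(kind = "character", pairs = "data.frame"))

setValidity("AnnotationTable", function(object) {
  msg <- character()
  if (length(object@kind) != 1L ||
      !object@kind %in% c("domain", "go", "subcellular"))
    msg <- c(msg, "kind must be one of 'domain', 'go', 'subcellular'")
  pr <- object@pairs
  if (!identical(colnames(pr), c("protein", "term")))
    msg <- c(msg, "pairs must have columns 'protein' and 'term'")
  else {
    if (!is.character(pr$protein) || !is.character(pr$term))
      msg <- c(msg, "pairs columns must be character")
    if (nrow(pr) > 0L) {
      if (any(!nzchar(pr$protein)) || any(!nzchar(pr$term)))
        msg <- c(msg, "identifiers must be non-empty")
      if (anyDuplicated(pr))
        msg <- c(msg, "duplicate (protein, term) pairs are not allowed")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Multi-relation protein tensor
#'
#' The three-way array T over proteins, stored as a list of sparse symmetric
#' n x n slices, one per relation type. Entry \code{t(i, j, k)} is the weight
#' of relation \code{k} between proteins \code{i} and \code{j}; all weights
#' lie in [0, 1], every slice is exactly symmetric and the diagonal is empty
#' (the network carries no self-interactions).
#'
#' For the standard construction there are three slices in the fixed order
#' co_neighbor, co_domain, co_annotation; the class accepts any number of
#' slices so degenerate single-relation tensors can be analyzed.
#'
#' @slot proteins character vector, the protein index.
#' @slot slices named list of \code{dgCMatrix} slices, all n x n.
#'
#' @seealso [buildTensor()], [runHept()], [tensorSlices()]
#' @export
setClass("RelationTensor",
  representation(proteins = "character", slices = "list"))

setValidity("RelationTensor", function(object) {
  n <- length(object@proteins)
  msg <- character()
  if (n < 1L) msg <- c(msg, "at least one protein is required")
  if (anyDuplicated(object@proteins))
    msg <- c(msg, "protein identifiers must be unique")
  if (length(object@slices) < 1L)
    msg <- c(msg, "at least one relation slice is required")
  if (is.null(names(object@slices)) || anyDuplicated(names(object@slices)))
    msg <- c(msg, "slices must be uniquely named")
  for (k in seq_along(object@slices)) {
    s <- object@slices[[k]]
    if (!is(s, "dgCMatrix")) {
      msg <- c(msg, sprintf("slice %d is not a dgCMatrix", k)); next
    }
    if (nrow(s) != n || ncol(s) != n) {
      msg <- c(msg, sprintf("slice %d is not n x n", k)); next
    }
    if (length(s@x)) {
      if (any(s@x < 0) || any(s@x > 1 + 1e-12))
        msg <- c(msg, sprintf("slice %d has weights outside [0, 1]", k))
    }
    if (any(Matrix::diag(s) != 0))
      msg <- c(msg, sprintf("slice %d has nonzero diagonal entries", k))
    if (!Matrix::isSymmetric(s, tol = 0))
      msg <- c(msg, sprintf("slice %d is not symmetric", k))
  }
  if (length(msg)) msg else TRUE
})

#' Jump (restart) probability vector
#'
#' The personalization distribution D mixed into the authority update:
#' \code{d_i = I(i) * S(i)}, the product of the protein's orthology
#' conservation score and its best subcellular compartment score, L1
#' normalized by default. If every raw product is zero the vector falls back
#' to the uniform distribution so the restart term stays well defined.
#'
#' @slot proteins character vector, the protein index.
#' @slot d numeric vector of restart weights, length n, all >= 0; sums to 1
#'   when \code{normalized}.
#' @slot orthology numeric vector I of per-protein orthology scores in [0, 1].
#' @slot subcellular numeric vector S of per-protein localization scores in
#'   [0, 1].
#' @slot normalized logical flag.
#'
#' @seealso [buildJumpVector()], [orthologyScores()], [subcellularScores()]
#' @export
setClass("JumpVector",
  representation(proteins = "character", d = "numeric",
    orthology = "numeric", subcellular = "numeric", normalized = "logical"))

setValidity("JumpVector", function(object) {
  n <- length(object@proteins)
  msg <- character()
  if (length(object@d) != n || length(object@orthology) != n ||
      length(object@subcellular) != n)
    msg <- c(msg, "d, orthology and subcellular must have length n")
  if (any(object@d < 0)) msg <- c(msg, "restart weights must be >= 0")
  if (isTRUE(object@normalized) && length(object@d) &&
      abs(sum(object@d) - 1) > 1e-12)
    msg <- c(msg, "normalized jump vector must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Result of the tensor HITS iteration
#'
#' The converged (or max-iteration) score state: the authority vector VA used
#' for ranking, the hub vector VH, and the edge-type importance vector VE
#' weighting each relation slice, together with iteration diagnostics and the
#' configuration that produced them.
#'
#' @slot proteins character vector, the protein index.
#' @slot VA numeric authority scores, length n.
#' @slot VH numeric hub scores, length n.
#' @slot VE named numeric edge-type importance scores, length m.
#' @slot iterations integer, number of iterations performed.
#' @slot converged logical, whether the summed L1 change fell below epsilon.
#' @slot finalChange numeric, summed L1 change at the last iteration.
#' @slot alpha,epsilon,maxIter,normalizeState configuration echo.
#'
#' @seealso [runHept()], [rankProteins()], [authorityScores()]
#' @export
setClass("HeptResult",
  representation(proteins = "character", VA = "numeric", VH = "numeric",
    VE = "numeric", iterations = "integer", converged = "logical",
    finalChange = "numeric", alpha = "numeric", epsilon = "numeric",
    maxIter = "integer", normalizeState = "logical"))

setValidity("HeptResult", function(object) {
  n <- length(object@proteins)
  msg <- character()
  if (length(object@VA) != n || length(object@VH) != n)
    msg <- c(msg, "VA and VH must have length n")
  if (any(object@VA < 0) || any(object@VH < 0) || any(object@VE < 0))
    msg <- c(msg, "score vectors must be non-negative")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
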