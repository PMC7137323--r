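## Construction of the three-slice relation tensor. Each slice is computed
## only over candidate pairs found by a sparse inverted-index join (shared
## neighbor / shared domain / shared GO term): all three weight formulas are
## zero without a shared item, so this is exact, and it is what makes
## n ~ 5000 feasible (never n^2 pairs).

SLICE_NAMES <- c("co_neighbor", "co_domain", "co_annotation")

## symmetric dgCMatrix from upper-triangle triplets (i < j)
symmetricSlice <- function(i, j, x, n, ids) {
  keep <- x > 0
  i <- i[keep]; j <- j[keep]; x <- x[keep]
  s <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
    dims = c(n, n), dimnames = list(ids, ids))
  methods::as(s, "CsparseMatrix")
}

emptySlice <- function(n, ids) {
  methods::as(Matrix::sparseMatrix(i = integer(), j = integer(),
    x = numeric(), dims = c(n, n), dimnames = list(ids, ids)),
    "CsparseMatrix")
}

#' Co-neighbor weight between two proteins
#'
#' Weight of the co-neighbor relation from the two proteins' PPI neighbor
#' sets: \code{|Ni n Nj|^2 / ((|Ni| - 1) (|Nj| - 1))} when both proteins have
#' more than one neighbor, and 0 otherwise. The ratio can exceed 1 (e.g. two
#' degree-2 proteins sharing both neighbors give 4); by default it is clipped
#' to 1 so all tensor weights stay interpretable as probabilities.
#'
#' @param neighborsI,neighborsJ neighbor sets (vectors of identifiers or
#'   indices); a protein is never its own neighbor.
#' @param clip clip values above 1 to 1 (default \code{TRUE}).
#' @return numeric weight.
#' @examples
#' coNeighborWeight(c("a", "b", "c"), c("b", "c", "d")) # 4/4 = 1
#' coNeighborWeight(c("a", "b", "c"), c("c", "d", "e")) # 1/4
#' @export
coNeighborWeight <- function(neighborsI, neighborsJ, clip = TRUE) {
  ni <- length(unique(neighborsI)); nj <- length(unique(neighborsJ))
  if (ni <= 1L || nj <= 1L) return(0)
  w <- length(intersect(neighborsI, neighborsJ))^2 / ((ni - 1) * (nj - 1))
  if (clip) min(w, 1) else w
}

#' Per-protein domain scores
#'
#' For each protein the raw score sums, over the domains it contains, the
#' reciprocal of the number of indexed proteins carrying that domain
#' (rare domains contribute more; domain-rich proteins score higher). Raw
#' scores are then min-max normalized over all n proteins, so the scores lie
#' in [0, 1] with the minimum-scoring protein at 0 and the maximum at 1.
#' When all raw scores are equal (e.g. no protein has any domain) the
#' normalization is undefined and all scores are set to 0 with a warning.
#'
#' @param table an \linkS4class{AnnotationTable} of kind \code{"domain"}.
#' @param network a \linkS4class{PpiNetwork} (or character id vector)
#'   defining the protein index; annotations outside it are ignored.
#' @return named numeric vector of length n.
#' @export
domainScores <- function(table, network) {
  stopifnot(is(table, "AnnotationTable"))
  if (table@kind != "domain")
    stop("domainScores requires a 'domain' annotation table", call. = FALSE)
  ids <- if (is.character(network)) network else proteinIds(network)
  n <- length(ids)
  pr <- table@pairs
  pr <- pr[pr$protein %in% ids, , drop = FALSE]
  raw <- numeric(n)
  if (nrow(pr) > 0L) {
    np <- table(pr$term)  # proteins per domain, counted within the index
    contrib <- 1 / as.numeric(np[pr$term])
    idx <- match(pr$protein, ids)
    raw <- as.numeric(tapply(contrib, factor(idx, levels = seq_len(n)),
      sum, default = 0))
  }
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    if (n > 1L)
      warning("all raw domain scores are equal; setting all scores to 0",
        call. = FALSE)
    return(stats::setNames(numeric(n), ids))
  }
  stats::setNames((raw - rng[1L]) / (rng[2L] - rng[1L]), ids)
}

#' Co-domain weight between two proteins
#'
#' Product of the two proteins' normalized domain scores when they share at
#' least one domain type; 0 otherwise (the co-domain relation only exists
#' between proteins with a common domain).
#'
#' @param pdI,pdJ normalized domain scores in [0, 1].
#' @param sharedDomain logical; do the proteins share a domain type?
#' @return numeric weight in [0, 1].
#' @export
coDomainWeight <- function(pdI, pdJ, sharedDomain) {
  if (!isTRUE(sharedDomain)) return(0)
  pdI * pdJ
}

#' Co-annotation weight between two proteins
#'
#' Probability-of-shared-function weight from the proteins' (filtered) GO
#' term sets: \code{sqrt(|Fi n Fj|^2 / (|Fi| |Fj|))}, i.e. the geometric-mean
#' normalized overlap, when both sets are non-empty; 0 otherwise. Always in
#' [0, 1] by Cauchy-Schwarz.
#'
#' @param termsI,termsJ GO term sets (character vectors).
#' @return numeric weight in [0, 1].
#' @examples
#' coAnnotationWeight(paste0("g", 1:4), paste0("g", 2:10)) # 3/sqrt(36) = 0.5
#' @export
coAnnotationWeight <- function(termsI, termsJ) {
  fi <- unique(termsI); fj <- unique(termsJ)
  if (length(fi) == 0L || length(fj) == 0L) return(0)
  length(intersect(fi, fj)) / sqrt(length(fi) * length(fj))
}

## binary protein x term incidence over the index
incidenceMatrix <- function(pairs, ids) {
  terms <- unique(pairs$term)
  Matrix::sparseMatrix(
    i = match(pairs$protein, ids), j = match(pairs$term, terms),
    x = 1, dims = c(length(ids), length(terms)))
}

coNeighborSlice <- function(network, clip = TRUE) {
  ids <- proteinIds(network)
  n <- length(ids)
  A <- adjacencyMatrix(network)
  deg <- Matrix::colSums(A)
  C <- methods::as(Matrix::tcrossprod(A), "TsparseMatrix")  # common-neighbor counts
  ut <- C@i + 1L < C@j + 1L
  i <- C@i[ut] + 1L; j <- C@j[ut] + 1L; cnt <- C@x[ut]
  ok <- deg[i] > 1 & deg[j] > 1 & cnt > 0
  i <- i[ok]; j <- j[ok]; cnt <- cnt[ok]
  w <- cnt^2 / ((deg[i] - 1) * (deg[j] - 1))
  if (clip && any(w > 1)) {
    message(sprintf(
      "coNeighborSlice: clipped %d weight(s) above 1 to 1", sum(w > 1)))
    w <- pmin(w, 1)
  }
  symmetricSlice(i, j, w, n, ids)
}

coDomainSlice <- function(domains, network) {
  ids <- proteinIds(network)
  n <- length(ids)
  pd <- domainScores(domains, network)
  pr <- domains@pairs
  pr <- pr[pr$protein %in% ids, , drop = FALSE]
  if (nrow(pr) == 0L) return(emptySlice(n, ids))
  M <- incidenceMatrix(pr, ids)
  S <- methods::as(Matrix::tcrossprod(M), "TsparseMatrix")  # shared-domain counts
  ut <- S@i + 1L < S@j + 1L & S@x > 0
  i <- S@i[ut] + 1L; j <- S@j[ut] + 1L
  symmetricSlice(i, j, pd[i] * pd[j], n, ids)
}

coAnnotationSlice <- function(go, network) {
  ids <- proteinIds(network)
  n <- length(ids)
  pr <- go@pairs
  pr <- pr[pr$protein %in% ids, , drop = FALSE]
  if (nrow(pr) == 0L) return(emptySlice(n, ids))
  G <- incidenceMatrix(pr, ids)
  sz <- Matrix::rowSums(G)  # |F_i|
  S <- methods::as(Matrix::tcrossprod(G), "TsparseMatrix")
  ut <- S@i + 1L < S@j + 1L & S@x > 0
  i <- S@i[ut] + 1L; j <- S@j[ut] + 1L; cnt <- S@x[ut]
  symmetricSlice(i, j, cnt / sqrt(sz[i] * sz[j]), n, ids)
}

#' Build the three-slice relation tensor
#'
#' Constructs the sparse symmetric relation tensor over the network's
#' proteins with slices, in fixed order: \code{co_neighbor} (shared PPI
#' neighbors), \code{co_domain} (shared protein domains weighted by domain
#' scores) and \code{co_annotation} (shared filtered GO terms). Relations are
#' computed for any pair of proteins sharing the relevant item, whether or
#' not they interact directly; \code{restrictToPpi = TRUE} gives the
#' conservative variant that keeps only pairs that are PPI edges.
#'
#' Annotations for proteins outside the network are ignored (with a message
#' giving the count). The GO table should already be frequency-filtered (see
#' [filterGoTerms()]).
#'
#' @param network a \linkS4class{PpiNetwork}.
#' @param domains \linkS4class{AnnotationTable} of kind \code{"domain"}, or
#'   \code{NULL} for an all-zero co-domain slice.
#' @param go \linkS4class{AnnotationTable} of kind \code{"go"}, or
#'   \code{NULL} for an all-zero co-annotation slice.
#' @param restrictToPpi keep only weights between directly interacting pairs.
#' @param clipCoNeighbor clip co-neighbor weights above 1 to 1.
#' @return a \linkS4class{RelationTensor} with 3 slices.
#' @export
buildTensor <- function(network, domains = NULL, go = NULL,
    restrictToPpi = FALSE, clipCoNeighbor = TRUE) {
  stopifnot(is(network, "PpiNetwork"))
  ids <- proteinIds(network)
  n <- length(ids)
  s1 <- coNeighborSlice(network, clip = clipCoNeighbor)
  s2 <- if (is.null(domains)) emptySlice(n, ids) else {
    stopifnot(is(domains, "AnnotationTable"))
    coDomainSlice(restrictToNetwork(domains, network, quiet = TRUE), network)
  }
  s3 <- if (is.null(go)) emptySlice(n, ids) else {
    stopifnot(is(go, "AnnotationTable"))
    coAnnotationSlice(restrictToNetwork(go, network, quiet = TRUE), network)
  }
  slices <- list(s1, s2, s3)
  names(slices) <- SLICE_NAMES
  if (restrictToPpi) {
    A <- adjacencyMatrix(network)
    slices <- lapply(slices, function(s) Matrix::drop0(s * A))
  }
  newRelationTensor(ids, slices)
}

#' Construct a RelationTensor from slice matrices
#'
#' @param proteins character vector of protein identifiers.
#' @param slices named list of sparse symmetric n x n matrices with entries
#'   in [0, 1] and empty diagonal.
#' @return a \linkS4class{RelationTensor}.
#' @export
newRelationTensor <- function(proteins, slices) {
  if (is.null(names(slices)))
    names(slices) <- paste0("relation_", seq_along(slices))
  slices <- lapply(slices, function(s)
    Matrix::drop0(methods::as(methods::as(s, "generalMatrix"),
      "CsparseMatrix")))
  methods::new("RelationTensor", proteins = as.character(proteins),
    slices = slices)
}

#' Dump a relation tensor to TSV slices plus JSON metadata
#'
#' Writes one TSV per slice (\code{protein_i}, \code{protein_j},
#' \code{weight}, one row per unordered pair with \code{protein_i} before
#' \code{protein_j} lexicographically) and \code{tensor.json} recording n, m,
#' the slice order and names.
#'
#' @param tensor a \linkS4class{RelationTensor}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
writeTensor <- function(tensor, dir) {
  stopifnot(is(tensor, "RelationTensor"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- tensor@proteins
  paths <- character()
  for (k in seq_along(tensor@slices)) {
    s <- methods::as(tensor@slices[[k]], "TsparseMatrix")
    ut <- s@i < s@j
    i <- ids[s@i[ut] + 1L]; j <- ids[s@j[ut] + 1L]; x <- s@x[ut]
    swap <- i > j
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    o <- order(i, j)
    p <- file.path(dir, sprintf("slice_%d_%s.tsv", k,
      names(tensor@slices)[k]))
    utils::write.table(
      data.frame(protein_i = i[o], protein_j = j[o],
        weight = sprintf("%.17g", x[o])),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, "tensor.json")
  jsonlite::write_json(list(n = length(ids), m = length(tensor@slices),
    slices = names(tensor@slices)), meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, meta))
}
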