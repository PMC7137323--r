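## Independent brute-force oracles: dense triple-loop implementations of the
## relation weights, the fiber normalizations and the score updates, written
## against plain base-R arrays with no shared code with the package.

## dense co-neighbor weights from a 0/1 adjacency matrix
oracleCoNeighbor <- function(adj, clip = TRUE) {
  n <- nrow(adj)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ni <- which(adj[i, ] != 0)
    nj <- which(adj[j, ] != 0)
    if (length(ni) > 1 && length(nj) > 1) {
      w <- length(intersect(ni, nj))^2 / ((length(ni) - 1) * (length(nj) - 1))
      out[i, j] <- if (clip) min(w, 1) else w
    }
  }
  out
}

## raw-then-minmax domain scores from a (protein, term) pair data.frame
oracleDomainScores <- function(pairs, ids) {
  raw <- numeric(length(ids))
  pairs <- pairs[pairs$protein %in% ids, , drop = FALSE]
  for (i in seq_along(ids)) {
    myDoms <- unique(pairs$term[pairs$protein == ids[i]])
    for (d in myDoms) {
      np <- length(unique(pairs$protein[pairs$term == d]))
      raw[i] <- raw[i] + 1 / np
    }
  }
  if (max(raw) == min(raw)) return(numeric(length(ids)))
  (raw - min(raw)) / (max(raw) - min(raw))
}

## dense n x n x 3 relation tensor from adjacency + annotation pair sets
oracleTensor <- function(adj, domPairs, goPairs, ids, clip = TRUE) {
  n <- length(ids)
  arr <- array(0, dim = c(n, n, 3))
  arr[, , 1] <- oracleCoNeighbor(adj, clip = clip)
  pd <- oracleDomainScores(domPairs, ids)
  domSets <- lapply(ids, function(p)
    unique(domPairs$term[domPairs$protein == p]))
  goSets <- lapply(ids, function(p)
    unique(goPairs$term[goPairs$protein == p]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (length(intersect(domSets[[i]], domSets[[j]])) > 0)
      arr[i, j, 2] <- pd[i] * pd[j]
    fi <- goSets[[i]]; fj <- goSets[[j]]
    if (length(fi) > 0 && length(fj) > 0)
      arr[i, j, 3] <- sqrt(length(intersect(fi, fj))^2 /
        (length(fi) * length(fj)))
  }
  arr
}

## fiber normalization of a dense tensor with uniform fill-in
oracleTransition <- function(arr, mode) {
  n <- dim(arr)[1]; m <- dim(arr)[3]
  out <- array(0, dim = dim(arr))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(m)) {
    denom <- switch(mode,
      authority = sum(arr[, j, k]),
      hub = sum(arr[i, , k]),
      edge = sum(arr[i, j, ]))
    out[i, j, k] <- if (denom > 0) arr[i, j, k] / denom
      else if (mode == "edge") 1 / m else 1 / n
  }
  out
}

## one update of the three score vectors by explicit triple sums
oracleIterate <- function(Ta, Th, Te, state, d, alpha, normalize = TRUE) {
  n <- dim(Ta)[1]; m <- dim(Ta)[3]
  VA <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) for (k in seq_len(m))
      s <- s + Ta[i, j, k] * state$VH[j] * state$VE[k]
    VA[i] <- (1 - alpha) * d[i] + alpha * s
  }
  if (normalize) VA <- VA / sum(VA)
  VH <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(n)) for (k in seq_len(m))
      s <- s + Th[i, j, k] * VA[i] * state$VE[k]
    VH[j] <- s
  }
  if (normalize) VH <- VH / sum(VH)
  VE <- numeric(m)
  for (k in seq_len(m)) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      s <- s + Te[i, j, k] * VA[i] * VH[j]
    VE[k] <- s
  }
  if (normalize) VE <- VE / sum(VE)
  list(VA = VA, VH = VH, VE = VE)
}

## --- random instance generators (fixed-seed fixtures) ---

randomNetwork <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  newPpiNetwork(sprintf("P%02d", seq_len(n)), pairs[keep, , drop = FALSE])
}

randomAnnotation <- function(ids, nTerms, lambda, kind, prefix, seed) {
  set.seed(seed)
  p <- character(); t <- character()
  for (id in ids) {
    k <- rpois(1, lambda)
    if (k > 0) {
      terms <- unique(sample(sprintf("%s%03d", prefix, seq_len(nTerms)), k,
        replace = TRUE))
      p <- c(p, rep(id, length(terms))); t <- c(t, terms)
    }
  }
  newAnnotationTable(kind, p, t)
}

## random RelationTensor with controllable sparsity; proteins listed in
## `zeroOut` have their rows/columns emptied in the given slice to force
## uniform fibers
randomTensor <- function(n, m = 3, density = 0.2, seed = 1,
    zeroProteinFrac = 0.2) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n))
  slices <- lapply(seq_len(m), function(k) {
    M <- matrix(0, n, n)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < density
    w <- runif(nrow(pairs))
    for (r in which(keep)) {
      M[pairs[r, 1], pairs[r, 2]] <- w[r]
      M[pairs[r, 2], pairs[r, 1]] <- w[r]
    }
    nz <- floor(zeroProteinFrac * n)
    if (nz > 0) {
      drop <- sample(n, nz)
      M[drop, ] <- 0
      M[, drop] <- 0
    }
    M
  })
  names(slices) <- paste0("rel", seq_len(m))
  newRelationTensor(ids, lapply(slices, function(M)
    as(as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix"),
      "CsparseMatrix")))
}

denseSlices <- function(tensor) {
  m <- nSlices(tensor)
  n <- nProteins(tensor)
  arr <- array(0, dim = c(n, n, m))
  for (k in seq_len(m)) arr[, , k] <- as.matrix(tensorSlices(tensor)[[k]])
  arr
}

recallAtK <- function(ranking, essential, k) {
  topKEssentialCount(ranking, essential, k) / length(essential)
}
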