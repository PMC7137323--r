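test_that("co-neighbor weight follows the shared-neighbor formula", {
  # both degree > 1, full overlap of the non-self neighborhood
  expect_equal(coNeighborWeight(c("a", "b", "c"), c("b", "c", "d")), 1.0)
  expect_equal(coNeighborWeight(c("a", "b", "c"), c("c", "d", "e")), 0.25)
  # degree-1 protein on either side forces the zero branch
  expect_equal(coNeighborWeight("a", c("a", "b")), 0)
  expect_equal(coNeighborWeight(c("a", "b"), "a"), 0)
  # the raw ratio can exceed 1; clipped by default, exact when unclipped
  expect_equal(coNeighborWeight(c("a", "b"), c("a", "b")), 1)
  expect_equal(coNeighborWeight(c("a", "b"), c("a", "b"), clip = FALSE), 4)
})

test_that("domain scores min-max normalize the rarity-weighted sums", {
  ids <- c("A", "B", "C")
  tab <- newAnnotationTable("domain", c("A", "B", "C"), c("d1", "d2", "d2"))
  # raw: A = 1/1 = 1, B = C = 1/2; min-max over {1, .5, .5}
  expect_equal(domainScores(tab, ids), c(A = 1, B = 0, C = 0))

  # a protein with no domains is the raw minimum, hence normalized 0
  tab2 <- newAnnotationTable("domain", c("A", "B"), c("d1", "d2"))
  sc2 <- domainScores(tab2, c("A", "B", "C"))
  expect_equal(unname(sc2["C"]), 0)
  expect_equal(max(sc2), 1)

  # all proteins sharing one domain gives equal raw scores -> all 0 + warning
  tab3 <- newAnnotationTable("domain", ids, rep("d1", 3))
  expect_warning(sc3 <- domainScores(tab3, ids), "equal")
  expect_equal(unname(sc3), c(0, 0, 0))
})

test_that("co-domain and co-annotation weights match their formulas", {
  expect_equal(coDomainWeight(0.8, 0.5, TRUE), 0.4)
  expect_equal(coDomainWeight(0.8, 0.5, FALSE), 0)
  expect_equal(coDomainWeight(0, 0.9, TRUE), 0)

  expect_equal(coAnnotationWeight(paste0("g", 1:5), paste0("g", 1:5)), 1.0)
  expect_equal(coAnnotationWeight(paste0("g", 1:4), paste0("g", 2:10)), 0.5)
  expect_equal(coAnnotationWeight(character(), paste0("g", 1:3)), 0)
})

test_that("degenerate topologies give an all-zero co-neighbor slice", {
  # path A-B-C: the only co-neighbor pair (A,C) has both degrees 1
  path <- newPpiNetwork(c("A", "B", "C"), rbind(c(1, 2), c(2, 3)))
  s <- tensorSlices(buildTensor(path))[["co_neighbor"]]
  expect_equal(length(s@x), 0L)

  # star: leaf pairs share the center but have degree 1; center-leaf pairs
  # share no neighbor
  star <- newPpiNetwork(c("c", "x", "y", "z"),
    rbind(c(1, 2), c(1, 3), c(1, 4)))
  s2 <- tensorSlices(buildTensor(star))[["co_neighbor"]]
  expect_equal(length(s2@x), 0L)
})

test_that("empty annotations give all-zero domain and GO slices", {
  net <- randomNetwork(8, 0.5, seed = 3)
  tens <- buildTensor(net)
  expect_equal(length(tensorSlices(tens)[["co_domain"]]@x), 0L)
  expect_equal(length(tensorSlices(tens)[["co_annotation"]]@x), 0L)
  expect_true(length(tensorSlices(tens)[["co_neighbor"]]@x) > 0L)
})

test_that("sparse construction equals the dense triple-loop oracle", {
  for (seed in 1:5) {
    n <- c(12, 18, 25, 30, 9)[seed]
    net <- randomNetwork(n, 0.25, seed = seed)
    ids <- proteinIds(net)
    dom <- randomAnnotation(ids, 6, 1.2, "domain", "d", seed + 100)
    go <- randomAnnotation(ids, 8, 1.5, "go", "g", seed + 200)
    tens <- suppressWarnings(suppressMessages(
      buildTensor(net, dom, go)))
    oracle <- suppressWarnings(oracleTensor(as.matrix(adjacencyMatrix(net)),
      annotationPairs(dom), annotationPairs(go), ids))
    expect_equal(denseSlices(tens), oracle, tolerance = 1e-12)
  }
})

test_that("tensor slices are symmetric, bounded and diagonal-free", {
  for (seed in 1:3) {
    net <- randomNetwork(20, 0.3, seed = seed)
    ids <- proteinIds(net)
    dom <- randomAnnotation(ids, 5, 1.5, "domain", "d", seed)
    go <- randomAnnotation(ids, 6, 2, "go", "g", seed + 50)
    tens <- suppressWarnings(suppressMessages(buildTensor(net, dom, go)))
    for (s in tensorSlices(tens)) {
      expect_true(Matrix::isSymmetric(s, tol = 0))
      expect_true(all(s@x >= 0 & s@x <= 1))
      expect_true(all(Matrix::diag(s) == 0))
    }
  }
})

test_that("tensor construction is permutation-equivariant", {
  net <- randomNetwork(15, 0.3, seed = 7)
  ids <- proteinIds(net)
  dom <- randomAnnotation(ids, 5, 1.5, "domain", "d", 7)
  go <- randomAnnotation(ids, 6, 2, "go", "g", 77)
  tens <- suppressMessages(buildTensor(net, dom, go))

  set.seed(42)
  perm <- sample(length(ids))
  e <- networkEdges(net)
  netP <- newPpiNetwork(ids[perm],
    cbind(match(ids[e[, 1]], ids[perm]), match(ids[e[, 2]], ids[perm])))
  tensP <- suppressMessages(buildTensor(netP, dom, go))
  inv <- match(ids, ids[perm])  # position of original protein i in permuted
  for (k in 1:3) {
    A <- as.matrix(tensorSlices(tens)[[k]])
    B <- as.matrix(tensorSlices(tensP)[[k]])[inv, inv]
    expect_equal(unname(B), unname(A), tolerance = 1e-14)
  }
})

test_that("slice sparsity respects the candidate-pair bounds", {
  net <- randomNetwork(30, 0.15, seed = 11)
  ids <- proteinIds(net)
  dom <- randomAnnotation(ids, 8, 1, "domain", "d", 11)
  go <- randomAnnotation(ids, 10, 1.5, "go", "g", 111)
  tens <- suppressWarnings(suppressMessages(buildTensor(net, dom, go)))
  A <- as.matrix(adjacencyMatrix(net))
  # pairs at distance 2 (shared neighbor)
  C <- A %*% A; diag(C) <- 0
  expect_lte(length(tensorSlices(tens)[["co_neighbor"]]@x) / 2,
    sum(C[upper.tri(C)] > 0))
  sharedCount <- function(tab) {
    pr <- annotationPairs(tab)
    sets <- lapply(ids, function(p) unique(pr$term[pr$protein == p]))
    cnt <- 0
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids))
      if (length(intersect(sets[[i]], sets[[j]])) > 0) cnt <- cnt + 1
    cnt
  }
  expect_lte(length(tensorSlices(tens)[["co_domain"]]@x) / 2,
    sharedCount(dom))
  expect_lte(length(tensorSlices(tens)[["co_annotation"]]@x) / 2,
    sharedCount(go))
})

test_that("restrictToPpi keeps only directly interacting pairs", {
  net <- randomNetwork(15, 0.25, seed = 5)
  ids <- proteinIds(net)
  go <- randomAnnotation(ids, 4, 2, "go", "g", 5)
  tens <- suppressMessages(buildTensor(net, go = go, restrictToPpi = TRUE))
  A <- adjacencyMatrix(net)
  for (s in tensorSlices(tens)) {
    sT <- as(s, "TsparseMatrix")
    if (length(sT@x))
      expect_true(all(A[cbind(sT@i + 1, sT@j + 1)] == 1))
  }
})

test_that("tensor dump writes per-slice TSVs plus metadata", {
  net <- randomNetwork(10, 0.4, seed = 2)
  tens <- buildTensor(net)
  dir <- withr::local_tempdir()
  paths <- writeTensor(tens, dir)
  expect_true(file.exists(file.path(dir, "tensor.json")))
  meta <- jsonlite::read_json(file.path(dir, "tensor.json"))
  expect_equal(meta$n, 10L)
  expect_equal(meta$m, 3L)
  tsv <- utils::read.delim(file.path(dir, "slice_1_co_neighbor.tsv"),
    colClasses = c("character", "character", "numeric"))
  expect_true(all(tsv$protein_i < tsv$protein_j))
  s <- tensorSlices(tens)[["co_neighbor"]]
  expect_equal(nrow(tsv), length(s@x) / 2)
})
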