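test_that("fiber normalization divides by the fiber sum or fills uniformly", {
  # slice 1, column 4 carries weights (0.2, 0.3, 0.5): already a distribution
  ids <- c("A", "B", "C", "D")
  s1 <- Matrix::sparseMatrix(i = c(1, 2, 3, 4, 4, 4), j = c(4, 4, 4, 1, 2, 3),
    x = c(0.2, 0.3, 0.5, 0.2, 0.3, 0.5), dims = c(4, 4))
  s2 <- Matrix::sparseMatrix(i = 1, j = 2, x = 0.4, dims = c(4, 4),
    symmetric = FALSE)
  s2 <- s2 + Matrix::t(s2)
  tens <- newRelationTensor(ids, list(a = s1, b = s2))
  ta <- denseTransitionTensor(tens, "authority")
  expect_equal(ta[, 4, 1], c(0.2, 0.3, 0.5, 0))
  # column 3 of slice 2 is all-zero: uniform 1/n fill
  expect_equal(ta[, 3, 2], rep(1 / 4, 4))
  # scaling a fiber leaves its normalization unchanged
  tens2 <- newRelationTensor(ids, list(a = s1 / 2, b = s2))
  expect_equal(denseTransitionTensor(tens2, "authority")[, 4, 1],
    c(0.2, 0.3, 0.5, 0))
})

test_that("edge-mode normalization spreads mass across slices", {
  ids <- c("A", "B", "C")
  mk <- function(w) {
    s <- Matrix::sparseMatrix(i = 1, j = 2, x = w, dims = c(3, 3))
    s + Matrix::t(s)
  }
  zero <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
    dims = c(3, 3))
  tens <- newRelationTensor(ids, list(x = mk(0.5), y = zero, z = mk(0.5)))
  te <- denseTransitionTensor(tens, "edge")
  expect_equal(te[1, 2, ], c(0.5, 0, 0.5))
  # pairs with no relation in any slice (incl. the diagonal) get 1/m
  expect_equal(te[1, 3, ], rep(1 / 3, 3))
  expect_equal(te[2, 2, ], rep(1 / 3, 3))
})

test_that("every transition fiber sums to 1 on random tensors", {
  for (seed in 1:6) {
    n <- c(6, 11, 17, 23, 30, 8)[seed]
    tens <- randomTensor(n, m = 3, density = 0.25, seed = seed,
      zeroProteinFrac = c(0, 0.3, 0.2, 0.5, 0.1, 1)[seed])
    ta <- denseTransitionTensor(tens, "authority")
    th <- denseTransitionTensor(tens, "hub")
    te <- denseTransitionTensor(tens, "edge")
    expect_equal(apply(ta, c(2, 3), sum),
      matrix(1, n, 3), tolerance = 1e-12)
    expect_equal(apply(th, c(1, 3), sum),
      matrix(1, n, 3), tolerance = 1e-12)
    expect_equal(apply(te, c(1, 2), sum),
      matrix(1, n, n), tolerance = 1e-12)
  }
})

test_that("implicit sparse contraction equals the dense triple-loop oracle", {
  for (seed in 1:4) {
    n <- c(10, 16, 24, 30)[seed]
    tens <- randomTensor(n, m = 3, density = 0.2, seed = seed,
      zeroProteinFrac = 0.25)
    tt <- transitionTensors(tens)
    arr <- denseSlices(tens)
    Ta <- oracleTransition(arr, "authority")
    Th <- oracleTransition(arr, "hub")
    Te <- oracleTransition(arr, "edge")
    # the package's dense materialization must equal the oracle's
    expect_equal(denseTransitionTensor(tens, "authority"), Ta,
      tolerance = 1e-12)
    expect_equal(denseTransitionTensor(tens, "hub"), Th, tolerance = 1e-12)
    expect_equal(denseTransitionTensor(tens, "edge"), Te, tolerance = 1e-12)

    set.seed(seed + 500)
    d <- runif(n); d <- d / sum(d)
    state <- list(VA = rep(1 / n, n), VH = rep(1 / n, n),
      VE = rep(1 / 3, 3))
    for (step in 1:4) {
      got <- iterateHept(state, tt, d, alpha = 0.3)
      want <- oracleIterate(Ta, Th, Te, state, d, alpha = 0.3)
      expect_equal(got$VA, want$VA, tolerance = 1e-10)
      expect_equal(got$VH, want$VH, tolerance = 1e-10)
      expect_equal(unname(got$VE), want$VE, tolerance = 1e-10)
      state <- got
    }
  }
})

test_that("alpha = 0 makes the authority vector the restart vector", {
  tens <- randomTensor(12, seed = 3)
  set.seed(99)
  d <- runif(12); d <- d / sum(d)
  tt <- transitionTensors(tens)
  st <- iterateHept(list(VA = rep(1 / 12, 12), VH = rep(1 / 12, 12),
    VE = rep(1 / 3, 3)), tt, d, alpha = 0)
  expect_equal(st$VA, d, tolerance = 1e-14)
})

test_that("alpha = 1 on an all-zero tensor reaches the uniform fixed point", {
  n <- 7
  ids <- sprintf("P%d", 1:n)
  zero <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
    dims = c(n, n))
  tens <- newRelationTensor(ids, list(a = zero, b = zero, c = zero))
  res <- runHept(tens, alpha = 1, epsilon = 1e-12)
  expect_true(res@converged)
  expect_lte(res@iterations, 2L)
  expect_equal(unname(authorityScores(res)), rep(1 / n, n))
  expect_equal(unname(hubScores(res)), rep(1 / n, n))
  expect_equal(unname(edgeTypeScores(res)), rep(1 / 3, 3))
})

test_that("single-slice iteration matches a dense personalized-HITS oracle", {
  for (seed in 1:3) {
    n <- c(12, 20, 30)[seed]
    tens <- randomTensor(n, m = 1, density = 0.25, seed = seed,
      zeroProteinFrac = 0.2)
    M <- as.matrix(tensorSlices(tens)[[1]])
    cs <- colSums(M)
    Ma <- sapply(seq_len(n), function(j)
      if (cs[j] > 0) M[, j] / cs[j] else rep(1 / n, n))  # authority transition
    rs <- rowSums(M)
    Mh <- t(sapply(seq_len(n), function(i)
      if (rs[i] > 0) M[i, ] / rs[i] else rep(1 / n, n)))  # hub transition
    set.seed(seed + 40)
    d <- runif(n); d <- d / sum(d)
    alpha <- 0.3
    tt <- transitionTensors(tens)
    state <- list(VA = rep(1 / n, n), VH = rep(1 / n, n), VE = 1)
    oVA <- rep(1 / n, n); oVH <- rep(1 / n, n)
    for (step in 1:8) {
      state <- iterateHept(state, tt, d, alpha = alpha)
      oVA <- (1 - alpha) * d + alpha * as.numeric(Ma %*% oVH)
      oVA <- oVA / sum(oVA)
      oVH <- as.numeric(t(Mh) %*% oVA)
      oVH <- oVH / sum(oVH)
      expect_equal(state$VA, oVA, tolerance = 1e-10)
      expect_equal(state$VH, oVH, tolerance = 1e-10)
      expect_equal(unname(state$VE), 1, tolerance = 1e-12)
    }
  }
})

test_that("state vectors stay non-negative distributions at every iteration", {
  tens <- randomTensor(15, seed = 8, zeroProteinFrac = 0.3)
  tt <- transitionTensors(tens)
  set.seed(8)
  d <- runif(15); d <- d / sum(d)
  state <- list(VA = rep(1 / 15, 15), VH = rep(1 / 15, 15),
    VE = rep(1 / 3, 3))
  for (step in 1:10) {
    state <- iterateHept(state, tt, d, alpha = 0.3)
    expect_true(all(state$VA >= 0) && all(state$VH >= 0) &&
      all(state$VE >= 0))
    expect_equal(sum(state$VA), 1, tolerance = 1e-10)
    expect_equal(sum(state$VH), 1, tolerance = 1e-10)
    expect_equal(sum(state$VE), 1, tolerance = 1e-10)
  }
})

test_that("a huge threshold stops after one iteration, converged", {
  tens <- randomTensor(10, seed = 4)
  res <- runHept(tens, epsilon = 10)
  expect_true(res@converged)
  expect_equal(res@iterations, 1L)
})

test_that("hitting the iteration cap warns and flags non-convergence", {
  tens <- randomTensor(10, seed = 4)
  expect_warning(res <- runHept(tens, epsilon = 1e-15, maxIter = 1L),
    "did not converge")
  expect_false(res@converged)
  expect_equal(res@iterations, 1L)
})

test_that("the converged state is a fixed point and the run deterministic", {
  tens <- randomTensor(20, seed = 10, zeroProteinFrac = 0.2)
  set.seed(10)
  d <- runif(20); d <- d / sum(d)
  eps <- 1e-10
  res1 <- runHept(tens, d, epsilon = eps)
  res2 <- runHept(tens, d, epsilon = eps)
  expect_true(res1@converged)
  expect_identical(res1@VA, res2@VA)
  expect_identical(res1@VH, res2@VH)
  expect_identical(res1@VE, res2@VE)
  # one more update moves the state by less than 10 * epsilon
  tt <- transitionTensors(tens)
  nxt <- iterateHept(list(VA = res1@VA, VH = res1@VH, VE = res1@VE), tt, d,
    alpha = 0.3)
  drift <- sum(abs(nxt$VA - res1@VA)) + sum(abs(nxt$VH - res1@VH)) +
    sum(abs(nxt$VE - res1@VE))
  expect_lt(drift, 10 * eps)
})

test_that("relabeling proteins permutes all scores identically", {
  tens <- randomTensor(14, seed = 21, zeroProteinFrac = 0.2)
  ids <- proteinIds(tens)
  set.seed(21)
  d <- runif(14); d <- d / sum(d)
  res <- runHept(tens, d, epsilon = 1e-12)

  perm <- sample(14)
  slicesP <- lapply(tensorSlices(tens), function(s) {
    sp <- s[perm, perm, drop = FALSE]
    dimnames(sp) <- list(ids[perm], ids[perm])
    sp
  })
  tensP <- newRelationTensor(ids[perm], slicesP)
  resP <- runHept(tensP, d[perm], epsilon = 1e-12)
  expect_equal(resP@VA, res@VA[perm], tolerance = 1e-12)
  expect_equal(resP@VH, res@VH[perm], tolerance = 1e-12)
  expect_equal(unname(resP@VE), unname(res@VE), tolerance = 1e-12)
  # rankings agree as id -> rank maps (scores are tie-free here)
  r1 <- rankProteins(res)
  r2 <- rankProteins(resP)
  expect_equal(r2$protein, r1$protein)
})

test_that("ranking sorts by score with lexicographic tie-break", {
  expect_equal(
    rankProteins(c(P1 = 0.5, P2 = 0.3, P3 = 0.2))$protein,
    c("P1", "P2", "P3"))
  expect_equal(
    rankProteins(c(P2 = 0.4, P1 = 0.4, P3 = 0.2))$protein,
    c("P1", "P2", "P3"))
  expect_equal(
    rankProteins(c(P3 = 1, P2 = 1, P1 = 1))$protein,
    c("P1", "P2", "P3"))
  expect_equal(nrow(rankProteins(c(A = 1, B = 2, C = 3), topN = 2)), 2L)
})

test_that("mismatched jump vector is rejected", {
  tens <- randomTensor(6, seed = 1)
  jv <- uniformJumpVector(sprintf("Q%d", 1:6))
  expect_error(runHept(tens, jv), "different proteins")
})
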