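## Evaluation of a ranked protein list against a known essential set:
## top-K counts, cutoff-sweep precision-recall, jackknife cumulative-count
## curves with (normalized) trapezoid areas, and pairwise ranking overlap.

rankingIds <- function(ranking) {
  if (is.data.frame(ranking)) {
    stopifnot("protein" %in% names(ranking))
    if ("score" %in% names(ranking) &&
        is.unsorted(rev(ranking$score), strictly = FALSE))
      stop("ranking scores must be in descending order", call. = FALSE)
    ids <- ranking$protein
  } else ids <- as.character(ranking)
  if (anyDuplicated(ids))
    stop("ranking contains duplicate protein identifiers", call. = FALSE)
  ids
}

#' Number of true essentials among the top K
#'
#' @param ranking a ranking data.frame (see [rankProteins()]) or an ordered
#'   character vector of protein identifiers, best first.
#' @param essential character vector of known essential protein ids.
#' @param k cutoff, 1 <= k <= length of the ranking.
#' @return integer count.
#' @export
topKEssentialCount <- function(ranking, essential, k) {
  ids <- rankingIds(ranking)
  if (k < 1L || k > length(ids))
    stop(sprintf("k must lie in [1, %d]", length(ids)), call. = FALSE)
  sum(ids[seq_len(k)] %in% essential)
}

#' Cutoff-sweep precision-recall curve
#'
#' For every cutoff K = 1..n the top K proteins are called candidate
#' essentials: precision(K) = TP(K)/K and recall(K) = TP(K)/E, where E is
#' the number of essential proteins present in the ranking. Points are
#' returned at every K, uninterpolated.
#'
#' @inheritParams topKEssentialCount
#' @return data.frame with columns \code{k}, \code{tp}, \code{recall},
#'   \code{precision}, in increasing K.
#' @export
prCurve <- function(ranking, essential) {
  ids <- rankingIds(ranking)
  hit <- ids %in% essential
  e <- sum(hit)
  if (e == 0L)
    stop("no essential protein occurs in the ranking", call. = FALSE)
  tp <- cumsum(hit)
  k <- seq_along(ids)
  data.frame(k = k, tp = tp, recall = tp / e, precision = tp / k)
}

## trapezoid area under cumulative counts y_1..y_n with y_0 = 0, unit steps
trapezoidArea <- function(y) {
  y0 <- c(0, y)
  sum((y0[-1] + y0[-length(y0)]) / 2)
}

#' Jackknife cumulative-count curve and area
#'
#' Walks the ranking from strongest to weakest prediction and accumulates
#' the count of true essentials encountered; the area under this curve
#' (trapezoid rule, unit rank steps) summarizes ranking quality. The raw
#' area is reported together with the area normalized by the perfect ranking
#' (all essentials first), so a perfect ranking scores 1. The expected curve
#' and area of a uniformly random ranking (the diagonal, y = K E / n) are
#' returned for comparison, as is the worst-case (all essentials last) area.
#'
#' @inheritParams topKEssentialCount
#' @return list with elements \code{points} (data.frame \code{rank},
#'   \code{cumulative}, \code{random}), \code{auc} (raw),
#'   \code{aucNormalized}, \code{randomAucNormalized},
#'   \code{worstAucNormalized}.
#' @export
jackknifeCurve <- function(ranking, essential) {
  ids <- rankingIds(ranking)
  hit <- ids %in% essential
  e <- sum(hit)
  if (e == 0L)
    stop("no essential protein occurs in the ranking", call. = FALSE)
  n <- length(ids)
  y <- cumsum(hit)
  auc <- trapezoidArea(y)
  perfect <- trapezoidArea(cumsum(c(rep(TRUE, e), rep(FALSE, n - e))))
  worst <- trapezoidArea(cumsum(c(rep(FALSE, n - e), rep(TRUE, e))))
  randomY <- seq_len(n) * e / n
  list(
    points = data.frame(rank = seq_len(n), cumulative = y, random = randomY),
    auc = auc,
    aucNormalized = auc / perfect,
    randomAucNormalized = trapezoidArea(randomY) / perfect,
    worstAucNormalized = worst / perfect)
}

#' Relative improvement between two jackknife areas
#'
#' \code{(a - b) / b}, the fractional improvement of area \code{a} over
#' area \code{b} (multiply by 100 for percent).
#'
#' @param a,b areas (raw or normalized, consistently).
#' @return numeric.
#' @export
aucImprovement <- function(a, b) (a - b) / b

#' Overlap analysis between two rankings' top K
#'
#' Compares the top-K sets of a reference ranking A and a competitor B:
#' the overlap \code{|A n B|}, the proteins found only by B \code{|B - A|},
#' how many of those are non-essential, and what fraction of those
#' non-essentials the reference ranking itself places low (outside its top
#' \code{n * (1 - lowFraction)} positions; by default "low" means the bottom
#' 75\% of A's ranking — an interpretation knob, not a fixed convention).
#'
#' @param rankingA,rankingB rankings (data.frame or ordered id vector).
#' @param essential character vector of essential protein ids.
#' @param k top-K cutoff.
#' @param lowFraction fraction of A's ranking counted as "low", from the
#'   bottom; default 0.75.
#' @return list with \code{overlap}, \code{onlyB}, \code{nonEssentialOnlyB},
#'   \code{pctNonEssentialLowInA} (percent, \code{NaN} when there are no
#'   non-essential B-only proteins).
#' @export
overlapAnalysis <- function(rankingA, rankingB, essential, k,
    lowFraction = 0.75) {
  a <- rankingIds(rankingA)
  b <- rankingIds(rankingB)
  stopifnot(k >= 1L, k <= length(a), k <= length(b))
  topA <- a[seq_len(k)]
  topB <- b[seq_len(k)]
  onlyB <- setdiff(topB, topA)
  nonEss <- onlyB[!onlyB %in% essential]
  cutRank <- ceiling(length(a) * (1 - lowFraction))
  posInA <- match(nonEss, a)
  low <- sum(!is.na(posInA) & posInA > cutRank) + sum(is.na(posInA))
  list(overlap = length(intersect(topA, topB)), onlyB = length(onlyB),
    nonEssentialOnlyB = length(nonEss),
    pctNonEssentialLowInA = 100 * low / length(nonEss))
}

#' Degree centrality baseline ranking
#'
#' Ranks proteins by their PPI degree, descending, with ties broken by
#' ascending identifier; the classical DC baseline.
#'
#' @param network a \linkS4class{PpiNetwork}.
#' @return data.frame with columns \code{rank}, \code{protein}, \code{score}
#'   (the degree).
#' @export
degreeCentralityBaseline <- function(network) {
  stopifnot(is(network, "PpiNetwork"))
  deg <- Matrix::colSums(adjacencyMatrix(network))
  rankProteins(stats::setNames(as.numeric(deg), proteinIds(network)))
}

#' Full evaluation report for one ranking
#'
#' Bundles top-K counts at the requested cutoffs, the PR curve and the
#' jackknife curve into one list (JSON-serializable apart from the curve
#' data.frames).
#'
#' @inheritParams topKEssentialCount
#' @param ks cutoffs for the top-K counts.
#' @return list with \code{topk} (named integer vector), \code{pr}
#'   (data.frame), \code{jackknife} (list, see [jackknifeCurve()]).
#' @export
evaluationReport <- function(ranking, essential,
    ks = c(100L, 200L, 300L, 400L, 500L, 600L)) {
  ids <- rankingIds(ranking)
  ks <- ks[ks <= length(ids)]
  topk <- vapply(ks, function(k) topKEssentialCount(ids, essential, k), 0L)
  names(topk) <- paste0("top", ks)
  list(topk = topk, pr = prCurve(ids, essential),
    jackknife = jackknifeCurve(ids, essential))
}
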