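## Restart (jump) vector: per-protein orthology conservation times best
## subcellular compartment score, L1-normalized into a distribution.

#' Orthology conservation scores
#'
#' Max-normalized ortholog species counts: \code{I(i) = NI(i) / max_j NI(j)},
#' where NI(i) is the number of reference organisms with an identified
#' ortholog of protein i. Proteins missing from \code{counts} get NI = 0.
#' If every count is 0 all scores are 0, with a warning.
#'
#' @param counts named non-negative integer vector of ortholog counts (see
#'   [readOrthologCounts()]).
#' @param network a \linkS4class{PpiNetwork} (or character id vector).
#' @return named numeric vector I of length n with entries in [0, 1].
#' @examples
#' orthologyScores(c(P2 = 5, P3 = 10), c("P1", "P2", "P3")) # 0, 0.5, 1
#' @export
orthologyScores <- function(counts, network) {
  ids <- if (is.character(network)) network else proteinIds(network)
  stopifnot(is.numeric(counts), all(counts >= 0))
  ni <- counts[match(ids, names(counts))]
  ni[is.na(ni)] <- 0
  mx <- max(ni)
  if (mx == 0) {
    if (length(counts))
      warning("all ortholog counts are 0 on this network; orthology scores are all 0",
        call. = FALSE)
    return(stats::setNames(numeric(length(ids)), ids))
  }
  stats::setNames(as.numeric(ni) / mx, ids)
}

#' Subcellular compartment scores
#'
#' Score of each compartment: its number of annotated indexed proteins
#' divided by the size of the largest compartment,
#' \code{F_S(j) = |p_j| / max_k |p_k|}.
#'
#' @param table an \linkS4class{AnnotationTable} of kind \code{"subcellular"}.
#' @param network a \linkS4class{PpiNetwork} (or character id vector);
#'   annotations outside the index are ignored.
#' @return named numeric vector over compartments (empty for an empty table).
#' @export
compartmentScores <- function(table, network) {
  stopifnot(is(table, "AnnotationTable"))
  if (table@kind != "subcellular")
    stop("compartmentScores requires a 'subcellular' annotation table",
      call. = FALSE)
  ids <- if (is.character(network)) network else proteinIds(network)
  pr <- table@pairs
  pr <- pr[pr$protein %in% ids, , drop = FALSE]
  if (nrow(pr) == 0L) return(stats::setNames(numeric(), character()))
  sz <- table(pr$term)
  stats::setNames(as.numeric(sz) / max(sz), names(sz))
}

#' Per-protein subcellular localization scores
#'
#' \code{S(i)} is the maximum compartment score over the compartments the
#' protein is annotated to; 0 for proteins with no localization annotation.
#'
#' @param table an \linkS4class{AnnotationTable} of kind \code{"subcellular"}.
#' @param network a \linkS4class{PpiNetwork} (or character id vector).
#' @param fs optional precomputed compartment scores (from
#'   [compartmentScores()]); computed from \code{table} when \code{NULL}.
#' @return named numeric vector S of length n with entries in [0, 1].
#' @export
subcellularScores <- function(table, network, fs = NULL) {
  stopifnot(is(table, "AnnotationTable"))
  if (table@kind != "subcellular")
    stop("subcellularScores requires a 'subcellular' annotation table",
      call. = FALSE)
  ids <- if (is.character(network)) network else proteinIds(network)
  if (is.null(fs)) fs <- compartmentScores(table, ids)
  s <- stats::setNames(numeric(length(ids)), ids)
  pr <- table@pairs
  pr <- pr[pr$protein %in% ids & pr$term %in% names(fs), , drop = FALSE]
  if (nrow(pr) > 0L) {
    best <- tapply(fs[pr$term], pr$protein, max)
    s[names(best)] <- as.numeric(best)
  }
  s
}

#' Build the jump (restart) probability vector
#'
#' Combines orthology and localization per protein, \code{d_i = I(i) * S(i)},
#' and L1-normalizes the result into a distribution (disable with
#' \code{normalize = FALSE}). If every raw product is 0 the vector falls
#' back to the uniform distribution 1/n, with a warning, so the restart term
#' of the iteration stays a proper distribution.
#'
#' @param orthology numeric vector I of length n, entries in [0, 1].
#' @param subcellular numeric vector S of length n, entries in [0, 1].
#' @param proteins character vector of protein identifiers (defaults to the
#'   names of \code{orthology}).
#' @param normalize L1-normalize to sum 1 (default \code{TRUE}).
#' @return a \linkS4class{JumpVector}.
#' @export
buildJumpVector <- function(orthology, subcellular,
    proteins = names(orthology), normalize = TRUE) {
  if (length(orthology) != length(subcellular))
    stop("orthology and subcellular score vectors differ in length",
      call. = FALSE)
  if (is.null(proteins))
    proteins <- paste0("p", seq_along(orthology))
  stopifnot(length(proteins) == length(orthology))
  d <- as.numeric(orthology) * as.numeric(subcellular)
  if (any(d < 0)) stop("negative restart weight", call. = FALSE)
  tot <- sum(d)
  if (tot == 0) {
    warning("all restart weights are 0; falling back to the uniform distribution",
      call. = FALSE)
    d <- rep.int(1 / length(d), length(d))
    tot <- 1
  }
  if (normalize) d <- d / tot
  methods::new("JumpVector", proteins = as.character(proteins), d = d,
    orthology = as.numeric(orthology),
    subcellular = as.numeric(subcellular),
    normalized = isTRUE(normalize) || sum(d) == 1)
}

#' Uniform jump vector
#'
#' Convenience constructor for the uniform restart distribution 1/n, used
#' when no orthology/localization data are available.
#'
#' @param network a \linkS4class{PpiNetwork} (or character id vector).
#' @return a \linkS4class{JumpVector}.
#' @export
uniformJumpVector <- function(network) {
  ids <- if (is.character(network)) network else proteinIds(network)
  n <- length(ids)
  methods::new("JumpVector", proteins = ids, d = rep.int(1 / n, n),
    orthology = rep.int(1, n), subcellular = rep.int(1, n),
    normalized = TRUE)
}

#' Dump a jump vector as TSV
#'
#' Writes \code{protein}, \code{orthology}, \code{subcellular}, \code{d}.
#'
#' @param jump a \linkS4class{JumpVector}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeJumpVector <- function(jump, path) {
  stopifnot(is(jump, "JumpVector"))
  utils::write.table(
    data.frame(protein = jump@proteins,
      orthology = sprintf("%.17g", jump@orthology),
      subcellular = sprintf("%.17g", jump@subcellular),
      d = sprintf("%.17g", jump@d)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
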