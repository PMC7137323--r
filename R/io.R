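## Input readers for the five annotation/network tables plus the essential
## protein list. All readers are strict about malformed lines (they name the
## offending line), skip '#' comment lines and blank lines, and match
## identifiers exactly (case-sensitive, no aliasing).

readTokenLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

splitColumns <- function(lines, lineno, ncol, path) {
  tok <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(tok, length, 1L) != ncol)
  if (length(bad)) {
    stop(sprintf("malformed line %d in '%s': expected %d columns, got %d",
      lineno[bad[1L]], path, ncol, length(tok[[bad[1L]]])), call. = FALSE)
  }
  do.call(rbind, tok)
}

#' Read an undirected PPI edge list
#'
#' Reads a two-column whitespace/tab separated file of interacting protein
#' pairs. Self-interactions are removed and duplicate edges (in either
#' orientation) are collapsed, so the result carries each undirected edge
#' exactly once. The protein index covers every identifier appearing in any
#' edge, in order of first appearance.
#'
#' @param path path to the edge list file; lines beginning with \code{#} are
#'   skipped.
#' @return a \linkS4class{PpiNetwork}.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "C\tC", "B\tC"), f)
#' net <- readPpiEdges(f)
#' networkEdges(net, ids = TRUE)
#' @export
readPpiEdges <- function(path) {
  tk <- readTokenLines(path)
  if (length(tk$lines) == 0L)
    stop(sprintf("empty PPI edge file: '%s'", path), call. = FALSE)
  m <- splitColumns(tk$lines, tk$lineno, 2L, path)
  keep <- m[, 1L] != m[, 2L]
  nSelf <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  # index only proteins that survive self-loop removal
  ids <- unique(as.vector(t(m)))
  i <- match(m[, 1L], ids)
  j <- match(m[, 2L], ids)
  e <- unique(cbind(pmin(i, j), pmax(i, j)))
  if (nSelf > 0L)
    message(sprintf("readPpiEdges: removed %d self-interaction(s)", nSelf))
  dup <- sum(keep) - nrow(e)
  if (dup > 0L)
    message(sprintf("readPpiEdges: collapsed %d repeated interaction(s)", dup))
  if (nrow(e) == 0L)
    stop(sprintf("no usable edges in '%s' after filtering", path),
      call. = FALSE)
  newPpiNetwork(ids, e)
}

#' Construct a PpiNetwork from identifiers and an index edge matrix
#'
#' @param proteins character vector of unique identifiers.
#' @param edges two-column matrix of integer indices; canonicalized to
#'   \code{i < j}, with self-loops and duplicates removed.
#' @return a \linkS4class{PpiNetwork}.
#' @export
newPpiNetwork <- function(proteins, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  e <- unique(cbind(pmin(edges[, 1L], edges[, 2L]),
                    pmax(edges[, 1L], edges[, 2L])))
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  dimnames(e) <- NULL
  methods::new("PpiNetwork", proteins = as.character(proteins), edges = e)
}

#' Read a two-column protein annotation table
#'
#' Reads (protein, term) pairs of a given kind: \code{"domain"} (Pfam-style
#' domain identifiers), \code{"go"} (GO term identifiers) or
#' \code{"subcellular"} (compartment identifiers). Duplicate pairs are
#' collapsed. Proteins that do not occur in a PPI network are retained here;
#' downstream computations ignore them and report the count.
#'
#' @param path path to the TSV file (tab or whitespace separated).
#' @param kind annotation kind.
#' @return an \linkS4class{AnnotationTable}. An empty file yields an empty
#'   (valid) table.
#' @export
readAnnotations <- function(path,
    kind = c("domain", "go", "subcellular")) {
  kind <- match.arg(kind)
  tk <- readTokenLines(path)
  if (length(tk$lines) == 0L) {
    return(newAnnotationTable(kind, character(), character()))
  }
  m <- splitColumns(tk$lines, tk$lineno, 2L, path)
  newAnnotationTable(kind, m[, 1L], m[, 2L])
}

#' Construct an AnnotationTable from protein/term vectors
#'
#' @param kind annotation kind.
#' @param protein,term character vectors of equal length; duplicate pairs are
#'   collapsed.
#' @return an \linkS4class{AnnotationTable}.
#' @export
newAnnotationTable <- function(kind, protein, term) {
  pr <- unique(data.frame(protein = as.character(protein),
    term = as.character(term), stringsAsFactors = FALSE))
  rownames(pr) <- NULL
  methods::new("AnnotationTable", kind = kind, pairs = pr)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Alternative GO input path: extracts (DB Object ID, GO ID) pairs from the
#' standard 17-column Gene Association File format, ignoring evidence codes
#' and qualifiers. Rows whose qualifier contains \code{NOT} are dropped.
#'
#' @param path path to an (uncompressed) GAF 2.x file; \code{!} header lines
#'   are skipped.
#' @return an \linkS4class{AnnotationTable} of kind \code{"go"}.
#' @export
readGaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(!|#|$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(newAnnotationTable("go", character(), character()))
  tok <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(tok, length, 1L) < 5L)
  if (length(bad))
    stop(sprintf("malformed GAF line %d in '%s': fewer than 5 columns",
      which(keep)[bad[1L]], path), call. = FALSE)
  qualifier <- vapply(tok, `[`, "", 4L)
  tok <- tok[!grepl("(^|\\|)NOT(\\||$)", qualifier)]
  newAnnotationTable("go",
    vapply(tok, `[`, "", 2L), vapply(tok, `[`, "", 5L))
}

#' Filter GO terms by annotation frequency
#'
#' Retains exactly the GO terms annotating at least \code{minCount} and at
#' most \code{maxCount} distinct proteins, dropping all pairs of excluded
#' terms. This removes terms that are too specific or too general to carry
#' co-annotation signal. Counts are taken over the distinct proteins present
#' in \code{table} itself (restrict the table to a network first if the
#' filter should be network-relative).
#'
#' @param table an \linkS4class{AnnotationTable} of kind \code{"go"}.
#' @param minCount,maxCount inclusive frequency bounds; defaults 10 and 200.
#' @return the filtered \linkS4class{AnnotationTable}.
#' @export
filterGoTerms <- function(table, minCount = 10L, maxCount = 200L) {
  stopifnot(is(table, "AnnotationTable"))
  if (table@kind != "go")
    stop("filterGoTerms applies to GO annotation tables only", call. = FALSE)
  stopifnot(minCount >= 1L, minCount <= maxCount)
  pr <- table@pairs
  if (nrow(pr) == 0L) return(table)
  cnt <- table(pr$term)
  keep <- names(cnt)[cnt >= minCount & cnt <= maxCount]
  newAnnotationTable("go", pr$protein[pr$term %in% keep],
    pr$term[pr$term %in% keep])
}

#' Restrict an annotation table to a protein index
#'
#' Drops pairs whose protein does not occur in the network; reports how many
#' annotated proteins were outside the index.
#'
#' @param table an \linkS4class{AnnotationTable}.
#' @param network a \linkS4class{PpiNetwork} (or character vector of ids).
#' @param quiet suppress the unmatched-protein message.
#' @return the restricted \linkS4class{AnnotationTable}.
#' @export
restrictToNetwork <- function(table, network, quiet = FALSE) {
  stopifnot(is(table, "AnnotationTable"))
  ids <- if (is.character(network)) network else proteinIds(network)
  pr <- table@pairs
  inNet <- pr$protein %in% ids
  nOut <- length(unique(pr$protein[!inNet]))
  if (nOut > 0L && !quiet)
    message(sprintf(
      "restrictToNetwork: ignoring %d annotated protein(s) not in the network",
      nOut))
  newAnnotationTable(table@kind, pr$protein[inNet], pr$term[inNet])
}

#' Read per-protein ortholog species counts
#'
#' Reads a two-column table mapping protein identifier to the number of
#' reference organisms in which an ortholog of the protein was identified
#' (InParanoid-style NI counts). Counts must be non-negative integers;
#' duplicate protein rows are an error unless the counts agree.
#'
#' @param path path to the TSV file.
#' @return named integer vector of counts.
#' @export
readOrthologCounts <- function(path) {
  tk <- readTokenLines(path)
  if (length(tk$lines) == 0L) return(stats::setNames(integer(), character()))
  m <- splitColumns(tk$lines, tk$lineno, 2L, path)
  cnt <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(cnt) || any(cnt < 0L))
    stop(sprintf("non-integer or negative ortholog count in '%s'", path),
      call. = FALSE)
  df <- unique(data.frame(p = m[, 1L], c = cnt))
  if (anyDuplicated(df$p))
    stop(sprintf("conflicting ortholog counts for a protein in '%s'", path),
      call. = FALSE)
  stats::setNames(df$c, df$p)
}

#' Read a known essential protein list
#'
#' One identifier per line; duplicates are collapsed. The list is used for
#' evaluation only. When a network is supplied, the number of listed proteins
#' absent from it is reported (they stay in the returned set).
#'
#' @param path path to the list file.
#' @param network optional \linkS4class{PpiNetwork} for the unmatched count.
#' @return character vector of unique identifiers; an empty file yields an
#'   empty vector with a warning.
#' @export
readEssentialList <- function(path, network = NULL) {
  tk <- readTokenLines(path)
  if (length(tk$lines) == 0L) {
    warning(sprintf("essential protein list '%s' is empty", path),
      call. = FALSE)
    return(character())
  }
  ids <- unique(trimws(tk$lines))
  ids <- ids[nzchar(ids)]
  if (!is.null(network)) {
    nOut <- sum(!ids %in% proteinIds(network))
    if (nOut > 0L)
      message(sprintf(
        "readEssentialList: %d of %d essential protein(s) not in the network",
        nOut, length(ids)))
  }
  ids
}

#' Write a protein ranking as TSV
#'
#' Writes the columns \code{rank}, \code{protein}, \code{score} with scores
#' at full double precision (round-trippable via \code{read.delim}).
#'
#' @param ranking data.frame as returned by [rankProteins()].
#' @param path output path.
#' @param topN optional truncation to the first \code{topN} rows.
#' @return invisibly, the written data.frame.
#' @export
writeRanking <- function(ranking, path, topN = NULL) {
  stopifnot(is.data.frame(ranking),
    all(c("rank", "protein", "score") %in% names(ranking)))
  out <- ranking[, c("rank", "protein", "score")]
  if (!is.null(topN)) out <- utils::head(out, topN)
  out$score <- sprintf("%.17g", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(out)
}

#' Write an annotation table as two-column TSV
#'
#' @param table an \linkS4class{AnnotationTable} or a named integer vector of
#'   ortholog counts.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeAnnotations <- function(table, path) {
  if (is(table, "AnnotationTable")) {
    utils::write.table(table@pairs, path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  } else if (is.numeric(table) && !is.null(names(table))) {
    utils::write.table(
      data.frame(names(table), as.integer(table)), path, sep = "\t",
      quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else stop("unsupported table type", call. = FALSE)
  invisible(path)
}
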