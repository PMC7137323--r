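## Synthetic input bundles with planted essential proteins. The generator
## emulates the statistical structure the method assumes: essential proteins
## are high-degree hubs of a scale-free PPI network, are domain-rich, share
## GO annotations, are conserved across many organisms, and concentrate in a
## favored (large) compartment. A single `bias` multiplier controls all five
## signals; bias = 1 is the exact null (labels independent of every feature).

subStreamSeeds <- function(seed, k = 6L) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

## one draw mechanism shared by domain/GO/compartment assignment: each of
## `count` draws comes from the enriched subset with probability pEnrich,
## otherwise from the full pool (optionally weighted)
drawTerms <- function(count, pool, enriched, pEnrich, poolWeights = NULL) {
  if (count == 0L) return(character())
  fromEnriched <- stats::runif(count) < pEnrich
  out <- character(count)
  nE <- sum(fromEnriched)
  if (nE > 0L)
    out[fromEnriched] <- sample(enriched, nE, replace = TRUE)
  if (nE < count)
    out[!fromEnriched] <- sample(pool, count - nE, replace = TRUE,
      prob = poolWeights)
  unique(out)
}

#' Generate a synthetic input bundle with planted essential proteins
#'
#' Produces, deterministically for a fixed seed, all six inputs the method
#' consumes: a preferential-attachment PPI network in which planted
#' essentials attract edges at \code{bias}-scaled rates; domain and GO
#' annotation tables in which essentials carry \code{bias}-scaled numbers of
#' annotations drawn preferentially from small enriched term pools (so they
#' share them); ortholog species counts with a \code{bias}-scaled mean for
#' essentials; a subcellular table in which essentials favor the largest
#' compartment; and the planted essential list itself.
#'
#' With \code{bias = 1} every feature is drawn identically for essential and
#' non-essential proteins: the labels carry no signal and any ranking
#' recovers them only at chance rate. Each data type is driven by its own
#' seeded random stream derived from \code{seed}, so e.g. changing
#' \code{nGoTerms} does not perturb the network topology.
#'
#' @param nProteins number of proteins (all appear in the network).
#' @param nEssential number of planted essential proteins
#'   (< \code{nProteins}).
#' @param bias signal strength multiplier >= 1; 1 is the null model.
#' @param attachEdges edges attached by each incoming node of the
#'   preferential-attachment growth (also sizes the seed clique).
#' @param nDomains,nGoTerms,nCompartments annotation vocabulary sizes.
#' @param seed integer seed.
#' @return a list (class \code{heptBundle}) with elements \code{network}
#'   (\linkS4class{PpiNetwork}), \code{domains}, \code{go},
#'   \code{subcellular} (\linkS4class{AnnotationTable}s), \code{orthologs}
#'   (named integer vector), \code{essential} (character vector) and
#'   \code{config}.
#' @examples
#' b <- syntheticBundle(nProteins = 50, nEssential = 5, bias = 5, seed = 1)
#' b$network
#' @export
syntheticBundle <- function(nProteins = 200L, nEssential = 20L, bias = 5,
    attachEdges = 3L, nDomains = 60L, nGoTerms = 40L, nCompartments = 8L,
    seed = 1L) {
  stopifnot(nEssential < nProteins, nProteins >= attachEdges + 2L,
    bias >= 1, attachEdges >= 1L, nDomains >= 1L, nGoTerms >= 1L,
    nCompartments >= 1L)
  ids <- sprintf("P%0*d", nchar(as.character(nProteins)), seq_len(nProteins))
  ss <- subStreamSeeds(seed, 6L)
  biasOf <- function(isEss) ifelse(isEss, bias, 1)

  ## stream 1: planted labels
  set.seed(ss[1L])
  essential <- sort(sample(ids, nEssential))
  isEss <- ids %in% essential

  ## stream 2: topology — preferential attachment with biased target weights
  set.seed(ss[2L])
  arrival <- sample.int(nProteins)
  m0 <- attachEdges + 1L
  seedNodes <- arrival[seq_len(m0)]
  edges <- t(utils::combn(seedNodes, 2L))
  deg <- integer(nProteins)
  deg[seedNodes] <- m0 - 1L
  present <- logical(nProteins)
  present[seedNodes] <- TRUE
  for (v in arrival[(m0 + 1L):nProteins]) {
    cand <- which(present)
    w <- (deg[cand] + 1) * biasOf(isEss[cand])
    tgt <- cand[sample.int(length(cand), min(attachEdges, length(cand)),
      prob = w)]
    edges <- rbind(edges, cbind(v, tgt))
    deg[v] <- deg[v] + length(tgt)
    deg[tgt] <- deg[tgt] + 1L
    present[v] <- TRUE
  }
  network <- newPpiNetwork(ids, edges)

  ## stream 3: domains — essentials are domain-rich and share enriched ones
  set.seed(ss[3L])
  domPool <- sprintf("D%03d", seq_len(nDomains))
  domEnriched <- domPool[seq_len(max(1L, round(0.2 * nDomains)))]
  fracDom <- length(domEnriched) / nDomains
  domP <- character(); domT <- character()
  for (i in seq_len(nProteins)) {
    k <- stats::rpois(1L, 1.5 * biasOf(isEss[i]))
    terms <- drawTerms(k, domPool, domEnriched,
      min(1, fracDom * biasOf(isEss[i])))
    domP <- c(domP, rep(ids[i], length(terms))); domT <- c(domT, terms)
  }
  domains <- newAnnotationTable("domain", domP, domT)

  ## stream 4: GO terms — essentials co-annotated to enriched terms
  set.seed(ss[4L])
  goPool <- sprintf("GO:%07d", seq_len(nGoTerms))
  goEnriched <- goPool[seq_len(max(1L, round(0.2 * nGoTerms)))]
  fracGo <- length(goEnriched) / nGoTerms
  goP <- character(); goT <- character()
  for (i in seq_len(nProteins)) {
    k <- stats::rpois(1L, 3 * biasOf(isEss[i]))
    terms <- drawTerms(k, goPool, goEnriched,
      min(1, fracGo * biasOf(isEss[i])))
    goP <- c(goP, rep(ids[i], length(terms))); goT <- c(goT, terms)
  }
  go <- newAnnotationTable("go", goP, goT)

  ## stream 5: ortholog species counts out of 100 reference organisms
  set.seed(ss[5L])
  orthologs <- stats::setNames(stats::rbinom(nProteins, 100L,
    pmin(0.9, 0.08 * biasOf(isEss))), ids)

  ## stream 6: compartments — sizes decay across the vocabulary; essentials
  ## favor the largest compartment
  set.seed(ss[6L])
  compPool <- sprintf("C%02d", seq_len(nCompartments))
  compW <- rev(seq_len(nCompartments))
  pFavBase <- compW[1L] / sum(compW)
  subP <- character(); subT <- character()
  for (i in seq_len(nProteins)) {
    k <- 1L + stats::rpois(1L, 0.5)
    terms <- drawTerms(k, compPool, compPool[1L],
      min(1, pFavBase * biasOf(isEss[i])), poolWeights = compW)
    subP <- c(subP, rep(ids[i], length(terms))); subT <- c(subT, terms)
  }
  subcellular <- newAnnotationTable("subcellular", subP, subT)

  structure(list(network = network, domains = domains, go = go,
    subcellular = subcellular, orthologs = orthologs,
    essential = essential,
    config = list(nProteins = nProteins, nEssential = nEssential,
      bias = bias, attachEdges = attachEdges, nDomains = nDomains,
      nGoTerms = nGoTerms, nCompartments = nCompartments, seed = seed)),
    class = "heptBundle")
}

#' Write a synthetic bundle to a directory
#'
#' Writes the six plain-text files in exactly the formats the readers
#' consume: \code{ppi.tsv}, \code{domains.tsv}, \code{go.tsv},
#' \code{subcellular.tsv}, \code{orthologs.tsv}, \code{essential.txt}.
#'
#' @param bundle a bundle from [syntheticBundle()].
#' @param dir output directory (created if needed).
#' @param force overwrite existing files (default \code{FALSE}: an existing
#'   target file is an error).
#' @return invisibly, a named character vector of the six file paths.
#' @export
writeBundle <- function(bundle, dir, force = FALSE) {
  stopifnot(inherits(bundle, "heptBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ppi = "ppi.tsv", domains = "domains.tsv", go = "go.tsv",
    subcellular = "subcellular.tsv", orthologs = "orthologs.tsv",
    essential = "essential.txt")
  paths <- stats::setNames(file.path(dir, paths), names(paths))
  if (!force) {
    ex <- paths[file.exists(paths)]
    if (length(ex))
      stop(sprintf("refusing to overwrite existing file(s): %s (use force = TRUE)",
        paste(basename(ex), collapse = ", ")), call. = FALSE)
  }
  e <- networkEdges(bundle$network, ids = TRUE)
  utils::write.table(e, paths[["ppi"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeAnnotations(bundle$domains, paths[["domains"]])
  writeAnnotations(bundle$go, paths[["go"]])
  writeAnnotations(bundle$subcellular, paths[["subcellular"]])
  writeAnnotations(bundle$orthologs, paths[["orthologs"]])
  writeLines(bundle$essential, paths[["essential"]])
  invisible(paths)
}

#' Read a bundle directory back into memory
#'
#' Counterpart of [writeBundle()]: reads the six files of a bundle
#' directory. Round-tripping a bundle reproduces the identical edge set and
#' annotation pair sets.
#'
#' @param dir directory holding the six bundle files.
#' @return a list of class \code{heptBundle} (without the generator
#'   \code{config}).
#' @export
readBundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  network <- readPpiEdges(p("ppi.tsv"))
  structure(list(network = network,
    domains = readAnnotations(p("domains.tsv"), "domain"),
    go = readAnnotations(p("go.tsv"), "go"),
    subcellular = readAnnotations(p("subcellular.tsv"), "subcellular"),
    orthologs = readOrthologCounts(p("orthologs.tsv")),
    essential = suppressMessages(readEssentialList(p("essential.txt"))),
    config = NULL), class = "heptBundle")
}

#' Run the full method on an in-memory bundle
#'
#' Applies the GO frequency filter, builds the relation tensor and the jump
#' vector from the bundle's tables, and runs the iteration.
#'
#' @param bundle a bundle (from [syntheticBundle()] or [readBundle()]).
#' @param alpha,epsilon,maxIter,normalizeState see [runHept()].
#' @param goMin,goMax see [filterGoTerms()].
#' @param restrictToPpi,clipCoNeighbor see [buildTensor()].
#' @param normalizeD see [buildJumpVector()].
#' @return list with \code{result} (\linkS4class{HeptResult}),
#'   \code{ranking} (data.frame), \code{tensor}, \code{jump},
#'   \code{network} and \code{essential}.
#' @export
runHeptOnBundle <- function(bundle, alpha = 0.3, epsilon = 1e-8,
    maxIter = 1000L, normalizeState = TRUE, goMin = 10L, goMax = 200L,
    restrictToPpi = FALSE, clipCoNeighbor = TRUE, normalizeD = TRUE) {
  stopifnot(inherits(bundle, "heptBundle"))
  network <- bundle$network
  goTab <- filterGoTerms(
    restrictToNetwork(bundle$go, network, quiet = TRUE), goMin, goMax)
  tensor <- buildTensor(network, domains = bundle$domains, go = goTab,
    restrictToPpi = restrictToPpi, clipCoNeighbor = clipCoNeighbor)
  I <- orthologyScores(bundle$orthologs, network)
  S <- subcellularScores(bundle$subcellular, network)
  jump <- buildJumpVector(I, S, proteins = proteinIds(network),
    normalize = normalizeD)
  result <- runHept(tensor, jump, alpha = alpha, epsilon = epsilon,
    maxIter = maxIter, normalizeState = normalizeState)
  list(result = result, ranking = rankProteins(result), tensor = tensor,
    jump = jump, network = network, essential = bundle$essential)
}
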