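#' Import dated mutations and pair coalescence times from tree-sequence
#' tables
#'
#' Adapter for succinct tree-sequence output (tskit-style node / edge /
#' site / mutation tables, e.g. dumped to text by a coalescent simulator).
#' Each mapped mutation yields an age interval equal to the times of the
#' node below and the node above its branch in the local tree (the node's
#' parent at the mutation's position); the carrier count is the number of
#' samples below that branch. For requested sample pairs, the TMRCA is
#' extracted in every local tree together with its genomic span, giving
#' the ground truth that [directMLEFromTimes()] consumes.
#'
#' @param nodes data.frame with columns `id`, `time` (generations),
#'   `isSample` (0/1)
#' @param edges data.frame with columns `left`, `right` (bp, half-open),
#'   `parent`, `child` (node ids)
#' @param sites data.frame with columns `id`, `position` (bp, 0-based),
#'   `ancestralState`
#' @param muts data.frame with columns `site` (site id), `node`,
#'   `derivedState`
#' @param samplePairs optional data.frame with columns `a`, `b` (sample
#'   node ids)
#' @param generationTime years per generation for the emitted table
#' @param tOut age cap in generations for root-branch mutations
#' @param chrom chromosome label for the emitted table
#' @return list with `table` (a [DatedMutationTable-class]), `pairTimes`
#'   (data.frame `a`, `b`, `T`, `t0`, `span`), and `skipped` (number of
#'   unmapped/undated/non-ACGT mutations dropped)
#' @export
importTreeTables <- function(nodes, edges, sites, muts, samplePairs = NULL,
                             generationTime = 28,
                             tOut = 1e7 / generationTime, chrom = "chr1") {
  stopifnot(all(c("id", "time") %in% names(nodes)),
            all(c("left", "right", "parent", "child") %in% names(edges)),
            all(c("id", "position", "ancestralState") %in% names(sites)),
            all(c("site", "node", "derivedState") %in% names(muts)))
  if (is.null(nodes$isSample)) nodes$isSample <- 0
  sampleIds <- nodes$id[nodes$isSample > 0]
  nSamples <- length(sampleIds)
  idTime <- stats::setNames(nodes$time, as.character(nodes$id))

  bp <- sort(unique(c(edges$left, edges$right)))
  mutPos <- sites$position[match(muts$site, sites$id)]
  mutAnc <- toupper(sites$ancestralState[match(muts$site, sites$id)])
  mutDer <- toupper(muts$derivedState)

  chain <- function(par, id) {
    out <- id
    while (!is.na(par[as.character(id)])) {
      id <- par[as.character(id)]
      out <- c(out, id)
    }
    out
  }

  recs <- list()
  pairRecs <- list()
  skipped <- 0L
  for (k in seq_len(length(bp) - 1)) {
    x <- bp[k]; y <- bp[k + 1]
    act <- edges$left <= x & edges$right >= y
    par <- stats::setNames(edges$parent[act], as.character(edges$child[act]))
    chains <- lapply(sampleIds, chain, par = par)
    names(chains) <- as.character(sampleIds)
    carriers <- table(unlist(chains))

    inTree <- which(mutPos >= x & mutPos < y)
    for (i in inTree) {
      nd <- muts$node[i]
      lo <- idTime[as.character(nd)]
      p <- par[as.character(nd)]
      hi <- if (is.na(p)) tOut else idTime[as.character(p)]
      ok <- !is.na(lo) && is.finite(lo) && hi > lo &&
        mutAnc[i] %in% DNA_BASES && mutDer[i] %in% DNA_BASES &&
        mutAnc[i] != mutDer[i]
      if (!ok) { skipped <- skipped + 1L; next }
      cc <- carriers[as.character(nd)]
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = chrom, pos = as.integer(floor(mutPos[i])) + 1L,
        anc = mutAnc[i], der = mutDer[i],
        ageLower = unname(lo), ageUpper = unname(min(hi, tOut)),
        carrierCount = as.integer(if (is.na(cc)) 0 else cc),
        isFixed = is.na(p) &&
          !is.na(cc) && as.integer(cc) == nSamples,
        stringsAsFactors = FALSE)
    }
    if (!is.null(samplePairs)) {
      for (j in seq_len(nrow(samplePairs))) {
        ca <- chains[[as.character(samplePairs$a[j])]]
        cb <- chains[[as.character(samplePairs$b[j])]]
        common <- intersect(ca, cb)
        if (!length(common)) next
        tm <- min(idTime[as.character(common)])
        pairRecs[[length(pairRecs) + 1L]] <- data.frame(
          a = samplePairs$a[j], b = samplePairs$b[j], T = tm,
          t0 = max(idTime[as.character(samplePairs$a[j])],
                   idTime[as.character(samplePairs$b[j])]),
          span = y - x)
      }
    }
  }
  d <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(0), pos = integer(0), anc = character(0),
               der = character(0), ageLower = numeric(0),
               ageUpper = numeric(0), carrierCount = integer(0),
               isFixed = logical(0), stringsAsFactors = FALSE)
  if (nrow(d)) {
    dup <- duplicated(paste(d$chrom, d$pos))
    skipped <- skipped + sum(dup)
    d <- d[!dup, , drop = FALSE]
    d$isFixed <- d$isFixed & abs(d$ageUpper - tOut) < 1e-9 * tOut
  }
  list(table = DatedMutationTable(d, tOut = tOut,
                                  generationTime = generationTime,
                                  source = "tree-sequence tables"),
       pairTimes = if (length(pairRecs)) do.call(rbind, pairRecs) else NULL,
       skipped = skipped)
}
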