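#' Polarize a biallelic site against an ancestral base
#'
#' Orients the (ref, alt) allele pair so that `anc` equals the ancestral
#' genome's base at the site. Sites where the ancestral base is unknown
#' (`N`) or matches neither allele cannot be polarized and are rejected
#' (returned as `NA`).
#'
#' @param refAllele,altAllele single bases (vectors allowed)
#' @param ancestralBase ancestral genome base at the site
#' @return data.frame with columns `anc`, `der` (NA rows = rejected)
#' @export
polarizeAlleles <- function(refAllele, altAllele, ancestralBase) {
  refAllele <- toupper(refAllele); altAllele <- toupper(altAllele)
  ancestralBase <- toupper(ancestralBase)
  n <- max(length(refAllele), length(altAllele), length(ancestralBase))
  refAllele <- rep_len(refAllele, n); altAllele <- rep_len(altAllele, n)
  ancestralBase <- rep_len(ancestralBase, n)
  anc <- der <- rep(NA_character_, n)
  asRef <- ancestralBase == refAllele
  asAlt <- ancestralBase == altAllele
  ok <- ancestralBase %in% DNA_BASES & (asRef | asAlt)
  anc[ok & asRef] <- refAllele[ok & asRef]
  der[ok & asRef] <- altAllele[ok & asRef]
  anc[ok & asAlt] <- altAllele[ok & asAlt]
  der[ok & asAlt] <- refAllele[ok & asAlt]
  data.frame(anc = anc, der = der, stringsAsFactors = FALSE)
}

#' Read-level quality filter
#'
#' A read passes when its mapping quality exceeds 30, its length exceeds
#' 34 bp, it has fewer than three mismatches against the reference, and the
#' covered site lies at least `endTrim` bases from the nearer read end
#' (default 2, trimming the damage-enriched termini). All thresholds are
#' strict in the stated direction.
#'
#' @param mappingQuality,readLength,mismatchCount,offset numeric vectors
#'   (recycled); `offset` is the distance of the site from the nearer read
#'   end
#' @param endTrim bases excluded at each read end
#' @return logical vector: `TRUE` = read accepted
#' @export
filterRead <- function(mappingQuality, readLength, mismatchCount, offset,
                       endTrim = 2) {
  mappingQuality > 30 & readLength > 34 & mismatchCount < 3 &
    offset >= endTrim
}

#' Coverage-based accessibility mask
#'
#' Declares a site passing iff its depth is at least 5x and below twice the
#' mean genomic coverage. Returns merged intervals in BED convention
#' (0-based, half-open).
#'
#' @param depth numeric vector of per-site depths at consecutive positions
#' @param meanCoverage mean genomic coverage (> 0)
#' @param chrom chromosome label for the output intervals
#' @param posStart 1-based position of `depth[1]`
#' @return data.frame(chrom, start, end) of 0-based half-open intervals
#' @seealso [maskToGRanges()], [applyMask()]
#' @export
buildCoverageMask <- function(depth, meanCoverage, chrom = "chr1",
                              posStart = 1L) {
  stopifnot(meanCoverage > 0)
  pass <- depth >= 5 & depth < 2 * meanCoverage
  if (!any(pass))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(chrom = chrom,
             start = starts[keep] + posStart - 2L,   # 0-based
             end = ends[keep] + posStart - 1L)        # half-open
}

#' Convert a BED-convention mask to GRanges
#' @param bed data.frame(chrom, start, end), 0-based half-open
#' @return a `GRanges` (1-based, closed)
#' @export
maskToGRanges <- function(bed) {
  GenomicRanges::GRanges(bed$chrom,
                         IRanges::IRanges(bed$start + 1L, bed$end))
}

#' Restrict a mutation table to masked-in sites
#'
#' @param table a [DatedMutationTable-class]
#' @param mask a BED-convention data.frame or a `GRanges`
#' @return the filtered table
#' @export
applyMask <- function(table, mask) {
  if (is.data.frame(mask)) mask <- maskToGRanges(mask)
  d <- mutations(table)
  sites <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos))
  keep <- IRanges::overlapsAny(sites, mask)
  DatedMutationTable(d[keep, , drop = FALSE], tOut = tOut(table),
                     generationTime = generationTime(table),
                     source = table@source)
}

#' Distribute a mutation's age mass onto the time grid
#'
#' A mutation's age is uniform on its branch, i.e. on
#' `[ageLower, ageUpper]`. The interval is first clamped to
#' `[max(ageLower, t0), ageUpper]`; if it is empty after clamping the
#' mutation is inconsistent with the sample-age constraint and gets
#' all-zero weights (flagged in the `"inconsistent"` attribute). Otherwise
#' each bin receives mass proportional to its overlap with the clamped
#' interval, summing to 1. Degenerate (point) intervals put mass 1 on the
#' containing bin.
#'
#' @param ageLower,ageUpper numeric vectors, generations
#' @param grid a [TimeGrid-class]
#' @param t0 earliest possible coalescence time, generations
#' @return numeric matrix (length(ageLower) x nBins) with attribute
#'   `"inconsistent"` (logical vector)
#' @export
binMutationMass <- function(ageLower, ageUpper, grid, t0 = 0) {
  if (any(ageLower > ageUpper)) stop("need ageLower <= ageUpper")
  b <- boundaries(grid)
  nb <- length(b) - 1L
  n <- length(ageLower)
  lo <- pmax(ageLower, t0)
  hi <- ageUpper
  len <- hi - lo
  inconsistent <- hi < t0 | (hi == t0 & t0 > 0)
  W <- matrix(0, n, nb)
  if (n == 0) { attr(W, "inconsistent") <- logical(0); return(W) }
  Lm <- matrix(b[-length(b)], n, nb, byrow = TRUE)
  Rm <- matrix(b[-1], n, nb, byrow = TRUE)
  ov <- pmax(pmin(Rm, hi) - pmax(Lm, lo), 0)
  pos <- len > 0 & !inconsistent
  if (any(pos)) W[pos, ] <- ov[pos, , drop = FALSE] / len[pos]
  pt <- len <= 0 & !inconsistent            # point age at hi (> t0 or == 0)
  if (any(pt)) {
    idx <- findInterval(hi[pt], b, rightmost.closed = TRUE, left.open = TRUE)
    idx[idx < 1] <- 1L
    idx[idx > nb] <- nb
    W[cbind(which(pt), idx)] <- 1
  }
  attr(W, "inconsistent") <- inconsistent
  W
}

# Assign 1-based positions to genomic blocks; returns a factor key plus the
# block definition table.
.blockKeys <- function(chrom, pos, blockSize) {
  idx <- (pos - 1) %/% blockSize
  key <- paste0(chrom, ":", idx)
  defs <- unique(data.frame(chrom = chrom, idx = idx,
                            stringsAsFactors = FALSE))
  defs <- defs[order(defs$chrom, defs$idx), , drop = FALSE]
  blocks <- data.frame(chrom = defs$chrom,
                       start = defs$idx * blockSize + 1,
                       end = (defs$idx + 1) * blockSize)
  list(key = factor(key, levels = paste0(defs$chrom, ":", defs$idx)),
       blocks = blocks)
}

# Assemble a SharingCounts object from per-site shared/not-shared weights.
# Singleton sharing mass is kept separate for the EM's age re-tilting.
# Binning is chunked so the site-by-bin weight matrix never has to be
# materialised for whole-genome inputs.
.assembleCounts <- function(d, sharedW, notsharedW, grid, t0, blockSize,
                            dropSharedSingletons, extraDiagnostics = list()) {
  singleton <- !is.na(d$carrierCount) & d$carrierCount == 1L
  bk <- .blockKeys(d$chrom, d$pos, blockSize)
  nb <- nBins(grid)
  B <- nlevels(bk$key)
  shared <- notshared <- singShared <- matrix(0, B, nb)
  droppedBelowT0 <- 0
  n <- nrow(d)
  chunk <- 200000L
  starts <- seq(1L, max(n, 1L), by = chunk)
  if (n == 0) starts <- integer(0)
  for (cs in starts) {
    ce <- min(cs + chunk - 1L, n)
    i <- cs:ce
    W <- binMutationMass(d$ageLower[i], d$ageUpper[i], grid, t0)
    inconsistent <- attr(W, "inconsistent")
    sw <- sharedW[i]; nw <- notsharedW[i]; sg <- singleton[i]
    droppedBelowT0 <- droppedBelowT0 + sum(sw[inconsistent] > 0)
    sw[inconsistent] <- 0
    nw[inconsistent] <- 0
    key <- bk$key[i]
    accum <- function(full, w) {
      if (!any(w > 0)) return(full)
      m <- rowsum(W * w, key)
      idx <- match(rownames(m), levels(key))
      full[idx, ] <- full[idx, , drop = FALSE] + m
      full
    }
    shared <- accum(shared, sw * !sg)
    singShared <- if (dropSharedSingletons) singShared
                  else accum(singShared, sw * sg)
    notshared <- accum(notshared, nw)
  }
  new("SharingCounts", grid = grid, t0 = t0,
      shared = shared, notshared = notshared,
      singletonShared = singShared, blocks = bk$blocks,
      diagnostics = c(list(droppedBelowT0 = droppedBelowT0,
                           nSites = n), extraDiagnostics))
}

#' Sharing observations from unphased genotypes
#'
#' Converts unphased diploid (or haploid) dosages at dated sites into the
#' binned shared/not-shared sufficient statistics. In `"cross"` mode, a
#' site with reference dosage \eqn{g_r \ge 1} and non-missing target dosage
#' \eqn{g_t} contributes `shared = g_r * g_t` and
#' `notshared = g_r * (ploidyTarget - g_t)`: the likelihood is multiplied
#' across all homologous chromosome pairs, so no phase information is
#' needed. In `"within"` mode a single individual's dosages are split into
#' one target and one reference allele, assigned uniformly at random at
#' each heterozygous site (seeded); homozygous-derived sites contribute one
#' carried copy on each side.
#'
#' Masks and any transversion restriction are applied to `table` upstream
#' (see [applyMask()], [filterTransversions()]). Shared observations whose
#' age interval lies entirely below `t0` are impossible under the model and
#' are dropped (counted in `diagnostics$droppedBelowT0`).
#'
#' @param table a [DatedMutationTable-class]; rows align with the dosage
#'   vectors
#' @param targetGts,referenceGts integer dosages in `0..ploidy` (NA =
#'   missing), one per table row; `referenceGts` is ignored in within mode
#' @param grid a [TimeGrid-class]
#' @param tTargetYears,tReferenceYears sample ages in years before present
#' @param mode `"cross"` or `"within"`
#' @param ploidyTarget,ploidyReference chromosome copies per sample
#' @param blockSize genomic block length (bp) for the sufficient
#'   statistics; 20 Mb by default, the block-bootstrap unit
#' @param seed RNG seed for the within-mode allele split
#' @param dropSharedSingletons drop shared observations at genealogy
#'   singletons instead of re-tilting their ages during EM
#' @return a [SharingCounts-class]
#' @export
genotypeObservations <- function(table, targetGts, referenceGts = NULL,
                                 grid, tTargetYears = 0, tReferenceYears = 0,
                                 mode = c("cross", "within"),
                                 ploidyTarget = 2, ploidyReference = 2,
                                 blockSize = 2e7, seed = NULL,
                                 dropSharedSingletons = FALSE) {
  mode <- match.arg(mode)
  d <- mutations(table)
  gt <- generationTime(table)
  t0 <- max(tTargetYears, tReferenceYears) / gt
  if (mode == "cross") {
    stopifnot(length(targetGts) == nrow(d), length(referenceGts) == nrow(d))
    if (any(!is.na(targetGts) & !(targetGts %in% 0:ploidyTarget)))
      stop("target dosage outside 0..ploidy")
    if (any(!is.na(referenceGts) & !(referenceGts %in% 0:ploidyReference)))
      stop("reference dosage outside 0..ploidy")
    use <- !is.na(referenceGts) & referenceGts >= 1 & !is.na(targetGts)
    sharedW <- ifelse(use, referenceGts * targetGts, 0)
    notsharedW <- ifelse(use, referenceGts * (ploidyTarget - targetGts), 0)
  } else {
    stopifnot(length(targetGts) == nrow(d))
    g <- targetGts
    if (any(!is.na(g) & !(g %in% 0:2)))
      stop("within mode expects diploid dosages 0/1/2")
    sharedW <- notsharedW <- numeric(nrow(d))
    hom <- !is.na(g) & g == 2
    sharedW[hom] <- 1
    het <- which(!is.na(g) & g == 1)
    toRef <- withSeed(seed, runif(length(het)) < 0.5)
    # derived allele lands on the reference side: target copy is ancestral
    notsharedW[het[toRef]] <- 1
  }
  .assembleCounts(d, sharedW, notsharedW, grid, t0, blockSize,
                  dropSharedSingletons)
}

#' Read a per-read pileup table
#'
#' A plain-text pileup of reference-aligned reads restricted to the dated
#' sites: tab-separated with a `#`-prefixed header and one row per read,
#' columns `chrom pos base mq len mm offset` (`offset` = distance of the
#' site from the nearer read end). This is the per-read expansion of a
#' samtools-mpileup site summary, retaining the fields the read filter
#' needs.
#'
#' @param file path or connection
#' @return data.frame of reads
#' @export
readPileupTable <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t", comment.char = "",
                  stringsAsFactors = FALSE)
  names(d) <- sub("^X\\.", "", names(d))
  names(d)[1] <- sub("^#", "", names(d)[1])
  req <- c("chrom", "pos", "base", "mq", "len", "mm", "offset")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("pileup missing column(s): ",
                         paste(miss, collapse = ", "))
  d$base <- toupper(d$base)
  d
}

#' Sharing observations from read pileups
#'
#' The low-coverage path: instead of genotypes, each passing read at a
#' dated site is an observation, and the likelihood is multiplied across
#' reads (and across pairs of reads when the reference is also given as a
#' pileup). The reference carried-copy weight at a site is its derived
#' dosage when genotypes are supplied, or the number of derived-supporting
#' passing reads when a reference pileup is supplied. Each passing target
#' read then contributes `shared += w_r` if it shows the derived allele and
#' `notshared += w_r` if it shows the ancestral allele; reads showing any
#' other base are skipped, and sites where more than two distinct alleles
#' are observed are skipped entirely.
#'
#' @param table a [DatedMutationTable-class]
#' @param targetPileup data.frame of target reads (see
#'   [readPileupTable()] for columns)
#' @param referenceGts integer dosages per table row (mutually exclusive
#'   with `referencePileup`)
#' @param referencePileup data.frame of reference reads
#' @param grid a [TimeGrid-class]
#' @param tTargetYears,tReferenceYears sample ages in years
#' @param endTrim bases excluded at each read end (see [filterRead()])
#' @param maxReadsPerSite optional cap on passing target reads used per
#'   site (default `Inf`: multiply across all reads)
#' @param blockSize genomic block length (bp)
#' @param dropSharedSingletons see [genotypeObservations()]
#' @return a [SharingCounts-class]
#' @export
readObservations <- function(table, targetPileup, referenceGts = NULL,
                             referencePileup = NULL, grid,
                             tTargetYears = 0, tReferenceYears = 0,
                             endTrim = 2, maxReadsPerSite = Inf,
                             blockSize = 2e7,
                             dropSharedSingletons = FALSE) {
  if (is.null(referenceGts) == is.null(referencePileup))
    stop("supply exactly one of referenceGts / referencePileup")
  d <- mutations(table)
  gt <- generationTime(table)
  t0 <- max(tTargetYears, tReferenceYears) / gt
  siteKey <- paste(d$chrom, d$pos)

  prep <- function(p) {
    pass <- filterRead(p$mq, p$len, p$mm, p$offset, endTrim)
    p <- p[pass, , drop = FALSE]
    p$site <- match(paste(p$chrom, p$pos), siteKey)
    if (anyNA(p$site)) p <- p[!is.na(p$site), , drop = FALSE]
    p
  }
  tp <- prep(targetPileup)

  nSites <- nrow(d)
  # reference carried-copy weight per site
  if (!is.null(referenceGts)) {
    stopifnot(length(referenceGts) == nSites)
    wr <- ifelse(is.na(referenceGts), 0, referenceGts)
    refBases <- NULL
  } else {
    rp <- prep(referencePileup)
    wr <- tabulate(rp$site[rp$base == d$der[rp$site]], nbins = nSites)
    refBases <- rp[, c("site", "base")]
  }

  # biallelic restriction: at most two distinct observed alleles per site
  obs <- tp[, c("site", "base")]
  if (!is.null(refBases)) obs <- rbind(obs, refBases)
  seen <- vapply(DNA_BASES, function(bs)
    tabulate(obs$site[obs$base == bs], nbins = nSites) > 0, logical(nSites))
  if (is.null(dim(seen))) seen <- matrix(seen, nrow = nSites)
  multiallelic <- if (nSites) rowSums(seen) > 2 else logical(0)

  if (is.finite(maxReadsPerSite) && nrow(tp)) {
    ord <- order(tp$site)
    tp <- tp[ord, , drop = FALSE]
    nth <- sequence(tabulate(tp$site, nbins = nSites)[sort(unique(tp$site))])
    tp <- tp[nth <= maxReadsPerSite, , drop = FALSE]
  }
  nDer <- tabulate(tp$site[tp$base == d$der[tp$site]], nbins = nSites)
  nAnc <- tabulate(tp$site[tp$base == d$anc[tp$site]], nbins = nSites)
  sharedW <- wr * nDer
  notsharedW <- wr * nAnc
  sharedW[multiallelic] <- 0
  notsharedW[multiallelic] <- 0
  .assembleCounts(d, sharedW, notsharedW, grid, t0, blockSize,
                  dropSharedSingletons,
                  extraDiagnostics = list(multiallelicSites =
                                            sum(multiallelic)))
}

#' Serialize sharing counts to JSON
#'
#' Grid boundaries and `t0` are written in years; count matrices and block
#' definitions round-trip exactly.
#'
#' @param counts a [SharingCounts-class]
#' @param file output path
#' @export
writeSharingCounts <- function(counts, file) {
  g <- counts@grid
  obj <- list(
    grid_boundaries_years = boundaries(g) * generationTime(g),
    generation_time = generationTime(g),
    t0_years = counts@t0 * generationTime(g),
    blocks = counts@blocks,
    shared = counts@shared,
    notshared = counts@notshared,
    singleton_shared = counts@singletonShared,
    diagnostics = counts@diagnostics)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read sharing counts from JSON
#' @param file path written by [writeSharingCounts()]
#' @return a [SharingCounts-class]
#' @export
readSharingCounts <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  gt <- obj$generation_time
  grid <- TimeGrid(obj$grid_boundaries_years / gt, generationTime = gt)
  asMat <- function(m) {
    m <- as.matrix(m)
    if (!length(m)) m <- matrix(0, nrow(obj$blocks), nBins(grid))
    m
  }
  new("SharingCounts", grid = grid, t0 = obj$t0_years / gt,
      shared = asMat(obj$shared), notshared = asMat(obj$notshared),
      singletonShared = asMat(obj$singleton_shared),
      blocks = as.data.frame(obj$blocks), diagnostics = obj$diagnostics)
}
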