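#' Canonical strand-collapsed trinucleotide mutation class
#'
#' Maps a mutation with its flanking ancestral bases to the canonical
#' class in which the central (mutating) base is a pyrimidine: if the
#' ancestral central base is a purine, the whole triplet and both alleles
#' are reverse-complemented (flanks swap and complement). There are
#' 4 x 4 x 3 / 2 = 96 such classes. Idempotent, and invariant under
#' reverse complement of the input.
#'
#' @param left,anc,der,right single bases (vectors recycled to the longest)
#' @return character vector of labels like `"TCC>TTC"`
#' @export
canonicalClass <- function(left, anc, der, right) {
  n <- max(length(left), length(anc), length(der), length(right))
  left <- toupper(rep_len(left, n)); right <- toupper(rep_len(right, n))
  anc <- toupper(rep_len(anc, n)); der <- toupper(rep_len(der, n))
  if (!all(c(left, anc, der, right) %in% DNA_BASES))
    stop("invalid base; need A/C/G/T")
  if (any(anc == der)) stop("anc must differ from der")
  flip <- anc %in% c("A", "G")
  if (any(flip)) {
    newLeft <- left; newRight <- right
    newLeft[flip] <- complementBase(right[flip])
    newRight[flip] <- complementBase(left[flip])
    anc[flip] <- complementBase(anc[flip])
    der[flip] <- complementBase(der[flip])
    left <- newLeft; right <- newRight
  }
  paste0(left, anc, right, ">", left, der, right)
}

# Pluggable CpG-context rules operating on canonical (pyrimidine-central)
# classes. "pulse20" flags: ancestral CpG (central C, right flank G; 12
# classes), derived CpG on the forward strand (T>C with right flank G; 4),
# and derived CpG on the opposite strand via a left-flank C with T>G (4) —
# 20 classes in total. The rule is a reconstruction constrained to the
# count of excluded triplets (96 - 76 = 20); symmetric "either allele
# contains CG on either strand" definitions flag 23-24 classes instead.
.cpgRules <- list(
  pulse20 = function(left, anc, der, right)
    (anc == "C" & right == "G") |
    (anc == "T" & der == "C" & right == "G") |
    (anc == "T" & der == "G" & left == "C"))

#' Enumerate strand-collapsed triplet classes
#'
#' All 96 canonical classes, or the subset outside CpG context under a
#' named rule. The shipped default rule `"pulse20"` flags exactly 20
#' classes, leaving the 76 used for relative mutation-rate work; see the
#' package vignette for why the rule is an explicit reconstruction.
#'
#' @param excludeCpg drop CpG-context classes
#' @param cpgRule name of the context rule
#' @return data.frame with columns `label`, `left`, `anc`, `der`,
#'   `right`, `cpg`
#' @export
enumerateClasses <- function(excludeCpg = FALSE, cpgRule = "pulse20") {
  if (!cpgRule %in% names(.cpgRules))
    stop("unknown CpG rule '", cpgRule, "'; available: ",
         paste(names(.cpgRules), collapse = ", "))
  g <- expand.grid(left = DNA_BASES, anc = c("C", "T"), der = DNA_BASES,
                   right = DNA_BASES, stringsAsFactors = FALSE)
  g <- g[g$der != g$anc, , drop = FALSE]
  g$label <- paste0(g$left, g$anc, g$right, ">", g$left, g$der, g$right)
  g$cpg <- .cpgRules[[cpgRule]](g$left, g$anc, g$der, g$right)
  g <- g[order(g$label), c("label", "left", "anc", "der", "right", "cpg")]
  rownames(g) <- NULL
  if (excludeCpg) g[!g$cpg, , drop = FALSE] else g
}

#' Relative mutation-rate curve for a triplet class
#'
#' Per epoch, counts the age-binned mutations in each retained
#' (non-CpG-context) class, divides by the class's genomic opportunity
#' `L_c` (how often its ancestral context occurs), and expresses the focal
#' class's density relative to the average density across the retained
#' classes. Shared trends across classes cancel, as does any common
#' opportunity rescaling. Singletons and terminal-branch mutations are
#' excluded (terminal status from an `isTerminal` column when present,
#' otherwise `carrierCount == 1` is used as a proxy with a warning).
#'
#' @param table a [DatedMutationTable-class] for one individual, with
#'   flanking-context columns
#' @param opportunities named numeric vector of per-class context counts
#'   `L_c` (names = class labels), or a single number for flat
#'   opportunities
#' @param grid a [TimeGrid-class]
#' @param focalClass canonical label, default `"TCC>TTC"`
#' @param excludeCpg restrict to non-CpG-context classes
#' @param cpgRule context rule name
#' @param dropSingletons exclude `carrierCount == 1` mutations
#' @return a [RateCurve-class]; epochs with zero total density are `NA`
#' @export
relativeRateCurve <- function(table, opportunities = 1, grid,
                              focalClass = "TCC>TTC", excludeCpg = TRUE,
                              cpgRule = "pulse20", dropSingletons = TRUE) {
  d <- mutations(table)
  if (all(is.na(d$leftBase)) || all(is.na(d$rightBase)))
    stop("flanking-context columns are required")
  hasCtx <- !is.na(d$leftBase) & !is.na(d$rightBase)
  if (!all(hasCtx)) {
    warning(sum(!hasCtx), " mutation(s) without context dropped")
    d <- d[hasCtx, , drop = FALSE]
  }
  if (dropSingletons) d <- d[is.na(d$carrierCount) | d$carrierCount != 1L,
                             , drop = FALSE]
  if ("isTerminal" %in% names(d)) {
    d <- d[!d$isTerminal, , drop = FALSE]
  } else {
    warning("no isTerminal column; carrierCount == 1 used as the ",
            "terminal-branch proxy")
  }
  classes <- enumerateClasses(excludeCpg, cpgRule)
  if (!focalClass %in% classes$label)
    stop("focal class ", focalClass, " not among retained classes")
  Lc <- if (length(opportunities) == 1 && is.null(names(opportunities)))
    stats::setNames(rep(opportunities, nrow(classes)), classes$label)
  else opportunities
  missL <- setdiff(classes$label, names(Lc))
  if (length(missL)) stop("opportunities missing for ", length(missL),
                          " class(es)")
  if (any(Lc[classes$label] <= 0)) stop("opportunities must be positive")

  cls <- canonicalClass(d$leftBase, d$anc, d$der, d$rightBase)
  keep <- cls %in% classes$label
  d <- d[keep, , drop = FALSE]
  cls <- cls[keep]
  nb <- nBins(grid)
  M <- matrix(0, nrow(classes), nb, dimnames = list(classes$label, NULL))
  if (nrow(d)) {
    W <- binMutationMass(d$ageLower, d$ageUpper, grid, t0 = 0)
    agg <- rowsum(W, cls)
    M[rownames(agg), ] <- agg
  }
  dens <- M / Lc[classes$label]
  denom <- colMeans(dens)
  vals <- ifelse(denom > 0, dens[focalClass, ] / denom, NA_real_)
  RateCurve(grid, vals, scalingWindow = c(1e5, 1e6), focalClass = focalClass)
}

#' Integrated mutation intensity (IMI)
#'
#' Quantifies the strength of a mutation-rate elevation as the area
#' between the scaled relative-rate curve and the constant baseline 1,
#' integrated over 14 thousand to 1 million years before present with
#' time measured in log10 units (upweighting the recent past). The curve
#' is first scaled to mean 1 over the epochs intersecting the scaling
#' window (1e5 to 1e6 years, predating the signature of interest); epochs
#' missing at the recent end take the earliest available value (constant
#' extrapolation back to 14k years, as needed for samples older than
#' 14k years). A constant curve has an IMI of exactly 0.
#'
#' @param curve a [RateCurve-class]
#' @param scale divide by the scaling-window mean first (disable only for
#'   curves already scaled)
#' @param windowYears integration window, years
#' @return scalar IMI (log10-years units)
#' @export
imi <- function(curve, scale = TRUE, windowYears = c(14e3, 1e6)) {
  g <- curve@grid
  byr <- boundaries(g) * generationTime(g)
  v <- curve@values
  nb <- length(v)
  if (byr[nb + 1] < windowYears[1])
    stop("curve does not reach the integration window")
  if (scale) {
    sw <- curve@scalingWindow
    inWin <- byr[-1] > sw[1] & byr[-(nb + 1)] < sw[2]
    sv <- v[inWin & !is.na(v)]
    if (!length(sv)) stop("no epochs with data in the scaling window")
    # x/x == 1 exactly, so a constant curve scales to exactly 1 and its
    # integrated excess is exactly 0
    s <- if (max(sv) == min(sv)) sv[1] else mean(sv)
    v <- v / s
  }
  # fill missing epochs: most recent available value extrapolates toward
  # the present; older gaps carry the adjacent more recent value forward
  if (anyNA(v)) {
    firstOk <- which(!is.na(v))[1]
    if (is.na(firstOk)) stop("curve has no data")
    if (firstOk > 1) v[seq_len(firstOk - 1)] <- v[firstOk]
    for (e in seq_len(nb)[-1]) if (is.na(v[e])) v[e] <- v[e - 1]
  }
  l <- pmax(byr[-(nb + 1)], windowYears[1])
  r <- pmin(byr[-1], windowYears[2])
  w <- ifelse(r > l, log10(r) - log10(l), 0)
  sum((v - 1) * w)
}

#' Low-coverage TCC>TTC proportion
#'
#' For samples too shallow for rate curves: among dated sites with at
#' least `minDepth` reads and at least `minDerived` reads supporting the
#' derived allele (strong evidence of a heterozygous or homozygous derived
#' state), and whose branch upper age is below `ageCapYears` (restricting
#' to the era of the signature), the proportion whose canonical class is
#' TCC>TTC relative to all C>T transitions outside CpG context.
#' Confidence intervals come from a block bootstrap (10 Mb blocks).
#'
#' @param pileup data.frame of (already filtered) reads, columns `chrom
#'   pos base` at table sites
#' @param table a [DatedMutationTable-class] with flanking context
#' @param minDepth minimum reads mapping at a site
#' @param minDerived minimum derived-supporting reads
#' @param ageCapYears branch upper-age ascertainment cap, years
#' @param blockSize bootstrap block length, bp
#' @param nReps bootstrap replicates
#' @param seed RNG seed
#' @param cpgRule CpG-context rule name
#' @return list with `proportion`, `ciLower`, `ciUpper`, `nNumerator`,
#'   `nDenominator`
#' @export
tccProportionLowcov <- function(pileup, table, minDepth = 4, minDerived = 4,
                                ageCapYears = 1e5, blockSize = 1e7,
                                nReps = 100, seed = NULL,
                                cpgRule = "pulse20") {
  d <- mutations(table)
  if (all(is.na(d$leftBase))) stop("flanking-context columns are required")
  siteKey <- paste(d$chrom, d$pos)
  site <- match(paste(pileup$chrom, pileup$pos), siteKey)
  ok <- !is.na(site)
  depth <- tabulate(site[ok], nbins = nrow(d))
  derOk <- ok & toupper(pileup$base) == d$der[site]
  nDer <- tabulate(site[derOk & !is.na(derOk)], nbins = nrow(d))
  ageCap <- ageCapYears / generationTime(table)
  hasCtx <- !is.na(d$leftBase) & !is.na(d$rightBase)
  qual <- depth >= minDepth & nDer >= minDerived & d$ageUpper < ageCap &
    hasCtx
  cls <- rep(NA_character_, nrow(d))
  cls[hasCtx] <- canonicalClass(d$leftBase[hasCtx], d$anc[hasCtx],
                                d$der[hasCtx], d$rightBase[hasCtx])
  # canonical components: "LAR>LDR"
  cAnc <- substr(cls, 2, 2); cDer <- substr(cls, 6, 6)
  cLeft <- substr(cls, 1, 1); cRight <- substr(cls, 3, 3)
  isCT <- !is.na(cls) & cAnc == "C" & cDer == "T"
  cpg <- rep(TRUE, nrow(d))
  cpg[hasCtx] <- .cpgRules[[cpgRule]](cLeft[hasCtx], cAnc[hasCtx],
                                      cDer[hasCtx], cRight[hasCtx])
  den <- qual & isCT & !cpg
  num <- den & cls == "TCC>TTC"
  if (!any(den))
    stop("no qualifying non-CpG C>T transition sites (",
         sum(qual, na.rm = TRUE), " qualifying sites overall)")
  prop <- sum(num) / sum(den)

  bk <- .blockKeys(d$chrom, d$pos, blockSize)
  numB <- as.numeric(rowsum(as.numeric(num), bk$key))
  denB <- as.numeric(rowsum(as.numeric(den), bk$key))
  B <- length(numB)
  reps <- withSeed(seed, vapply(seq_len(nReps), function(r) {
    repeat {
      idx <- sample.int(B, B, replace = TRUE)
      if (sum(denB[idx]) > 0) break
    }
    sum(numB[idx]) / sum(denB[idx])
  }, numeric(1)))
  ci <- quantile(reps, c(0.025, 0.975), names = FALSE)
  list(proportion = prop, ciLower = ci[1], ciUpper = ci[2],
       nNumerator = sum(num), nDenominator = sum(den))
}
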