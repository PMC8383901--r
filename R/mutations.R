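#' Read a dated-mutation table (agecoal-mut TSV)
#'
#' The "agecoal-mut v1" dialect serialises mutations dated by a genome-wide
#' genealogy: tab-separated, a `#`-prefixed header line, required columns
#' `chrom pos anc der age_lower_years age_upper_years carrier_count
#' is_fixed`, optional `left_base right_base` (flanking ancestral bases).
#' Ages on file are in years and converted to generations on read. A
#' converter from genealogy-inference ".mut"/".anc" outputs would target
#' this dialect; that mapping is upstream of this package.
#'
#' Rows with `age_lower >= age_upper` are rejected with a warning; fixed
#' rows whose upper age is not `tOut` are capped to `tOut` with a warning;
#' duplicate positions on a chromosome are an error (two-state model).
#'
#' @param file path or connection
#' @param generationTime years per generation
#' @param tOutYears outgroup TMRCA cap in years
#' @return a [DatedMutationTable-class] (ages in generations)
#' @seealso [writeMutationTable()]
#' @export
readMutationTable <- function(file, generationTime = 28, tOutYears = 1e7) {
  lines <- readLines(file)
  if (!length(lines)) stop("empty mutation table")
  if (!startsWith(lines[1], "#")) stop("missing '#'-prefixed header row")
  header <- strsplit(sub("^#\\s*", "", lines[1]), "\t")[[1]]
  req <- c("chrom", "pos", "anc", "der", "age_lower_years",
           "age_upper_years", "carrier_count", "is_fixed")
  miss <- setdiff(req, header)
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, ": expected ",
         length(header), " fields, got ", lengths(fields)[bad[1]])
  m <- do.call(rbind, fields)
  colnames(m) <- header
  d <- data.frame(
    chrom = m[, "chrom"],
    pos = as.integer(m[, "pos"]),
    anc = toupper(m[, "anc"]),
    der = toupper(m[, "der"]),
    ageLower = as.numeric(m[, "age_lower_years"]) / generationTime,
    ageUpper = as.numeric(m[, "age_upper_years"]) / generationTime,
    carrierCount = as.integer(m[, "carrier_count"]),
    isFixed = as.logical(as.integer(m[, "is_fixed"])),
    stringsAsFactors = FALSE)
  d$leftBase <- if ("left_base" %in% header)
    toupper(m[, "left_base"]) else NA_character_
  d$rightBase <- if ("right_base" %in% header)
    toupper(m[, "right_base"]) else NA_character_
  d$leftBase[d$leftBase %in% c("", ".", "N")] <- NA_character_
  d$rightBase[d$rightBase %in% c("", ".", "N")] <- NA_character_
  tOutGen <- tOutYears / generationTime
  drop <- d$ageLower >= d$ageUpper
  if (any(drop)) {
    warning(sum(drop), " record(s) rejected: age_lower >= age_upper")
    d <- d[!drop, , drop = FALSE]
  }
  fixBad <- d$isFixed & abs(d$ageUpper - tOutGen) > 1e-6 * tOutGen
  if (any(fixBad)) {
    warning(sum(fixBad),
            " fixed record(s) had age_upper != tOut; capped to tOut")
    d$ageUpper[fixBad] <- tOutGen
  }
  if (anyDuplicated(paste(d$chrom, d$pos)))
    stop("duplicate position on a chromosome (infinite-sites violation)")
  DatedMutationTable(d, tOut = tOutGen, generationTime = generationTime,
                     source = if (is.character(file)) file else "connection")
}

#' Write a dated-mutation table (agecoal-mut TSV)
#'
#' Inverse of [readMutationTable()]; ages are written in years with
#' canonical `%.6f`-free formatting (`format(..., digits = 17)`) so that a
#' write/read round trip reproduces the table exactly.
#'
#' @param table a [DatedMutationTable-class]
#' @param file path or connection
#' @export
writeMutationTable <- function(table, file) {
  d <- mutations(table)
  gt <- generationTime(table)
  fmt <- function(x) vapply(x * gt, format, character(1), digits = 17)
  out <- c(paste0("#", paste(c("chrom", "pos", "anc", "der",
                               "age_lower_years", "age_upper_years",
                               "carrier_count", "is_fixed",
                               "left_base", "right_base"), collapse = "\t")),
           paste(d$chrom, d$pos, d$anc, d$der,
                 fmt(d$ageLower), fmt(d$ageUpper),
                 d$carrierCount, as.integer(d$isFixed),
                 ifelse(is.na(d$leftBase), ".", d$leftBase),
                 ifelse(is.na(d$rightBase), ".", d$rightBase),
                 sep = "\t"))
  writeLines(out, file)
  invisible(file)
}

#' Augment a table with fixed derived sites up to the outgroup cap
#'
#' Sites fixed and derived in all samples of the dating genealogy must be
#' included, because additional target/reference samples can coalesce into
#' the root branch. Without an explicit outgroup, their number in a region
#' of `l` base pairs is Poisson with mean `mu * l * (tOut - tSample)`,
#' where `tSample` is the local TMRCA of the dating sample; positions are
#' drawn uniformly with replacement and repeats are collapsed to one record
#' (two-state model). If `tSample >= tOut` no fixed sites are added. Added
#' records have age interval `[tSample, tOut]` and `isFixed = TRUE`.
#'
#' @param table a [DatedMutationTable-class]
#' @param mu per-bp per-generation mutation rate
#' @param chrom chromosome label of the region
#' @param start,end 1-based inclusive region bounds
#' @param tSample local TMRCA of the dating sample, generations
#' @param seed optional integer for reproducible draws
#' @param ancAlleles optional function(n) returning ancestral bases for the
#'   new sites; default draws uniformly
#' @return the augmented [DatedMutationTable-class]
#' @export
augmentFixedSites <- function(table, mu, chrom, start, end, tSample,
                              seed = NULL, ancAlleles = NULL) {
  stopifnot(mu > 0, end >= start, tSample >= 0)
  tout <- tOut(table)
  if (tSample >= tout) return(table)
  l <- end - start + 1
  d <- mutations(table)
  add <- withSeed(seed, {
    n <- rpois(1, mu * l * (tout - tSample))
    pos <- if (n > 0) unique(sample.int(l, n, replace = TRUE)) + start - 1L
           else integer(0)
    # drop positions already occupied on this chromosome (second hits at a
    # derived fixed site leave the observed state unchanged)
    pos <- setdiff(pos, d$pos[d$chrom == chrom])
    if (!length(pos)) NULL else {
      anc <- if (is.null(ancAlleles)) sample(DNA_BASES, length(pos), TRUE)
             else ancAlleles(length(pos))
      der <- vapply(anc, function(a) sample(setdiff(DNA_BASES, a), 1),
                    character(1))
      data.frame(chrom = chrom, pos = as.integer(pos), anc = anc,
                 der = unname(der), ageLower = tSample, ageUpper = tout,
                 carrierCount = max(d$carrierCount, 2L, na.rm = TRUE),
                 isFixed = TRUE, leftBase = NA_character_,
                 rightBase = NA_character_, stringsAsFactors = FALSE)
    }
  })
  if (is.null(add)) return(table)
  DatedMutationTable(rbind(d, add), tOut = tout,
                     generationTime = generationTime(table),
                     source = table@source)
}

#' Restrict a table to transversions
#'
#' Removes exactly the sites whose unordered allele pair is \{A,G\} or
#' \{C,T\}. Transversions are immune to the C-to-T deamination damage
#' typical of ancient DNA, so a transversion-only analysis avoids that
#' error mode.
#'
#' @param table a [DatedMutationTable-class]
#' @return the filtered table
#' @export
filterTransversions <- function(table) {
  d <- mutations(table)
  keep <- isTransversion(d$anc, d$der)
  DatedMutationTable(d[keep, , drop = FALSE], tOut = tOut(table),
                     generationTime = generationTime(table),
                     source = table@source)
}
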