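test_that("alleles polarize against the ancestral base", {
  expect_equal(polarizeAlleles("C", "T", "C"),
               data.frame(anc = "C", der = "T"))
  expect_equal(polarizeAlleles("C", "T", "T"),
               data.frame(anc = "T", der = "C"))
  expect_true(all(is.na(polarizeAlleles("C", "T", "N"))))
  expect_true(all(is.na(polarizeAlleles("C", "T", "G"))))
  out <- polarizeAlleles(c("C", "A"), c("T", "G"), c("T", "N"))
  expect_equal(out$anc, c("T", NA))
})

test_that("read filter applies strict thresholds and end trimming", {
  expect_false(filterRead(30, 50, 0, 10))   # MQ must exceed 30
  expect_true(filterRead(31, 35, 2, 2))     # all thresholds just met
  expect_false(filterRead(60, 100, 3, 10))  # fewer than 3 mismatches
  expect_false(filterRead(60, 34, 0, 10))   # length must exceed 34
  expect_false(filterRead(60, 100, 0, 1))   # inside the 2 bp end trim
  expect_equal(filterRead(c(31, 29), c(50, 50), c(0, 0), c(5, 5)),
               c(TRUE, FALSE))
})

test_that("coverage masks keep sites in [5x, 2*mean)", {
  depth <- c(4, 5, 10, 20, 19, 3, 7)
  bed <- buildCoverageMask(depth, meanCoverage = 10)
  # passing: positions 2,3 (5,10), 5 (19), 7 (7); 20 = 2*mean fails
  expect_equal(bed$start, c(1, 4, 6))
  expect_equal(bed$end, c(3, 5, 7))
  gr <- maskToGRanges(bed)
  expect_equal(GenomicRanges::start(gr), c(2, 5, 7))
  expect_equal(sum(GenomicRanges::width(gr)), 4L)
  expect_equal(nrow(buildCoverageMask(c(1, 2), 10)), 0L)
})

test_that("masks subset mutation tables by position", {
  tab <- makeTable(50, seed = 5)
  pos <- mutations(tab)$pos
  bed <- data.frame(chrom = "chr1", start = pos[3] - 1, end = pos[7])
  kept <- applyMask(tab, bed)
  expect_equal(mutations(kept)$pos, pos[pos >= pos[3] & pos <= pos[7]])
})

test_that("age mass is distributed over bins by overlap fraction", {
  g <- TimeGrid(c(0, 200, 400, 600), generationTime = GT)
  W <- binMutationMass(100, 300, g)
  expect_equal(as.numeric(W), c(0.5, 0.5, 0))

  expect_equal(as.numeric(binMutationMass(250, 350, g)), c(0, 1, 0))

  Wc <- binMutationMass(100, 300, g, t0 = 150)
  expect_equal(as.numeric(Wc), c(1/3, 2/3, 0))

  Wbad <- binMutationMass(10, 40, g, t0 = 100)
  expect_equal(as.numeric(Wbad), c(0, 0, 0))
  expect_true(attr(Wbad, "inconsistent"))
})

test_that("bin masses always sum to one for consistent mutations", {
  set.seed(11)
  g <- buildLogGrid(100, 1e5, 7)
  lo <- runif(200, 0, 5e4)
  hi <- lo + runif(200, 0.001, 5e4)
  hi <- pmin(hi, 1e5)
  t0 <- 50
  W <- binMutationMass(lo, hi, g, t0)
  ok <- !attr(W, "inconsistent")
  expect_true(all(abs(rowSums(W[ok, , drop = FALSE]) - 1) < 1e-12))
  expect_true(all(rowSums(W[!ok, , drop = FALSE]) == 0))
})

test_that("cross-mode genotype observations weight chromosome pairs", {
  g <- TimeGrid(c(0, 1000), generationTime = GT)
  d <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                  anc = "C", der = "A",
                  ageLower = c(100, 100, 100, 100),
                  ageUpper = c(200, 200, 200, 200),
                  carrierCount = 3L, isFixed = FALSE,
                  stringsAsFactors = FALSE)
  tab <- DatedMutationTable(d, tOut = 1000, generationTime = GT)
  cnt <- genotypeObservations(tab, targetGts = c(1L, 0L, NA, 2L),
                              referenceGts = c(1L, 2L, 1L, 0L), grid = g)
  # site1: g_r=1,g_t=1 -> 1 shared, 1 notshared; site2: g_r=2,g_t=0 ->
  # 0 shared, 4 notshared; site3: missing target; site4: g_r=0
  expect_equal(sum(cnt@shared), 1)
  expect_equal(sum(cnt@notshared), 1 + 4)
  expect_error(genotypeObservations(tab, targetGts = c(3L, 0L, 0L, 0L),
                                    referenceGts = rep(1L, 4), grid = g),
               "dosage")
})

test_that("within-mode splits heterozygous sites with a seeded RNG", {
  g <- TimeGrid(c(0, 1000), generationTime = GT)
  n <- 400
  d <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L, anc = "C",
                  der = "A", ageLower = 100, ageUpper = 200,
                  carrierCount = 3L, isFixed = FALSE,
                  stringsAsFactors = FALSE)
  tab <- DatedMutationTable(d, tOut = 1000, generationTime = GT)
  gts <- rep(c(1L, 2L), n / 2)
  a <- genotypeObservations(tab, gts, grid = g, mode = "within", seed = 4)
  b <- genotypeObservations(tab, gts, grid = g, mode = "within", seed = 4)
  expect_identical(a@shared, b@shared)
  expect_identical(a@notshared, b@notshared)
  # hom-derived sites: one copy each side, always shared
  expect_equal(sum(a@shared), n / 2)
  # het sites contribute (as not-shared) only when the derived allele
  # lands on the reference side: about half of them
  expect_lt(abs(sum(a@notshared) - n / 4), 3 * sqrt(n / 4))
})

test_that("read observations multiply across reads and respect w_r", {
  g <- TimeGrid(c(0, 1000), generationTime = GT)
  d <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), anc = "C",
                  der = "A", ageLower = 100, ageUpper = 200,
                  carrierCount = 3L, isFixed = FALSE,
                  stringsAsFactors = FALSE)
  tab <- DatedMutationTable(d, tOut = 1000, generationTime = GT)
  pile <- data.frame(chrom = "chr1",
                     pos = c(10, 10, 10, 20, 20, 20, 30),
                     base = c("A", "C", "A",   # site1: der, anc, der
                              "A", "C", "G",   # site2: 3 distinct alleles
                              "T"),            # site3: third allele only
                     mq = 60, len = 100, mm = 0, offset = 10)
  cnt <- readObservations(tab, pile, referenceGts = c(1L, 1L, 1L), grid = g)
  expect_equal(sum(cnt@shared), 2)       # site1 only
  expect_equal(sum(cnt@notshared), 1)
  expect_equal(cnt@diagnostics$multiallelicSites, 1L)

  # doubling the reference weight doubles the site contributions
  cnt2 <- readObservations(tab, pile, referenceGts = c(2L, 2L, 2L), grid = g)
  expect_equal(sum(cnt2@shared), 4)

  # failing reads are ignored entirely
  pileBad <- transform(pile, mq = 20)
  cnt3 <- readObservations(tab, pileBad, referenceGts = c(1L, 1L, 1L),
                           grid = g)
  expect_equal(sum(cnt3@shared) + sum(cnt3@notshared), 0)
})

test_that("reference pileups set carried-copy weights from derived reads", {
  g <- TimeGrid(c(0, 1000), generationTime = GT)
  d <- data.frame(chrom = "chr1", pos = 10L, anc = "C", der = "A",
                  ageLower = 100, ageUpper = 200, carrierCount = 3L,
                  isFixed = FALSE, stringsAsFactors = FALSE)
  tab <- DatedMutationTable(d, tOut = 1000, generationTime = GT)
  tp <- data.frame(chrom = "chr1", pos = 10, base = c("A", "C"),
                   mq = 60, len = 100, mm = 0, offset = 10)
  rp <- data.frame(chrom = "chr1", pos = 10, base = c("A", "A", "C"),
                   mq = 60, len = 100, mm = 0, offset = 10)
  cnt <- readObservations(tab, tp, referencePileup = rp, grid = g)
  expect_equal(sum(cnt@shared), 2 * 1)      # w_r = 2 derived ref reads
  expect_equal(sum(cnt@notshared), 2 * 1)
})

test_that("counts are additive over genomic blocks", {
  set.seed(21)
  g <- buildLogGrid(100, TOUT_GEN, 6)
  tab <- makeTable(300, seed = 21)
  n <- length(tab)
  tg <- sample(0:2, n, TRUE)
  rg <- sample(0:2, n, TRUE)
  whole <- genotypeObservations(tab, tg, rg, grid = g, blockSize = 1e9)
  blocked <- genotypeObservations(tab, tg, rg, grid = g, blockSize = 1e5)
  expect_gt(nrow(blocked@blocks), 1)
  expect_equal(colSums(blocked@shared), colSums(whole@shared))
  expect_equal(colSums(blocked@notshared), colSums(whole@notshared))
})

test_that("shared observations below t0 are dropped and counted", {
  g <- TimeGrid(c(0, 100, 1000), generationTime = GT)
  d <- data.frame(chrom = "chr1", pos = c(10L, 20L), anc = "C", der = "A",
                  ageLower = c(10, 500), ageUpper = c(50, 900),
                  carrierCount = 3L, isFixed = FALSE,
                  stringsAsFactors = FALSE)
  tab <- DatedMutationTable(d, tOut = 1000, generationTime = GT)
  cnt <- genotypeObservations(tab, targetGts = c(2L, 2L),
                              referenceGts = c(2L, 2L), grid = g,
                              tTargetYears = 100 * GT)   # t0 = 100 gen
  expect_equal(cnt@diagnostics$droppedBelowT0, 1L)
  expect_equal(sum(cnt@shared[, 1]), 0)     # bin below t0 stays empty
})

test_that("sharing counts survive a JSON round trip", {
  set.seed(2)
  g <- buildLogGrid(100, TOUT_GEN, 4)
  tab <- makeTable(50, seed = 2)
  n <- length(tab)
  cnt <- genotypeObservations(tab, sample(0:2, n, TRUE),
                              sample(0:2, n, TRUE), grid = g,
                              blockSize = 2e5)
  f <- withr::local_tempfile(fileext = ".json")
  writeSharingCounts(cnt, f)
  back <- readSharingCounts(f)
  expect_equal(back@shared, cnt@shared)
  expect_equal(back@notshared, cnt@notshared)
  expect_equal(back@t0, cnt@t0)
  expect_equal(boundaries(back@grid), boundaries(cnt@grid))
})

test_that("pileup tables read from their TSV dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tbase\tmq\tlen\tmm\toffset",
               "chr1\t10\ta\t60\t100\t0\t5"), f)
  p <- readPileupTable(f)
  expect_equal(p$base, "A")
  expect_equal(p$pos, 10L)
})
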