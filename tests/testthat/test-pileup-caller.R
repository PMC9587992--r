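refP <- c(t = randomLocusSequence(c(300L, 300L), seed = 31L))

# hand-built alignments: three 50 bp reads covering position 100
mkAln <- function(readId, segStart, segEnd, refStart, refEnd,
                  strand = "+", cigar = paste0(segEnd - segStart, "M")) {
  data.frame(readId = readId, segStart = segStart, segEnd = segEnd,
             refName = "t", refStart = refStart, refEnd = refEnd,
             strand = strand, mismatches = 0L, ambiguous = FALSE,
             round = 1L, cigar = cigar, stringsAsFactors = FALSE)
}

test_that("pileup counts every aligned base once per fragment", {
  reads <- data.frame(
    readId = c("a", "b", "c"),
    seq = substring(refP[[1L]], c(61L, 81L, 91L), c(110L, 130L, 140L)),
    stringsAsFactors = FALSE)
  aln <- rbind(mkAln("a", 0L, 50L, 60L, 110L),
               mkAln("b", 0L, 50L, 80L, 130L),
               mkAln("c", 0L, 50L, 90L, 140L))
  pu <- pileupAlignments(aln, reads, refP)
  expect_equal(depthAt(pu, "t", 100L), 3L)
  expect_equal(depthAt(pu, "t", 59L), 0L)
  expect_equal(sum(pu@depth$t), 150L)      # conservation
  expect_equal(pu@alignedBases, 150)
  expect_equal(nrow(pu@altCounts), 0L)

  # one read carrying an ALT base at a het site
  altSeq <- reads$seq[1L]
  substr(altSeq, 41L, 41L) <- if (substr(altSeq, 41L, 41L) == "A") "C"
                              else "A"
  reads2 <- rbind(reads, data.frame(readId = "d", seq = altSeq))
  aln2 <- rbind(aln, mkAln("d", 0L, 50L, 60L, 110L))
  pu2 <- pileupAlignments(aln2, reads2, refP)
  expect_equal(sum(pu2@altCounts$count), 1L)
  expect_equal(pu2@altCounts$pos, 100L)  # 60 + 41 - 1
})

test_that("empty alignments give an all-zero pileup", {
  pu <- pileupAlignments(mkAln("a", 0L, 50L, 60L, 110L)[0, ],
                         data.frame(readId = character(),
                                    seq = character()), refP)
  expect_true(all(pu@depth$t == 0L))
})

test_that("alignments outside the reference are rejected", {
  reads <- data.frame(readId = "a", seq = strrep("A", 50L))
  expect_error(pileupAlignments(mkAln("a", 0L, 50L, 580L, 630L), reads,
                                refP), "outside reference")
})

test_that("on-target statistics match their definition", {
  aln <- rbind(mkAln("a", 0L, 100L, 50L, 150L),
               mkAln("b", 0L, 100L, 400L, 500L))
  roiAll <- data.frame(refName = "t", start = 0L, end = 600L)
  expect_equal(onTargetStats(aln, roiAll)$fraction, 1.0)
  roiHalf <- data.frame(refName = "t", start = 0L, end = 300L)
  st <- onTargetStats(aln, roiHalf)
  expect_equal(st$fraction, 0.5)
  expect_equal(st$onTargetNt, 100)
  expect_equal(st$meanDepthInRoi, 100 / 300)
  expect_error(onTargetStats(aln, roiAll[0, ]), "empty region")
})

test_that("coverage at minimum depth counts thresholded positions", {
  roi <- data.frame(refName = "t", start = 100L, end = 200L)
  expect_equal(coverageAtDepth(makePileup("t", 600L, 30L), 25L,
                               roi)$percent, 100)
  expect_equal(coverageAtDepth(makePileup("t", 600L, 30L), 100L,
                               roi)$percent, 0)
  half <- makePileup("t", 600L, c(rep(30L, 150L), rep(0L, 450L)))
  cv <- coverageAtDepth(half, 25L, roi)
  expect_equal(cv$percent, 50)
  expect_equal(cv$zeroDepthIntervals$start, 150L)
  expect_equal(cv$zeroDepthIntervals$end, 200L)
})

test_that("depth and allele-fraction filters gate genotype calls", {
  alt <- function(count) data.frame(refName = "t", pos = 150L,
                                    allele = "A", count = count)
  base <- substr(refP[[1L]], 151L, 151L)
  altAllele <- if (base == "A") "C" else "A"
  alt <- function(count) data.frame(refName = "t", pos = 150L,
                                    allele = altAllele, count = count)
  # depth one below the short-read preset: never called
  pu24 <- makePileup("t", 600L, 24L, alt(12L))
  expect_equal(nrow(callVariants(pu24, shortReadCallerConfig(), refP)), 0L)
  # at depth 40 with half ALT: a het call
  pu40 <- makePileup("t", 600L, 40L, alt(20L))
  c40 <- callVariants(pu40, shortReadCallerConfig(), refP)
  expect_equal(c40$genotype, "0/1")
  expect_equal(c40$altFraction, 0.5)
  expect_equal(c40$ref, base)
  expect_equal(c40$alt, altAllele)
  # all-ALT at depth 200 under the long-read preset: a hom call
  pu200 <- makePileup("t", 600L, 200L, alt(200L))
  c200 <- callVariants(pu200, longReadCallerConfig(), refP)
  expect_equal(c200$genotype, "1/1")
  # below the absolute ALT floor: no het call
  pu30 <- makePileup("t", 600L, 30L,
                     data.frame(refName = "t", pos = 150L,
                                allele = altAllele, count = 4L))
  expect_equal(nrow(callVariants(pu30, callerConfig(minDepth = 10L,
                                                    hetAfLow = 0.1),
                                 refP)), 0L)
})

test_that("indel alleles are keyed and called in padded VCF form", {
  pos <- 200L
  base <- substr(refP[[1L]], pos + 1L, pos + 1L)
  insRows <- data.frame(refName = "t", pos = pos, allele = "+GG",
                        count = 15L)
  ci <- callVariants(makePileup("t", 600L, 30L, insRows),
                     shortReadCallerConfig(), refP)
  expect_equal(ci$ref, base)
  expect_equal(ci$alt, paste0(base, "GG"))
  expect_equal(ci$kind, "INDEL")
  delRows <- data.frame(refName = "t", pos = pos, allele = "-2",
                        count = 15L)
  cd <- callVariants(makePileup("t", 600L, 30L, delRows),
                     shortReadCallerConfig(), refP)
  expect_equal(cd$ref, substr(refP[[1L]], pos + 1L, pos + 3L))
  expect_equal(cd$alt, base)
})

test_that("an error-free simulation recovers the planted genotypes exactly", {
  loc <- fixtureLocus(seed = 29L, nFragments = 6L, fragmentLength = 1100L,
                      nHetSnvs = 5L, nHetIndels = 1L)
  sim <- fixtureSim(loc, platform = "long", nCircles = 60L, nReads = 120L)
  res <- mapReads(sim$reads, sim$index, nlaIII(), longReadMapperParams())
  pu <- pileupAlignments(res$alignments, sim$reads, sim$refs)
  cfg <- callerConfig(minDepth = 20L)
  calls <- callVariants(pu, cfg, sim$refs)
  v <- variants(loc)
  covered <- depthAt(pu, refName(loc), v$pos) >= 20L
  expect_true(all(covered))
  expect_equal(nrow(calls), nrow(v))
  expect_equal(calls$pos, v$pos)
  expect_equal(calls$ref, v$ref)
  expect_equal(calls$alt, v$alt)
  expect_true(all(calls$genotype == "0/1"))
})
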