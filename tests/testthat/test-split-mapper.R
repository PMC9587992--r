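# A locus with SNVs only, so that short-read gapless segments are exactly
# recoverable; indel handling is exercised with the long profile.
locusM <- fixtureLocus(seed = 7L)
simL <- fixtureSim(locusM, platform = "long", nCircles = 40L, nReads = 40L)
locusS <- fixtureLocus(seed = 19L, nHetIndels = 0L)
simS <- fixtureSim(locusS, platform = "short", nCircles = 40L, nReads = 60L)

test_that("the seed index reports all occurrences, sorted", {
  refs <- c(r1 = paste0(strrep("ACGT", 6), "TTGCAGTCAATCGGA"))
  idx <- buildIndex(refs, k = 12L)
  hits <- kmerHits(idx, "ACGTACGTACGT")
  expect_equal(hits$pos, c(1L, 5L, 9L, 13L))  # every period-4 occurrence
  expect_equal(nrow(kmerHits(idx, "AAAAAAAAAAAA")), 0L)
  # duplicated reference: every k-mer occurs at least twice
  idx2 <- buildIndex(c(a = refs[[1]], b = refs[[1]]), k = 12L)
  expect_gte(nrow(kmerHits(idx2, "ACGTACGTACGT")), 8L)
  expect_error(buildIndex(refs, k = 5L), "k must be")
  expect_error(buildIndex(c(a = "ACGT"), k = 21L), "larger than every")
})

test_that("alignSegment places exact substrings uniquely and flags decoys", {
  ref <- refSeq(locusM)
  idx1 <- simL$index
  seg <- substr(ref, 2001, 2120)
  a <- alignSegment(seg, idx1, mapperParams())
  expect_equal(nrow(a), 1L)
  expect_equal(a$refStart, 2000L)
  expect_equal(a$refEnd, 2120L)
  expect_equal(a$mismatches, 0L)
  expect_false(a$ambiguous)

  # identical decoy copy: two co-optimal placements, ambiguous
  idx2 <- buildIndex(c(target = ref, decoy = ref), k = 21L)
  a2 <- alignSegment(seg, idx2, mapperParams())
  expect_equal(nrow(a2), 2L)
  expect_true(all(a2$ambiguous))
  expect_setequal(a2$refName, c("target", "decoy"))

  # a random 50-mer verified absent from the reference maps nowhere
  set.seed(33)
  repeat {
    rnd <- paste(sample(c("A", "C", "G", "T"), 50L, replace = TRUE),
                 collapse = "")
    if (!grepl(rnd, ref, fixed = TRUE) &&
        !grepl(tlaphaser:::revComp(rnd), ref, fixed = TRUE)) break
  }
  expect_equal(nrow(alignSegment(rnd, idx1, mapperParams())), 0L)

  # reverse-complemented segments are found on the minus strand
  a3 <- alignSegment(tlaphaser:::revComp(seg), idx1, mapperParams())
  expect_equal(a3$strand, "-")
  expect_equal(a3$refStart, 2000L)
})

test_that("splitMap decomposes two-fragment chimeras and reports remnants", {
  ref <- refSeq(locusM)
  fr <- digest(ref, nlaIII())
  idx <- simL$index
  # chimera of two complete non-adjacent fragments
  read <- paste0(fr$seq[2L], fr$seq[5L])
  res <- splitMap(read, "chim", idx, nlaIII(), mapperParams())
  al <- res$alignments[order(res$alignments$segStart), ]
  expect_equal(nrow(al), 2L)
  expect_equal(al$refStart, c(fr$start[2L], fr$start[5L]))
  expect_equal(al$refEnd, c(fr$end[2L], fr$end[5L]))
  expect_equal(sort(unique(al$round)), 1:2)
  expect_equal(nrow(res$remnants), 0L)

  # read within one fragment: single alignment, no split
  inner <- substr(ref, fr$start[3L] + 11L, fr$start[3L] + 210L)
  res1 <- splitMap(inner, "inner", idx, nlaIII(), mapperParams())
  expect_equal(nrow(res1$alignments), 1L)
  expect_equal(res1$alignments$round, 1L)

  # mappable fragment plus a CATG-free random tail: alignment + remnant
  set.seed(41)
  repeat {
    tail <- paste(sample(c("A", "C", "G", "T"), 60L, replace = TRUE),
                  collapse = "")
    if (!grepl("CATG", tail, fixed = TRUE)) break
  }
  read2 <- paste0(fr$seq[2L], tail)
  res2 <- splitMap(read2, "tailed", idx, nlaIII(), mapperParams())
  expect_equal(nrow(res2$alignments), 1L)
  expect_equal(nrow(res2$remnants), 1L)
  expect_equal(res2$remnants$segStart, nchar(fr$seq[2L]))
  expect_equal(res2$remnants$segEnd, nchar(read2))
})

test_that("segments and remnants partition every read", {
  res <- mapReads(simL$reads[1:15, ], simL$index, nlaIII(),
                  longReadMapperParams())
  for (id in simL$reads$readId[1:15]) {
    al <- res$alignments[res$alignments$readId == id, ]
    al <- al[!duplicated(al$segStart), ]  # co-optimal copies share geometry
    rem <- res$remnants[res$remnants$readId == id, ]
    iv <- rbind(al[, c("segStart", "segEnd")],
                setNames(rem[, c("segStart", "segEnd")],
                         c("segStart", "segEnd")))
    iv <- iv[order(iv$segStart), ]
    expect_equal(iv$segStart[1L], 0L)
    expect_equal(iv$segEnd[nrow(iv)],
                 nchar(simL$reads$seq[simL$reads$readId == id]))
    if (nrow(iv) > 1L)
      expect_equal(iv$segStart[-1L], iv$segEnd[-nrow(iv)])
  }
})

test_that("error-free segments recover the simulator's provenance exactly", {
  checkRecovery <- function(sim, params, minLen = 15L) {
    res <- mapReads(sim$reads, sim$index, nlaIII(), params)
    ok <- 0L
    for (id in sim$reads$readId) {
      pv <- collapseProvenance(
        sim$provenance[sim$provenance$readId == id, ])
      pv <- pv[pv$readEnd - pv$readStart >= minLen, , drop = FALSE]
      al <- res$alignments[res$alignments$readId == id, ]
      al <- al[order(al$segStart), ]
      good <- nrow(pv) == nrow(al) &&
        all(abs(pv$readStart - al$segStart) <= 4L) &&
        all(abs(pv$readEnd - al$segEnd) <= 4L) &&
        all(abs(pv$refStart - al$refStart) <= 4L) &&
        all(abs(pv$refEnd - al$refEnd) <= 4L) &&
        all(pv$strand == al$strand)
      ok <- ok + good
    }
    ok / length(sim$reads$readId)
  }
  expect_equal(checkRecovery(simL, longReadMapperParams()), 1.0)
  expect_equal(checkRecovery(simS, shortReadMapperParams()), 1.0)

  # brute-force CATG decomposition (exact search against the haplotype
  # sequences) agrees with the collapsed provenance in read space
  haps <- c(h1 = hapSeq(simL$locus, 1), h2 = hapSeq(simL$locus, 2))
  for (id in simL$reads$readId[1:10]) {
    pv <- collapseProvenance(simL$provenance[simL$provenance$readId == id, ])
    bf <- bruteDecompose(simL$reads$seq[simL$reads$readId == id][1L], haps)
    expect_equal(bf$start, pv$readStart)
    expect_equal(bf$end, pv$readEnd)
  }
})

test_that("sub-k fragments between close CATG sites get no direct coverage", {
  # construct a locus with one 12 bp fragment (two CATG sites 12 bp apart)
  lens <- c(1500L, 1400L, 12L, 1600L, 1500L)
  seq <- randomLocusSequence(lens, seed = 23L)
  loc <- diploidLocus(seq, NULL, name = "drop")
  fr <- digest(seq, nlaIII())
  expect_equal(fr$end - fr$start, lens)
  fbh <- digestLocus(loc)
  vp <- designViewpoint(loc, fr$start[1L] + 100L)
  circles <- simulateCircles(fbh, vp, n = 40L, seed = 3L)
  amps <- amplify(circles, vp)
  rr <- generateReads(amps, longReadProfile(subErrorRate = 0,
                                            indelErrorRate = 0),
                      n = 40L, seed = 4L)
  idx <- buildIndex(setNames(seq, "drop"), k = 21L)
  res <- mapReads(rr$reads, idx, nlaIII(), longReadMapperParams())
  small <- fr[3L, ]
  contained <- res$alignments$refStart >= small$start &
    res$alignments$refEnd <= small$end
  expect_equal(sum(contained), 0L)
  # yet the truth provenance shows the fragment was sequenced
  touched <- sum(tlaphaser:::overlapWidth(rr$provenance$refStart,
                                          rr$provenance$refEnd,
                                          small$start, small$end))
  expect_gt(touched, 0L)
})

test_that("ambiguity policies drop or randomise co-optimal placements", {
  ref <- refSeq(locusM)
  idx2 <- buildIndex(c(target = ref, decoy = ref), k = 21L)
  seg <- substr(ref, 3001, 3200)
  keep <- splitMap(seg, "r", idx2, nlaIII(),
                   mapperParams(ambiguityPolicy = "keep"))
  expect_equal(nrow(keep$alignments), 2L)
  drop <- splitMap(seg, "r", idx2, nlaIII(),
                   mapperParams(ambiguityPolicy = "drop"))
  expect_equal(nrow(drop$alignments), 0L)
  expect_equal(drop$remnants$reason, "ambiguous_dropped")
  set.seed(1)
  rnd <- splitMap(seg, "r", idx2, nlaIII(),
                  mapperParams(ambiguityPolicy = "random"))
  expect_equal(nrow(rnd$alignments), 1L)
})
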