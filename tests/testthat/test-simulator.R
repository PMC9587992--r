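locusA <- fixtureLocus(seed = 7L)
fbhA <- digestLocus(locusA)
vpA <- designViewpoint(locusA, variants(locusA)$pos[1L])

test_that("circles are haplotype-pure, contain the viewpoint, and are deterministic", {
  circles <- simulateCircles(fbhA, vpA, n = 50L, seed = 2L)
  for (circ in circles) {
    expect_true(all(circ$frags$hap == circ$hap))
    vpHit <- any(!is.na(circ$frags$refStart) &
                 circ$frags$refStart <= vpA@refPos &
                 vpA@refPos < circ$frags$refEnd)
    expect_true(vpHit)
  }
  again <- simulateCircles(fbhA, vpA, n = 50L, seed = 2L)
  expect_identical(circles, again)
  haps <- vapply(circles, function(c) c$hap, integer(1))
  expect_true(all(haps %in% 1:2))
})

test_that("impossible amplicon bounds raise a simulation error", {
  tight <- contactModel(minAmpliconLen = 99990L, maxAmpliconLen = 99999L)
  set.seed(1)
  expect_error(simulateCircle(fbhA, vpA, tight, maxAttempts = 20L),
               "amplicon length bounds")
})

test_that("amplicons are primer-rotated circles within the length bounds", {
  circles <- simulateCircles(fbhA, vpA, n = 40L, seed = 3L)
  amps <- amplify(circles, vpA)
  expect_length(amps, length(circles))
  lens <- vapply(amps, function(a) nchar(a$seq), integer(1))
  expect_true(all(lens >= 4000L & lens <= 10000L))
  for (a in amps[1:5]) {
    # provenance maps every base and is consistent with the haplotype
    expect_equal(sum(a$provenance$ampEnd - a$provenance$ampStart),
                 nchar(a$seq))
    hs <- hapSeq(locusA, a$hap)
    for (i in seq_len(nrow(a$provenance))) {
      p <- a$provenance[i, ]
      expect_identical(substr(a$seq, p$ampStart + 1L, p$ampEnd),
                       substr(hs, p$hapStart + 1L, p$hapEnd))
    }
  }
  # an injected circle lacking the viewpoint fragment is dropped
  noVp <- circles[[1L]]
  keep <- noVp$frags$refStart > vpA@fragEnd | noVp$frags$refEnd <= vpA@fragStart
  noVp$frags <- noVp$frags[keep, , drop = FALSE]
  expect_length(amplify(list(noVp), vpA), 0L)
})

test_that("short mode emits fixed-length mates; long zero-noise reads equal amplicons", {
  circles <- simulateCircles(fbhA, vpA, n = 20L, seed = 4L)
  amps <- amplify(circles, vpA)
  rs <- generateReads(amps, shortReadProfile(subErrorRate = 0), n = 25L,
                      seed = 5L)
  expect_equal(nrow(rs$reads), 50L)  # 25 pairs
  expect_true(all(nchar(rs$reads$seq) == 150L))
  expect_true(all(grepl("/[12]$", rs$reads$readId)))

  rl <- generateReads(amps, longReadProfile(subErrorRate = 0,
                                            indelErrorRate = 0),
                      n = 10L, seed = 6L)
  ampSeqs <- vapply(amps, function(a) a$seq, character(1))
  ids <- vapply(amps, function(a) a$circleId, integer(1))
  for (i in seq_len(nrow(rl$reads))) {
    cid <- rl$provenance$circleId[rl$provenance$readId ==
                                  rl$reads$readId[i]][1L]
    expect_identical(rl$reads$seq[i], ampSeqs[ids == cid])
  }
})

test_that("long-mode substitution errors follow the binomial expectation", {
  circles <- simulateCircles(fbhA, vpA, n = 30L, seed = 7L)
  amps <- amplify(circles, vpA)
  rl <- generateReads(amps, longReadProfile(subErrorRate = 0.01,
                                            indelErrorRate = 0),
                      n = 30L, seed = 8L)
  ampSeqs <- vapply(amps, function(a) a$seq, character(1))
  ids <- vapply(amps, function(a) a$circleId, integer(1))
  tot <- 0L; n <- 0L
  for (i in seq_len(nrow(rl$reads))) {
    cid <- rl$provenance$circleId[rl$provenance$readId ==
                                  rl$reads$readId[i]][1L]
    src <- ampSeqs[ids == cid]
    tot <- tot + sum(charToRaw(rl$reads$seq[i]) != charToRaw(src))
    n <- n + nchar(src)
  }
  expect_lt(abs(tot - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))
})

test_that("haplotype assignment is balanced across many circles", {
  circles <- simulateCircles(fbhA, vpA, n = 2000L, seed = 9L)
  frac0 <- mean(vapply(circles, function(c) c$hap, integer(1)) == 1L)
  expect_lt(abs(frac0 - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("truth depth decays with fragment distance from the viewpoint", {
  circles <- simulateCircles(fbhA, vpA, n = 150L, seed = 10L)
  amps <- amplify(circles, vpA)
  rr <- generateReads(amps, longReadProfile(subErrorRate = 0,
                                            indelErrorRate = 0),
                      n = 150L, seed = 11L)
  d <- provenanceDepthByFragment(rr$provenance, locusA, vpA)
  rho <- cor(d$meanDepth, d$distance, method = "spearman")
  expect_lte(rho, -0.5)
  expect_equal(which.max(d$meanDepth), which(d$distance == 0L))
})

test_that("simulateRun writes byte-identical outputs for the same config", {
  loc <- fixtureLocus(seed = 21L, nFragments = 6L, fragmentLength = 1100L,
                      nHetSnvs = 4L, nHetIndels = 0L)
  refDir <- tempfile("simrun_in_")
  dir.create(refDir)
  writeFasta(setNames(refSeq(loc), refName(loc)),
             file.path(refDir, "ref.fa"))
  writePhasedVcf(variants(loc), refName(loc), nchar(refSeq(loc)),
                 file.path(refDir, "truth.vcf"))
  vp <- designViewpoint(loc, variants(loc)$pos[1L])
  gr <- GenomicRanges::GRanges(refName(loc),
          IRanges::IRanges(start = vp@refPos + 1L, width = 1L))
  gr$name <- "vp1"
  rtracklayer::export(gr, file.path(refDir, "vps.bed"))
  cfg <- list(referenceFasta = file.path(refDir, "ref.fa"),
              truthVcf = file.path(refDir, "truth.vcf"),
              viewpointBed = file.path(refDir, "vps.bed"),
              platform = "short", nCircles = 20L, nReads = 30L,
              seed = 5L, outDir = tempfile("simrun_out_"))
  p1 <- simulateRun(cfg)
  md1 <- tools::md5sum(unlist(p1))
  cfg$outDir <- tempfile("simrun_out_")
  p2 <- simulateRun(cfg)
  expect_identical(unname(md1), unname(tools::md5sum(unlist(p2))))
  # provenance rows cover every emitted read
  prov <- read.table(p1$provenance, header = TRUE, sep = "\t")
  reads <- readFastq(p1$fastq)
  expect_setequal(unique(prov$readId), reads$readId)

  cfg$nCircles <- 0L
  cfg$outDir <- tempfile("simrun_out_")
  expect_error(simulateRun(cfg[setdiff(names(cfg), "truthVcf")]),
               "missing key")
})
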