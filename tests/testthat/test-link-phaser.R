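test_that("allele co-occurrence on one molecule yields cis/trans links", {
  ref <- c(t = randomLocusSequence(c(400L, 400L), seed = 51L))
  hetA <- 100L; hetB <- 300L
  baseA <- substr(ref[[1L]], hetA + 1L, hetA + 1L)
  baseB <- substr(ref[[1L]], hetB + 1L, hetB + 1L)
  altA <- setdiff(c("A", "C", "G", "T"), baseA)[1L]
  altB <- setdiff(c("A", "C", "G", "T"), baseB)[1L]
  hets <- data.frame(refName = "t", pos = c(hetA, hetB),
                     ref = c(baseA, baseB), alt = c(altA, altB),
                     genotype = "0/1", stringsAsFactors = FALSE)
  # one molecule with two segments: ALT at site A, REF at site B
  seg1 <- substr(ref[[1L]], 51L, 150L)
  substr(seg1, 51L, 51L) <- altA  # ref pos 100 = segment offset 50 (0-based)
  seg2 <- substr(ref[[1L]], 251L, 350L)
  reads <- data.frame(readId = c("m1/1", "m1/2"), seq = c(seg1, seg2),
                      stringsAsFactors = FALSE)
  aln <- data.frame(readId = c("m1/1", "m1/2"), segStart = 0L,
                    segEnd = 100L, refName = "t",
                    refStart = c(50L, 250L), refEnd = c(150L, 350L),
                    strand = "+", mismatches = c(1L, 0L),
                    ambiguous = FALSE, round = 1L, cigar = "100M",
                    stringsAsFactors = FALSE)
  out <- extractLinks(aln, hets, reads, ref)
  expect_equal(nrow(out$observations), 2L)
  expect_equal(sort(out$observations$allele), c(0L, 1L))
  expect_equal(nrow(out$links), 1L)
  expect_equal(out$links$nTrans, 1L)
  expect_equal(out$links$nCis, 0L)

  # a molecule covering a single het: one observation, no link
  out1 <- extractLinks(aln[1L, ], hets, reads[1L, ], ref)
  expect_equal(nrow(out1$observations), 1L)
  expect_equal(nrow(out1$links), 0L)
})

test_that("error-free simulated links are pure and match the truth phase", {
  loc <- fixtureLocus(seed = 37L, nFragments = 6L, fragmentLength = 1100L,
                      nHetSnvs = 5L, nHetIndels = 1L)
  sim <- fixtureSim(loc, platform = "long", nCircles = 50L, nReads = 100L)
  res <- mapReads(sim$reads, sim$index, nlaIII(), longReadMapperParams())
  v <- variants(loc)
  hets <- data.frame(refName = refName(loc), pos = v$pos, ref = v$ref,
                     alt = v$alt, genotype = "0/1",
                     stringsAsFactors = FALSE)
  out <- extractLinks(res$alignments, hets, sim$reads, sim$refs)
  expect_gt(nrow(out$links), 0L)
  expect_true(all(out$links$nCis == 0L | out$links$nTrans == 0L))
  # cis/trans orientation matches the planted phase
  hc <- out$hetCalls
  for (i in seq_len(nrow(out$links))) {
    a <- out$links$varA[i]; b <- out$links$varB[i]
    va <- v[v$pos == hc$pos[hc$variantId == a], ]
    vb <- v[v$pos == hc$pos[hc$variantId == b], ]
    sameHap <- va$gt1 == vb$gt1
    if (out$links$nCis[i] > 0L) expect_true(sameHap)
    else expect_false(sameHap)
  }
})

test_that("majority rule and canonical orientation govern two-variant blocks", {
  hc <- data.frame(refName = "t", pos = c(100L, 200L), ref = "A",
                   alt = "C", variantId = 1:2)
  links <- data.frame(varA = 1L, varB = 2L, nCis = 6L, nTrans = 4L)
  ph <- phaseVariants(links, hc)
  expect_equal(nrow(ph$blocks), 2L)
  expect_equal(ph$blocks$side, c(0L, 0L))       # cis, canonicalised
  expect_equal(ph$blockScores$score, 6L)
  trans <- phaseVariants(data.frame(varA = 1L, varB = 2L, nCis = 1L,
                                    nTrans = 9L), hc)
  expect_equal(trans$blocks$side, c(0L, 1L))
  expect_equal(trans$blockScores$score, 9L)
})

test_that("no links means no phased variants", {
  hc <- data.frame(refName = "t", pos = c(1L, 2L, 3L) * 100L, ref = "A",
                   alt = "C", variantId = 1:3)
  ph <- phaseVariants(data.frame(varA = integer(), varB = integer(),
                                 nCis = integer(), nTrans = integer()), hc)
  expect_equal(nrow(ph$blocks), 0L)
  expect_equal(ph$unphased, 1:3)
})

test_that("contradictory zero-weight components are left unphased", {
  hc <- data.frame(refName = "t", pos = c(100L, 200L), ref = "A",
                   alt = "C", variantId = 1:2)
  expect_warning(
    ph <- phaseVariants(data.frame(varA = 1L, varB = 2L, nCis = 3L,
                                   nTrans = 3L), hc),
    "contradictory")
  expect_equal(nrow(ph$blocks), 0L)
})

test_that("the exhaustive oracle bounds and mostly equals the greedy phaser", {
  # fully consistent 5-het instance: greedy equals brute force
  hc5 <- data.frame(refName = "t", pos = (1:5) * 100L, ref = "A",
                    alt = "C", variantId = 1:5)
  links5 <- data.frame(varA = c(1L, 2L, 3L, 4L, 1L),
                       varB = c(2L, 3L, 4L, 5L, 3L),
                       nCis = c(5L, 0L, 4L, 6L, 0L),
                       nTrans = c(0L, 7L, 0L, 0L, 6L))
  ph <- phaseVariants(links5, hc5)
  bf <- bruteForcePhase(links5, hc5)
  expect_equal(sum(ph$blockScores$score), bf$score)

  # random 8-het instances: never above, equal on >= 95%
  set.seed(123)
  eq <- 0L; n <- 60L
  for (i in seq_len(n)) {
    inst <- randomLinkInstance(8L, 12L)
    if (!nrow(inst$links)) { eq <- eq + 1L; next }
    ph <- suppressWarnings(phaseVariants(inst$links, inst$hetCalls))
    bf <- bruteForcePhase(inst$links, inst$hetCalls)
    expect_lte(sum(ph$blockScores$score), bf$score)
    if (sum(ph$blockScores$score) == bf$score) eq <- eq + 1L
  }
  expect_gte(eq / n, 0.95)

  # tree-structured instances: always equal
  set.seed(7)
  for (i in 1:20) {
    nH <- 7L
    hc <- data.frame(refName = "t", pos = seq_len(nH) * 50L, ref = "A",
                     alt = "C", variantId = seq_len(nH))
    parent <- c(NA, vapply(2:nH, function(v) sample(v - 1L, 1L),
                           integer(1)))
    links <- data.frame(varA = parent[-1L], varB = 2:nH,
                        nCis = sample(0:8, nH - 1L, replace = TRUE),
                        nTrans = sample(0:8, nH - 1L, replace = TRUE))
    links[links$nCis + links$nTrans == 0L, "nCis"] <- 1L
    sw <- links$varA > links$varB
    tmp <- links$varA[sw]; links$varA[sw] <- links$varB[sw]
    links$varB[sw] <- tmp
    ph <- suppressWarnings(phaseVariants(links, hc))
    bf <- bruteForcePhase(links, hc)
    expect_equal(sum(ph$blockScores$score), bf$score)
  }
})

test_that("bruteForcePhase refuses oversized instances", {
  hc <- data.frame(refName = "t", pos = (1:13) * 10L, ref = "A",
                   alt = "C", variantId = 1:13)
  expect_error(bruteForcePhase(data.frame(varA = 1L, varB = 2L,
                                          nCis = 1L, nTrans = 0L),
                               hc, limit = 12L), "refuses")
})

test_that("noise-free long reads phase every het concordantly", {
  loc <- fixtureLocus(seed = 43L, nFragments = 6L, fragmentLength = 1100L,
                      nHetSnvs = 5L, nHetIndels = 1L)
  sim <- fixtureSim(loc, platform = "long", nCircles = 60L, nReads = 150L)
  res <- mapReads(sim$reads, sim$index, nlaIII(), longReadMapperParams())
  pu <- pileupAlignments(res$alignments, sim$reads, sim$refs)
  calls <- callVariants(pu, callerConfig(minDepth = 20L), sim$refs)
  hets <- calls[calls$genotype == "0/1", ]
  out <- extractLinks(res$alignments, hets, sim$reads, sim$refs)
  ph <- phaseVariants(out$links, out$hetCalls)
  cmp <- comparePhasing(ph, out$hetCalls, variants(loc))
  expect_equal(cmp$nHeterozygous, 6L)
  expect_equal(cmp$nPhased, 6L)
  expect_equal(cmp$nConcordantPhased, 6L)
  expect_equal(cmp$nSwitchErrors, 0L)
  expect_equal(cmp$nBlocks, 1L)
})
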