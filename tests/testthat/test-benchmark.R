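truthB <- data.frame(
  refName = "t",
  pos = c(100L, 200L, 300L, 400L, 500L),
  ref = c("A", "C", "G", "GTT", "T"),
  alt = c("C", "T", "A", "G", "TG"),
  gt1 = c(0L, 1L, 1L, 0L, 1L),
  gt2 = c(1L, 0L, 1L, 1L, 0L),
  stringsAsFactors = FALSE)

callsFromTruth <- function(tr) {
  het <- tr$gt1 != tr$gt2
  data.frame(refName = tr$refName, pos = tr$pos, ref = tr$ref,
             alt = tr$alt, genotype = ifelse(het, "0/1", "1/1"),
             depth = 50L, altCount = 25L, altFraction = 0.5,
             kind = ifelse(nchar(tr$ref) == 1L & nchar(tr$alt) == 1L,
                           "SNV", "INDEL"), stringsAsFactors = FALSE)
}

test_that("perfect calls at full coverage are fully concordant", {
  pu <- makePileup("t", 700L, 50L)
  cmp <- compareGenotypes(callsFromTruth(truthB), truthB, pu,
                          shortReadCallerConfig(), "t")
  expect_equal(cmp$nInReference, c(3L, 2L))      # SNV, INDEL
  expect_equal(cmp$nCovered, c(3L, 2L))
  expect_equal(cmp$nConcordant, c(3L, 2L))
  expect_equal(cmp$nDiscordant, c(0L, 0L))
  expect_equal(cmp$nMissing, c(0L, 0L))
})

test_that("a spurious call counts as discordant, not concordant", {
  calls <- rbind(callsFromTruth(truthB),
                 data.frame(refName = "t", pos = 600L, ref = "A",
                            alt = "G", genotype = "0/1", depth = 50L,
                            altCount = 25L, altFraction = 0.5,
                            kind = "SNV", stringsAsFactors = FALSE))
  cmp <- compareGenotypes(calls, truthB, makePileup("t", 700L, 50L),
                          shortReadCallerConfig(), "t")
  snv <- cmp[cmp$class == "SNV", ]
  expect_equal(snv$nCalled, snv$nConcordant + 1L)
  expect_equal(snv$nDiscordant, 1L)
})

test_that("truth variants below the depth filter are neither covered nor missing", {
  depth <- rep(50L, 700L)
  depth[101L] <- 10L  # truth SNV at pos 100 under-covered
  pu <- makePileup("t", 700L, depth)
  calls <- callsFromTruth(truthB)
  calls <- calls[calls$pos != 100L, ]
  cmp <- compareGenotypes(calls, truthB, pu, shortReadCallerConfig(), "t")
  snv <- cmp[cmp$class == "SNV", ]
  expect_equal(snv$nInReference, 3L)
  expect_equal(snv$nCovered, 2L)
  expect_equal(snv$nMissing, 0L)
  # a genotype mismatch (hom called het) is discordant
  calls2 <- callsFromTruth(truthB)
  calls2$genotype[calls2$pos == 300L] <- "0/1"  # truth is 1/1
  cmp2 <- compareGenotypes(calls2, truthB, makePileup("t", 700L, 50L),
                           shortReadCallerConfig(), "t")
  expect_equal(cmp2[cmp2$class == "SNV", "nDiscordant"], 1L)
  expect_error(compareGenotypes(calls2, truthB, makePileup("t", 700L, 50L),
                                shortReadCallerConfig(), "elsewhere"),
               "mismatch")
})

# Phasing comparisons ------------------------------------------------------

mkPhase <- function(hc, sides, blockId = 1L) {
  list(blocks = data.frame(blockId = blockId, variantId = hc$variantId,
                           pos = hc$pos, side = sides),
       blockScores = data.frame(blockId = unique(blockId), score = 1L),
       unphased = integer(0))
}

hcB <- local({
  tr <- truthB[truthB$gt1 != truthB$gt2, ]
  data.frame(refName = "t", pos = tr$pos, ref = tr$ref, alt = tr$alt,
             genotype = "0/1", variantId = seq_len(nrow(tr)),
             stringsAsFactors = FALSE)
})
truthSides <- local({
  tr <- truthB[truthB$gt1 != truthB$gt2, ]
  ifelse(tr$gt1 == 1L, 0L, 1L)
})

test_that("phasing comparison is invariant to a global block flip", {
  direct <- comparePhasing(mkPhase(hcB, truthSides), hcB, truthB)
  flipped <- comparePhasing(mkPhase(hcB, 1L - truthSides), hcB, truthB)
  expect_equal(direct$nConcordantPhased, nrow(hcB))
  expect_equal(direct$nSwitchErrors, 0L)
  expect_equal(flipped$nConcordantPhased, direct$nConcordantPhased)
  expect_equal(flipped$nSwitchErrors, direct$nSwitchErrors)
})

test_that("one interior flip in a four-variant block gives two switch errors", {
  sides <- truthSides
  sides[2L] <- 1L - sides[2L]
  cmp <- comparePhasing(mkPhase(hcB, sides), hcB, truthB)
  expect_equal(cmp$nPhased, 4L)
  expect_equal(cmp$nConcordantPhased, 3L)
  expect_equal(cmp$nSwitchErrors, 2L)
})

test_that("an unphased call set yields all-zero phased counters", {
  empty <- list(blocks = data.frame(blockId = integer(),
                                    variantId = integer(),
                                    pos = integer(), side = integer()),
                blockScores = data.frame(), unphased = hcB$variantId)
  cmp <- comparePhasing(empty, hcB, truthB)
  expect_equal(cmp$nPhased, 0L)
  expect_equal(cmp$nConcordantPhased, 0L)
  expect_equal(cmp$nHeterozygous, 4L)
})

test_that("truth versus truth is perfectly concordant end to end", {
  loc <- fixtureLocus(seed = 47L, nFragments = 5L, fragmentLength = 900L,
                      nHetSnvs = 4L, nHetIndels = 1L)
  v <- variants(loc)
  calls <- data.frame(refName = refName(loc), pos = v$pos, ref = v$ref,
                      alt = v$alt,
                      genotype = ifelse(v$gt1 != v$gt2, "0/1", "1/1"),
                      depth = 200L, altCount = 100L, altFraction = 0.5,
                      kind = v$kind, stringsAsFactors = FALSE)
  pu <- makePileup(refName(loc), nchar(refSeq(loc)), 200L)
  cmp <- compareGenotypes(calls, v, pu, callerConfig(), refName(loc))
  expect_equal(sum(cmp$nConcordant), nrow(v))
  expect_equal(sum(cmp$nDiscordant), 0L)
  hets <- calls[calls$genotype == "0/1", ]
  hets$variantId <- seq_len(nrow(hets))
  vhet <- v[v$gt1 != v$gt2, ]
  cmp2 <- comparePhasing(mkPhase(hets, ifelse(vhet$gt1 == 1L, 0L, 1L)),
                         hets, v)
  expect_equal(cmp2$nConcordantPhased, nrow(hets))
  expect_equal(cmp2$nSwitchErrors, 0L)
})
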