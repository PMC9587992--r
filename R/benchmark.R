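#' @include phaser.R
NULL

# Genotype class of a truth variant row ("het", "homalt" or "homref").
.truthGtClass <- function(v) {
  ifelse(v$gt1 != v$gt2, "het", ifelse(v$gt1 == 1L, "homalt", "homref"))
}

#' Compare genotype calls against a phased truth set
#'
#' Counts, per variant class (SNV, INDEL): variants in the truth set,
#' truth variants covered at the caller's minimum depth, calls made,
#' concordant calls (position, alleles and genotype all match), discordant
#' calls (calls absent from the truth or with a mismatched genotype), and
#' covered truth variants with no call at all (missing). Truth variants
#' below the depth threshold are counted in the reference total but are
#' neither covered nor missing.
#'
#' @param calls Call data.frame from [callVariants()].
#' @param truth Truth variant data.frame (`pos`, `ref`, `alt`, `gt1`,
#'   `gt2`; a `refName` column must match the calls').
#' @param pileup The [Pileup-class] the calls were made from.
#' @param config The [CallerConfig-class] used.
#' @param targetRef Reference name the truth refers to.
#' @return data.frame with one row per class and columns `class`,
#'   `nInReference`, `nCovered`, `nCalled`, `nConcordant`, `nDiscordant`,
#'   `nMissing`.
#' @export
compareGenotypes <- function(calls, truth, pileup, config,
                             targetRef = NULL) {
  if (is.null(targetRef)) {
    targetRef <- if (nrow(truth) && !is.null(truth$refName))
      truth$refName[1L] else names(pileup@refLens)[1L]
  }
  if (!targetRef %in% names(pileup@refLens))
    stop("truth/call reference name mismatch: ", targetRef)
  tr <- truth
  if (!is.null(tr$refName)) tr <- tr[tr$refName == targetRef, , drop = FALSE]
  tr$kind <- ifelse(nchar(tr$ref) == 1L & nchar(tr$alt) == 1L,
                    "SNV", "INDEL")
  tr$gtClass <- .truthGtClass(tr)
  tr <- tr[tr$gtClass != "homref", , drop = FALSE]
  cl <- calls[calls$refName == targetRef, , drop = FALSE]
  out <- lapply(c("SNV", "INDEL"), function(kind) {
    t0 <- tr[tr$kind == kind, , drop = FALSE]
    c0 <- cl[cl$kind == kind, , drop = FALSE]
    depth <- if (nrow(t0))
      pileup@depth[[targetRef]][t0$pos + 1L] else integer(0)
    covered <- depth >= config@minDepth
    key <- function(d) paste(d$pos, d$ref, d$alt)
    match <- match(key(c0), key(t0))
    gtOk <- !is.na(match) &
      ((c0$genotype == "0/1" & t0$gtClass[match] == "het") |
       (c0$genotype == "1/1" & t0$gtClass[match] == "homalt"))
    nConc <- sum(gtOk)
    hasConcCall <- logical(nrow(t0))
    hasConcCall[match[gtOk]] <- TRUE
    hasAnyCall <- t0$pos %in% c0$pos
    data.frame(class = kind,
               nInReference = nrow(t0),
               nCovered = sum(covered),
               nCalled = nrow(c0),
               nConcordant = nConc,
               nDiscordant = nrow(c0) - nConc,
               nMissing = sum(covered & !hasAnyCall),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare a phasing result against the truth phase
#'
#' For every block the global orientation (flip or keep) maximising
#' per-variant agreement with the truth is chosen; variants agreeing
#' under that orientation count as concordantly phased. Switch errors are
#' the number of adjacent agreement-state changes along the
#' position-sorted phased variants of each block. Only phased variants
#' matching a truth heterozygous site (position and alleles) enter the
#' comparison.
#'
#' @param phased Result of [phaseVariants()].
#' @param hetCalls The heterozygous call table the phaser ran on (with
#'   `variantId`).
#' @param truth Truth variant data.frame (phased; `gt1`/`gt2`).
#' @return List with `nHeterozygous`, `nPhased`, `nConcordantPhased`,
#'   `nSwitchErrors`, `nBlocks` and `perBlock` detail.
#' @export
comparePhasing <- function(phased, hetCalls, truth) {
  tr <- truth
  tr$gtClass <- .truthGtClass(tr)
  trHet <- tr[tr$gtClass == "het", , drop = FALSE]
  nHet <- nrow(trHet)
  blocks <- phased$blocks
  if (!nrow(blocks))
    return(list(nHeterozygous = nHet, nPhased = 0L,
                nConcordantPhased = 0L, nSwitchErrors = 0L, nBlocks = 0L,
                perBlock = data.frame()))
  hc <- hetCalls
  key <- paste(trHet$pos, trHet$ref, trHet$alt)
  # truth side: 0 when the ALT allele sits on haplotype 1
  trSide <- ifelse(trHet$gt1 == 1L, 0L, 1L)
  perBlock <- list()
  nPhased <- 0L; nConc <- 0L; nSwitch <- 0L
  for (b in unique(blocks$blockId)) {
    bd <- blocks[blocks$blockId == b, , drop = FALSE]
    bd <- bd[order(bd$pos), , drop = FALSE]
    vi <- match(bd$variantId, hc$variantId)
    tKey <- paste(hc$pos[vi], hc$ref[vi], hc$alt[vi])
    ti <- match(tKey, key)
    known <- !is.na(ti)
    nPhased <- nPhased + sum(known)
    if (!any(known)) next
    agree0 <- bd$side[known] == trSide[ti[known]]
    agree <- if (sum(agree0) >= sum(!agree0)) agree0 else !agree0
    conc <- sum(agree)
    sw <- if (length(agree) > 1L) sum(diff(agree) != 0L) else 0L
    nConc <- nConc + conc
    nSwitch <- nSwitch + sw
    perBlock[[length(perBlock) + 1L]] <- data.frame(
      blockId = b, nVariants = nrow(bd), nComparable = sum(known),
      nConcordant = conc, nSwitchErrors = sw)
  }
  list(nHeterozygous = nHet, nPhased = nPhased, nConcordantPhased = nConc,
       nSwitchErrors = nSwitch, nBlocks = length(unique(blocks$blockId)),
       perBlock = if (length(perBlock)) do.call(rbind, perBlock)
                  else data.frame())
}

#' Assemble a benchmark report
#'
#' @param genotypes Output of [compareGenotypes()].
#' @param phasing Output of [comparePhasing()].
#' @return A [BenchmarkReport-class].
#' @export
benchmarkReport <- function(genotypes, phasing) {
  new("BenchmarkReport", genotypes = genotypes, phasing = phasing)
}
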