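#' @include split-mapper.R
NULL

# Left-normalisation of indel observations (standard VCF left-alignment):
# shift the event left while the base before it equals its last base.
.leftNormIns <- function(refSeq, anchor0, insSeq) {
  n <- nchar(insSeq)
  while (anchor0 > 0L) {
    b <- substr(refSeq, anchor0 + 1L, anchor0 + 1L)
    if (b != substr(insSeq, n, n)) break
    insSeq <- paste0(b, substr(insSeq, 1L, n - 1L))
    anchor0 <- anchor0 - 1L
  }
  list(pos = anchor0, seq = insSeq)
}

.leftNormDel <- function(refSeq, anchor0, len) {
  while (anchor0 > 0L &&
         substr(refSeq, anchor0 + 1L, anchor0 + 1L) ==
         substr(refSeq, anchor0 + 1L + len, anchor0 + 1L + len)) {
    anchor0 <- anchor0 - 1L
  }
  anchor0
}

# Oriented segment sequence of an alignment row (as aligned to the
# forward reference strand).
.orientedSeg <- function(readSeq, a) {
  sub <- substring(readSeq, a$segStart + 1L, a$segEnd)
  if (a$strand == "-") revComp(sub) else sub
}

.parseCigar <- function(cigar) {
  runs <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1L]]
  list(len = as.integer(sub("[MID]", "", runs)), op = sub("\\d+", "", runs))
}

# ---------------------------------------------------------------------------
# Pileup construction
# ---------------------------------------------------------------------------

#' Build a pileup from fragment alignments
#'
#' Every aligned (non-clipped) base contributes one unit of depth at its
#' reference position; mismatching bases are recorded as SNV ALT
#' observations and indels as left-anchored `+SEQ` / `-N` observations.
#' Depth counts fragments, not molecules: two segments of one read
#' overlapping the same position count twice.
#'
#' @param alignments Alignment data.frame from [mapReads()].
#' @param reads Read data.frame (`readId`, `seq`).
#' @param references Named character vector of reference sequences, or a
#'   [SeedIndex-class].
#' @return A [Pileup-class].
#' @export
pileupAlignments <- function(alignments, reads, references) {
  if (methods::is(references, "SeedIndex"))
    references <- references@refSeqs
  refLens <- setNames(nchar(references), names(references))
  seqs <- setNames(reads$seq, reads$readId)
  n <- nrow(alignments)
  mList <- vector("list", n)
  oList <- vector("list", n)
  readIds <- alignments$readId
  refNames <- alignments$refName
  cigars <- alignments$cigar
  refStarts <- alignments$refStart
  refEnds <- alignments$refEnd
  for (i in seq_len(n)) {
    rn <- refNames[i]
    if (refEnds[i] > refLens[[rn]] || refStarts[i] < 0L)
      stop("alignment interval outside reference ", rn)
    q <- .orientedSeg(seqs[[readIds[i]]], alignments[i, ])
    rseq <- references[[rn]]
    cg <- .parseCigar(cigars[i])
    qpos <- 1L; rpos <- refStarts[i]  # rpos 0-based
    mS <- integer(0); mE <- integer(0)
    oPos <- integer(0); oAll <- character(0)
    for (j in seq_along(cg$op)) {
      len <- cg$len[j]
      if (cg$op[j] == "M") {
        mS <- c(mS, rpos); mE <- c(mE, rpos + len)
        qa <- charToRaw(substr(q, qpos, qpos + len - 1L))
        ra <- charToRaw(substr(rseq, rpos + 1L, rpos + len))
        mm <- which(qa != ra)
        if (length(mm)) {
          oPos <- c(oPos, rpos + mm - 1L)
          oAll <- c(oAll, strsplit(rawToChar(qa[mm]), "")[[1L]])
        }
        qpos <- qpos + len; rpos <- rpos + len
      } else if (cg$op[j] == "I") {
        if (rpos > 0L) {
          norm <- .leftNormIns(rseq, rpos - 1L,
                               substr(q, qpos, qpos + len - 1L))
          oPos <- c(oPos, norm$pos)
          oAll <- c(oAll, paste0("+", norm$seq))
        }
        qpos <- qpos + len
      } else {
        if (rpos > 0L) {
          oPos <- c(oPos, .leftNormDel(rseq, rpos - 1L, len))
          oAll <- c(oAll, paste0("-", len))
        }
        rpos <- rpos + len
      }
    }
    mList[[i]] <- list(ref = rn, s = mS, e = mE)
    if (length(oPos)) oList[[i]] <- list(ref = rn, pos = oPos, all = oAll)
  }
  mRef <- rep(vapply(mList, `[[`, character(1), "ref"),
              vapply(mList, function(x) length(x$s), integer(1)))
  mS <- unlist(lapply(mList, `[[`, "s"), use.names = FALSE)
  mE <- unlist(lapply(mList, `[[`, "e"), use.names = FALSE)
  oKeep <- oList[!vapply(oList, is.null, logical(1))]
  oRef <- rep(vapply(oKeep, `[[`, character(1), "ref"),
              vapply(oKeep, function(x) length(x$pos), integer(1)))
  oPos <- unlist(lapply(oKeep, `[[`, "pos"), use.names = FALSE)
  oAll <- unlist(lapply(oKeep, `[[`, "all"), use.names = FALSE)
  if (is.null(mS)) { mS <- integer(0); mE <- integer(0) }
  if (is.null(oPos)) { oPos <- integer(0); oAll <- character(0) }
  depth <- lapply(names(refLens), function(rn) {
    sel <- mRef == rn
    if (!any(sel)) return(integer(refLens[[rn]]))
    cov <- IRanges::coverage(IRanges::IRanges(start = mS[sel] + 1L,
                                              end = mE[sel]),
                             width = refLens[[rn]])
    as.integer(cov)
  })
  names(depth) <- names(refLens)
  altCounts <- if (length(oPos)) {
    ag <- aggregate(list(count = rep(1L, length(oPos))),
                    by = list(refName = oRef, pos = oPos, allele = oAll),
                    FUN = sum)
    ag[order(ag$refName, ag$pos, ag$allele), ]
  } else data.frame(refName = character(), pos = integer(),
                    allele = character(), count = integer())
  rownames(altCounts) <- NULL
  new("Pileup", refLens = refLens, depth = depth, altCounts = altCounts,
      alignedBases = sum(as.numeric(mE - mS)))
}

#' Depth at a reference position
#'
#' @param pileup A [Pileup-class].
#' @param refName Reference name.
#' @param pos 0-based position(s).
#' @return Integer depth(s).
#' @export
depthAt <- function(pileup, refName, pos) {
  pileup@depth[[refName]][pos + 1L]
}

# ---------------------------------------------------------------------------
# On-target and coverage statistics
# ---------------------------------------------------------------------------

.roiAsDf <- function(roi) {
  if (methods::is(roi, "GRanges")) {
    data.frame(refName = as.character(GenomicRanges::seqnames(roi)),
               start = GenomicRanges::start(roi) - 1L,
               end = GenomicRanges::end(roi), stringsAsFactors = FALSE)
  } else as.data.frame(roi)
}

#' On-target nucleotide statistics
#'
#' The share of aligned nucleotides falling inside the region of interest,
#' and the average depth the on-target nucleotides imply.
#'
#' @param alignments Alignment data.frame from [mapReads()].
#' @param roi Regions of interest: `GRanges` or data.frame with `refName`,
#'   `start`, `end` (0-based half-open).
#' @return List with `onTargetNt`, `totalNt`, `fraction`,
#'   `meanDepthInRoi`.
#' @export
onTargetStats <- function(alignments, roi) {
  roi <- .roiAsDf(roi)
  if (!nrow(roi)) stop("empty region of interest")
  total <- sum(as.numeric(alignments$refEnd - alignments$refStart))
  onT <- 0
  for (i in seq_len(nrow(roi))) {
    sel <- alignments$refName == roi$refName[i]
    onT <- onT + sum(as.numeric(overlapWidth(
      alignments$refStart[sel], alignments$refEnd[sel],
      roi$start[i], roi$end[i])))
  }
  roiLen <- sum(roi$end - roi$start)
  list(onTargetNt = onT, totalNt = total,
       fraction = if (total > 0) onT / total else NA_real_,
       meanDepthInRoi = onT / roiLen)
}

#' Positions covered at a minimum depth
#'
#' @param pileup A [Pileup-class].
#' @param minDepth Depth threshold (e.g. 25 for short reads, 100 for long
#'   reads).
#' @param roi Regions of interest (as in [onTargetStats()]).
#' @return List with `coveredPositions`, `roiLength`, `percent` and
#'   `zeroDepthIntervals` (data.frame of maximal zero-depth runs within
#'   the ROI).
#' @export
coverageAtDepth <- function(pileup, minDepth, roi) {
  stopifnot(minDepth >= 1L)
  roi <- .roiAsDf(roi)
  covered <- 0L; roiLen <- 0L
  zeros <- list()
  for (i in seq_len(nrow(roi))) {
    d <- pileup@depth[[roi$refName[i]]][(roi$start[i] + 1L):roi$end[i]]
    covered <- covered + sum(d >= minDepth)
    roiLen <- roiLen + length(d)
    r <- rle(d == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    z <- which(r$values)
    if (length(z))
      zeros[[length(zeros) + 1L]] <- data.frame(
        refName = roi$refName[i],
        start = roi$start[i] + starts[z] - 1L,
        end = roi$start[i] + ends[z], stringsAsFactors = FALSE)
  }
  zeroDf <- if (length(zeros)) do.call(rbind, zeros) else
    data.frame(refName = character(), start = integer(), end = integer())
  list(coveredPositions = covered, roiLength = roiLen,
       percent = 100 * covered / roiLen, zeroDepthIntervals = zeroDf)
}

# ---------------------------------------------------------------------------
# Genotype calling
# ---------------------------------------------------------------------------

# Convert an internal allele key at an anchor position to padded VCF
# ref/alt strings.
.alleleToVcf <- function(key, refSeq, pos) {
  base <- substr(refSeq, pos + 1L, pos + 1L)
  if (grepl("^\\+", key)) {
    list(ref = base, alt = paste0(base, sub("^\\+", "", key)),
         kind = "INDEL")
  } else if (grepl("^-", key)) {
    d <- as.integer(sub("^-", "", key))
    list(ref = substr(refSeq, pos + 1L, pos + 1L + d), alt = base,
         kind = "INDEL")
  } else {
    list(ref = base, alt = key, kind = "SNV")
  }
}

#' Depth-filtered genotype calling from a pileup
#'
#' Positions with depth below `minDepth` are never called. At the
#' remaining positions the dominant ALT observation is genotyped by
#' allele fraction: within the heterozygous band (and above the absolute
#' ALT floor) a 0/1 call is emitted; at or above `homAfMin` a 1/1 call.
#'
#' @param pileup A [Pileup-class].
#' @param config A [CallerConfig-class].
#' @param references Named character vector of reference sequences (for
#'   padded indel alleles), or a [SeedIndex-class].
#' @return data.frame with `refName`, `pos` (0-based), `ref`, `alt`,
#'   `genotype` ("0/1" or "1/1"), `depth`, `altCount`, `altFraction`,
#'   `kind`.
#' @export
callVariants <- function(pileup, config = callerConfig(), references) {
  if (methods::is(references, "SeedIndex"))
    references <- references@refSeqs
  ac <- pileup@altCounts
  out <- list()
  if (nrow(ac)) {
    for (i in seq_len(nrow(ac))) {
      rn <- ac$refName[i]; pos <- ac$pos[i]
      depth <- pileup@depth[[rn]][pos + 1L]
      if (is.na(depth) || depth < config@minDepth) next
      af <- ac$count[i] / depth
      genotype <- if (af >= config@homAfMin) "1/1"
        else if (af >= config@hetAfLow && af <= config@hetAfHigh &&
                 ac$count[i] >= config@minAltCount) "0/1"
        else NA_character_
      if (is.na(genotype)) next
      al <- .alleleToVcf(ac$allele[i], references[[rn]], pos)
      out[[length(out) + 1L]] <- data.frame(
        refName = rn, pos = pos, ref = al$ref, alt = al$alt,
        genotype = genotype, depth = depth, altCount = ac$count[i],
        altFraction = af, kind = al$kind, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(refName = character(), pos = integer(), ref = character(),
               alt = character(), genotype = character(), depth = integer(),
               altCount = integer(), altFraction = numeric(),
               kind = character(), stringsAsFactors = FALSE)
  # one call per position: keep the best-supported allele
  if (nrow(calls) > 1L) {
    calls <- calls[order(calls$refName, calls$pos, -calls$altCount,
                         calls$alt), ]
    calls <- calls[!duplicated(calls[, c("refName", "pos")]), ]
  }
  rownames(calls) <- NULL
  calls
}
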