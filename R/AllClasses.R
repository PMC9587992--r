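#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# RestrictionEnzyme
# ---------------------------------------------------------------------------

#' Restriction enzyme description
#'
#' A recognition motif (IUPAC codes allowed) plus the offset within the
#' motif at which the fragment boundary falls. For NlaIII (CATG, 3'
#' overhang) the boundary sits immediately after the motif, so every
#' fragment retains CATG at its 3' end.
#'
#' @slot enzymeName Enzyme name.
#' @slot motif Recognition sequence, IUPAC codes allowed.
#' @slot cutOffset Integer offset of the cut within the motif (0..motif
#'   length).
#' @export
setClass("RestrictionEnzyme",
  representation(enzymeName = "character", motif = "character",
                 cutOffset = "integer"),
  validity = function(object) {
    msg <- character()
    if (nchar(object@motif) < 4L) msg <- c(msg, "motif length must be >= 4")
    if (object@cutOffset < 0L || object@cutOffset > nchar(object@motif))
      msg <- c(msg, "cutOffset must lie within the motif")
    if (!grepl("^[ACGTRYSWKMBDHVN]+$", object@motif))
      msg <- c(msg, "motif must be DNA (IUPAC codes allowed)")
    if (length(msg)) msg else TRUE
  })

#' @param name,motif,cutOffset See slots.
#' @rdname RestrictionEnzyme-class
#' @export
restrictionEnzyme <- function(name, motif, cutOffset) {
  new("RestrictionEnzyme", enzymeName = name, motif = toupper(motif),
      cutOffset = as.integer(cutOffset))
}

#' @rdname RestrictionEnzyme-class
#' @export
nlaIII <- function() restrictionEnzyme("NlaIII", "CATG", 4L)

#' @rdname RestrictionEnzyme-class
#' @export
nspI <- function() restrictionEnzyme("NspI", "RCATGY", 5L)

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s (cut after %d)\n",
              object@enzymeName, object@motif, object@cutOffset))
})

# ---------------------------------------------------------------------------
# DiploidLocus
# ---------------------------------------------------------------------------

#' Diploid locus: reference, phased variants and haplotype sequences
#'
#' Holds a reference sequence together with a phased variant table and the
#' two realised haplotype sequences, plus monotone coordinate maps between
#' reference and haplotype space (needed because indels shift coordinates).
#'
#' The variant table has columns `pos` (0-based reference coordinate),
#' `ref`, `alt` (padded VCF-style alleles), `gt1`, `gt2` (allele index on
#' haplotype 1 and 2), `id` and `kind` (`"SNV"` or `"INDEL"`).
#'
#' @slot refName Reference sequence name.
#' @slot refSeq Reference sequence (character, A/C/G/T only).
#' @slot variants Phased variant data.frame (see Details).
#' @slot hapSeqs Character vector of the two haplotype sequences.
#' @slot refToHap List of two integer vectors mapping each 0-based
#'   reference position to its 0-based haplotype position (NA within
#'   deletions).
#' @slot hapToRef The inverse maps (NA within insertions).
#' @export
setClass("DiploidLocus",
  representation(refName = "character", refSeq = "character",
                 variants = "data.frame", hapSeqs = "character",
                 refToHap = "list", hapToRef = "list"),
  validity = function(object) {
    msg <- character()
    if (!nchar(object@refSeq)) msg <- c(msg, "empty reference sequence")
    if (grepl("[^ACGT]", object@refSeq))
      msg <- c(msg, "reference alphabet restricted to A/C/G/T")
    if (length(object@hapSeqs) != 2L) msg <- c(msg, "need two haplotypes")
    v <- object@variants
    if (nrow(v)) {
      if (is.unsorted(v$pos, strictly = TRUE))
        msg <- c(msg, "variants must be sorted by position")
      if (any(v$pos[-1L] < (v$pos + nchar(v$ref))[-nrow(v)]))
        msg <- c(msg, "variants must not overlap")
      # round-trip: planted alleles must be recoverable through the maps
      for (hap in 1:2) {
        map <- object@refToHap[[hap]]
        gt <- if (hap == 1L) v$gt1 else v$gt2
        for (i in seq_len(nrow(v))) {
          allele <- if (gt[i] == 1L) v$alt[i] else v$ref[i]
          hp <- map[v$pos[i] + 1L]
          got <- substr(object@hapSeqs[hap], hp + 1L, hp + nchar(allele))
          if (is.na(hp) || got != allele) {
            msg <- c(msg, sprintf("allele round-trip failed at pos %d hap %d",
                                  v$pos[i], hap))
            break
          }
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "DiploidLocus", function(object) {
  v <- object@variants
  cat(sprintf("DiploidLocus '%s': %d bp reference, %d variant(s) (%d SNV, %d INDEL, %d het)\n",
              object@refName, nchar(object@refSeq), nrow(v),
              sum(v$kind == "SNV"), sum(v$kind == "INDEL"),
              sum(v$gt1 != v$gt2)))
})

#' @rdname DiploidLocus-class
#' @param x A `DiploidLocus`.
#' @export
refName <- function(x) x@refName

#' @rdname DiploidLocus-class
#' @export
refSeq <- function(x) x@refSeq

#' @rdname DiploidLocus-class
#' @export
variants <- function(x) x@variants

#' @rdname DiploidLocus-class
#' @param hap Haplotype index (1 or 2).
#' @export
hapSeq <- function(x, hap) x@hapSeqs[[hap]]

# ---------------------------------------------------------------------------
# Viewpoint
# ---------------------------------------------------------------------------

#' TLA viewpoint
#'
#' The NlaIII restriction fragment that carries the inverse PCR primer
#' pair. Every amplified circle contains this fragment; amplicons are the
#' circle sequence rotated so that position zero is the forward primer
#' start.
#'
#' @slot vpName Viewpoint name.
#' @slot refPos Anchor position (0-based, on the reference) used to locate
#'   the fragment.
#' @slot fragStart,fragEnd Fragment interval on the reference (0-based
#'   half-open), coinciding with digestion boundaries.
#' @slot primerOffset Forward primer start, as an offset within the
#'   fragment.
#' @export
setClass("Viewpoint",
  representation(vpName = "character", refPos = "integer",
                 fragStart = "integer", fragEnd = "integer",
                 primerOffset = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@fragEnd <= object@fragStart) msg <- c(msg, "empty fragment")
    if (object@primerOffset < 0L ||
        object@primerOffset >= object@fragEnd - object@fragStart)
      msg <- c(msg, "primer must lie inside the fragment")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Viewpoint", function(object) {
  cat(sprintf("Viewpoint '%s': fragment [%d,%d), forward primer at +%d\n",
              object@vpName, object@fragStart, object@fragEnd,
              object@primerOffset))
})

# ---------------------------------------------------------------------------
# ContactModel
# ---------------------------------------------------------------------------

#' Proximity-ligation contact model
#'
#' Fragments are drawn into a circle with probability proportional to
#' `(1 + d)^-decayExponent`, where `d` is the ordinal (fragment-count)
#' distance from the viewpoint fragment -- the standard power-law decay of
#' proximity-ligation contact frequency. The number of non-viewpoint
#' fragments follows a shifted geometric distribution, truncated by the
#' amplicon length bounds (TLA-PCR amplicons are typically 4-10 kb).
#'
#' @slot decayExponent Positive decay exponent (default 1).
#' @slot meanExtraFragments Mean number of non-viewpoint fragments per
#'   circle (default 3).
#' @slot minAmpliconLen,maxAmpliconLen Amplicon length bounds in bp
#'   (defaults 4000 and 10000).
#' @export
setClass("ContactModel",
  representation(decayExponent = "numeric", meanExtraFragments = "numeric",
                 minAmpliconLen = "integer", maxAmpliconLen = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@decayExponent <= 0) msg <- c(msg, "decayExponent must be > 0")
    if (object@meanExtraFragments <= 0)
      msg <- c(msg, "meanExtraFragments must be > 0")
    if (object@minAmpliconLen <= 0L ||
        object@minAmpliconLen >= object@maxAmpliconLen)
      msg <- c(msg, "need 0 < minAmpliconLen < maxAmpliconLen")
    if (length(msg)) msg else TRUE
  })

#' @param decayExponent,meanExtraFragments,minAmpliconLen,maxAmpliconLen
#'   See slots.
#' @rdname ContactModel-class
#' @export
contactModel <- function(decayExponent = 1, meanExtraFragments = 3,
                         minAmpliconLen = 4000L, maxAmpliconLen = 10000L) {
  new("ContactModel", decayExponent = decayExponent,
      meanExtraFragments = meanExtraFragments,
      minAmpliconLen = as.integer(minAmpliconLen),
      maxAmpliconLen = as.integer(maxAmpliconLen))
}

# ---------------------------------------------------------------------------
# ReadProfile
# ---------------------------------------------------------------------------

#' Sequencing platform read model
#'
#' `"short"` emulates paired-end 150 bp sequencing of tagmented amplicon
#' sub-fragments with substitution errors only; `"long"` emulates
#' single-molecule sequencing of whole amplicons with substitution and
#' indel errors, and a length bias weighting amplicons by
#' `length^-lengthBiasExponent` (long-read platforms preferentially
#' sequence shorter molecules).
#'
#' @slot platform `"short"` or `"long"`.
#' @slot readLength Mate length in bp (short mode; default 150).
#' @slot insertMin,insertMax Insert size range in bp (short mode).
#' @slot subErrorRate Per-base substitution error rate.
#' @slot indelErrorRate Per-base indel error rate (long mode).
#' @slot lengthBiasExponent Amplicon sampling weight exponent (long mode).
#' @slot qualityQ Constant Phred quality emitted in FASTQ.
#' @export
setClass("ReadProfile",
  representation(platform = "character", readLength = "integer",
                 insertMin = "integer", insertMax = "integer",
                 subErrorRate = "numeric", indelErrorRate = "numeric",
                 lengthBiasExponent = "numeric", qualityQ = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@platform %in% c("short", "long"))
      msg <- c(msg, "platform must be 'short' or 'long'")
    if (object@readLength < 20L) msg <- c(msg, "readLength must be >= 20")
    if (object@subErrorRate < 0 || object@subErrorRate >= 1 ||
        object@indelErrorRate < 0 || object@indelErrorRate >= 1)
      msg <- c(msg, "error rates must be in [0, 1)")
    if (object@insertMin > object@insertMax)
      msg <- c(msg, "insertMin must be <= insertMax")
    if (length(msg)) msg else TRUE
  })

#' @param platform,readLength,insertMin,insertMax,subErrorRate,indelErrorRate,lengthBiasExponent,qualityQ
#'   See slots.
#' @rdname ReadProfile-class
#' @export
readProfile <- function(platform = c("short", "long"), readLength = 150L,
                        insertMin = 300L, insertMax = 700L,
                        subErrorRate = 0.001, indelErrorRate = 0,
                        lengthBiasExponent = 1, qualityQ = 30L) {
  platform <- match.arg(platform)
  new("ReadProfile", platform = platform, readLength = as.integer(readLength),
      insertMin = as.integer(insertMin), insertMax = as.integer(insertMax),
      subErrorRate = subErrorRate, indelErrorRate = indelErrorRate,
      lengthBiasExponent = lengthBiasExponent, qualityQ = as.integer(qualityQ))
}

#' @rdname ReadProfile-class
#' @param ... Overrides passed on to [readProfile()].
#' @export
shortReadProfile <- function(...) {
  args <- list(platform = "short", subErrorRate = 0.001, qualityQ = 30L)
  args[names(list(...))] <- list(...)
  do.call(readProfile, args)
}

#' @rdname ReadProfile-class
#' @export
longReadProfile <- function(...) {
  args <- list(platform = "long", subErrorRate = 0.02,
               indelErrorRate = 0.01, qualityQ = 12L)
  args[names(list(...))] <- list(...)
  do.call(readProfile, args)
}

# ---------------------------------------------------------------------------
# MapperParams
# ---------------------------------------------------------------------------

#' Split-mapper parameters
#'
#' @slot k Seed k-mer length (default 21).
#' @slot maxMismatchRate Maximum per-segment mismatch (plus indel event)
#'   rate; defaults 0.05 for short reads and 0.15 for long reads.
#' @slot minSegmentLen Minimum segment length considered mappable
#'   (default 15 bp, echoing the read-length floor used when trimming
#'   real libraries).
#' @slot ambiguityPolicy `"keep"` retains all co-optimal placements,
#'   `"drop"` discards ambiguous segments, `"random"` keeps one placement
#'   chosen at random.
#' @slot indelTolerant When TRUE, seed extension may switch diagonals by
#'   up to 2 bp (banded extension), tolerating the indel errors of
#'   long-read platforms.
#' @export
setClass("MapperParams",
  representation(k = "integer", maxMismatchRate = "numeric",
                 minSegmentLen = "integer", ambiguityPolicy = "character",
                 indelTolerant = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@k < 11L) msg <- c(msg, "k must be >= 11")
    if (object@maxMismatchRate < 0 || object@maxMismatchRate >= 1)
      msg <- c(msg, "maxMismatchRate must be in [0, 1)")
    if (!object@ambiguityPolicy %in% c("keep", "drop", "random"))
      msg <- c(msg, "ambiguityPolicy must be keep, drop or random")
    if (length(msg)) msg else TRUE
  })

#' @param k,maxMismatchRate,minSegmentLen,ambiguityPolicy,indelTolerant
#'   See slots.
#' @rdname MapperParams-class
#' @export
mapperParams <- function(k = 21L, maxMismatchRate = 0.05,
                         minSegmentLen = 15L, ambiguityPolicy = "keep",
                         indelTolerant = FALSE) {
  new("MapperParams", k = as.integer(k), maxMismatchRate = maxMismatchRate,
      minSegmentLen = as.integer(minSegmentLen),
      ambiguityPolicy = ambiguityPolicy, indelTolerant = indelTolerant)
}

#' @rdname MapperParams-class
#' @param ... Overrides passed on to [mapperParams()].
#' @export
shortReadMapperParams <- function(...) {
  args <- list(maxMismatchRate = 0.05, indelTolerant = FALSE)
  args[names(list(...))] <- list(...)
  do.call(mapperParams, args)
}

#' @rdname MapperParams-class
#' @export
longReadMapperParams <- function(...) {
  args <- list(maxMismatchRate = 0.15, indelTolerant = TRUE)
  args[names(list(...))] <- list(...)
  do.call(mapperParams, args)
}

# ---------------------------------------------------------------------------
# CallerConfig
# ---------------------------------------------------------------------------

#' Depth-filtered genotype caller configuration
#'
#' Positions below `minDepth` are never called: the short-read preset uses
#' the 25X minimum depth and the long-read preset the 100X minimum depth
#' applied to the respective platforms. Allele-fraction rules then decide
#' the genotype: ALT fraction within `[hetAfLow, hetAfHigh]` with at least
#' `minAltCount` supporting fragments yields a heterozygous 0/1 call; ALT
#' fraction of at least `homAfMin` yields a homozygous 1/1 call.
#'
#' @slot minDepth Minimum pileup depth for any call.
#' @slot hetAfLow,hetAfHigh Heterozygous allele-fraction band.
#' @slot homAfMin Minimum ALT fraction for a homozygous-alt call.
#' @slot minAltCount Absolute ALT fragment floor for het calls.
#' @export
setClass("CallerConfig",
  representation(minDepth = "integer", hetAfLow = "numeric",
                 hetAfHigh = "numeric", homAfMin = "numeric",
                 minAltCount = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@minDepth < 1L) msg <- c(msg, "minDepth must be >= 1")
    if (!(object@hetAfLow > 0 && object@hetAfLow < object@hetAfHigh &&
          object@hetAfHigh < 1))
      msg <- c(msg, "need 0 < hetAfLow < hetAfHigh < 1")
    if (length(msg)) msg else TRUE
  })

#' @param minDepth,hetAfLow,hetAfHigh,homAfMin,minAltCount See slots.
#' @rdname CallerConfig-class
#' @export
callerConfig <- function(minDepth = 25L, hetAfLow = 0.25, hetAfHigh = 0.75,
                         homAfMin = 0.85, minAltCount = 5L) {
  new("CallerConfig", minDepth = as.integer(minDepth), hetAfLow = hetAfLow,
      hetAfHigh = hetAfHigh, homAfMin = homAfMin,
      minAltCount = as.integer(minAltCount))
}

#' @rdname CallerConfig-class
#' @param ... Overrides passed on to [callerConfig()].
#' @export
shortReadCallerConfig <- function(...) {
  args <- list(minDepth = 25L)
  args[names(list(...))] <- list(...)
  do.call(callerConfig, args)
}

#' @rdname CallerConfig-class
#' @export
longReadCallerConfig <- function(...) {
  args <- list(minDepth = 100L)
  args[names(list(...))] <- list(...)
  do.call(callerConfig, args)
}

# ---------------------------------------------------------------------------
# SeedIndex
# ---------------------------------------------------------------------------

#' k-mer seed index over a set of reference sequences
#'
#' Maps every k-mer of every reference (forward strand; queries are also
#' searched as their reverse complement) to its sorted occurrence
#' positions. Stands in for an external aligner index at desk scale.
#'
#' @slot k Seed length.
#' @slot refNames,refSeqs Reference names and sequences.
#' @slot refRaws Raw-vector copies of the references for fast comparison.
#' @slot table Environment mapping k-mer to encoded occurrence vector.
#' @export
setClass("SeedIndex",
  representation(k = "integer", refNames = "character", refSeqs = "character",
                 refRaws = "list", table = "environment"))

setMethod("show", "SeedIndex", function(object) {
  cat(sprintf("SeedIndex: k=%d over %d reference(s) (%s), %d distinct k-mers\n",
              object@k, length(object@refNames),
              paste(sprintf("%s:%dbp", object@refNames,
                            nchar(object@refSeqs)), collapse = ", "),
              length(ls(object@table))))
})

# ---------------------------------------------------------------------------
# Pileup
# ---------------------------------------------------------------------------

#' Per-position depth and allele counts
#'
#' Depth counts aligned (non-clipped) fragment bases; two segments of one
#' read overlapping the same position count twice. ALT observations are
#' keyed by SNV base, `+SEQ` (insertion after the anchor position) or
#' `-N` (deletion of N bases after the anchor position), all left-anchored.
#'
#' @slot refLens Named integer vector of reference lengths.
#' @slot depth List of per-reference integer depth vectors.
#' @slot altCounts data.frame with columns `refName`, `pos` (0-based),
#'   `allele`, `count`.
#' @slot alignedBases Total aligned bases contributing to depth.
#' @export
setClass("Pileup",
  representation(refLens = "integer", depth = "list",
                 altCounts = "data.frame", alignedBases = "numeric"))

setMethod("show", "Pileup", function(object) {
  cat(sprintf("Pileup over %d reference(s), %.0f aligned bases, %d ALT allele record(s)\n",
              length(object@refLens), object@alignedBases,
              nrow(object@altCounts)))
  for (rn in names(object@refLens)) {
    d <- object@depth[[rn]]
    cat(sprintf("  %s: %d bp, mean depth %.1f, max %d\n", rn,
                object@refLens[[rn]], mean(d), max(d)))
  }
})

# ---------------------------------------------------------------------------
# BenchmarkReport
# ---------------------------------------------------------------------------

#' Genotype and phasing concordance report
#'
#' @slot genotypes Per-class (SNV/INDEL) genotype comparison counters.
#' @slot phasing Phasing comparison: totals plus per-block detail.
#' @export
setClass("BenchmarkReport",
  representation(genotypes = "data.frame", phasing = "list"))

setMethod("show", "BenchmarkReport", function(object) {
  cat("Genotype concordance (vs phased truth):\n")
  print(object@genotypes, row.names = FALSE)
  p <- object@phasing
  cat(sprintf(paste0("Phasing: %d heterozygous, %d phased, %d concordantly",
                     " phased, %d switch error(s) in %d block(s)\n"),
              p$nHeterozygous, p$nPhased, p$nConcordantPhased,
              p$nSwitchErrors, p$nBlocks))
})

#' @rdname BenchmarkReport-class
#' @param x A `BenchmarkReport`.
#' @export
genotypeComparison <- function(x) x@genotypes

#' @rdname BenchmarkReport-class
#' @export
phasingComparison <- function(x) x@phasing
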