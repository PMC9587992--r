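#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Variant application and coordinate maps
# ---------------------------------------------------------------------------

.validateVariants <- function(refSeq, variants) {
  v <- variants
  if (!nrow(v)) return(invisible(TRUE))
  if (is.unsorted(v$pos, strictly = TRUE))
    stop("variants must be sorted by position and unique")
  ends <- v$pos + nchar(v$ref)
  if (any(v$pos[-1L] < ends[-length(ends)]))
    stop("overlapping variants at positions ",
         paste(v$pos[c(FALSE, v$pos[-1L] < ends[-length(ends)])],
               collapse = ", "))
  got <- substring(refSeq, v$pos + 1L, v$pos + nchar(v$ref))
  bad <- which(got != v$ref)
  if (length(bad))
    stop(sprintf("ref allele mismatch at position %d: expected '%s', reference has '%s'",
                 v$pos[bad[1L]], v$ref[bad[1L]], got[bad[1L]]))
  invisible(TRUE)
}

#' Realise one haplotype from a reference plus phased variants
#'
#' Substitutes the haplotype's allele at every variant and builds monotone
#' coordinate maps between reference and haplotype space.
#'
#' @param refSeq Reference sequence (character).
#' @param variants Variant data.frame with columns `pos` (0-based), `ref`,
#'   `alt`, `gt1`, `gt2`.
#' @param hapIndex 1 or 2.
#' @return A list with `seq` (the haplotype sequence), `refToHap` and
#'   `hapToRef` (0-based integer maps; NA inside deletions/insertions
#'   respectively).
#' @examples
#' v <- data.frame(pos = 2L, ref = "G", alt = "T", gt1 = 1L, gt2 = 0L)
#' applyVariants("ACGTACGT", v, 1)$seq  # "ACTTACGT"
#' @export
applyVariants <- function(refSeq, variants, hapIndex) {
  stopifnot(hapIndex %in% 1:2)
  n <- nchar(refSeq)
  if (is.null(variants) || !nrow(variants))
    return(list(seq = refSeq, refToHap = seq_len(n) - 1L,
                hapToRef = seq_len(n) - 1L))
  .validateVariants(refSeq, variants)
  v <- variants
  gt <- if (hapIndex == 1L) v$gt1 else v$gt2
  if (!is.null(gt) && length(gt) && !all(gt %in% 0:1))
    stop("genotype entries must be 0 or 1")
  pieces <- character(0)
  refToHap <- integer(n)
  cur <- 0L     # next unconsumed reference position
  hapPos <- 0L  # length of haplotype built so far
  hapToRef <- integer(0)
  take <- function(from, to) { # ref interval [from,to) copied verbatim
    if (to > from) {
      pieces[[length(pieces) + 1L]] <<- substring(refSeq, from + 1L, to)
      refToHap[(from + 1L):to] <<- hapPos + seq_len(to - from) - 1L
      hapToRef <<- c(hapToRef, from:(to - 1L))
      hapPos <<- hapPos + (to - from)
    }
  }
  for (i in seq_len(nrow(v))) {
    take(cur, v$pos[i])
    allele <- if (gt[i] == 1L) v$alt[i] else v$ref[i]
    nr <- nchar(v$ref[i])
    # map: first base of the padded allele always corresponds to pos
    refToHap[(v$pos[i] + 1L):(v$pos[i] + nr)] <- NA_integer_
    refToHap[v$pos[i] + 1L] <- hapPos
    hm <- rep(NA_integer_, nchar(allele))
    hm[1L] <- v$pos[i]
    if (gt[i] == 0L || (nchar(allele) == nr && nr == nchar(v$alt[i]) &&
                        gt[i] == 1L && nr == 1L)) {
      # ref allele kept, or 1-bp SNV: positions map one-to-one
      if (nchar(allele) == nr) {
        refToHap[(v$pos[i] + 1L):(v$pos[i] + nr)] <-
          hapPos + seq_len(nr) - 1L
        hm <- v$pos[i] + seq_len(nr) - 1L
      }
    }
    pieces[[length(pieces) + 1L]] <- allele
    hapToRef <- c(hapToRef, hm)
    hapPos <- hapPos + nchar(allele)
    cur <- v$pos[i] + nr
  }
  take(cur, n)
  list(seq = paste(pieces, collapse = ""), refToHap = refToHap,
       hapToRef = hapToRef)
}

#' Construct a DiploidLocus
#'
#' @param refSeq Reference sequence.
#' @param variants Phased variant data.frame (`pos`, `ref`, `alt`, `gt1`,
#'   `gt2`; optional `id`).
#' @param name Reference name.
#' @return A [DiploidLocus-class] object.
#' @export
diploidLocus <- function(refSeq, variants = NULL, name = "locus") {
  if (is.null(variants) || !nrow(variants)) {
    variants <- data.frame(pos = integer(), ref = character(),
                           alt = character(), gt1 = integer(),
                           gt2 = integer(), stringsAsFactors = FALSE)
  }
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  if (is.null(variants$id))
    variants$id <- if (nrow(variants))
      sprintf("%s_%d_%s_%s", name, variants$pos, variants$ref, variants$alt)
    else character(0)
  variants$kind <- ifelse(nchar(variants$ref) == 1L &
                          nchar(variants$alt) == 1L, "SNV", "INDEL")
  h1 <- applyVariants(refSeq, variants, 1L)
  h2 <- applyVariants(refSeq, variants, 2L)
  new("DiploidLocus", refName = name, refSeq = refSeq, variants = variants,
      hapSeqs = c(h1$seq, h2$seq),
      refToHap = list(h1$refToHap, h2$refToHap),
      hapToRef = list(h1$hapToRef, h2$hapToRef))
}

# ---------------------------------------------------------------------------
# Restriction digestion
# ---------------------------------------------------------------------------

#' Cut positions of an enzyme in a sequence
#'
#' @param seq Character DNA sequence.
#' @param enzyme A [RestrictionEnzyme-class].
#' @return Sorted 0-based cut coordinates strictly inside the sequence.
#' @export
findCutSites <- function(seq, enzyme) {
  m <- Biostrings::matchPattern(enzyme@motif, Biostrings::DNAString(seq),
                                fixed = FALSE)
  cuts <- Biostrings::start(m) - 1L + enzyme@cutOffset
  sort(unique(cuts[cuts > 0L & cuts < nchar(seq)]))
}

#' Digest a sequence into ordered restriction fragments
#'
#' Fragments tile the sequence exactly; every internal boundary is a motif
#' cut position. With the NlaIII convention (cut offset 4) each fragment
#' retains CATG at its 3' end.
#'
#' @inheritParams findCutSites
#' @return data.frame with columns `index` (1-based ordinal), `start`,
#'   `end` (0-based half-open) and `seq`.
#' @examples
#' digest("AAACATGTTTCATGGG", nlaIII())$seq  # "AAACATG" "TTTCATG" "GG"
#' @export
digest <- function(seq, enzyme) {
  stopifnot(nchar(seq) > 0L)
  cuts <- findCutSites(seq, enzyme)
  bounds <- c(0L, cuts, nchar(seq))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  data.frame(index = seq_along(starts), start = starts, end = ends,
             seq = substring(seq, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Digest both haplotypes of a locus
#'
#' @param locus A [DiploidLocus-class].
#' @param enzyme A [RestrictionEnzyme-class].
#' @return List of two fragment data.frames (haplotype coordinates) with
#'   extra columns `refStart`, `refEnd` projecting each fragment onto the
#'   reference through the coordinate maps, and `hap`.
#' @export
digestLocus <- function(locus, enzyme = nlaIII()) {
  lapply(1:2, function(hap) {
    fr <- digest(hapSeq(locus, hap), enzyme)
    map <- locus@hapToRef[[hap]]
    fr$refStart <- vapply(seq_len(nrow(fr)), function(i) {
      m <- map[(fr$start[i] + 1L):fr$end[i]]
      m <- m[!is.na(m)]
      if (length(m)) m[1L] else NA_integer_
    }, integer(1))
    fr$refEnd <- vapply(seq_len(nrow(fr)), function(i) {
      m <- map[(fr$start[i] + 1L):fr$end[i]]
      m <- m[!is.na(m)]
      if (length(m)) m[length(m)] + 1L else NA_integer_
    }, integer(1))
    fr$hap <- hap
    fr
  })
}

# ---------------------------------------------------------------------------
# Homolog (pseudogene) decoys
# ---------------------------------------------------------------------------

#' Generate a paralogous copy of a sequence at a given identity
#'
#' Each position is substituted independently with probability
#' `1 - identity` (the substitute base drawn uniformly from the three
#' alternatives), emulating a pseudogene such as the 94%-identical
#' neighbours of CYP2D6.
#'
#' @param seq Character DNA sequence.
#' @param identity Target identity in (0, 1].
#' @param seed Integer seed (deterministic output).
#' @return A sequence of the same length.
#' @export
makeHomolog <- function(seq, identity, seed) {
  if (!(identity > 0 && identity <= 1))
    stop("identity must be in (0, 1]")
  if (identity == 1) return(seq)
  withSeed(seed, {
    chars <- s2c(seq)
    hit <- runif(length(chars)) < (1 - identity)
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(.BASES, b), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    paste(chars, collapse = "")
  })
}

# ---------------------------------------------------------------------------
# Synthetic locus generation
# ---------------------------------------------------------------------------

# Random sequence free of the given motif (by local repair).
.motifFreeDna <- function(n, gc, motif = "CATG") {
  seq <- randomDna(n, gc)
  repeat {
    hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(seq)
    for (h in hits) {
      b <- substr(seq, h + 1L, h + 1L)
      substr(seq, h + 1L, h + 1L) <- sample(setdiff(.BASES, b), 1L)
    }
  }
}

#' Random locus sequence with controlled NlaIII fragment structure
#'
#' Builds a reference in which CATG occurs exactly at the requested
#' fragment boundaries, so that fragment sizes are known by construction.
#' Used by the scenario presets; real loci have random motif spacing.
#'
#' @param fragmentLengths Integer vector of fragment lengths (each >= 8,
#'   including the trailing CATG every fragment retains: the simulated
#'   window is delimited by NlaIII sites, as any real locus window is
#'   embedded in a digestible chromosome).
#' @param gc GC content of the random portions.
#' @param seed Integer seed.
#' @return Character sequence whose [digest()] with [nlaIII()] yields
#'   exactly these fragments.
#' @export
randomLocusSequence <- function(fragmentLengths, gc = 0.45, seed = 1L) {
  stopifnot(all(fragmentLengths >= 8L))
  withSeed(seed, {
    pieces <- vapply(fragmentLengths, function(len) {
      paste0(.motifFreeDna(len - 4L, gc), "CATG")
    }, character(1))
    paste(pieces, collapse = "")
  })
}

#' Synthesise a diploid locus with planted phased variants
#'
#' Generates a reference of `nFragments` NlaIII fragments of roughly
#' `fragmentLength` bp, then plants heterozygous SNVs/INDELs (random phase)
#' and optional homozygous-alt SNVs. Variant positions avoid CATG motifs
#' and alleles are rejected if they would create or destroy a recognition
#' site, so digestion boundaries are identical on the reference and both
#' haplotypes.
#'
#' @param nFragments Number of NlaIII fragments.
#' @param fragmentLength Mean fragment length in bp (jittered +-15%).
#' @param nHetSnvs,nHetIndels,nHomSnvs Variant counts to plant.
#' @param gc GC content.
#' @param seed Integer seed.
#' @param variantZone Fractional interval of each fragment within which
#'   variant positions are drawn (default `c(0.1, 0.9)`).
#' @param name Reference name.
#' @return A [DiploidLocus-class].
#' @export
synthesizeLocus <- function(nFragments = 8L, fragmentLength = 1200L,
                            nHetSnvs = 8L, nHetIndels = 0L, nHomSnvs = 0L,
                            gc = 0.45, seed = 1L,
                            variantZone = c(0.1, 0.9), name = "locus") {
  withSeed(stageSeed(seed, "locus"), {
    jitter <- round(fragmentLength *
                    runif(nFragments, -0.15, 0.15))
    fragLens <- pmax(40L, as.integer(fragmentLength + jitter))
    refSeq <- randomLocusSequence(fragLens, gc,
                                  seed = sample.int(2^31 - 1L, 1L))
    frags <- digest(refSeq, nlaIII())
    stopifnot(nrow(frags) == nFragments)
    nVar <- nHetSnvs + nHetIndels + nHomSnvs
    # spread variants over fragments round-robin so links can form
    fragOrder <- rep(sample(nFragments), length.out = nVar)
    taken <- integer(0)
    rows <- vector("list", nVar)
    kindPool <- sample(c(rep("hetSNV", nHetSnvs), rep("INDEL", nHetIndels),
                         rep("homSNV", nHomSnvs)))
    for (i in seq_len(nVar)) {
      f <- frags[fragOrder[i], ]
      lo <- f$start + max(6L, floor((f$end - f$start) * variantZone[1L]))
      hi <- f$end - max(10L, ceiling((f$end - f$start) *
                                     (1 - variantZone[2L])))
      for (attempt in 1:200) {
        pos <- sample(lo:hi, 1L)
        kind <- kindPool[i]
        refA <- substr(refSeq, pos + 1L, pos + 1L)
        if (kind == "INDEL") {
          if (runif(1) < 0.5) {            # insertion of 1-2 bp
            ins <- paste(sample(.BASES, sample(1:2, 1L), replace = TRUE),
                         collapse = "")
            ref <- refA; alt <- paste0(refA, ins)
            # keep only left-normalised representations
            if (substr(ins, nchar(ins), nchar(ins)) == refA) next
          } else {                          # deletion of 1-2 bp
            d <- sample(1:2, 1L)
            ref <- substr(refSeq, pos + 1L, pos + 1L + d)
            alt <- refA
            if (substr(ref, nchar(ref), nchar(ref)) == refA) next
          }
        } else {
          ref <- refA
          alt <- sample(setdiff(.BASES, refA), 1L)
        }
        # no overlap with already planted variants (with 4 bp spacing)
        span <- (pos - 4L):(pos + nchar(ref) + 4L)
        if (length(intersect(span, taken))) next
        # must not create or destroy a CATG site near the edit
        wlo <- max(0L, pos - 6L)
        whiR <- min(nchar(refSeq), pos + nchar(ref) + 6L)
        refWin <- substr(refSeq, wlo + 1L, whiR)
        altWin <- paste0(substr(refSeq, wlo + 1L, pos), alt,
                         substr(refSeq, pos + nchar(ref) + 1L, whiR))
        if (grepl("CATG", refWin, fixed = TRUE) ||
            grepl("CATG", altWin, fixed = TRUE)) next
        gt <- if (kind == "homSNV") c(1L, 1L)
              else if (runif(1) < 0.5) c(0L, 1L) else c(1L, 0L)
        rows[[i]] <- data.frame(pos = pos, ref = ref, alt = alt,
                                gt1 = gt[1L], gt2 = gt[2L],
                                stringsAsFactors = FALSE)
        taken <- c(taken, span)
        break
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    v <- if (length(rows)) do.call(rbind, rows) else NULL
    diploidLocus(refSeq, v, name = name)
  })
}

# ---------------------------------------------------------------------------
# FASTA / VCF I/O
# ---------------------------------------------------------------------------

#' Read and write reference FASTA
#'
#' Thin wrappers over Biostrings keeping the package's character-based
#' sequence representation.
#'
#' @param path File path.
#' @return `readFasta`: named character vector of sequences.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname readFasta
#' @param seqs Named character vector of sequences.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a phased single-sample VCF
#'
#' Genotypes use the `|` separator; block membership, when present, is
#' carried in the `PS` FORMAT field. The `##fileDate` header line is
#' removed after writing so that identical inputs give byte-identical
#' files.
#'
#' @param variants data.frame with `pos` (0-based), `ref`, `alt`, `gt1`,
#'   `gt2`; optional `phased` (logical) and `ps` (integer block id).
#' @param refName,refLen Reference name and length.
#' @param path Output path.
#' @param sample Sample name.
#' @export
writePhasedVcf <- function(variants, refName, refLen, path,
                           sample = "SAMPLE") {
  v <- variants[order(variants$pos), , drop = FALSE]
  n <- nrow(v)
  gr <- GenomicRanges::GRanges(refName,
          IRanges::IRanges(start = v$pos + 1L, width = nchar(v$ref)))
  names(gr) <- sprintf("var%04d", seq_len(n))
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(if (n) v$ref else character(0)),
    ALT = Biostrings::DNAStringSetList(as.list(if (n) v$alt
                                               else character(0))),
    QUAL = rep(NA_real_, n), FILTER = rep("PASS", n))
  sep <- if (is.null(v$phased)) rep("|", n)
         else ifelse(v$phased, "|", "/")
  gt <- matrix(paste0(v$gt1, sep, v$gt2), ncol = 1L,
               dimnames = list(names(gr), sample))
  geno <- S4Vectors::SimpleList(GT = gt)
  if (!is.null(v$ps)) {
    ps <- matrix(as.integer(v$ps), ncol = 1L,
                 dimnames = list(names(gr), sample))
    geno$PS <- ps
  }
  hdr <- VariantAnnotation::VCFHeader(
    samples = sample,
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.3",
                                        row.names = "fileformat"),
      contig = S4Vectors::DataFrame(length = as.character(refLen),
                                    row.names = refName),
      FORMAT = S4Vectors::DataFrame(
        Number = c("1", "1"), Type = c("String", "Integer"),
        Description = c("Genotype", "Phase set"),
        row.names = c("GT", "PS"))[c("GT", if (!is.null(v$ps)) "PS"), ,
                                   drop = FALSE]))
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed,
                                colData = S4Vectors::DataFrame(
                                  Samples = 1L, row.names = sample),
                                geno = geno, collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  # strip the date stamp for deterministic output
  lines <- readLines(path)
  writeLines(lines[!grepl("^##fileDate=", lines)], path)
  invisible(path)
}

#' Read a phased single-sample VCF into the package's variant table
#'
#' @param path VCF path.
#' @return data.frame with `pos` (0-based), `ref`, `alt`, `gt1`, `gt2`,
#'   `phased`, `ps` (NA when absent) and `refName`.
#' @export
readPhasedVcf <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
  alt <- vapply(VariantAnnotation::alt(vcf), function(a)
    as.character(a)[1L], character(1))
  ps <- if ("PS" %in% names(VariantAnnotation::geno(vcf)))
    as.integer(VariantAnnotation::geno(vcf)$PS[, 1L])
  else rep(NA_integer_, length(gt))
  phased <- grepl("|", gt, fixed = TRUE)
  alleles <- strsplit(gt, "[|/]")
  data.frame(
    refName = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    gt1 = as.integer(vapply(alleles, `[`, character(1), 1L)),
    gt2 = as.integer(vapply(alleles, `[`, character(1), 2L)),
    phased = phased, ps = ps, stringsAsFactors = FALSE)
}
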