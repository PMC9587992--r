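#' @include locus-model.R
NULL

# ---------------------------------------------------------------------------
# Viewpoint design
# ---------------------------------------------------------------------------

#' Place a viewpoint in the fragment containing a reference position
#'
#' @param locus A [DiploidLocus-class].
#' @param at 0-based reference position; the enclosing NlaIII fragment
#'   becomes the viewpoint fragment.
#' @param name Viewpoint name.
#' @param primerOffset Forward primer start within the fragment (bp).
#' @param enzyme Restriction enzyme (default NlaIII).
#' @return A [Viewpoint-class].
#' @export
designViewpoint <- function(locus, at, name = "vp1", primerOffset = 40L,
                            enzyme = nlaIII()) {
  frags <- digest(refSeq(locus), enzyme)
  hit <- which(frags$start <= at & at < frags$end)
  if (!length(hit)) stop("position ", at, " outside the reference")
  f <- frags[hit[1L], ]
  po <- min(as.integer(primerOffset), f$end - f$start - 1L)
  new("Viewpoint", vpName = name, refPos = as.integer(at),
      fragStart = f$start, fragEnd = f$end, primerOffset = po)
}

# Fragment index containing the viewpoint on each haplotype.
.viewpointFragIndex <- function(fragsByHap, viewpoint) {
  vapply(fragsByHap, function(fr) {
    hit <- which(!is.na(fr$refStart) & fr$refStart <= viewpoint@refPos &
                 viewpoint@refPos < fr$refEnd)
    if (!length(hit)) stop("viewpoint fragment missing on a haplotype")
    hit[1L]
  }, integer(1))
}

# ---------------------------------------------------------------------------
# Circles
# ---------------------------------------------------------------------------

#' Simulate one haplotype-pure proximity-ligation circle
#'
#' A haplotype is chosen uniformly; the viewpoint fragment of that
#' haplotype is always included, and further fragments are drawn without
#' replacement from the same haplotype with probability proportional to
#' `(1 + d)^-alpha` in ordinal fragment distance `d`. Draws whose total
#' length falls outside the amplicon bounds are rejected and resampled.
#' Uses the current RNG state (seed upstream).
#'
#' @param fragsByHap Output of [digestLocus()].
#' @param viewpoint A [Viewpoint-class].
#' @param model A [ContactModel-class].
#' @param maxAttempts Resampling cap before an error is raised.
#' @return List with `hap`, `fragIdx` (haplotype fragment indices in
#'   ligation order, viewpoint first), `seq` (circle sequence starting at
#'   the viewpoint fragment) and `frags` (the fragment rows, ordered).
#' @export
simulateCircle <- function(fragsByHap, viewpoint, model = contactModel(),
                           maxAttempts = 500L) {
  vpIdx <- .viewpointFragIndex(fragsByHap, viewpoint)
  for (attempt in seq_len(maxAttempts)) {
    hap <- sample(1:2, 1L)
    fr <- fragsByHap[[hap]]
    vi <- vpIdx[hap]
    nOther <- nrow(fr) - 1L
    p <- 1 / (1 + model@meanExtraFragments)
    nExtra <- min(nOther, 1L + rgeom(1L, p))
    others <- setdiff(seq_len(nrow(fr)), vi)
    w <- (1 + abs(others - vi))^(-model@decayExponent)
    pick <- if (nExtra > 0L)
      others[sample.int(length(others), nExtra, prob = w)]
    else integer(0)
    order <- c(vi, pick[sample.int(length(pick))])
    total <- sum(fr$end[order] - fr$start[order])
    if (total < model@minAmpliconLen || total > model@maxAmpliconLen) next
    return(list(hap = hap, fragIdx = order,
                seq = paste(fr$seq[order], collapse = ""),
                frags = fr[order, , drop = FALSE]))
  }
  stop("no admissible circle within [", model@minAmpliconLen, ", ",
       model@maxAmpliconLen, "] bp after ", maxAttempts,
       " attempts; adjust the amplicon length bounds or fragment sizes")
}

#' Simulate a batch of circles
#'
#' @inheritParams simulateCircle
#' @param n Number of circles.
#' @param seed Optional integer seed; when given the batch is reproducible
#'   in isolation.
#' @return List of circles (see [simulateCircle()]), each with a
#'   `circleId`.
#' @export
simulateCircles <- function(fragsByHap, viewpoint, model = contactModel(),
                            n = 100L, seed = NULL) {
  run <- function() {
    lapply(seq_len(n), function(i) {
      circ <- simulateCircle(fragsByHap, viewpoint, model)
      circ$circleId <- i
      circ
    })
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

# ---------------------------------------------------------------------------
# Amplicons
# ---------------------------------------------------------------------------

#' Linearise circles into viewpoint-anchored PCR amplicons
#'
#' Each circle containing the viewpoint yields one amplicon: the circle
#' sequence rotated so that position zero is the forward primer start
#' within the viewpoint fragment. Circles lacking the viewpoint fragment
#' (possible only when injected by hand) are dropped. Provenance maps
#' every amplicon base to its haplotype and reference interval; the
#' viewpoint fragment appears as two rows (tail after the primer, head
#' before it).
#'
#' @param circles List of circles from [simulateCircles()].
#' @param viewpoint The [Viewpoint-class] used for simulation.
#' @return List of amplicons: `seq`, `hap`, `circleId`, and `provenance`
#'   (data.frame `ampStart`, `ampEnd`, `hapStart`, `hapEnd`, `refStart`,
#'   `refEnd`).
#' @export
amplify <- function(circles, viewpoint) {
  out <- lapply(circles, function(circ) {
    fr <- circ$frags
    containsVp <- any(!is.na(fr$refStart) &
                      fr$refStart <= viewpoint@refPos &
                      viewpoint@refPos < fr$refEnd)
    if (!containsVp) return(NULL)
    off <- viewpoint@primerOffset
    L <- nchar(circ$seq)
    seq <- paste0(substring(circ$seq, off + 1L, L),
                  substring(circ$seq, 1L, off))
    # provenance in rotated coordinates
    lens <- fr$end - fr$start
    startsInCircle <- cumsum(c(0L, lens[-length(lens)]))
    rows <- list()
    addRow <- function(ampStart, hapStart, hapEnd, fi) {
      width <- hapEnd - hapStart
      if (width <= 0L) return()
      # reference projection proportional to the haplotype slice
      fragHapLen <- fr$end[fi] - fr$start[fi]
      refStart <- fr$refStart[fi] + (hapStart - fr$start[fi])
      refEnd <- fr$refEnd[fi] - (fr$end[fi] - hapEnd)
      rows[[length(rows) + 1L]] <<- data.frame(
        ampStart = ampStart, ampEnd = ampStart + width,
        hapStart = hapStart, hapEnd = hapEnd,
        refStart = refStart, refEnd = refEnd, stringsAsFactors = FALSE)
    }
    # viewpoint fragment tail (from the primer to the fragment end)
    addRow(0L, fr$start[1L] + off, fr$end[1L], 1L)
    cursor <- (fr$end[1L] - fr$start[1L]) - off
    if (length(lens) > 1L) {
      for (i in 2:nrow(fr)) {
        addRow(cursor, fr$start[i], fr$end[i], i)
        cursor <- cursor + lens[i]
      }
    }
    # viewpoint fragment head (before the primer), closing the circle
    addRow(cursor, fr$start[1L], fr$start[1L] + off, 1L)
    list(seq = seq, hap = circ$hap, circleId = circ$circleId,
         provenance = do.call(rbind, rows))
  })
  out[!vapply(out, is.null, logical(1))]
}

# ---------------------------------------------------------------------------
# Reads
# ---------------------------------------------------------------------------

# Apply substitution (+ optional indel) errors; returns the new sequence
# and an integer map from error-free coordinates to new coordinates.
.applyErrors <- function(seq, subRate, indelRate) {
  n <- nchar(seq)
  chars <- s2c(seq)
  if (subRate > 0) {
    hit <- which(runif(n) < subRate)
    for (i in hit) chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  if (indelRate <= 0)
    return(list(seq = paste(chars, collapse = ""),
                map = seq_len(n) - 1L))
  u <- runif(n)
  insAt <- u < indelRate / 2
  delAt <- u >= indelRate / 2 & u < indelRate
  out <- vector("list", n)
  map <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    if (delAt[i]) { map[i] <- NA_integer_; next }
    map[i] <- pos
    if (insAt[i]) {
      out[[i]] <- c(chars[i], sample(.BASES, 1L))
      pos <- pos + 2L
    } else {
      out[[i]] <- chars[i]
      pos <- pos + 1L
    }
  }
  list(seq = paste(unlist(out), collapse = ""), map = map)
}

# Provenance rows for an error-free window [a, b) of an amplicon, in read
# coordinates. strand "-" flips read coordinates (read = revcomp(window)).
.windowProvenance <- function(amp, a, b, strand) {
  pv <- amp$provenance
  keep <- pv$ampEnd > a & pv$ampStart < b
  pv <- pv[keep, , drop = FALSE]
  if (!nrow(pv)) return(pv)
  clipS <- pmax(pv$ampStart, a)
  clipE <- pmin(pv$ampEnd, b)
  refS <- pv$refStart + (clipS - pv$ampStart)
  refE <- pv$refEnd - (pv$ampEnd - clipE)
  if (strand == "+") {
    data.frame(readStart = clipS - a, readEnd = clipE - a,
               refStart = refS, refEnd = refE, strand = "+",
               stringsAsFactors = FALSE)
  } else {
    w <- b - a
    data.frame(readStart = w - (clipE - a), readEnd = w - (clipS - a),
               refStart = refS, refEnd = refE, strand = "-",
               stringsAsFactors = FALSE)
  }
}

#' Generate platform reads from amplicons with truth provenance
#'
#' Short mode draws `n` insert windows (insert size uniform within the
#' profile's range, amplicons weighted by length, as tagmentation would)
#' and emits two 150 bp mates with substitution errors. Long mode draws
#' `n` whole amplicons weighted by `length^-beta` and applies substitution
#' and indel errors. Every read records its source circle, haplotype and
#' per-segment reference intervals. Uses the current RNG state unless
#' `seed` is given.
#'
#' @param amplicons List from [amplify()].
#' @param profile A [ReadProfile-class].
#' @param n Number of read pairs (short) or reads (long).
#' @param seed Optional integer seed.
#' @return List with `reads` (data.frame `readId`, `seq`, `qual`) and
#'   `provenance` (data.frame `readId`, `circleId`, `hap`, `readStart`,
#'   `readEnd`, `refStart`, `refEnd`, `strand`).
#' @export
generateReads <- function(amplicons, profile, n = 100L, seed = NULL) {
  if (!length(amplicons)) stop("no amplicons to sequence")
  run <- function() {
    lens <- vapply(amplicons, function(a) nchar(a$seq), integer(1))
    qual <- function(len) strrep(rawToChar(as.raw(profile@qualityQ + 33L)),
                                 len)
    reads <- list(); prov <- list()
    if (profile@platform == "short") {
      wA <- lens / sum(lens)
      for (i in seq_len(n)) {
        ai <- sample.int(length(amplicons), 1L, prob = wA)
        amp <- amplicons[[ai]]
        L <- lens[ai]
        insert <- min(L, sample(profile@insertMin:profile@insertMax, 1L))
        a <- sample.int(L - insert + 1L, 1L) - 1L
        rl <- min(profile@readLength, insert)
        id <- sprintf("r%06d", i)
        w1 <- c(a, a + rl)
        w2 <- c(a + insert - rl, a + insert)
        s1 <- substring(amp$seq, w1[1L] + 1L, w1[2L])
        s2 <- revComp(substring(amp$seq, w2[1L] + 1L, w2[2L]))
        e1 <- .applyErrors(s1, profile@subErrorRate, 0)
        e2 <- .applyErrors(s2, profile@subErrorRate, 0)
        reads[[length(reads) + 1L]] <- data.frame(
          readId = paste0(id, c("/1", "/2")), seq = c(e1$seq, e2$seq),
          qual = c(qual(nchar(e1$seq)), qual(nchar(e2$seq))),
          stringsAsFactors = FALSE)
        p1 <- .windowProvenance(amp, w1[1L], w1[2L], "+")
        p2 <- .windowProvenance(amp, w2[1L], w2[2L], "-")
        p1$readId <- paste0(id, "/1"); p2$readId <- paste0(id, "/2")
        p <- rbind(p1, p2)
        p$circleId <- amp$circleId; p$hap <- amp$hap
        prov[[length(prov) + 1L]] <- p
      }
    } else {
      w <- lens^(-profile@lengthBiasExponent)
      wA <- w / sum(w)
      for (i in seq_len(n)) {
        ai <- sample.int(length(amplicons), 1L, prob = wA)
        amp <- amplicons[[ai]]
        id <- sprintf("r%06d", i)
        err <- .applyErrors(amp$seq, profile@subErrorRate,
                            profile@indelErrorRate)
        reads[[length(reads) + 1L]] <- data.frame(
          readId = id, seq = err$seq, qual = qual(nchar(err$seq)),
          stringsAsFactors = FALSE)
        p <- .windowProvenance(amp, 0L, lens[ai], "+")
        if (nrow(p)) {
          # shift read coordinates through the error map
          p$readStart <- vapply(p$readStart, function(x) {
            m <- err$map[(x + 1L):min(length(err$map), x + 3L)]
            m <- m[!is.na(m)]
            if (length(m)) m[1L] else NA_integer_
          }, integer(1))
          p$readEnd <- vapply(p$readEnd, function(x) {
            m <- err$map[max(1L, x - 2L):x]
            m <- m[!is.na(m)]
            if (length(m)) m[length(m)] + 1L else NA_integer_
          }, integer(1))
          p <- p[!is.na(p$readStart) & !is.na(p$readEnd), , drop = FALSE]
        }
        p$readId <- id; p$circleId <- amp$circleId; p$hap <- amp$hap
        prov[[length(prov) + 1L]] <- p
      }
    }
    reads <- do.call(rbind, reads)
    prov <- do.call(rbind, prov)
    prov <- prov[, c("readId", "circleId", "hap", "readStart", "readEnd",
                     "refStart", "refEnd", "strand")]
    rownames(reads) <- rownames(prov) <- NULL
    list(reads = reads, provenance = prov)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

# ---------------------------------------------------------------------------
# FASTQ I/O and end-to-end simulation
# ---------------------------------------------------------------------------

#' Write and read FASTQ
#'
#' @param reads data.frame with `readId`, `seq`, `qual`.
#' @param path File path (plain text).
#' @export
writeFastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$readId
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(readId = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Run the full simulator from a configuration
#'
#' Convenience wrapper: reference FASTA + phased truth VCF + viewpoint BED
#' in, FASTQ + provenance TSV + truth phase table out. Reruns with the
#' same configuration are byte-identical.
#'
#' @param config Named list (or path to a YAML file) with entries
#'   `referenceFasta`, `truthVcf`, `viewpointBed`, `platform` ("short" or
#'   "long"), `nCircles`, `nReads`, `seed`, `outDir`; optional `profile`
#'   overrides (e.g. `subErrorRate`) and `contact` overrides (e.g.
#'   `decayExponent`).
#' @return Invisibly, a list of output paths.
#' @export
simulateRun <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("referenceFasta", "truthVcf", "viewpointBed", "platform",
            "nCircles", "seed", "outDir")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("malformed simulateRun config; missing key(s): ",
         paste(missing, collapse = ", "))
  seqs <- readFasta(config$referenceFasta)
  tv <- readPhasedVcf(config$truthVcf)
  targetName <- names(seqs)[1L]
  v <- tv[tv$refName == targetName, , drop = FALSE]
  locus <- diploidLocus(seqs[[1L]],
                        v[, c("pos", "ref", "alt", "gt1", "gt2")],
                        name = targetName)
  bed <- rtracklayer::import(config$viewpointBed)
  vps <- lapply(seq_along(bed), function(i) {
    designViewpoint(locus, GenomicRanges::start(bed)[i] - 1L,
                    name = if (!is.null(bed$name)) bed$name[i]
                           else sprintf("vp%d", i))
  })
  profArgs <- config$profile
  profile <- if (identical(config$platform, "short"))
    do.call(shortReadProfile, as.list(profArgs))
  else do.call(longReadProfile, as.list(profArgs))
  model <- do.call(contactModel, as.list(config$contact))
  nReads <- if (is.null(config$nReads)) config$nCircles else config$nReads
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  fragsByHap <- digestLocus(locus)
  allReads <- list(); allProv <- list()
  for (vi in seq_along(vps)) {
    circles <- simulateCircles(fragsByHap, vps[[vi]], model,
                               n = config$nCircles,
                               seed = stageSeed(config$seed,
                                                paste0("circles", vi)))
    amps <- amplify(circles, vps[[vi]])
    rr <- generateReads(amps, profile, n = nReads,
                        seed = stageSeed(config$seed, paste0("reads", vi)))
    rr$reads$readId <- paste0(vps[[vi]]@vpName, "_", rr$reads$readId)
    rr$provenance$readId <- paste0(vps[[vi]]@vpName, "_",
                                   rr$provenance$readId)
    rr$provenance$viewpoint <- vps[[vi]]@vpName
    allReads[[vi]] <- rr$reads
    allProv[[vi]] <- rr$provenance
  }
  reads <- do.call(rbind, allReads)
  prov <- do.call(rbind, allProv)
  fq <- file.path(config$outDir, "reads.fastq")
  if (nrow(reads)) writeFastq(reads, fq) else file.create(fq)
  provPath <- file.path(config$outDir, "provenance.tsv")
  writeTsv(prov, provPath)
  phasePath <- file.path(config$outDir, "truth_phase.tsv")
  writeTsv(variants(locus), phasePath)
  invisible(list(fastq = fq, provenance = provPath,
                 truthPhase = phasePath))
}

# ---------------------------------------------------------------------------
# Provenance summaries
# ---------------------------------------------------------------------------

#' Per-fragment depth from provenance, with distance rank to a viewpoint
#'
#' Computes, before any mapping, the mean truth depth of every reference
#' NlaIII fragment together with its ordinal distance from the viewpoint
#' fragment. Used to check the coverage-decay property (depth is highest
#' around the viewpoint and drops with distance).
#'
#' @param provenance Provenance data.frame from [generateReads()].
#' @param locus The simulated [DiploidLocus-class].
#' @param viewpoint The [Viewpoint-class].
#' @return data.frame with `index`, `distance`, `meanDepth`.
#' @export
provenanceDepthByFragment <- function(provenance, locus, viewpoint) {
  frags <- digest(refSeq(locus), nlaIII())
  vpIdx <- which(frags$start <= viewpoint@refPos &
                 viewpoint@refPos < frags$end)[1L]
  depth <- vapply(seq_len(nrow(frags)), function(i) {
    ov <- overlapWidth(provenance$refStart, provenance$refEnd,
                       frags$start[i], frags$end[i])
    sum(ov) / (frags$end[i] - frags$start[i])
  }, numeric(1))
  data.frame(index = frags$index, distance = abs(frags$index - vpIdx),
             meanDepth = depth)
}

#' Collapse provenance rows that are genomically contiguous on the read
#'
#' When a circle ligates two genomically adjacent fragments in their
#' original order, the resulting read is locally indistinguishable from
#' an unbroken molecule, and a mapper necessarily reports one merged
#' segment. This helper merges such provenance rows (same strand,
#' abutting read and reference intervals), giving the set of maximal
#' mapper-recoverable segments.
#'
#' @param provenance Provenance data.frame of one read (columns
#'   `readStart`, `readEnd`, `refStart`, `refEnd`, `strand`).
#' @return The collapsed data.frame, sorted by `readStart`.
#' @export
collapseProvenance <- function(provenance) {
  pv <- provenance[order(provenance$readStart), , drop = FALSE]
  if (nrow(pv) < 2L) return(pv)
  out <- pv[1L, , drop = FALSE]
  for (i in 2:nrow(pv)) {
    prev <- nrow(out)
    contig <- pv$readStart[i] == out$readEnd[prev] &&
      pv$strand[i] == out$strand[prev] &&
      ((pv$strand[i] == "+" && pv$refStart[i] == out$refEnd[prev]) ||
       (pv$strand[i] == "-" && pv$refEnd[i] == out$refStart[prev]))
    if (contig) {
      out$readEnd[prev] <- pv$readEnd[i]
      if (pv$strand[i] == "+") out$refEnd[prev] <- pv$refEnd[i]
      else out$refStart[prev] <- pv$refStart[i]
    } else {
      out <- rbind(out, pv[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}
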