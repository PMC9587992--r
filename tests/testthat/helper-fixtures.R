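# Shared fixtures and independent oracles, built in code at test time.

# Independent digestion oracle: plain regex scan for the motif, cutting
# after each occurrence (NlaIII convention).
oracleDigest <- function(seq, motif = "CATG", cutOffset = 4L) {
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  cuts <- if (hits[1L] == -1L) integer(0) else hits - 1L + cutOffset
  cuts <- sort(unique(cuts[cuts > 0L & cuts < nchar(seq)]))
  bounds <- c(0L, cuts, nchar(seq))
  substring(seq, bounds[-length(bounds)] + 1L, bounds[-1L])
}

# Brute-force chimeric read decomposition: cut the read at every CATG
# boundary (both strand conventions), then find, per maximal run of
# pieces, the exact reference placements by exhaustive substring search.
# Returns the maximal contiguous read intervals that match a reference
# exactly (either strand).
bruteDecompose <- function(readSeq, references) {
  L <- nchar(readSeq)
  hits <- gregexpr("CATG", readSeq, fixed = TRUE)[[1L]]
  ms <- if (hits[1L] == -1L) integer(0) else hits - 1L
  cuts <- sort(unique(c(ms, ms + 4L)))
  cuts <- cuts[cuts > 0L & cuts < L]
  bounds <- c(0L, cuts, L)
  occurs <- function(piece) {
    for (rn in names(references)) {
      if (grepl(piece, references[[rn]], fixed = TRUE) ||
          grepl(tlaphaser:::revComp(piece), references[[rn]], fixed = TRUE))
        return(TRUE)
    }
    FALSE
  }
  # dynamic programme over boundary pairs: longest exact segments first
  n <- length(bounds)
  segs <- list()
  i <- 1L
  while (i < n) {
    best <- NULL
    for (j in n:(i + 1L)) {
      piece <- substring(readSeq, bounds[i] + 1L, bounds[j])
      if (occurs(piece)) { best <- j; break }
    }
    if (is.null(best)) { i <- i + 1L; next }
    segs[[length(segs) + 1L]] <- c(bounds[i], bounds[best])
    i <- best
  }
  if (!length(segs))
    return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1L], end = m[, 2L])
}

# Small standard locus used across mapper/caller/phaser tests.
fixtureLocus <- function(seed = 7L, nHetIndels = 2L, nHetSnvs = 8L,
                         nFragments = 8L, fragmentLength = 1200L, ...) {
  synthesizeLocus(nFragments = nFragments, fragmentLength = fragmentLength,
                  nHetSnvs = nHetSnvs, nHetIndels = nHetIndels,
                  seed = seed, ...)
}

# Simulated reads + index for a locus (error-free unless stated).
fixtureSim <- function(locus, platform = "long", nCircles = 40L,
                       nReads = 40L, seedCircles = 11L, seedReads = 5L,
                       profile = NULL) {
  fbh <- digestLocus(locus)
  vp <- designViewpoint(locus, variants(locus)$pos[1L])
  circles <- simulateCircles(fbh, vp, n = nCircles, seed = seedCircles)
  amps <- amplify(circles, vp)
  if (is.null(profile)) {
    profile <- if (platform == "long")
      longReadProfile(subErrorRate = 0, indelErrorRate = 0)
    else shortReadProfile(subErrorRate = 0)
  }
  rr <- generateReads(amps, profile, n = nReads, seed = seedReads)
  refs <- setNames(refSeq(locus), refName(locus))
  list(locus = locus, viewpoint = vp, circles = circles, amps = amps,
       reads = rr$reads, provenance = rr$provenance,
       refs = refs, index = buildIndex(refs, k = 21L))
}

# Construct a Pileup by hand for caller unit tests.
makePileup <- function(refName, refLen, depth, altRows = NULL) {
  d <- rep_len(depth, refLen)
  alt <- if (is.null(altRows))
    data.frame(refName = character(), pos = integer(),
               allele = character(), count = integer())
  else altRows
  methods::new("Pileup", refLens = setNames(as.integer(refLen), refName),
               depth = setNames(list(as.integer(d)), refName),
               altCounts = alt, alignedBases = sum(as.numeric(d)))
}

# Random link instances for phaser oracle properties.
randomLinkInstance <- function(nHet = 8L, nLinks = 12L) {
  hc <- data.frame(refName = "t", pos = seq_len(nHet) * 100L,
                   ref = "A", alt = "C", stringsAsFactors = FALSE)
  hc$variantId <- seq_len(nHet)
  pairs <- t(utils::combn(nHet, 2L))
  pick <- pairs[sample.int(nrow(pairs), min(nLinks, nrow(pairs))), ,
                drop = FALSE]
  links <- data.frame(varA = pick[, 1L], varB = pick[, 2L],
                      nCis = sample(0:6, nrow(pick), replace = TRUE),
                      nTrans = sample(0:6, nrow(pick), replace = TRUE))
  links <- links[links$nCis + links$nTrans > 0L, , drop = FALSE]
  list(hetCalls = hc, links = links)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
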