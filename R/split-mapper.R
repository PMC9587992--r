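#' @include AllClasses.R
NULL

.CODE <- 16777216L  # position encoding base for the seed index

.EMPTY_ALN <- data.frame(segStart = integer(), segEnd = integer(),
                         refName = character(), refStart = integer(),
                         refEnd = integer(), strand = character(),
                         mismatches = integer(), indels = integer(),
                         score = integer(), cigar = character(),
                         ambiguous = logical(), stringsAsFactors = FALSE)

# ---------------------------------------------------------------------------
# Seed index
# ---------------------------------------------------------------------------

#' Build a k-mer seed index over reference sequences
#'
#' @param references Named character vector (or `DNAStringSet`) of
#'   reference sequences, including any homolog decoys.
#' @param k Seed length (>= 11, default 21).
#' @return A [SeedIndex-class].
#' @export
buildIndex <- function(references, k = 21L) {
  if (methods::is(references, "DNAStringSet"))
    references <- setNames(as.character(references), names(references))
  stopifnot(length(references) > 0L, !is.null(names(references)))
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11")
  if (all(nchar(references) < k))
    stop("k is larger than every reference")
  allK <- character(0); allC <- numeric(0)
  for (ri in seq_along(references)) {
    s <- references[[ri]]
    n <- nchar(s)
    if (n < k) next
    idx <- seq_len(n - k + 1L)
    allK <- c(allK, substring(s, idx, idx + k - 1L))
    allC <- c(allC, (ri - 1L) * .CODE + idx)
  }
  tab <- list2env(split(allC, allK), hash = TRUE)
  new("SeedIndex", k = k, refNames = names(references),
      refSeqs = setNames(unname(references), names(references)),
      refRaws = lapply(references, charToRaw), table = tab)
}

#' Look up a k-mer in a seed index
#'
#' @param index A [SeedIndex-class].
#' @param kmer Character k-mer of length `index@k`.
#' @return data.frame with `ref` (index into `refNames`) and `pos`
#'   (1-based), sorted; zero rows when absent.
#' @export
kmerHits <- function(index, kmer) {
  v <- index@table[[kmer]]
  if (is.null(v)) return(data.frame(ref = integer(), pos = integer()))
  data.frame(ref = as.integer(v %/% .CODE) + 1L,
             pos = as.integer(v %% .CODE))
}

# ---------------------------------------------------------------------------
# Seed extension
# ---------------------------------------------------------------------------

# Matches within the next w positions starting at (qi, ri); used to score
# diagonal-shift options when tolerating indels.
.laMatches <- function(q, r, qi, ri, w) {
  n <- min(w, length(q) - qi + 1L, length(r) - ri + 1L)
  if (n <= 0L) return(0L)
  sum(q[qi:(qi + n - 1L)] == r[ri:(ri + n - 1L)])
}

# Greedy scored extension to the right from (qi, ri) (both 1-based, the
# first positions to compare). Match +1, substitution -3, indel event -5;
# stops 12 below the running maximum (X-drop); the endpoint is the argmax.
# Indel events (diagonal shifts of up to 2 bp) are recorded so a CIGAR can
# be assembled without re-alignment.
.extendRight <- function(q, r, qi, ri, allowIndel) {
  q0 <- qi; r0 <- ri
  score <- 0L; best <- 0L
  bq <- qi - 1L; br <- ri - 1L; bnm <- 0L; bev <- 0L
  nm <- 0L
  evQ <- integer(0); evLen <- integer(0); evIns <- logical(0)
  nq <- length(q); nr <- length(r)
  while (qi <= nq && ri <= nr) {
    chunk <- min(256L, nq - qi + 1L, nr - ri + 1L)
    qa <- q[qi:(qi + chunk - 1L)]
    ra <- r[ri:(ri + chunk - 1L)]
    neq <- which(qa != ra)
    if (!length(neq)) {
      score <- score + chunk
      qi <- qi + chunk; ri <- ri + chunk
      if (score > best) {
        best <- score; bq <- qi - 1L; br <- ri - 1L; bnm <- nm
        bev <- length(evQ)
      }
      next
    }
    m <- neq[1L] - 1L
    if (m > 0L) {
      score <- score + m
      qi <- qi + m; ri <- ri + m
      if (score > best) {
        best <- score; bq <- qi - 1L; br <- ri - 1L; bnm <- nm
        bev <- length(evQ)
      }
    }
    # mismatch at (qi, ri): substitution, or a 1-2 bp diagonal shift
    shifted <- FALSE
    if (allowIndel) {
      stay <- .laMatches(q, r, qi + 1L, ri + 1L, 16L)
      bestD <- 0L; bestSc <- stay
      for (d in c(1L, -1L, 2L, -2L)) {
        sc <- if (d > 0L) .laMatches(q, r, qi + d, ri, 16L)
              else .laMatches(q, r, qi, ri - d, 16L)
        # a true indel restores near-perfect matching downstream; the 13/16
        # floor rejects chance-level improvements (e.g. across a ligation
        # junction, where continuation matches only one base in four)
        if (sc >= bestSc + 3L && sc >= 13L) { bestSc <- sc; bestD <- d }
      }
      if (bestD != 0L) {
        evQ <- c(evQ, qi - q0); evLen <- c(evLen, abs(bestD))
        evIns <- c(evIns, bestD > 0L)
        if (bestD > 0L) qi <- qi + bestD else ri <- ri - bestD
        score <- score - 5L
        shifted <- TRUE
      }
    }
    if (!shifted) {
      nm <- nm + 1L
      score <- score - 3L
      qi <- qi + 1L; ri <- ri + 1L
    }
    if (score < best - 12L) break
  }
  keep <- seq_len(bev)
  list(qLen = bq - q0 + 1L, rLen = br - r0 + 1L, nMismatch = bnm,
       nIndel = bev, score = best,
       evQ = evQ[keep], evLen = evLen[keep], evIns = evIns[keep])
}

# Leftward extension, implemented on reversed prefixes.
.extendLeft <- function(q, r, qi, ri, allowIndel) {
  if (qi < 1L || ri < 1L)
    return(list(qLen = 0L, rLen = 0L, nMismatch = 0L, nIndel = 0L,
                score = 0L, evQ = integer(0), evLen = integer(0),
                evIns = logical(0)))
  .extendRight(rev(q[seq_len(qi)]), rev(r[seq_len(ri)]), 1L, 1L, allowIndel)
}

# Run-list (op/len) for one extension side given its events.
.sideRuns <- function(qLen, evQ, evLen, evIns) {
  ops <- character(0); lens <- integer(0)
  prevQ <- 0L
  for (i in seq_along(evQ)) {
    m <- evQ[i] - prevQ
    if (m > 0L) { ops <- c(ops, "M"); lens <- c(lens, m) }
    ops <- c(ops, if (evIns[i]) "I" else "D")
    lens <- c(lens, evLen[i])
    prevQ <- evQ[i] + if (evIns[i]) evLen[i] else 0L
  }
  m <- qLen - prevQ
  if (m > 0L) { ops <- c(ops, "M"); lens <- c(lens, m) }
  list(op = ops, len = lens)
}

# Assemble the full CIGAR: reversed left side + k-mer seed + right side.
.assembleCigar <- function(lt, rt, k) {
  lruns <- .sideRuns(lt$qLen, lt$evQ, lt$evLen, lt$evIns)
  rruns <- .sideRuns(rt$qLen, rt$evQ, rt$evLen, rt$evIns)
  ops <- c(rev(lruns$op), "M", rruns$op)
  lens <- c(rev(lruns$len), k, rruns$len)
  # merge adjacent identical ops
  keep <- c(TRUE, ops[-1L] != ops[-length(ops)])
  grp <- cumsum(keep)
  lens <- as.integer(tapply(lens, grp, sum))
  ops <- ops[keep]
  paste0(lens, ops, collapse = "")
}

# Mismatches of an oriented query against its reference slice under a
# CIGAR (cheap vectorised recount, used after junction trimming).
.countMismatches <- function(qSeq, rSeq, cigar) {
  runs <- regmatches(cigar, gregexpr("\\d+[MID]", cigar))[[1L]]
  lens <- as.integer(sub("[MID]", "", runs))
  ops <- sub("\\d+", "", runs)
  q <- charToRaw(qSeq); r <- charToRaw(rSeq)
  qi <- 1L; ri <- 1L; nm <- 0L
  for (j in seq_along(ops)) {
    len <- lens[j]
    if (ops[j] == "M") {
      nm <- nm + sum(q[qi:(qi + len - 1L)] != r[ri:(ri + len - 1L)])
      qi <- qi + len; ri <- ri + len
    } else if (ops[j] == "I") qi <- qi + len
    else ri <- ri + len
  }
  as.integer(nm)
}

# ---------------------------------------------------------------------------
# Segment alignment
# ---------------------------------------------------------------------------

#' Align one read segment by seed-and-extend
#'
#' Seeds the segment (both orientations) against the k-mer index and
#' extends each candidate diagonal with a scored greedy extension
#' (band width 2 when `indelTolerant`). By default all co-optimal
#' placements under the score are returned and more than one placement
#' sets the `ambiguous` flag; with `all = TRUE` every candidate passing
#' the mismatch-rate filter is returned (used internally to cache
#' whole-read candidates across split rounds). Segments shorter than `k`
#' are located by exact search only.
#'
#' @param segSeq Character segment sequence.
#' @param index A [SeedIndex-class].
#' @param params A [MapperParams-class].
#' @param all Return all candidates instead of the co-optimal set.
#' @return data.frame with columns `segStart`, `segEnd` (0-based half-open
#'   within the segment, original orientation), `refName`, `refStart`,
#'   `refEnd`, `strand`, `mismatches`, `indels`, `score`, `cigar`,
#'   `ambiguous`; zero rows when unmapped.
#' @export
alignSegment <- function(segSeq, index, params = mapperParams(),
                         all = FALSE) {
  len <- nchar(segSeq)
  empty <- .EMPTY_ALN
  if (len < 1L) return(empty)
  k <- index@k
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") segSeq else revComp(segSeq)
    if (len < k) {
      for (ri in seq_along(index@refSeqs)) {
        hits <- gregexpr(q, index@refSeqs[[ri]], fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (h in hits) {
          rows[[length(rows) + 1L]] <- data.frame(
            oqs = 1L, oqe = len, ref = ri, refStart = h - 1L,
            refEnd = h - 1L + len, strand = strand, mismatches = 0L,
            indels = 0L, score = len, cigar = paste0(len, "M"),
            stringsAsFactors = FALSE)
        }
      }
      next
    }
    qr <- charToRaw(q)
    stride <- max(7L, min(47L, (len - k) %/% 24L + 1L))
    starts <- unique(c(seq.int(1L, len - k + 1L, by = stride), len - k + 1L))
    bins <- new.env(hash = TRUE)
    binOrder <- character(0)
    for (st in starts) {
      hits <- index@table[[substr(q, st, st + k - 1L)]]
      if (is.null(hits) || length(hits) > 64L) next
      for (code in hits) {
        ri <- as.integer(code %/% .CODE) + 1L
        pos <- as.integer(code %% .CODE)
        diag <- pos - st
        key <- paste0(ri, ":", diag %/% 16L)
        if (is.null(bins[[key]])) {
          bins[[key]] <- c(st, pos, ri)
          binOrder <- c(binOrder, key)
        }
      }
      if (length(binOrder) > 96L) break
    }
    for (key in binOrder) {
      anchor <- bins[[key]]
      st <- anchor[1L]; pos <- anchor[2L]; ri <- anchor[3L]
      rr <- index@refRaws[[ri]]
      lt <- .extendLeft(qr, rr, st - 1L, pos - 1L, params@indelTolerant)
      rt <- .extendRight(qr, rr, st + k, pos + k, params@indelTolerant)
      oqs <- st - lt$qLen; oqe <- st + k - 1L + rt$qLen       # 1-based
      rs <- pos - lt$rLen; re <- pos + k - 1L + rt$rLen       # 1-based
      nm <- lt$nMismatch + rt$nMismatch
      ev <- lt$nIndel + rt$nIndel
      alen <- oqe - oqs + 1L
      if (alen < k) next
      if ((nm + ev) > params@maxMismatchRate * alen) next
      rows[[length(rows) + 1L]] <- data.frame(
        oqs = oqs, oqe = oqe, ref = ri, refStart = rs - 1L, refEnd = re,
        strand = strand, mismatches = nm, indels = ev,
        score = lt$score + rt$score + k,
        cigar = .assembleCigar(lt, rt, k), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  cand <- do.call(rbind, rows)
  cand <- cand[!duplicated(cand[, c("ref", "refStart", "refEnd", "strand",
                                    "oqs", "oqe")]), , drop = FALSE]
  if (!all) {
    best <- max(cand$score)
    cand <- cand[cand$score == best, , drop = FALSE]
  }
  cand <- cand[order(cand$ref, cand$refStart, cand$strand), , drop = FALSE]
  # oriented 1-based query interval -> original 0-based half-open
  segStart <- ifelse(cand$strand == "+", cand$oqs - 1L, len - cand$oqe)
  segEnd <- ifelse(cand$strand == "+", cand$oqe, len - cand$oqs + 1L)
  data.frame(segStart = as.integer(segStart), segEnd = as.integer(segEnd),
             refName = index@refNames[cand$ref],
             refStart = cand$refStart, refEnd = cand$refEnd,
             strand = cand$strand, mismatches = cand$mismatches,
             indels = cand$indels, score = cand$score, cigar = cand$cigar,
             ambiguous = if (all) NA else nrow(cand) > 1L,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Junction snapping and cigar trimming
# ---------------------------------------------------------------------------

# Trim t bases from the read-space left or right end of an alignment row.
# Returns NULL when the corresponding terminal cigar run is not a
# sufficiently long M (snapping is then skipped).
.trimAlignment <- function(aln, side, t) {
  if (t <= 0L) return(aln)
  runs <- regmatches(aln$cigar, gregexpr("\\d+[MID]", aln$cigar))[[1L]]
  lens <- as.integer(sub("[MID]", "", runs))
  ops <- sub("\\d+", "", runs)
  cigSide <- if (aln$strand == "+") side
             else if (side == "left") "right" else "left"
  i <- if (cigSide == "left") 1L else length(ops)
  if (ops[i] != "M" || lens[i] <= t) return(NULL)
  lens[i] <- lens[i] - t
  if (cigSide == "left") aln$refStart <- aln$refStart + t
  else aln$refEnd <- aln$refEnd - t
  if (side == "left") aln$segStart <- aln$segStart + t
  else aln$segEnd <- aln$segEnd - t
  aln$cigar <- paste0(lens, ops, collapse = "")
  aln
}

# ---------------------------------------------------------------------------
# Iterative split mapping
# ---------------------------------------------------------------------------

#' Iteratively split-map one chimeric read
#'
#' Implements the TLA mapping loop: align the read; where an alignment is
#' clipped, split the unmapped remainder at the NlaIII recognition-site
#' boundary closest to the clipped end of the mapped portion, and re-map
#' the remainders; repeat until everything is mapped or cannot be further
#' split. Both cut conventions (after the palindromic CATG on the forward
#' strand, before it on reverse-complemented reads) are handled.
#' Alignment ends are snapped to a junction boundary at most 8 bp away,
#' which removes the few chance-matching bases an extension may gain
#' across a ligation junction. Candidate placements found on the
#' whole-read pass are cached and reused when aligning remainders.
#'
#' @param readSeq,readId Read sequence and identifier.
#' @param index A [SeedIndex-class].
#' @param enzyme The splitting enzyme (default NlaIII).
#' @param params A [MapperParams-class].
#' @return List with `alignments` (data.frame: `readId`, `segStart`,
#'   `segEnd`, `refName`, `refStart`, `refEnd`, `strand`, `mismatches`,
#'   `ambiguous`, `round`, `cigar`) and `remnants` (data.frame: `readId`,
#'   `segStart`, `segEnd`, `reason`). Emitted segments and remnants
#'   partition the read.
#' @export
splitMap <- function(readSeq, readId, index, enzyme = nlaIII(),
                     params = mapperParams()) {
  L <- nchar(readSeq)
  ms <- if (grepl("^[ACGT]+$", enzyme@motif)) {
    hits <- gregexpr(enzyme@motif, readSeq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else hits - 1L
  } else {
    m <- Biostrings::matchPattern(enzyme@motif,
                                  Biostrings::DNAString(readSeq),
                                  fixed = FALSE)
    Biostrings::start(m) - 1L
  }
  inside <- function(x) x[x > 0L & x < L]
  # forward-strand junctions cut after the motif; on a reverse-complemented
  # read the cut convention mirrors to before the motif
  cutsFwd <- inside(ms + enzyme@cutOffset)
  cutsRev <- inside(ms + (nchar(enzyme@motif) - enzyme@cutOffset))
  cuts <- sort(unique(c(cutsFwd, cutsRev)))
  cache <- NULL

  alignIn <- function(s, e) {
    if (is.null(cache)) {
      res <- alignSegment(readSeq, index, params, all = TRUE)
      cache <<- res
    }
    sel <- cache[cache$segStart >= s - 8L & cache$segEnd <= e + 8L, ,
                 drop = FALSE]
    if (nrow(sel)) {
      out <- list()
      for (i in seq_len(nrow(sel))) {
        row <- sel[i, , drop = FALSE]
        tl <- max(0L, s - row$segStart)
        tr <- max(0L, row$segEnd - e)
        if (tl > 0L) row <- .trimAlignment(row, "left", tl)
        if (!is.null(row) && tr > 0L) row <- .trimAlignment(row, "right", tr)
        if (is.null(row)) next
        if (row$segEnd - row$segStart < max(params@minSegmentLen, index@k))
          next
        row$score <- row$score - (tl + tr)
        out[[length(out) + 1L]] <- row
      }
      if (length(out)) {
        cand <- do.call(rbind, out)
        best <- max(cand$score)
        cand <- cand[cand$score == best, , drop = FALSE]
        cand <- cand[order(cand$refName, cand$refStart, cand$strand), ,
                     drop = FALSE]
        cand$ambiguous <- nrow(cand) > 1L
        return(cand)
      }
    }
    res <- alignSegment(substring(readSeq, s + 1L, e), index, params)
    if (nrow(res)) {
      res$segStart <- res$segStart + s
      res$segEnd <- res$segEnd + s
    }
    res
  }

  recount <- function(row) {
    sub <- substring(readSeq, row$segStart + 1L, row$segEnd)
    q <- if (row$strand == "-") revComp(sub) else sub
    rs <- substr(index@refSeqs[[row$refName]], row$refStart + 1L,
                 row$refEnd)
    row$mismatches <- .countMismatches(q, rs, row$cigar)
    row
  }

  alns <- list(); rems <- list()
  addRemnant <- function(s, e, reason) {
    if (e > s)
      rems[[length(rems) + 1L]] <<- data.frame(
        readId = readId, segStart = s, segEnd = e, reason = reason,
        stringsAsFactors = FALSE)
  }
  work <- list(c(0L, L, 1L))
  while (length(work)) {
    it <- work[[1L]]; work <- work[-1L]
    s <- it[1L]; e <- it[2L]; r <- it[3L]
    if (e - s < params@minSegmentLen) { addRemnant(s, e, "too_short"); next }
    cand <- alignIn(s, e)
    if (!nrow(cand)) {
      cc <- cuts[cuts > s & cuts < e]
      if (!length(cc)) { addRemnant(s, e, "unmappable"); next }
      c0 <- cc[1L]  # ties and free choice resolved toward the 5' end
      work <- c(work, list(c(s, c0, r + 1L), c(c0, e, r + 1L)))
      next
    }
    amb <- isTRUE(cand$ambiguous[1L]) || nrow(cand) > 1L
    if (amb && params@ambiguityPolicy == "drop") {
      addRemnant(s, e, "ambiguous_dropped"); next
    }
    if (amb && params@ambiguityPolicy == "random")
      cand <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
    # keep co-optimal placements sharing the primary segment geometry
    cand <- cand[cand$segStart == cand$segStart[1L] &
                 cand$segEnd == cand$segEnd[1L], , drop = FALSE]
    qs <- cand$segStart[1L]
    qe <- cand$segEnd[1L]
    # snap clipped edges to the nearest junction boundary (<= 8 bp away),
    # using the cut convention matching the alignment's strand
    scuts <- if (cand$strand[1L] == "+") cutsFwd else cutsRev
    leftB <- qs; rightB <- qe
    if (qs > s) {
      cc <- scuts[scuts >= qs &
                  scuts <= min(qs + 8L, qe - params@minSegmentLen)]
      if (length(cc)) leftB <- cc[1L]
    }
    if (qe < e) {
      cc <- scuts[scuts <= qe &
                  scuts >= max(qe - 8L, qs + params@minSegmentLen,
                               leftB + params@minSegmentLen)]
      if (length(cc)) rightB <- cc[length(cc)]
    }
    tl <- leftB - qs; tr <- qe - rightB
    emitted <- cand
    ok <- TRUE
    for (i in seq_len(nrow(emitted))) {
      row <- emitted[i, , drop = FALSE]
      if (tl > 0L) row <- .trimAlignment(row, "left", tl)
      if (!is.null(row) && tr > 0L) row <- .trimAlignment(row, "right", tr)
      if (is.null(row)) { ok <- FALSE; break }
      emitted[i, ] <- recount(row)
    }
    if (!ok) {
      leftB <- qs; rightB <- qe
      emitted <- cand
      for (i in seq_len(nrow(emitted)))
        emitted[i, ] <- recount(emitted[i, , drop = FALSE])
    }
    emitted$readId <- readId
    emitted$round <- r
    emitted$ambiguous <- amb
    alns[[length(alns) + 1L]] <- emitted
    if (leftB > s) work <- c(work, list(c(s, leftB, r + 1L)))
    if (rightB < e) work <- c(work, list(c(rightB, e, r + 1L)))
  }
  alnDf <- if (length(alns)) do.call(rbind, alns) else
    data.frame(readId = character(), segStart = integer(),
               segEnd = integer(), refName = character(),
               refStart = integer(), refEnd = integer(),
               strand = character(), mismatches = integer(),
               indels = integer(), score = integer(), cigar = character(),
               ambiguous = logical(), round = integer(),
               stringsAsFactors = FALSE)
  if (nrow(alnDf)) {
    alnDf <- alnDf[order(alnDf$segStart, alnDf$refName, alnDf$refStart),
                   c("readId", "segStart", "segEnd", "refName", "refStart",
                     "refEnd", "strand", "mismatches", "ambiguous", "round",
                     "cigar")]
    rownames(alnDf) <- NULL
  }
  remDf <- if (length(rems)) do.call(rbind, rems) else
    data.frame(readId = character(), segStart = integer(),
               segEnd = integer(), reason = character(),
               stringsAsFactors = FALSE)
  list(alignments = alnDf, remnants = remDf)
}

#' Split-map a batch of reads
#'
#' Mates of a pair are mapped independently as single-end reads.
#'
#' @param reads data.frame with `readId`, `seq` (e.g. from [readFastq()]).
#' @inheritParams splitMap
#' @return List with combined `alignments` and `remnants` data.frames.
#' @export
mapReads <- function(reads, index, enzyme = nlaIII(),
                     params = mapperParams()) {
  outA <- vector("list", nrow(reads))
  outR <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    res <- splitMap(reads$seq[i], reads$readId[i], index, enzyme, params)
    outA[[i]] <- res$alignments
    outR[[i]] <- res$remnants
  }
  alignments <- do.call(rbind, outA[!vapply(outA, is.null, logical(1))])
  remnants <- do.call(rbind, outR[!vapply(outR, is.null, logical(1))])
  rownames(alignments) <- rownames(remnants) <- NULL
  list(alignments = alignments, remnants = remnants)
}

# ---------------------------------------------------------------------------
# SAM export
# ---------------------------------------------------------------------------

#' Export fragment alignments as minimal SAM
#'
#' One record per segment; secondary segments of a read are flagged
#' supplementary, soft clips encode the unaligned read remainder.
#'
#' @param alignments Alignment data.frame from [mapReads()].
#' @param reads Read data.frame (`readId`, `seq`).
#' @param index The [SeedIndex-class] used for mapping (for @SQ headers).
#' @param path Output path.
#' @export
exportSam <- function(alignments, reads, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(index@refNames))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", index@refNames[i],
                       nchar(index@refSeqs[[i]])), con)
  seqs <- setNames(reads$seq, reads$readId)
  seen <- character(0)
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    readSeq <- seqs[[a$readId]]
    L <- nchar(readSeq)
    flag <- 0L
    if (a$strand == "-") flag <- flag + 16L
    if (a$readId %in% seen) flag <- flag + 2048L else seen <- c(seen, a$readId)
    if (a$strand == "+") {
      lc <- a$segStart; rc <- L - a$segEnd
      seqOut <- readSeq
    } else {
      lc <- L - a$segEnd; rc <- a$segStart
      seqOut <- revComp(readSeq)
    }
    cigar <- paste0(if (lc > 0L) paste0(lc, "S") else "", a$cigar,
                    if (rc > 0L) paste0(rc, "S") else "")
    writeLines(paste(sub("/[12]$", "", a$readId), flag, a$refName,
                     a$refStart + 1L, if (a$ambiguous) 0L else 60L, cigar,
                     "*", 0L, 0L, seqOut, "*",
                     paste0("NM:i:", a$mismatches), sep = "\t"), con)
  }
  invisible(path)
}
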