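#' @include pileup.R
NULL

# ---------------------------------------------------------------------------
# Allele observations per molecule
# ---------------------------------------------------------------------------

# Allele carried by one alignment at one called variant site.
# Returns 0 (ref), 1 (alt) or NA (no usable observation). Indel events
# are left-normalised before comparison with the (canonical) call.
.alleleAt <- function(a, readSeq, refSeq, pos, ref, alt) {
  isIndel <- nchar(ref) > 1L || nchar(alt) > 1L
  refLen <- nchar(ref)
  if (isIndel) {
    # require the full allele plus one anchor base on each side
    if (a$refStart > pos - 1L || a$refEnd < pos + refLen + 1L)
      return(NA_integer_)
  } else {
    if (!(a$refStart <= pos && pos < a$refEnd)) return(NA_integer_)
  }
  q <- .orientedSeg(readSeq, a)
  cg <- .parseCigar(a$cigar)
  qpos <- 1L; rpos <- a$refStart
  if (!isIndel) {
    for (j in seq_along(cg$op)) {
      len <- cg$len[j]
      if (cg$op[j] == "M") {
        if (pos >= rpos && pos < rpos + len) {
          b <- substr(q, qpos + (pos - rpos), qpos + (pos - rpos))
          return(if (b == ref) 0L else if (b == alt) 1L else NA_integer_)
        }
        qpos <- qpos + len; rpos <- rpos + len
      } else if (cg$op[j] == "I") qpos <- qpos + len
      else rpos <- rpos + len
    }
    return(NA_integer_)
  }
  # indel: look for a matching event anchored at pos; any other event
  # touching the allele window voids the observation
  win <- c(pos, pos + refLen)  # ref interval of the padded REF allele
  sawOther <- FALSE; sawMatch <- FALSE
  for (j in seq_along(cg$op)) {
    len <- cg$len[j]
    if (cg$op[j] == "M") { qpos <- qpos + len; rpos <- rpos + len; next }
    if (cg$op[j] == "I") {
      norm <- .leftNormIns(refSeq, rpos - 1L,
                           substr(q, qpos, qpos + len - 1L))
      anchor <- norm$pos
      if (anchor == pos && paste0(ref, norm$seq) == alt &&
          refLen == 1L) sawMatch <- TRUE
      else if (anchor >= win[1L] && anchor < win[2L]) sawOther <- TRUE
      qpos <- qpos + len
    } else {
      anchor <- .leftNormDel(refSeq, rpos - 1L, len)
      if (anchor == pos && refLen - nchar(alt) == len &&
          nchar(alt) == 1L) sawMatch <- TRUE
      else if (anchor + len >= win[1L] && anchor < win[2L]) sawOther <- TRUE
      rpos <- rpos + len
    }
  }
  if (sawMatch && !sawOther) return(1L)
  if (sawOther) return(NA_integer_)
  # no event: check the M-aligned bases actually equal the REF allele
  qpos <- 1L; rpos <- a$refStart
  got <- character(0)
  for (j in seq_along(cg$op)) {
    len <- cg$len[j]
    if (cg$op[j] == "M") {
      ov <- overlapWidth(rpos, rpos + len, win[1L], win[2L])
      if (ov > 0L) {
        o <- max(win[1L], rpos) - rpos
        got <- c(got, substr(q, qpos + o, qpos + o + ov - 1L))
      }
      qpos <- qpos + len; rpos <- rpos + len
    } else if (cg$op[j] == "I") qpos <- qpos + len
    else rpos <- rpos + len
  }
  if (paste(got, collapse = "") == ref) 0L else NA_integer_
}

#' Extract allele observations and phase links from alignments
#'
#' All segments sharing a read id -- and both mates of a pair -- derive
#' from one circle, hence one haplotype; the allele each molecule carries
#' at every covered heterozygous site is extracted, and every pair of het
#' sites seen on the same molecule contributes one unit of cis
#' (same-allele-class) or trans evidence.
#'
#' @param alignments Alignment data.frame from [mapReads()].
#' @param hetCalls Heterozygous calls (genotype "0/1") from
#'   [callVariants()].
#' @param reads Read data.frame (`readId`, `seq`).
#' @param references Named character vector or [SeedIndex-class].
#' @return List with `observations` (data.frame `molecule`, `variantId`,
#'   `allele`) and `links` (data.frame `varA`, `varB`, `nCis`, `nTrans`;
#'   `varA < varB` by position order).
#' @export
extractLinks <- function(alignments, hetCalls, reads, references) {
  if (methods::is(references, "SeedIndex"))
    references <- references@refSeqs
  hc <- hetCalls[order(hetCalls$refName, hetCalls$pos), , drop = FALSE]
  rownames(hc) <- NULL
  hc$variantId <- seq_len(nrow(hc))
  seqs <- setNames(reads$seq, reads$readId)
  obs <- vector("list", nrow(hc))
  for (v in seq_len(nrow(hc))) {
    rn <- hc$refName[v]; pos <- hc$pos[v]
    refLen <- nchar(hc$ref[v])
    sel <- which(alignments$refName == rn &
                 alignments$refStart <= pos &
                 alignments$refEnd >= pos + refLen)
    mols <- character(length(sel)); als <- integer(length(sel))
    kept <- 0L
    for (i in sel) {
      a <- alignments[i, ]
      al <- .alleleAt(a, seqs[[a$readId]], references[[rn]], pos,
                      hc$ref[v], hc$alt[v])
      if (!is.na(al)) {
        kept <- kept + 1L
        mols[kept] <- sub("/[12]$", "", a$readId)
        als[kept] <- al
      }
    }
    if (kept)
      obs[[v]] <- data.frame(molecule = mols[seq_len(kept)],
                             variantId = v, allele = als[seq_len(kept)],
                             stringsAsFactors = FALSE)
  }
  obs <- obs[!vapply(obs, is.null, logical(1))]
  if (!length(obs))
    return(list(observations = data.frame(molecule = character(),
                                          variantId = integer(),
                                          allele = integer()),
                links = data.frame(varA = integer(), varB = integer(),
                                   nCis = integer(), nTrans = integer()),
                hetCalls = hc))
  ob <- do.call(rbind, obs)
  # one observation per (molecule, variant); conflicting segments drop out
  key <- paste(ob$molecule, ob$variantId)
  agree <- tapply(ob$allele, key, function(x) {
    u <- unique(x); if (length(u) == 1L) u else NA_integer_
  })
  ob <- ob[!duplicated(key), , drop = FALSE]
  ob$allele <- as.integer(agree[paste(ob$molecule, ob$variantId)])
  ob <- ob[!is.na(ob$allele), , drop = FALSE]
  rownames(ob) <- NULL
  # pairwise links within each molecule
  la <- integer(0); lb <- integer(0); lcis <- integer(0)
  for (mol in split(ob, ob$molecule)) {
    if (nrow(mol) < 2L) next
    mol <- mol[order(mol$variantId), ]
    cmb <- utils::combn(seq_len(nrow(mol)), 2L)
    la <- c(la, mol$variantId[cmb[1L, ]])
    lb <- c(lb, mol$variantId[cmb[2L, ]])
    lcis <- c(lcis, as.integer(mol$allele[cmb[1L, ]] ==
                               mol$allele[cmb[2L, ]]))
  }
  links <- if (length(la)) {
    ag <- aggregate(list(nCis = lcis, nTrans = 1L - lcis),
                    by = list(varA = la, varB = lb), FUN = sum)
    ag[order(ag$varA, ag$varB), ]
  } else data.frame(varA = integer(), varB = integer(), nCis = integer(),
                    nTrans = integer())
  rownames(links) <- NULL
  list(observations = ob, links = links, hetCalls = hc)
}

# ---------------------------------------------------------------------------
# Phasing
# ---------------------------------------------------------------------------

.linkScore <- function(links, side) {
  if (!nrow(links)) return(0L)
  same <- side[links$varA] == side[links$varB]
  sum(ifelse(same, links$nCis, links$nTrans))
}

#' Phase heterozygous variants from pairwise links
#'
#' Connected components of the link graph become phase blocks. Within a
#' component, a maximum-weight spanning tree (edge weight
#' `|nCis - nTrans|`) fixes relative orientations by majority sign,
#' propagated from the highest-degree node; greedy single-variant flips
#' then remove any remaining locally improvable disagreements. Blocks are
#' canonicalised so their lowest-position variant is assigned side 0.
#' Components whose edges all have zero weight are left unphased with a
#' warning; singletons are unphased.
#'
#' @param links Link data.frame from [extractLinks()].
#' @param hetCalls Heterozygous call data.frame (ordered; a `variantId`
#'   column is added if absent).
#' @return List with `blocks` (data.frame `blockId`, `variantId`, `pos`,
#'   `side`), `blockScores` (data.frame `blockId`, `score`) and
#'   `unphased` (variant ids).
#' @export
phaseVariants <- function(links, hetCalls) {
  hc <- hetCalls
  if (is.null(hc$variantId)) {
    hc <- hc[order(hc$refName, hc$pos), , drop = FALSE]
    hc$variantId <- seq_len(nrow(hc))
  }
  nV <- nrow(hc)
  blocks <- list(); scores <- list()
  inBlock <- integer(0)
  if (nrow(links)) {
    links$w <- abs(links$nCis - links$nTrans)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(links$varA),
                 to = as.character(links$varB), weight = links$w),
      directed = FALSE)
    comp <- igraph::components(g)
    bid <- 0L
    for (ci in seq_len(comp$no)) {
      memb <- as.integer(names(comp$membership)[comp$membership == ci])
      if (length(memb) < 2L) next
      sub <- links[links$varA %in% memb & links$varB %in% memb, ,
                   drop = FALSE]
      if (all(sub$w == 0L)) {
        warning("phase block with only contradictory links left unphased")
        next
      }
      side <- setNames(rep(NA_integer_, length(memb)), memb)
      # max-weight spanning tree on edges with positive weight
      gs <- igraph::graph_from_data_frame(
        data.frame(from = as.character(sub$varA),
                   to = as.character(sub$varB)), directed = FALSE)
      tree <- igraph::mst(gs, weights = -sub$w)
      te <- igraph::as_data_frame(tree, what = "edges")
      deg <- igraph::degree(gs)
      root <- names(deg)[order(-deg, as.integer(names(deg)))][1L]
      side[root] <- 0L
      # sign per edge: cis majority keeps the side, trans majority flips
      sign <- setNames(ifelse(sub$nCis >= sub$nTrans, 1L, -1L),
                       paste(sub$varA, sub$varB))
      frontier <- root
      while (length(frontier)) {
        nxt <- character(0)
        for (u in frontier) {
          adj <- te[te$from == u | te$to == u, , drop = FALSE]
          for (j in seq_len(nrow(adj))) {
            vtx <- if (adj$from[j] == u) adj$to[j] else adj$from[j]
            if (!is.na(side[vtx])) next
            a <- min(as.integer(u), as.integer(vtx))
            b <- max(as.integer(u), as.integer(vtx))
            sg <- sign[[paste(a, b)]]
            side[vtx] <- if (sg > 0L) side[[u]] else 1L - side[[u]]
            nxt <- c(nxt, vtx)
          }
        }
        frontier <- nxt
      }
      # greedy improvement against all component links: flipping a single
      # variant, or an entire subtree on one side of a spanning-tree edge
      # (which repairs correlated misorientations a single flip cannot)
      sv <- setNames(side[as.character(memb)], memb)
      flipSets <- lapply(names(sv), identity)
      if (nrow(te)) {
        adj <- split(c(te$to, te$from), c(te$from, te$to))
        for (j in seq_len(nrow(te))) {
          # nodes reachable from te$to[j] without crossing edge j
          seen <- te$to[j]; frontier <- seen
          while (length(frontier)) {
            nxt <- character(0)
            for (u in frontier) for (w in adj[[u]]) {
              if (u == te$from[j] ||
                  (u == te$to[j] && w == te$from[j])) next
              if (!w %in% seen) { seen <- c(seen, w); nxt <- c(nxt, w) }
            }
            frontier <- nxt
          }
          flipSets[[length(flipSets) + 1L]] <- seen
        }
      }
      scoreOf <- function(assign) {
        sum(ifelse(assign[as.character(sub$varA)] ==
                   assign[as.character(sub$varB)], sub$nCis, sub$nTrans))
      }
      cur <- scoreOf(sv)
      repeat {
        bestGain <- 0L; bestSet <- NULL
        for (S in flipSets) {
          svF <- sv; svF[S] <- 1L - svF[S]
          gain <- scoreOf(svF) - cur
          if (gain > bestGain) { bestGain <- gain; bestSet <- S }
        }
        if (is.null(bestSet)) break
        sv[bestSet] <- 1L - sv[bestSet]
        cur <- cur + bestGain
      }
      ids <- sort(as.integer(names(sv)))
      sideVec <- sv[as.character(ids)]
      lowest <- ids[which.min(hc$pos[match(ids, hc$variantId)])]
      if (sideVec[[as.character(lowest)]] == 1L) sideVec <- 1L - sideVec
      bid <- bid + 1L
      blocks[[bid]] <- data.frame(
        blockId = bid, variantId = ids,
        pos = hc$pos[match(ids, hc$variantId)],
        side = as.integer(sideVec), stringsAsFactors = FALSE)
      full <- setNames(as.integer(sideVec), ids)
      scores[[bid]] <- data.frame(
        blockId = bid,
        score = sum(ifelse(full[as.character(sub$varA)] ==
                           full[as.character(sub$varB)],
                           sub$nCis, sub$nTrans)))
      inBlock <- c(inBlock, ids)
    }
  }
  blocksDf <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(blockId = integer(), variantId = integer(), pos = integer(),
               side = integer())
  scoresDf <- if (length(scores)) do.call(rbind, scores) else
    data.frame(blockId = integer(), score = integer())
  list(blocks = blocksDf, blockScores = scoresDf,
       unphased = setdiff(seq_len(nV), inBlock))
}

#' Exhaustive phasing oracle
#'
#' Scores all `2^(n-1)` side assignments (the first variant fixed to side
#' 0) and returns a maximiser; ties break toward the lexicographically
#' smallest assignment. Refuses more than `limit` variants.
#'
#' @param links Link data.frame (`varA`, `varB`, `nCis`, `nTrans`).
#' @param hetCalls Heterozygous call data.frame.
#' @param limit Maximum number of variants (default 12).
#' @return List with `assignment` (integer sides named by variant id) and
#'   `score`.
#' @export
bruteForcePhase <- function(links, hetCalls, limit = 12L) {
  n <- nrow(hetCalls)
  if (n > limit)
    stop("bruteForcePhase refuses more than ", limit, " variants (got ",
         n, ")")
  if (n == 0L) return(list(assignment = integer(0), score = 0L))
  best <- -1L; bestSide <- NULL
  for (mask in 0:(2^(max(n - 1L, 0L)) - 1L)) {
    side <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1L)])
    sc <- .linkScore(links, side)
    if (sc > best) { best <- sc; bestSide <- side }
  }
  list(assignment = setNames(bestSide, seq_len(n)), score = best)
}
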