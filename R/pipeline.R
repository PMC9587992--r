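#' @include benchmark.R simulator.R
NULL

# ---------------------------------------------------------------------------
# Configuration handling
# ---------------------------------------------------------------------------

.defaultConfig <- function() {
  list(
    name = "run",
    seed = 1L,
    outDir = tempfile("tla_run_"),
    locus = list(nFragments = 8L, fragmentLength = 1200L, nHetSnvs = 8L,
                 nHetIndels = 0L, nHomSnvs = 0L, gc = 0.45,
                 variantZone = c(0.1, 0.9)),
    homolog = NULL,
    viewpoints = list(strategy = "het_fragment", n = 1L, positions = NULL),
    platform = "short",
    profile = list(),
    contact = list(),
    mapper = list(),
    caller = list(),
    nCircles = 250L,
    nReads = 1500L,
    roiMargin = 0.15)
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate and complete a pipeline configuration
#'
#' @param config Named list of overrides over the package defaults (or a
#'   path to a YAML file with the same structure).
#' @return The completed configuration list.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultConfig(), config)
  if (is.null(cfg$seed)) stop("config error: 'seed' is mandatory")
  if (!cfg$platform %in% c("short", "long"))
    stop("config error: platform must be 'short' or 'long'")
  bad <- setdiff(names(config), names(.defaultConfig()))
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  cfg
}

# ---------------------------------------------------------------------------
# Stage helpers
# ---------------------------------------------------------------------------

# Block-structured decoy: each target NlaIII fragment is copied with its
# leading `divergedFraction` substituted down to `divergedIdentity`, the
# remainder kept identical -- emulating the interleaved conserved and
# diverged tracts of real pseudogene pairs (overall identity ~94% with
# the defaults).
.makeDecoy <- function(targetSeq, homolog, seed) {
  frags <- digest(targetSeq, nlaIII())
  pieces <- vapply(seq_len(nrow(frags)), function(i) {
    fseq <- frags$seq[i]
    dLen <- floor(nchar(fseq) * homolog$divergedFraction)
    if (dLen < 1L) return(fseq)
    head <- makeHomolog(substr(fseq, 1L, dLen), homolog$divergedIdentity,
                        seed = stageSeed(seed, paste0("homolog", i)))
    paste0(head, substr(fseq, dLen + 1L, nchar(fseq)))
  }, character(1))
  paste(pieces, collapse = "")
}

.resolveViewpoints <- function(locus, vpCfg) {
  frags <- digest(refSeq(locus), nlaIII())
  v <- variants(locus)
  hets <- v[v$gt1 != v$gt2, , drop = FALSE]
  fragOf <- function(pos) which(frags$start <= pos & pos < frags$end)[1L]
  center <- nchar(refSeq(locus)) / 2
  primerOffsets <- NULL
  positions <- if (!is.null(vpCfg$positions)) {
    vpCfg$positions
  } else if (vpCfg$strategy == "het_fragment") {
    if (!nrow(hets)) stop("no heterozygous variant to anchor a viewpoint")
    # anchor on the het closest to a fragment edge, and place the primer
    # on the far side of the het: the het then flanks one of the two
    # viewpoint ligation junctions of every amplicon, where short read
    # pairs can link it to variants of the neighbouring fragment
    fi <- vapply(hets$pos, fragOf, integer(1))
    off <- hets$pos - frags$start[fi]
    fragLen <- frags$end[fi] - frags$start[fi]
    edge <- pmin(off, fragLen - off)
    ord <- order(edge, abs(hets$pos - center))[seq_len(vpCfg$n)]
    primerOffsets <- ifelse(off[ord] <= fragLen[ord] - off[ord],
                            off[ord] + 60L, 40L)
    hets$pos[ord]
  } else if (vpCfg$strategy == "no_het_fragment") {
    vFrag <- unique(vapply(v$pos, fragOf, integer(1)))
    free <- setdiff(seq_len(nrow(frags)), vFrag)
    if (!length(free)) stop("every fragment carries a variant")
    mid <- (frags$start[free] + frags$end[free]) / 2
    sel <- free[order(abs(mid - center))][seq_len(vpCfg$n)]
    as.integer((frags$start[sel] + frags$end[sel]) %/% 2)
  } else if (vpCfg$strategy == "even") {
    L <- nchar(refSeq(locus))
    as.integer(round(L * (seq_len(vpCfg$n) - 0.5) / vpCfg$n))
  } else stop("unknown viewpoint strategy: ", vpCfg$strategy)
  lapply(seq_along(positions), function(i)
    designViewpoint(locus, positions[i], name = sprintf("vp%d", i),
                    primerOffset = if (is.null(primerOffsets)) 40L
                                   else primerOffsets[i]))
}

.platformProfile <- function(cfg) {
  if (cfg$platform == "short")
    do.call(shortReadProfile, cfg$profile)
  else do.call(longReadProfile, cfg$profile)
}

.platformMapper <- function(cfg) {
  if (cfg$platform == "short")
    do.call(shortReadMapperParams, cfg$mapper)
  else do.call(longReadMapperParams, cfg$mapper)
}

.platformCaller <- function(cfg) {
  if (cfg$platform == "short")
    do.call(shortReadCallerConfig, cfg$caller)
  else do.call(longReadCallerConfig, cfg$caller)
}

# ---------------------------------------------------------------------------
# Pipeline
# ---------------------------------------------------------------------------

#' Run the simulate / map / call / phase / benchmark pipeline
#'
#' Executes the full TLA analysis on a synthetic locus described by the
#' configuration: locus synthesis, optional homolog decoy, viewpoint
#' placement, circle and read simulation per viewpoint (per-viewpoint
#' data are merged before pileup, as real multi-viewpoint libraries are),
#' split mapping, depth-filtered calling, link phasing and benchmarking.
#' All randomness derives from the run seed through named per-stage
#' substreams; identical configuration and seed give byte-identical
#' outputs and manifest.
#'
#' @param config Configuration (see [pipelineConfig()]).
#' @param outDir,seed Optional overrides of the config entries.
#' @return Invisibly, a list with all intermediate objects (`locus`,
#'   `viewpoints`, `reads`, `provenance`, `alignments`, `remnants`,
#'   `pileup`, `onTarget`, `coverage`, `calls`, `linkData`, `phased`,
#'   `report`, `manifest`, `outDir`).
#' @export
runPipeline <- function(config = list(), outDir = NULL, seed = NULL) {
  cfg <- pipelineConfig(config)
  if (!is.null(outDir)) cfg$outDir <- outDir
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  logLine <- function(...) writeLines(paste0(...), logCon)
  logLine("tlaphaser pipeline run: ", cfg$name)
  logLine("seed: ", cfg$seed)
  logLine("config:")
  writeLines(yaml::as.yaml(cfg[setdiff(names(cfg), "outDir")]), logCon)

  # --- locus -------------------------------------------------------------
  loc <- cfg$locus
  locus <- synthesizeLocus(nFragments = loc$nFragments,
                           fragmentLength = loc$fragmentLength,
                           nHetSnvs = loc$nHetSnvs,
                           nHetIndels = loc$nHetIndels,
                           nHomSnvs = loc$nHomSnvs, gc = loc$gc,
                           seed = cfg$seed, variantZone = loc$variantZone,
                           name = "target")
  refs <- setNames(refSeq(locus), refName(locus))
  decoyLocus <- NULL
  if (!is.null(cfg$homolog)) {
    hom <- .mergeConfig(list(divergedFraction = 0.3,
                             divergedIdentity = 0.8, enrich = TRUE),
                        cfg$homolog)
    cfg$homolog <- hom
    decoySeq <- .makeDecoy(refSeq(locus), hom, cfg$seed)
    refs <- c(refs, decoy = decoySeq)
    if (isTRUE(hom$enrich))
      decoyLocus <- diploidLocus(decoySeq, NULL, name = "decoy")
    logLine(sprintf("homolog decoy: %d bp, identity %.3f",
                    nchar(decoySeq),
                    mean(s2c(decoySeq) == s2c(refSeq(locus)))))
  }
  vps <- .resolveViewpoints(locus, cfg$viewpoints)
  L <- nchar(refSeq(locus))
  margin <- as.integer(round(L * cfg$roiMargin))
  roi <- data.frame(refName = refName(locus), start = margin,
                    end = L - margin, stringsAsFactors = FALSE)

  writeFasta(refs, file.path(cfg$outDir, "reference.fa"))
  writePhasedVcf(variants(locus), refName(locus), L,
                 file.path(cfg$outDir, "truth.vcf"))
  vpGr <- GenomicRanges::GRanges(
    refName(locus),
    IRanges::IRanges(start = vapply(vps, function(v) v@refPos, integer(1)) + 1L,
                     width = 1L))
  vpGr$name <- vapply(vps, function(v) v@vpName, character(1))
  rtracklayer::export(vpGr, file.path(cfg$outDir, "viewpoints.bed"))
  roiGr <- GenomicRanges::GRanges(roi$refName,
            IRanges::IRanges(start = roi$start + 1L, end = roi$end))
  roiGr$name <- "roi"
  rtracklayer::export(roiGr, file.path(cfg$outDir, "roi.bed"))

  # --- simulate ----------------------------------------------------------
  model <- do.call(contactModel, cfg$contact)
  profile <- .platformProfile(cfg)
  sources <- list(list(tag = "t", locus = locus, name = refName(locus)))
  if (!is.null(decoyLocus))
    sources <- c(sources, list(list(tag = "d", locus = decoyLocus,
                                    name = "decoy")))
  allReads <- list(); allProv <- list(); vpIndexByRead <- list()
  for (src in sources) {
    fragsByHap <- digestLocus(src$locus)
    for (vp in vps) {
      svp <- if (src$tag == "t") vp else
        designViewpoint(src$locus, vp@refPos, name = vp@vpName,
                        primerOffset = vp@primerOffset)
      tag <- paste0(src$tag, vp@vpName)
      circles <- simulateCircles(fragsByHap, svp, model, n = cfg$nCircles,
                                 seed = stageSeed(cfg$seed,
                                                  paste0("circles.", tag)))
      amps <- amplify(circles, svp)
      rr <- generateReads(amps, profile, n = cfg$nReads,
                          seed = stageSeed(cfg$seed, paste0("reads.", tag)))
      rr$reads$readId <- paste0(tag, "_", rr$reads$readId)
      rr$provenance$readId <- paste0(tag, "_", rr$provenance$readId)
      rr$provenance$refName <- src$name
      rr$provenance$viewpoint <- vp@vpName
      rr$provenance$source <- src$tag
      allReads[[tag]] <- rr$reads
      allProv[[tag]] <- rr$provenance
    }
  }
  reads <- do.call(rbind, allReads)
  prov <- do.call(rbind, allProv)
  rownames(reads) <- rownames(prov) <- NULL
  writeFastq(reads, file.path(cfg$outDir, "reads.fastq"))
  writeTsv(prov, file.path(cfg$outDir, "provenance.tsv"))
  logLine(sprintf("simulated %d reads (%d source/viewpoint combinations)",
                  nrow(reads), length(allReads)))

  # --- map ---------------------------------------------------------------
  params <- .platformMapper(cfg)
  index <- buildIndex(refs, k = params@k)
  mapped <- mapReads(reads, index, nlaIII(), params)
  writeTsv(mapped$alignments, file.path(cfg$outDir, "alignments.tsv"))
  writeTsv(mapped$remnants, file.path(cfg$outDir, "remnants.tsv"))
  logLine(sprintf("mapped: %d fragment alignments, %d unmapped remnants",
                  nrow(mapped$alignments), nrow(mapped$remnants)))

  # --- pileup / call -----------------------------------------------------
  callerCfg <- .platformCaller(cfg)
  pu <- pileupAlignments(mapped$alignments, reads, refs)
  onT <- onTargetStats(mapped$alignments, roi)
  cov <- coverageAtDepth(pu, callerCfg@minDepth, roi)
  calls <- callVariants(pu, callerCfg, refs)
  covDf <- data.frame(refName = roi$refName, roiStart = roi$start,
                      roiEnd = roi$end,
                      minDepth = callerCfg@minDepth,
                      coveredPositions = cov$coveredPositions,
                      roiLength = cov$roiLength, percent = cov$percent)
  writeTsv(covDf, file.path(cfg$outDir, "coverage.tsv"))
  if (nrow(cov$zeroDepthIntervals)) {
    zGr <- GenomicRanges::GRanges(
      cov$zeroDepthIntervals$refName,
      IRanges::IRanges(start = cov$zeroDepthIntervals$start + 1L,
                       end = cov$zeroDepthIntervals$end))
    rtracklayer::export(zGr, file.path(cfg$outDir, "zero_depth.bed"))
  }
  writeTsv(calls, file.path(cfg$outDir, "calls.tsv"))
  logLine(sprintf("on-target: %.1f%%; covered at %dX: %.1f%%; %d calls",
                  100 * onT$fraction, callerCfg@minDepth, cov$percent,
                  nrow(calls)))

  # --- phase -------------------------------------------------------------
  hets <- calls[calls$genotype == "0/1" &
                calls$refName == refName(locus), , drop = FALSE]
  linkData <- extractLinks(mapped$alignments, hets, reads, refs)
  phased <- phaseVariants(linkData$links, linkData$hetCalls)
  writeTsv(linkData$links, file.path(cfg$outDir, "links.tsv"))
  writeTsv(phased$blocks, file.path(cfg$outDir, "blocks.tsv"))
  # phased call VCF: block side 0 puts ALT on haplotype 1
  pc <- linkData$hetCalls
  side <- phased$blocks$side[match(pc$variantId, phased$blocks$variantId)]
  ps <- phased$blocks$blockId[match(pc$variantId, phased$blocks$variantId)]
  pc$phased <- !is.na(side)
  pc$gt1 <- ifelse(is.na(side), 0L, ifelse(side == 0L, 1L, 0L))
  pc$gt2 <- 1L - pc$gt1
  pc$ps <- ifelse(is.na(ps), 0L, as.integer(ps))
  homCalls <- calls[calls$genotype == "1/1" &
                    calls$refName == refName(locus), , drop = FALSE]
  homCalls$phased <- rep(FALSE, nrow(homCalls))
  homCalls$gt1 <- rep(1L, nrow(homCalls))
  homCalls$gt2 <- rep(1L, nrow(homCalls))
  homCalls$ps <- rep(0L, nrow(homCalls))
  cols <- c("pos", "ref", "alt", "gt1", "gt2", "phased", "ps")
  pc <- rbind(pc[, cols, drop = FALSE], homCalls[, cols, drop = FALSE])
  if (nrow(pc))
    writePhasedVcf(pc, refName(locus), L,
                   file.path(cfg$outDir, "phased_calls.vcf"))

  # --- benchmark ---------------------------------------------------------
  gcmp <- compareGenotypes(calls, variants(locus), pu, callerCfg,
                           targetRef = refName(locus))
  pcmp <- comparePhasing(phased, linkData$hetCalls, variants(locus))
  report <- benchmarkReport(gcmp, pcmp)
  reportList <- list(
    scenario = cfg$name, seed = cfg$seed,
    onTarget = onT[c("onTargetNt", "totalNt", "fraction",
                     "meanDepthInRoi")],
    coverage = list(minDepth = callerCfg@minDepth,
                    coveredPositions = cov$coveredPositions,
                    roiLength = cov$roiLength, percent = cov$percent),
    genotypes = gcmp,
    phasing = pcmp[c("nHeterozygous", "nPhased", "nConcordantPhased",
                     "nSwitchErrors", "nBlocks")])
  jsonlite::write_json(reportList, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  summaryPath <- file.path(cfg$outDir, "summary.txt")
  sink(summaryPath); show(report); sink()
  logLine(sprintf("benchmark: %d/%d het variants concordantly phased, %d switch errors",
                  pcmp$nConcordantPhased, pcmp$nHeterozygous,
                  pcmp$nSwitchErrors))
  close(logCon)
  on.exit(NULL)

  # --- manifest ----------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$outDir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$outDir, files))),
    stringsAsFactors = FALSE)
  writeTsv(manifest, file.path(cfg$outDir, "manifest.tsv"))

  invisible(list(config = cfg, locus = locus, viewpoints = vps,
                 reads = reads, provenance = prov,
                 alignments = mapped$alignments, remnants = mapped$remnants,
                 pileup = pu, onTarget = onT, coverage = cov, calls = calls,
                 linkData = linkData, phased = phased, report = report,
                 manifest = manifest, outDir = cfg$outDir))
}

# ---------------------------------------------------------------------------
# Scenario library
# ---------------------------------------------------------------------------

#' Named scenario presets
#'
#' Desk-scale stand-ins for the study designs the method is sensitive to:
#' a small locus with one viewpoint sequenced noise-free (long and short),
#' a large locus with four merged viewpoints, a locus flanked by a
#' ~94%-identical enriched pseudogene decoy (short and long), and a
#' viewpoint placed in a fragment with versus without a heterozygous
#' variant.
#'
#' @return Named list of configuration lists for [runPipeline()].
#' @export
makeScenarios <- function() {
  base <- list(seed = 42L)
  list(
    noise_free_long = .mergeConfig(base, list(
      name = "noise_free_long", platform = "long",
      profile = list(subErrorRate = 0, indelErrorRate = 0),
      locus = list(nHetSnvs = 8L, nHetIndels = 2L),
      nCircles = 250L, nReads = 700L)),
    noise_free_short = .mergeConfig(base, list(
      name = "noise_free_short", platform = "short",
      profile = list(subErrorRate = 0),
      locus = list(nHetSnvs = 8L, nHetIndels = 2L),
      nCircles = 250L, nReads = 2500L)),
    four_viewpoints = .mergeConfig(base, list(
      name = "four_viewpoints", platform = "short",
      locus = list(nFragments = 16L, nHetSnvs = 10L),
      viewpoints = list(strategy = "even", n = 4L),
      nCircles = 120L, nReads = 700L)),
    homolog_short = .mergeConfig(base, list(
      name = "homolog_short", platform = "short",
      locus = list(nHetSnvs = 6L, nHomSnvs = 4L,
                   variantZone = c(0.45, 0.9)),
      homolog = list(divergedFraction = 0.3, divergedIdentity = 0.8,
                     enrich = TRUE),
      nCircles = 200L, nReads = 2000L)),
    homolog_long = .mergeConfig(base, list(
      name = "homolog_long", platform = "long",
      locus = list(nHetSnvs = 6L, nHomSnvs = 4L,
                   variantZone = c(0.45, 0.9)),
      homolog = list(divergedFraction = 0.3, divergedIdentity = 0.8,
                     enrich = TRUE),
      nCircles = 200L, nReads = 500L)),
    viewpoint_with_het = .mergeConfig(base, list(
      name = "viewpoint_with_het", platform = "short",
      locus = list(nHetSnvs = 6L),
      viewpoints = list(strategy = "het_fragment", n = 1L),
      nCircles = 250L, nReads = 2000L)),
    viewpoint_no_het = .mergeConfig(base, list(
      name = "viewpoint_no_het", platform = "short",
      locus = list(nHetSnvs = 6L),
      viewpoints = list(strategy = "no_het_fragment", n = 1L),
      nCircles = 250L, nReads = 2000L)))
}
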