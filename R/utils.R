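# Internal helpers shared across modules. All sequence coordinates inside
# the package are 0-based half-open; VCF/BED I/O converts at the boundary.

.BASES <- c("A", "C", "G", "T")

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

revComp <- function(x) {
  chartr("ACGT", "TGCA", rawToChar(rev(charToRaw(x))))
}

#' Derive a stage-specific seed from a run seed
#'
#' One pipeline seed fans out into named per-stage substreams so that
#' stages sharing parameters (e.g. locus synthesis for a matched
#' short/long platform pair) consume identical random numbers regardless
#' of what other stages do.
#'
#' @param seed Integer run seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  code <- utf8ToInt(stage)
  h <- sum(code * seq_along(code))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Random DNA of a given length and GC content.
randomDna <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Write a data.frame as a deterministic TSV (no quotes, fixed NA token).
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n")
  invisible(path)
}

readTsv <- function(path, colClasses = NA) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = colClasses, comment.char = "")
}

# Overlap width of [s1,e1) with [s2,e2) (0-based half-open, vectorised).
overlapWidth <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
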