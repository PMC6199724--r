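#' Primer configuration
#'
#' Holds the amplification primers (IUPAC degenerate codes allowed), the
#' per-primer mismatch allowance, and named in-silico truncation primer sets
#' for short-read hypervariable regions.
#'
#' @param forward,reverse Amplification primers, 5'->3' (defaults: the
#'   universal full-length 16S primers F27 and R1492).
#' @param maxMismatches Per-primer mismatch budget for a hit (default 2;
#'   indels are not allowed in the hit, so they consume mismatches).
#' @param regions Named list of c(forward =, reverse =) primer pairs for
#'   [truncateToRegion()]; defaults cover V1-V3, V3-V5 and V4.
#' @return A list of class "PrimerConfig".
#' @export
primerConfig <- function(forward = DEFAULT_FORWARD_PRIMER,
                         reverse = DEFAULT_REVERSE_PRIMER,
                         maxMismatches = 2L,
                         regions = defaultRegionPrimers()) {
  if (!nzchar(forward) || !nzchar(reverse)) stop("primers must be non-empty")
  if (maxMismatches < 0) stop("mismatch allowance must be >= 0")
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 maxMismatches = as.integer(maxMismatches),
                 regions = regions),
            class = "PrimerConfig")
}

#' Default truncation primer pairs for V1-V3, V3-V5 and V4
#' @return Named list of c(forward =, reverse =) pairs.
#' @export
defaultRegionPrimers <- function() list(
  "V1-V3" = c(forward = "AGAGTTTGATCMTGGCTCAG", reverse = "ATTACCGCGGCTGCTGG"),
  "V3-V5" = c(forward = "CCTACGGGAGGCAGCAG", reverse = "CCGTCAATTCMTTTRAGT"),
  "V4"    = c(forward = "GTGCCAGCMGCCGCGGTAA", reverse = "GGACTACHVGGGTWTCTAAT")
)

# IUPAC-aware hit positions of a (possibly degenerate) primer in a set of
# sequences; indels are disallowed so they count against the mismatch budget.
.primerHits <- function(primer, seqs, maxMismatches) {
  hits <- Biostrings::vmatchPattern(
    Biostrings::DNAString(primer), seqs,
    max.mismatch = maxMismatches, with.indels = FALSE, fixed = "subject")
  lapply(as.list(hits), function(r)
    data.frame(start = IRanges::start(r), end = IRanges::end(r)))
}

#' Match, orient and trim amplification primers
#'
#' A read passes iff the forward primer and the reverse complement of the
#' reverse primer are each found exactly once across both strands, on the
#' same strand, with the forward hit upstream of the reverse hit. Passing
#' reads are oriented 5'->3' with respect to 16S transcription (reverse
#' complemented when the reverse primer came first) and both primers are
#' trimmed. Failures carry tags "absent", "multiple" or "misoriented".
#'
#' @param reads A [CcsReadSet-class].
#' @param config A [primerConfig()].
#' @return List with `pass` (trimmed, oriented CcsReadSet), `fail`
#'   (CcsReadSet) and `tags`.
#' @export
matchAndTrimPrimers <- function(reads, config = primerConfig()) {
  n <- length(reads)
  if (n == 0)
    return(list(pass = reads, fail = reads,
                tags = setNames(character(0), character(0))))
  fwd <- config$forward
  rcRev <- revComp(config$reverse)
  seqs <- readSequences(reads)
  rcSeqs <- Biostrings::reverseComplement(seqs)
  mm <- config$maxMismatches
  fF <- .primerHits(fwd, seqs, mm);   fR <- .primerHits(fwd, rcSeqs, mm)
  rF <- .primerHits(rcRev, seqs, mm); rR <- .primerHits(rcRev, rcSeqs, mm)
  status <- character(n); from <- integer(n); to <- integer(n)
  flip <- logical(n)
  for (i in seq_len(n)) {
    nf <- nrow(fF[[i]]) + nrow(fR[[i]])
    nr <- nrow(rF[[i]]) + nrow(rR[[i]])
    if (nf == 0 || nr == 0) { status[i] <- "absent"; next }
    if (nf > 1 || nr > 1) { status[i] <- "multiple"; next }
    if (nrow(fF[[i]]) == 1 && nrow(rF[[i]]) == 1 &&
        fF[[i]]$end < rF[[i]]$start) {
      status[i] <- "pass"; flip[i] <- FALSE
      from[i] <- fF[[i]]$end + 1L; to[i] <- rF[[i]]$start - 1L
    } else if (nrow(fR[[i]]) == 1 && nrow(rR[[i]]) == 1 &&
               fR[[i]]$end < rR[[i]]$start) {
      status[i] <- "pass"; flip[i] <- TRUE
      from[i] <- fR[[i]]$end + 1L; to[i] <- rR[[i]]$start - 1L
    } else status[i] <- "misoriented"
  }
  keep <- which(status == "pass")
  pass <- reads[keep]
  if (length(keep)) {
    newSeq <- character(length(keep)); newQual <- character(length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      s <- if (flip[i]) as.character(rcSeqs[[i]]) else
        as.character(seqs[[i]])
      q <- reads@quality[i]
      if (flip[i] && nchar(q))
        q <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
      newSeq[j] <- substr(s, from[i], to[i])
      if (nchar(q)) newQual[j] <- substr(q, from[i], to[i])
    }
    pass@sequences <- setNames(Biostrings::DNAStringSet(newSeq),
                               readIds(pass))
    pass@quality <- newQual
  }
  tags <- ifelse(status == "pass", NA_character_, status)
  list(pass = pass, fail = reads[which(status != "pass")],
       tags = setNames(tags, readIds(reads)))
}

#' In-silico truncation to a hypervariable region
#'
#' Extracts the segment strictly between a region's primer hits (primers
#' removed) from already primer-trimmed, oriented reads. Reads in which
#' either region primer is not found within the mismatch allowance miss and
#' are excluded. Truncation is therefore not idempotent: re-truncating an
#' already truncated read misses, because its region primers were removed.
#'
#' @param reads A [CcsReadSet-class] (oriented, amplification primers
#'   trimmed).
#' @param region Region name in `config$regions` (e.g. "V3-V5"), or a
#'   c(forward =, reverse =) primer pair.
#' @param config A [primerConfig()].
#' @return List with `pass` (truncated CcsReadSet) and `miss` (read ids).
#' @export
truncateToRegion <- function(reads, region = "V3-V5",
                             config = primerConfig()) {
  pair <- if (is.character(region) && length(region) == 1L)
    config$regions[[region]] else region
  if (is.null(pair)) stop(sprintf("unknown region '%s'", region))
  n <- length(reads)
  if (n == 0) return(list(pass = reads, miss = character(0)))
  seqs <- readSequences(reads)
  mm <- config$maxMismatches
  fH <- .primerHits(toupper(pair[["forward"]]), seqs, mm)
  rH <- .primerHits(revComp(toupper(pair[["reverse"]])), seqs, mm)
  from <- integer(n); to <- integer(n); ok <- logical(n)
  for (i in seq_len(n)) {
    if (nrow(fH[[i]]) < 1 || nrow(rH[[i]]) < 1) next
    f <- fH[[i]][1, ]; r <- rH[[i]][nrow(rH[[i]]), ]
    if (f$end >= r$start) next
    ok[i] <- TRUE; from[i] <- f$end + 1L; to[i] <- r$start - 1L
  }
  keep <- which(ok)
  pass <- reads[keep]
  if (length(keep)) {
    newSeq <- substr(as.character(seqs)[keep], from[keep], to[keep])
    newQual <- ifelse(nchar(reads@quality[keep]) > 0,
                      substr(reads@quality[keep], from[keep], to[keep]), "")
    pass@sequences <- setNames(Biostrings::DNAStringSet(newSeq),
                               readIds(pass))
    pass@quality <- newQual
  }
  list(pass = pass, miss = readIds(reads)[!ok])
}
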