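#' Cumulative expected error of Phred qualities
#'
#' EE = sum over positions of 10^(-Q/10), the expected number of erroneous
#' bases in a read given its Phred-scaled base quality scores.
#'
#' @param quality Integer vector of Phred scores, or a list of such vectors.
#' @return Numeric EE (vector when a list is given).
#' @examples
#' expectedError(rep(20, 10))  # 0.1
#' @export
expectedError <- function(quality) {
  if (is.list(quality)) return(vapply(quality, expectedError, numeric(1)))
  if (!length(quality)) stop("missing qualities: EE undefined")
  sum(10^(-as.numeric(quality) / 10))
}

#' @rdname fl16s-accessors
#' @export
setMethod("expectedErrors", "CcsReadSet", function(x) {
  ee <- rep(NA_real_, length(x))
  has <- nchar(x@quality) > 0
  ee[has] <- vapply(x@quality[has],
                    function(s) sum(10^(-(utf8ToInt(s) - 33) / 10)),
                    numeric(1))
  setNames(ee, readIds(x))
})

#' Per-kilobase expected error
#' @param x A [CcsReadSet-class].
#' @return EE x 1000 / read length, per read.
#' @export
expectedErrorsPerKb <- function(x)
  expectedErrors(x) * 1000 / Biostrings::width(readSequences(x))

.partition <- function(reads, keep, tag) {
  list(pass = reads[which(keep)], fail = reads[which(!keep)],
       tags = setNames(ifelse(keep, NA_character_, tag), readIds(reads)))
}

#' Filter reads by CCS pass count
#'
#' Reads with four or fewer passes are of much lower consensus quality and
#' are removed; reads lacking a pass annotation fail with tag
#' "no_pass_info" (fail-closed).
#'
#' @param reads A [CcsReadSet-class].
#' @param minPasses Minimum pass count retained (default 5).
#' @return List with elements `pass`, `fail` (both CcsReadSet) and `tags`.
#' @export
filterByPasses <- function(reads, minPasses = 5L) {
  p <- passCounts(reads)
  keep <- !is.na(p) & p >= minPasses
  out <- .partition(reads, keep, "low_passes")
  out$tags[is.na(p)] <- "no_pass_info"
  out
}

#' Filter reads by cumulative expected error
#'
#' Retains reads with EE <= maxEE (the comparator is configurable because
#' the boundary is convention; the default is inclusive). Reads without
#' qualities fail with tag "no_quality".
#'
#' @param reads A [CcsReadSet-class].
#' @param maxEE Maximum expected error (default 1.0).
#' @param inclusive Keep reads at exactly maxEE (default TRUE).
#' @return List with `pass`, `fail`, `tags`.
#' @export
filterByEE <- function(reads, maxEE = 1.0, inclusive = TRUE) {
  ee <- expectedErrors(reads)
  keep <- !is.na(ee) & (if (inclusive) ee <= maxEE else ee < maxEE)
  out <- .partition(reads, keep, "high_ee")
  out$tags[is.na(ee)] <- "no_quality"
  out
}

#' Filter reads by length
#'
#' Retains reads with min <= length <= max (inclusive bounds); defaults keep
#' 0.5-2 kb, the plausible size window for a full-length 16S amplicon
#' (~3 kb dimer artifacts and short fragments are removed).
#'
#' @param reads A [CcsReadSet-class].
#' @param min,max Inclusive length bounds (defaults 500, 2000).
#' @return List with `pass`, `fail`, `tags`.
#' @export
filterByLength <- function(reads, min = 500L, max = 2000L) {
  if (min > max) stop("length filter: min > max")
  w <- Biostrings::width(readSequences(reads))
  .partition(reads, w >= min & w <= max, "bad_length")
}

#' Demultiplex reads by terminal asymmetric barcode pairs
#'
#' A read is assigned to a sample iff exactly one sample's
#' (forward, reverse) barcode pair matches its termini within
#' `maxMismatches` per barcode, testing both orientations; ambiguous ties
#' and non-matching reads are left unassigned. The layout tested is
#' forward-barcode + amplicon + revcomp(reverse-barcode). Barcodes are
#' trimmed from assigned reads, which are also oriented forward.
#'
#' @param reads A [CcsReadSet-class].
#' @param barcodes data.frame with columns `sample`, `forward`, `reverse`
#'   (IUPAC allowed on the barcode side).
#' @param maxMismatches Per-barcode mismatch allowance (default 1).
#' @return List with `assigned` (trimmed, labeled CcsReadSet), `unassigned`
#'   (CcsReadSet) and `tags`.
#' @export
demultiplex <- function(reads, barcodes, maxMismatches = 1L) {
  req <- c("sample", "forward", "reverse")
  if (!all(req %in% names(barcodes))) stop("barcodes need sample/forward/reverse")
  key <- paste(toupper(barcodes$forward), toupper(barcodes$reverse))
  if (anyDuplicated(key)) stop("duplicate barcode pairs in config")
  seqs <- as.character(readSequences(reads))
  n <- length(seqs)
  assignedTo <- rep(NA_integer_, n)
  flipped <- rep(FALSE, n)
  ambiguous <- rep(FALSE, n)
  for (i in seq_len(n)) {
    s <- seqs[i]
    hits <- integer(0); orient <- logical(0)
    for (bi in seq_len(nrow(barcodes))) {
      fb <- toupper(barcodes$forward[bi])
      rb <- revComp(toupper(barcodes$reverse[bi]))
      if (nchar(s) < nchar(fb) + nchar(rb)) next
      fwdOk <- .iupacMismatches(fb, substr(s, 1, nchar(fb))) <= maxMismatches &&
        .iupacMismatches(rb, substr(s, nchar(s) - nchar(rb) + 1, nchar(s))) <=
          maxMismatches
      rs <- revComp(s)
      revOk <- .iupacMismatches(fb, substr(rs, 1, nchar(fb))) <= maxMismatches &&
        .iupacMismatches(rb, substr(rs, nchar(rs) - nchar(rb) + 1, nchar(rs))) <=
          maxMismatches
      if (fwdOk || revOk) {
        hits <- c(hits, bi); orient <- c(orient, !fwdOk && revOk)
      }
    }
    if (length(hits) == 1L) { assignedTo[i] <- hits; flipped[i] <- orient }
    else if (length(hits) > 1L) ambiguous[i] <- TRUE
  }
  keep <- which(!is.na(assignedTo))
  assigned <- reads[keep]
  if (length(keep)) {
    newSeq <- character(length(keep)); newQual <- character(length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      s <- seqs[i]; q <- reads@quality[i]
      if (flipped[i]) {
        s <- revComp(s)
        if (nchar(q)) q <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
      }
      bi <- assignedTo[i]
      fl <- nchar(barcodes$forward[bi]); rl <- nchar(barcodes$reverse[bi])
      newSeq[j] <- substr(s, fl + 1L, nchar(s) - rl)
      if (nchar(q)) newQual[j] <- substr(q, fl + 1L, nchar(q) - rl)
    }
    assigned@sequences <- setNames(Biostrings::DNAStringSet(newSeq),
                                   readIds(assigned))
    assigned@quality <- newQual
    assigned@sample <- barcodes$sample[assignedTo[keep]]
  }
  tags <- rep(NA_character_, n)
  tags[is.na(assignedTo) & ambiguous] <- "barcode_ambiguous"
  tags[is.na(assignedTo) & !ambiguous] <- "barcode_unmatched"
  list(assigned = assigned, unassigned = reads[which(is.na(assignedTo))],
       tags = setNames(tags, readIds(reads)))
}

# IUPAC-aware Hamming distance, pattern may be degenerate; N in the subject
# matches nothing
.iupacMismatches <- function(pattern, subject) {
  if (nchar(pattern) != nchar(subject)) return(Inf)
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  sum(!mapply(function(pb, sb) {
    if (!pb %in% names(IUPAC_CODES) || sb == "N") return(FALSE)
    sb %in% IUPAC_CODES[[pb]]
  }, p, s))
}

#' Assemble a per-stage filter report
#'
#' @param stages Named list of filter results (each with `pass` and `fail`).
#' @return data.frame with input/pass/fail counts per stage; input = pass +
#'   fail at every stage.
#' @export
filterReport <- function(stages) {
  data.frame(
    stage = names(stages),
    input = vapply(stages, function(s) length(s$pass) + length(s$fail),
                   numeric(1)),
    pass = vapply(stages, function(s) length(s$pass), numeric(1)),
    fail = vapply(stages, function(s) length(s$fail), numeric(1)),
    row.names = NULL
  )
}
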