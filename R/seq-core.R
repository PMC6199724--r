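#' Construct a CcsReadSet
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] of read
#'   bases (names become read ids; unnamed reads get "read<N>").
#' @param quality Optional list of integer Phred vectors, character vector of
#'   Phred+33 strings, or NULL.
#' @param passes Optional integer CCS pass counts (NA = unannotated).
#' @param sample Optional character sample labels.
#' @return A [CcsReadSet-class].
#' @examples
#' ccsReadSet(c(r1 = "ACGT"), quality = list(c(40, 40, 40, 40)), passes = 12)
#' @export
ccsReadSet <- function(sequences, quality = NULL, passes = NA_integer_,
                       sample = NA_character_) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  n <- length(sequences)
  if (n > 0 && is.null(names(sequences)))
    names(sequences) <- paste0("read", seq_len(n))
  if (is.null(quality)) {
    quality <- rep("", n)
  } else if (is.list(quality)) {
    quality <- vapply(quality, function(q) {
      if (!length(q)) return("")
      if (any(q < 0 | q > 93)) stop("Phred values must lie in [0, 93]")
      intToUtf8(as.integer(q) + 33L)
    }, character(1))
  }
  new("CcsReadSet", sequences = sequences,
      quality = rep_len(as.character(quality), n),
      passes = rep_len(as.integer(passes), n),
      sample = rep_len(as.character(sample), n))
}

#' Read a FASTQ file of CCS reads
#'
#' Reads plain or gzip-compressed 4-line FASTQ (Phred+33). CCS pass counts
#' are parsed from a `<token>=<n>` field in the read header (fields separated
#' by ";" or whitespace); a missing token leaves the pass count unset.
#' Sample labels are likewise parsed from a `sample=<s>` field when present.
#'
#' @param path File path (".gz" accepted) or character vector of FASTQ lines.
#' @param passesToken Header token naming the pass count (default "passes").
#' @return A [CcsReadSet-class].
#' @examples
#' fq <- c("@r1;passes=12", "ACGT", "+", "IIII")
#' readFastq(fq)
#' @export
readFastq <- function(path, passesToken = "passes") {
  lines <- if (length(path) == 1L && file.exists(path)) {
    con <- gzfile(path, open = "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  } else as.character(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) return(ccsReadSet(Biostrings::DNAStringSet()))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ: truncated 4-line block at record %d",
                 length(lines) %/% 4L + 1L))
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- !startsWith(hdr, "@") | !startsWith(plus, "+")
  if (any(bad))
    stop(sprintf("malformed FASTQ: bad 4-line block at record %d",
                 which(bad)[1]))
  mism <- nchar(seqs) != nchar(qual)
  if (any(mism))
    stop(sprintf("quality/sequence length mismatch at record %d",
                 which(mism)[1]))
  hdr <- sub("^@", "", hdr)
  ids <- sub("[;[:space:]].*$", "", hdr)
  passes <- .headerToken(hdr, passesToken)
  samples <- .headerTokenChr(hdr, "sample")
  ccsReadSet(setNames(Biostrings::DNAStringSet(seqs), ids),
             quality = qual, passes = passes, sample = samples)
}

.headerToken <- function(hdr, token) {
  pat <- paste0("(^|[;[:space:]])", token, "=([0-9]+)")
  m <- regmatches(hdr, regexpr(pat, hdr))
  out <- rep(NA_integer_, length(hdr))
  hit <- regexpr(pat, hdr) > 0
  out[hit] <- as.integer(sub(pat, "\\2", regmatches(hdr, regexpr(pat, hdr))))
  out
}

.headerTokenChr <- function(hdr, token) {
  pat <- paste0("(^|[;[:space:]])", token, "=([^;[:space:]]+)")
  out <- rep(NA_character_, length(hdr))
  hit <- regexpr(pat, hdr) > 0
  out[hit] <- sub(pat, "\\2", regmatches(hdr, regexpr(pat, hdr)))
  out
}

#' Write a CcsReadSet as FASTQ
#'
#' Headers carry `;passes=<n>` and `;sample=<s>` tokens when set, so that
#' `readFastq(writeFastq(x))` round-trips losslessly. Reads lacking quality
#' strings are written with a uniform placeholder quality of Phred 40.
#'
#' @param x A [CcsReadSet-class].
#' @param path Output path, or NULL to return the lines invisibly.
#' @return Invisibly, the FASTQ lines.
#' @export
writeFastq <- function(x, path = NULL) {
  hdr <- paste0("@", readIds(x))
  hdr <- ifelse(is.na(x@passes), hdr, paste0(hdr, ";passes=", x@passes))
  hdr <- ifelse(is.na(x@sample), hdr, paste0(hdr, ";sample=", x@sample))
  seqs <- as.character(x@sequences)
  qual <- ifelse(nchar(x@quality) > 0, x@quality,
                 vapply(nchar(seqs), function(w)
                   paste(rep("I", w), collapse = ""), character(1)))
  lines <- as.vector(rbind(hdr, seqs, "+", qual))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings. Multi-line (wrapped) records are accepted;
#' the writer wraps at 70 columns. Duplicate ids are returned as-is
#' (uniqueness is enforced where it matters, e.g. in [buildTaxDb()]).
#'
#' @param path FASTA path (gzip accepted).
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(x) == 0))
    stop("FASTA record with empty sequence")
  names(x) <- sub("[[:space:]].*$", "", names(x))
  x
}

#' @rdname readFasta
#' @param x A named [Biostrings::DNAStringSet] (or character vector).
#' @export
writeFasta <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Reverse complement (IUPAC-aware)
#'
#' @param bases Character vector of sequences over the IUPAC alphabet.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("AAC")  # "GTT"
#' @export
revComp <- function(bases) {
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(bases)))
  unname(out)
}

#' Single-base degenerate primer match
#'
#' TRUE iff `readBase` lies in the IUPAC expansion of `primerBase`. An N in
#' the read matches no primer base (conservative: avoids false primer hits).
#'
#' @param primerBase One IUPAC code (primer side).
#' @param readBase One of A, C, G, T, N (read side).
#' @return Logical.
#' @examples
#' iupacBaseMatch("Y", "C")  # TRUE
#' iupacBaseMatch("A", "N")  # FALSE
#' @export
iupacBaseMatch <- function(primerBase, readBase) {
  primerBase <- toupper(primerBase); readBase <- toupper(readBase)
  if (!primerBase %in% names(IUPAC_CODES))
    stop(sprintf("invalid IUPAC code '%s'", primerBase))
  if (!readBase %in% c("A", "C", "G", "T", "N"))
    stop(sprintf("invalid read base '%s'", readBase))
  if (readBase == "N") return(FALSE)
  readBase %in% IUPAC_CODES[[primerBase]]
}

#' End-free global alignment with identity
#'
#' Optimal global alignment under match +1, mismatch -2, gap open -4, gap
#' extend -1, with cost-free terminal gaps. Identity is computed over the
#' aligned core only: matches / (matches + mismatches + internal gap
#' columns); terminal gaps are excluded, matching the way "3% divergence" is
#' measured for near-full-length amplicons.
#'
#' @param a,b Non-empty sequences (character).
#' @param band Half-width of the alignment band, or NULL for automatic
#'   choice (full dynamic programming for short sequences, a band of
#'   max(50, length difference + 50) otherwise).
#' @return A [GlobalAlignment-class].
#' @examples
#' globalAlignIdentity("ACGT", "ACGA")@identity  # 0.75
#' @export
globalAlignIdentity <- function(a, b, band = NULL) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  if (is.null(band)) {
    band <- if (max(nchar(a), nchar(b)) <= 400) -1L
            else max(50L, abs(nchar(a) - nchar(b)) + 50L)
  }
  r <- .alignGlobalCpp(a, b, band = as.integer(band))
  new("GlobalAlignment",
      aligned_a = r$aligned_a, aligned_b = r$aligned_b,
      matches = r$matches, mismatches = r$mismatches,
      internal_gap_columns = r$internal_gap_columns,
      terminal_gap_a = r$terminal_gap_a, terminal_gap_b = r$terminal_gap_b,
      score = r$score, identity = r$identity)
}

#' Pairwise identity only
#'
#' Convenience wrapper returning just the identity fraction of
#' [globalAlignIdentity()].
#' @inheritParams globalAlignIdentity
#' @return Numeric identity in [0, 1].
#' @export
pairwiseIdentity <- function(a, b, band = NULL)
  globalAlignIdentity(a, b, band = band)@identity

# as.character that never loses names (base as.character drops them)
.asChar <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}

# --- k-mer helpers (shared by host screen, clustering prescreen, classifier)

# all k-mers of one sequence as character vector (may contain duplicates)
.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# canonical form: lexicographic min of k-mer and its reverse complement
.canonicalKmers <- function(seq, k) {
  km <- unique(.kmers(seq, k))
  km <- km[!grepl("[^ACGT]", km)]
  if (!length(km)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

# integer encoding of all ACGT k-mers (k <= 15); NA rows dropped
.kmerCodes <- function(seq, k) {
  v <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L; code[v == 67L] <- 1L
  code[v == 71L] <- 2L; code[v == 84L] <- 3L
  n <- length(code)
  if (n < k) return(integer(0))
  out <- integer(n - k + 1L)
  valid <- rep(TRUE, n - k + 1L)
  for (off in 0:(k - 1L)) {
    x <- code[(1L + off):(n - k + 1L + off)]
    valid <- valid & !is.na(x)
    x[is.na(x)] <- 0L
    out <- out * 4L + x
  }
  unique(out[valid]) + 1L  # 1-based
}
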