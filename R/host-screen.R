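#' Build a canonical k-mer index of a host/background genome
#'
#' @param host A [Biostrings::DNAStringSet], character vector of sequences,
#'   or FASTA path.
#' @param k K-mer size (default 21).
#' @return An environment of class "HostIndex" holding the canonical k-mer
#'   set.
#' @export
hostKmerIndex <- function(host, k = 21L) {
  if (is.character(host) && length(host) == 1L && file.exists(host))
    host <- readFasta(host)
  host <- as.character(host)
  if (!length(host) || !any(nchar(host) >= k))
    stop("empty host reference: no k-mers to index")
  kmers <- unique(unlist(lapply(host, .canonicalKmers, k = k)))
  structure(list(kmers = kmers, k = as.integer(k)), class = "HostIndex")
}

#' Screen reads against a host genome k-mer index
#'
#' Deterministic realization of a host-alignment filter: a read is called
#' host iff at least `screenFraction` of its canonical k-mers occur in the
#' host index. Verbatim host substrings share every k-mer with the index
#' (fraction 1); reads from 16S genes absent from the host share essentially
#' none.
#'
#' @param reads A [CcsReadSet-class].
#' @param host A "HostIndex" from [hostKmerIndex()], or anything accepted by
#'   it.
#' @param screenFraction Minimum shared-k-mer fraction to call host
#'   (default 0.5, reached inclusively).
#' @param k K-mer size when `host` is not already an index.
#' @return List with `host`, `nonHost` (CcsReadSet) and `tags`.
#' @export
hostScreen <- function(reads, host, screenFraction = 0.5, k = 21L) {
  if (!inherits(host, "HostIndex")) host <- hostKmerIndex(host, k = k)
  seqs <- as.character(readSequences(reads))
  frac <- vapply(seqs, function(s) {
    km <- .canonicalKmers(s, host$k)
    if (!length(km)) return(0)
    mean(km %in% host$kmers)
  }, numeric(1), USE.NAMES = FALSE)
  isHost <- frac >= screenFraction
  list(host = reads[which(isHost)], nonHost = reads[which(!isHost)],
       tags = setNames(ifelse(isHost, "host", NA_character_),
                       readIds(reads)),
       sharedFraction = setNames(frac, readIds(reads)))
}
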