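#' CcsReadSet: a set of CCS amplicon reads
#'
#' Container for circular-consensus reads: sequences, optional per-base Phred
#' qualities, optional CCS pass counts, and optional sample labels. Qualities
#' are stored Phred+33 encoded; an empty quality string marks an absent
#' quality. Read ids are the names of the sequence set.
#'
#' @slot sequences A [Biostrings::DNAStringSet] holding the read bases; names
#'   are read ids.
#' @slot quality Character vector of Phred+33 strings ("" when absent).
#' @slot passes Integer vector of CCS pass counts (NA when unannotated).
#' @slot sample Character vector of sample labels (NA when unassigned).
#'
#' @seealso [readFastq()], [ccsReadSet()], [expectedErrors()]
#' @export
setClass("CcsReadSet",
  representation(
    sequences = "DNAStringSet",
    quality = "character",
    passes = "integer",
    sample = "character"
  )
)

setValidity("CcsReadSet", function(object) {
  n <- length(object@sequences)
  if (length(object@quality) != n) return("quality length != number of reads")
  if (length(object@passes) != n) return("passes length != number of reads")
  if (length(object@sample) != n) return("sample length != number of reads")
  if (any(Biostrings::width(object@sequences) == 0))
    return("reads must have non-empty sequences")
  qw <- nchar(object@quality)
  bad <- qw > 0 & qw != Biostrings::width(object@sequences)
  if (any(bad))
    return(sprintf("quality/sequence length mismatch for read %d",
                   which(bad)[1]))
  for (q in object@quality[qw > 0][seq_len(min(5L, sum(qw > 0)))]) {
    ph <- utf8ToInt(q) - 33L
    if (any(ph < 0L | ph > 93L)) return("Phred values out of [0, 93]")
  }
  pa <- object@passes
  if (any(!is.na(pa) & pa < 0L)) return("pass counts must be >= 0")
  TRUE
})

#' GlobalAlignment: an end-free pairwise global alignment
#'
#' Result of [globalAlignIdentity()]. Terminal (end) gaps are cost-free and
#' excluded from the identity denominator:
#' identity = matches / (matches + mismatches + internal gap columns).
#'
#' @slot aligned_a,aligned_b Gapped strings of equal length.
#' @slot matches,mismatches,internal_gap_columns Column counts over the
#'   aligned core.
#' @slot terminal_gap_a,terminal_gap_b Terminal gap characters in each row.
#' @slot score Alignment score.
#' @slot identity Fraction in [0, 1].
#' @export
setClass("GlobalAlignment",
  representation(
    aligned_a = "character", aligned_b = "character",
    matches = "integer", mismatches = "integer",
    internal_gap_columns = "integer",
    terminal_gap_a = "integer", terminal_gap_b = "integer",
    score = "numeric", identity = "numeric"
  )
)

setValidity("GlobalAlignment", function(object) {
  la <- nchar(object@aligned_a)
  if (la != nchar(object@aligned_b)) return("gapped strings differ in length")
  tot <- object@matches + object@mismatches + object@internal_gap_columns +
    object@terminal_gap_a + object@terminal_gap_b
  if (tot != la) return("column counts do not sum to alignment length")
  if (object@identity < 0 || object@identity > 1)
    return("identity outside [0, 1]")
  TRUE
})

#' TaxDb: species-level 16S taxonomy database
#'
#' Reference sequences with a 7-rank Linnaean lineage per entry (utax
#' dialect). Accessions are unique and name both slots.
#'
#' @slot sequences A [Biostrings::DNAStringSet], names = accessions.
#' @slot lineage A data.frame with columns domain..species (NA where the
#'   lineage terminates early), rownames = accessions.
#' @export
setClass("TaxDb",
  representation(sequences = "DNAStringSet", lineage = "data.frame")
)

setValidity("TaxDb", function(object) {
  acc <- names(object@sequences)
  if (is.null(acc) || anyDuplicated(acc)) return("accessions must be unique")
  if (!identical(rownames(object@lineage), acc))
    return("lineage rownames must match sequence accessions")
  if (!identical(colnames(object@lineage), RANKS))
    return("lineage must have the 7 rank columns domain..species")
  # ranks filled contiguously from domain (no gaps, no headless lineages)
  filled <- !is.na(as.matrix(object@lineage))
  for (i in seq_len(nrow(filled))) {
    f <- filled[i, ]
    if (!f[1]) return(sprintf("entry %s lacks a domain", acc[i]))
    if (any(diff(f) > 0))
      return(sprintf("lineage not contiguous from domain for %s", acc[i]))
  }
  TRUE
})

#' OtuSet: result of greedy centroid OTU clustering
#'
#' @slot centroids A [Biostrings::DNAStringSet] of centroid sequences, names
#'   are OTU ids.
#' @slot members List (per OTU) of member unique-sequence indices.
#' @slot sizes Integer dereplicated-read totals per OTU.
#' @slot chim1 A data.frame of sequences discarded as de novo chimeras.
#' @slot chim2 Character vector of OTU ids removed by the reference chimera
#'   filter (kept for accounting; removed from `centroids`).
#' @slot counts Matrix OTU x sample of mapped read counts (filled by
#'   [mapReadsToCentroids()]).
#' @slot unassigned Named integer: per-sample counts of reads mapping to no
#'   centroid.
#' @slot taxonomy A data.frame of per-rank names and confidences (filled by
#'   classification).
#' @export
setClass("OtuSet",
  representation(
    centroids = "DNAStringSet", members = "list", sizes = "integer",
    chim1 = "data.frame", chim2 = "character", counts = "matrix",
    unassigned = "integer", taxonomy = "data.frame"
  )
)

setValidity("OtuSet", function(object) {
  k <- length(object@centroids)
  if (length(object@members) != k || length(object@sizes) != k)
    return("members/sizes must parallel centroids")
  if (length(object@counts) && any(object@counts < 0))
    return("per-sample counts must be >= 0")
  TRUE
})

#' CommunitySpec: simulator ground-truth community definition
#'
#' @slot references A [Biostrings::DNAStringSet] (one or more 16S copies per
#'   species; copy ids "species|copyN" when multi-copy).
#' @slot lineage data.frame of 7-rank lineages, one row per species.
#' @slot weights Numeric abundance weights per species (>= 0, positive sum).
#' @slot copyNumber Numeric 16S copies per genome per species.
#' @slot errorRates Named numeric: substitution, insertion, deletion per-base
#'   rates at the reference pass count (10 passes); realized per-read rate is
#'   scaled by 10 / passes.
#' @slot artifactRates Named numeric: chimera, host, dimer read fractions.
#' @slot hostGenome DNAStringSet used to draw host reads (may be empty).
#' @slot passRange Integer range from which CCS pass counts are drawn.
#' @export
setClass("CommunitySpec",
  representation(
    references = "DNAStringSet", lineage = "data.frame",
    weights = "numeric", copyNumber = "numeric",
    errorRates = "numeric", artifactRates = "numeric",
    hostGenome = "DNAStringSet", passRange = "integer"
  )
)

setValidity("CommunitySpec", function(object) {
  if (any(object@weights < 0) || sum(object@weights) <= 0)
    return("weights must be >= 0 with a positive sum")
  if (any(object@errorRates < 0 | object@errorRates > 1))
    return("error rates must be in [0, 1]")
  if (any(object@artifactRates < 0 | object@artifactRates > 1))
    return("artifact rates must be in [0, 1]")
  if (!all(c("substitution", "insertion", "deletion") %in%
           names(object@errorRates)))
    return("errorRates must name substitution, insertion, deletion")
  if (!all(c("chimera", "host", "dimer") %in% names(object@artifactRates)))
    return("artifactRates must name chimera, host, dimer")
  TRUE
})
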