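#' Look up 16S copy number by walking up the lineage
#'
#' Exact species match returns its value; otherwise ranks are walked upward
#' (genus, family, ...) and at the first rank with members the mean copy
#' number over all member species is returned (rrnDB-style fallback).
#'
#' @param lineage Named character of the query lineage (names in
#'   domain..species).
#' @param table data.frame with the 7 rank columns plus `copies`.
#' @return Numeric mean copy number.
#' @export
copyNumberLookup <- function(lineage, table) {
  if (!nrow(table)) stop("empty copy-number table")
  lineage <- as.list(lineage)
  for (rank in rev(RANKS)) {
    nm <- if (rank %in% names(lineage)) lineage[[rank]] else NA
    if (is.null(nm) || is.na(nm)) next
    hit <- !is.na(table[[rank]]) & table[[rank]] == nm
    if (any(hit)) return(mean(table$copies[hit]))
  }
  stop("no rank of the lineage matches the copy-number table")
}

#' Expected relative 16S abundances from mass, genome size and copy number
#'
#' p_i is proportional to (m_i / g_i) * c_i: DNA mass over genome size gives
#' genome (cell) abundance, times 16S copies per genome gives amplicon
#' template abundance, normalized to sum to 1.
#'
#' @param mass Non-negative DNA mass fractions (any scale; positive sum).
#' @param genomeSize Genome sizes in bp (> 0).
#' @param copies 16S copies per genome (> 0).
#' @return data.frame with columns mass, genome_size, copies, expected.
#' @examples
#' expectedAbundance(c(0.5, 0.5), c(2e6, 4e6), c(2, 1))$expected  # 0.8 0.2
#' @export
expectedAbundance <- function(mass, genomeSize, copies) {
  if (any(genomeSize <= 0)) stop("zero or negative genome size")
  if (any(mass < 0) || sum(mass) <= 0)
    stop("mass fractions must be >= 0 with positive sum")
  if (any(copies <= 0)) stop("copy numbers must be positive")
  p <- (mass / genomeSize) * copies
  data.frame(mass = mass, genome_size = genomeSize, copies = copies,
             expected = p / sum(p))
}

#' Binomial probability of observing zero reads
#'
#' Exact binomial mass at k = 0: (1 - p)^n, the chance that a taxon with
#' expected relative abundance p yields no reads among n.
#'
#' @param p Expected relative abundance in [0, 1].
#' @param n Total read count (>= 0).
#' @return Probability.
#' @examples
#' probZeroReads(24 / 6878, 6878)  # ~3.6e-11
#' @export
probZeroReads <- function(p, n) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(n < 0)) stop("n must be >= 0")
  (1 - p)^n
}

#' Ordinary least squares fit of observed on expected abundances
#'
#' @param observed Observed counts or relative abundances (matched order).
#' @param expected Expected relative abundances.
#' @param relative Convert observed counts to relative abundances first
#'   (default TRUE).
#' @return List with slope, intercept, r_squared and the fitted lm.
#' @export
fitObservedExpected <- function(observed, expected, relative = TRUE) {
  if (length(observed) != length(expected))
    stop("observed and expected must be matched")
  if (length(observed) < 3) stop("need at least 3 matched taxa")
  obs <- if (relative && sum(observed) > 0) observed / sum(observed) else
    observed
  fit <- lm(obs ~ expected)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Per-read error rates against a multi-copy reference
#'
#' Aligns every read to each reference 16S copy, keeps the highest-identity
#' copy, and reports substitutions (mismatches, excluding gap characters)
#' and gap columns separately; aggregate means are stratified into the
#' EE <= 1 and EE > 1 read classes.
#'
#' @param reads A [CcsReadSet-class].
#' @param referenceCopies DNAStringSet or character vector of reference 16S
#'   copies (>= 1).
#' @param eeCut Stratum boundary (default 1).
#' @return List with `perRead` (data.frame id, closest, mismatches, gaps,
#'   ee) and `byStratum` (mean mismatches/gaps for EE <= cut and EE > cut).
#' @export
estimateErrorRates <- function(reads, referenceCopies, eeCut = 1) {
  refs <- .asChar(referenceCopies)
  if (!length(refs)) stop("need at least one reference copy")
  if (is.null(names(refs))) names(refs) <- paste0("copy", seq_along(refs))
  seqs <- as.character(readSequences(reads))
  ee <- expectedErrors(reads)
  rows <- lapply(seq_along(seqs), function(i) {
    als <- lapply(refs, function(rf) globalAlignIdentity(seqs[i], rf))
    ids <- vapply(als, function(a) a@identity, numeric(1))
    best <- which.max(ids)
    data.frame(id = readIds(reads)[i], closest = names(refs)[best],
               mismatches = als[[best]]@mismatches,
               gaps = als[[best]]@internal_gap_columns,
               identity = ids[best], ee = unname(ee[i]))
  })
  perRead <- do.call(rbind, rows)
  strat <- function(sel) if (any(sel, na.rm = TRUE))
    c(mean_mismatches = mean(perRead$mismatches[which(sel)]),
      mean_gaps = mean(perRead$gaps[which(sel)]),
      n = sum(sel, na.rm = TRUE))
  else c(mean_mismatches = NA_real_, mean_gaps = NA_real_, n = 0)
  list(perRead = perRead,
       byStratum = rbind(`EE<=cut` = strat(!is.na(perRead$ee) &
                                             perRead$ee <= eeCut),
                         `EE>cut` = strat(!is.na(perRead$ee) &
                                            perRead$ee > eeCut)))
}

#' Community diversity summaries
#'
#' Richness (OTUs with count > 0), Shannon entropy H = -sum q_i ln q_i, and
#' Shannon's effective number of species e^H.
#'
#' @param counts Numeric vector of per-OTU counts for one sample, or a
#'   matrix (OTU x sample).
#' @return data.frame with sample, richness, shannon, effective_species.
#' @examples
#' diversityStats(c(25, 25, 25, 25))  # H = ln 4, effective 4
#' @export
diversityStats <- function(counts) {
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    res <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j) {
      r <- diversityStats(counts[, j])
      r$sample <- colnames(counts)[j] %||% paste0("sample", j)
      r
    }))
    return(res[, c("sample", "richness", "shannon", "effective_species")])
  }
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("all-zero sample: diversity undefined")
  q <- counts[counts > 0] / sum(counts)
  H <- -sum(q * log(q))
  data.frame(sample = NA_character_, richness = sum(counts > 0),
             shannon = H, effective_species = exp(H))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter an OTU x sample count table
#'
#' Drops samples with fewer than `minSample` total reads, then OTUs with a
#' grand total below `minOtu` (samples first; inclusive thresholds). An
#' empty result is flagged via attribute "empty" rather than raised as an
#' error.
#'
#' @param table OTU x sample count matrix.
#' @param minSample Minimum per-sample total retained (default 500).
#' @param minOtu Minimum per-OTU grand total retained (default 50).
#' @param relative Also return relative abundances.
#' @param logTransform Log-transform relative abundances after adding a
#'   pseudocount of 1 / (sample total).
#' @return Filtered matrix; when `relative` or `logTransform`, a list with
#'   `counts` plus `relative` / `logRelative`.
#' @export
filterCountTable <- function(table, minSample = 500, minOtu = 50,
                             relative = FALSE, logTransform = FALSE) {
  table <- as.matrix(table)
  keepS <- colSums(table) >= minSample
  out <- table[, keepS, drop = FALSE]
  keepO <- rowSums(out) >= minOtu
  out <- out[keepO, , drop = FALSE]
  attr(out, "empty") <- (nrow(out) == 0 || ncol(out) == 0)
  if (!relative && !logTransform) return(out)
  totals <- colSums(out)
  rel <- sweep(out, 2, pmax(totals, 1), "/")
  res <- list(counts = out, relative = rel)
  if (logTransform) {
    pseudo <- rep(1 / pmax(totals, 1), each = nrow(out))
    res$logRelative <- log(rel + matrix(pseudo, nrow(out)))
  }
  res
}

#' Core taxa present in every subject
#'
#' An OTU is core iff it has count > 0 in at least one sample of every
#' subject.
#'
#' @param table OTU x sample count matrix.
#' @param subjects Named character vector mapping sample -> subject (must
#'   cover every column).
#' @return Character vector of core OTU ids.
#' @export
coreTaxa <- function(table, subjects) {
  table <- as.matrix(table)
  unmapped <- setdiff(colnames(table), names(subjects))
  if (length(unmapped))
    stop(sprintf("unmapped sample '%s'", unmapped[1]))
  subj <- subjects[colnames(table)]
  presentBySubject <- vapply(unique(subj), function(s)
    rowSums(table[, subj == s, drop = FALSE] > 0) > 0,
    logical(nrow(table)))
  rownames(table)[rowSums(presentBySubject) == length(unique(subj))]
}
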