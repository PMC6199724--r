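#' Dereplicate reads into unique sequences
#'
#' Exact-string dereplication; the result is sorted by size (number of
#' identical reads) descending, ties broken lexicographically by sequence so
#' runs are bit-reproducible.
#'
#' @param reads A [CcsReadSet-class], [Biostrings::DNAStringSet] or
#'   character vector.
#' @return data.frame with columns `bases`, `size` and a list-column `ids`.
#' @export
dereplicate <- function(reads) {
  if (is(reads, "CcsReadSet")) {
    seqs <- setNames(as.character(readSequences(reads)), readIds(reads))
  } else {
    seqs <- .asChar(reads)
  }
  if (!length(seqs))
    return(data.frame(bases = character(0), size = integer(0),
                      ids = I(list())))
  if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  byseq <- split(names(seqs), seqs)
  bases <- names(byseq)
  size <- lengths(byseq)
  o <- order(-size, bases, method = "radix")
  data.frame(bases = bases[o], size = as.integer(size[o]),
             ids = I(unname(byseq[o])), row.names = NULL)
}

# --- incremental 8-mer presence index used to rank alignment targets -------

.kmerIndexNew <- function(word = 8L, capacity = 64L) {
  e <- new.env(parent = emptyenv())
  e$word <- as.integer(word)
  e$n <- 0L
  e$P <- matrix(0, nrow = 4L^word, ncol = capacity)
  e
}

.kmerIndexAdd <- function(idx, seq) {
  if (idx$n == ncol(idx$P))
    idx$P <- cbind(idx$P, matrix(0, nrow = nrow(idx$P), ncol = ncol(idx$P)))
  idx$n <- idx$n + 1L
  idx$P[.kmerCodes(seq, idx$word), idx$n] <- 1
  invisible(idx)
}

# indices of the topN entries by shared k-mer count (ties: earliest entry)
.kmerIndexRank <- function(idx, seq, topN) {
  if (idx$n == 0L) return(integer(0))
  q <- .kmerCodes(seq, idx$word)
  shared <- colSums(idx$P[q, seq_len(idx$n), drop = FALSE])
  head(order(-shared, seq_len(idx$n)), topN)
}

#' De novo two-parent chimera check (CHIM1 machinery)
#'
#' Tests whether a candidate sequence is better explained as a crossover of
#' two parents than by any single parent. The candidate is aligned to each
#' of the `topK` most similar parents; per-column match vectors in candidate
#' coordinates are combined over every ordered parent pair at the breakpoint
#' maximizing left-parent plus right-parent matches. The verdict is chimeric
#' iff the two-parent model identity reaches `modelMinIdentity` and exceeds
#' the best single-parent identity by at least `minGain`.
#'
#' @param candidate Candidate sequence (character).
#' @param parents Character vector (or DNAStringSet) of potential parents.
#' @param topK Number of most-similar parents considered (default 8).
#' @param modelMinIdentity Minimum two-parent model identity (default 0.995).
#' @param minGain Minimum gain of the model over the best single parent
#'   (default 0.01).
#' @param candidateId Optional id recorded in the call.
#' @return A list "ChimeraCall": candidate id, parent ids, breakpoint
#'   column, model_identity, best_single_identity, verdict.
#' @export
chimeraDenovoCheck <- function(candidate, parents, topK = 8L,
                               modelMinIdentity = 0.995, minGain = 0.01,
                               candidateId = NA_character_) {
  candidate <- toupper(as.character(candidate))
  parents <- .asChar(parents)
  if (is.null(names(parents)))
    names(parents) <- paste0("parent", seq_along(parents))
  call0 <- list(candidate = candidateId, parent_a = NA_character_,
                parent_b = NA_character_, breakpoint = NA_integer_,
                model_identity = NA_real_, best_single_identity = NA_real_,
                verdict = FALSE)
  if (length(parents) < 2L) return(call0)
  if (length(parents) > topK) {
    idx <- .kmerIndexNew()
    for (p in parents) .kmerIndexAdd(idx, p)
    parents <- parents[.kmerIndexRank(idx, candidate, topK)]
  }
  L <- nchar(candidate)
  mv <- lapply(parents, function(p) .matchVector(candidate, p))
  singles <- vapply(mv, sum, numeric(1)) / L
  cums <- lapply(mv, function(m) c(0, cumsum(m)))
  tots <- vapply(mv, sum, numeric(1))
  bestModel <- -1; bestA <- bestB <- NA_character_; bestBp <- NA_integer_
  for (ai in seq_along(parents)) for (bi in seq_along(parents)) {
    if (ai == bi) next
    tot <- cums[[ai]] + tots[bi] - cums[[bi]]
    i <- which.max(tot)
    if (tot[i] > bestModel) {
      bestModel <- tot[i]
      bestA <- names(parents)[ai]; bestB <- names(parents)[bi]
      bestBp <- i - 1L
    }
  }
  modelId <- bestModel / L
  bestSingle <- max(singles)
  verdict <- modelId >= modelMinIdentity &&
    (modelId - bestSingle) >= minGain
  list(candidate = candidateId, parent_a = bestA, parent_b = bestB,
       breakpoint = bestBp, model_identity = modelId,
       best_single_identity = bestSingle, verdict = verdict)
}

# per-candidate-position match vector against one parent
.matchVector <- function(candidate, parent) {
  al <- globalAlignIdentity(candidate, parent)
  a <- strsplit(al@aligned_a, "")[[1]]
  b <- strsplit(al@aligned_b, "")[[1]]
  inA <- a != "-"
  m <- (a == b)[inA]
  m
}

#' Greedy abundance-sorted centroid OTU clustering
#'
#' Unique sequences are processed in decreasing abundance. Each sequence
#' joins the highest-identity existing centroid when that identity reaches
#' `idThreshold` (ties go to the earliest-created centroid); otherwise, if a
#' de novo chimera check against existing centroids calls it chimeric it is
#' discarded (CHIM1), else it founds a new OTU. For speed, identities are
#' computed against the `maxTargets` centroids sharing the most 8-mers with
#' the sequence; with at most `maxTargets` centroids this is exactly
#' "compare to every centroid".
#'
#' @param uniques data.frame from [dereplicate()] (sorted by size desc).
#' @param idThreshold Identity threshold for membership (default 0.97, i.e.
#'   3% divergence).
#' @param chimeraCheck Apply the CHIM1 de novo chimera filter (default
#'   TRUE).
#' @param topK,modelMinIdentity,minGain Chimera-check parameters, see
#'   [chimeraDenovoCheck()].
#' @param maxTargets Number of k-mer-ranked centroids aligned per query
#'   (default 16).
#' @return An [OtuSet-class] (counts slot empty until
#'   [mapReadsToCentroids()]).
#' @export
greedyCluster <- function(uniques, idThreshold = 0.97, chimeraCheck = TRUE,
                          topK = 8L, modelMinIdentity = 0.995,
                          minGain = 0.01, maxTargets = 16L) {
  cent <- character(0)
  members <- list(); sizes <- integer(0)
  chim1 <- list()
  idx <- .kmerIndexNew()
  for (r in seq_len(nrow(uniques))) {
    u <- uniques$bases[r]; usize <- uniques$size[r]
    if (length(cent)) {
      cand <- .kmerIndexRank(idx, u, maxTargets)
      ids <- vapply(cand, function(ci) pairwiseIdentity(u, cent[ci]),
                    numeric(1))
      best <- max(ids)
      bestCi <- min(cand[ids == best])
    } else best <- -Inf
    if (is.finite(best) && best >= idThreshold) {
      members[[bestCi]] <- c(members[[bestCi]], r)
      sizes[bestCi] <- sizes[bestCi] + usize
      next
    }
    if (chimeraCheck && length(cent) >= 2L) {
      cc <- chimeraDenovoCheck(u, setNames(cent, names(cent)), topK = topK,
                               modelMinIdentity = modelMinIdentity,
                               minGain = minGain,
                               candidateId = sprintf("unique%d", r))
      if (isTRUE(cc$verdict)) {
        chim1[[length(chim1) + 1L]] <-
          data.frame(bases = u, size = usize, parent_a = cc$parent_a,
                     parent_b = cc$parent_b, breakpoint = cc$breakpoint,
                     model_identity = cc$model_identity,
                     best_single_identity = cc$best_single_identity)
        next
      }
    }
    cent <- c(cent, u)
    names(cent)[length(cent)] <- sprintf("OTU_%d", length(cent))
    members[[length(cent)]] <- r
    sizes[length(cent)] <- usize
    .kmerIndexAdd(idx, u)
  }
  chim1 <- if (length(chim1)) do.call(rbind, chim1) else
    data.frame(bases = character(0), size = integer(0),
               parent_a = character(0), parent_b = character(0),
               breakpoint = integer(0), model_identity = numeric(0),
               best_single_identity = numeric(0))
  new("OtuSet",
      centroids = setNames(Biostrings::DNAStringSet(unname(cent)),
                           names(cent)),
      members = members, sizes = sizes, chim1 = chim1,
      chim2 = character(0),
      counts = matrix(numeric(0), 0, 0), unassigned = integer(0),
      taxonomy = data.frame())
}

#' Reference-based chimera check of centroids (CHIM2)
#'
#' Applies the same two-parent crossover machinery as
#' [chimeraDenovoCheck()], with parents drawn from a curated reference set
#' (RDP-Gold-style plain FASTA). Flagged centroids are removed from the
#' OtuSet before classification; their ids are retained in the `chim2` slot
#' for accounting.
#'
#' @param otus An [OtuSet-class].
#' @param reference A [Biostrings::DNAStringSet], character vector, or FASTA
#'   path of reference sequences.
#' @param ... Passed to [chimeraDenovoCheck()].
#' @return The OtuSet with flagged centroids removed, plus an attribute
#'   "chimeraCalls" holding the per-centroid calls.
#' @export
chimeraRefCheck <- function(otus, reference, ...) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- readFasta(reference)
  reference <- .asChar(reference)
  if (!length(reference)) stop("unreadable or empty chimera reference")
  if (is.null(names(reference)))
    names(reference) <- paste0("ref", seq_along(reference))
  cent <- as.character(centroids(otus))
  calls <- lapply(seq_along(cent), function(i)
    chimeraDenovoCheck(cent[i], reference, candidateId = names(cent)[i],
                       ...))
  flagged <- vapply(calls, function(cc) isTRUE(cc$verdict), logical(1))
  out <- otus
  out@chim2 <- c(otus@chim2, names(cent)[flagged])
  out@centroids <- otus@centroids[!flagged]
  out@members <- otus@members[!flagged]
  out@sizes <- otus@sizes[!flagged]
  attr(out, "chimeraCalls") <- calls
  out
}

#' Map reads to final centroids to quantify OTU abundances
#'
#' Each read is assigned to its best-identity centroid iff that identity
#' reaches `idThreshold` (ties to the earliest centroid); other reads are
#' counted as unassigned. The read set here is deliberately the full
#' filtered set, not the EE-thresholded clustering input: abundances are
#' counted with no expected-error cutoff.
#'
#' @param reads A [CcsReadSet-class] with sample labels (NA labels are
#'   pooled as "unlabeled").
#' @param otus An [OtuSet-class] (post-CHIM2).
#' @param idThreshold Identity needed for a hit (default 0.97).
#' @param maxTargets K-mer prescreen width (default 16).
#' @return The OtuSet with `counts` (OTU x sample) and `unassigned` filled;
#'   attribute "assignments" maps read ids to OTU ids (NA = unassigned).
#' @export
mapReadsToCentroids <- function(reads, otus, idThreshold = 0.97,
                                maxTargets = 16L) {
  cent <- as.character(centroids(otus))
  samples <- sampleLabels(reads)
  samples[is.na(samples)] <- "unlabeled"
  sampleLevels <- unique(samples)
  counts <- matrix(0L, nrow = length(cent), ncol = length(sampleLevels),
                   dimnames = list(names(cent), sampleLevels))
  unassigned <- setNames(integer(length(sampleLevels)), sampleLevels)
  assign <- setNames(rep(NA_character_, length(reads)), readIds(reads))
  if (length(cent)) {
    idx <- .kmerIndexNew()
    for (p in cent) .kmerIndexAdd(idx, p)
    seqs <- as.character(readSequences(reads))
    for (i in seq_along(seqs)) {
      cand <- .kmerIndexRank(idx, seqs[i], maxTargets)
      ids <- vapply(cand, function(ci) pairwiseIdentity(seqs[i], cent[ci]),
                    numeric(1))
      best <- if (length(ids)) max(ids) else -Inf
      if (is.finite(best) && best >= idThreshold) {
        ci <- min(cand[ids == best])
        counts[ci, samples[i]] <- counts[ci, samples[i]] + 1L
        assign[i] <- names(cent)[ci]
      } else unassigned[samples[i]] <- unassigned[samples[i]] + 1L
    }
  } else if (length(reads)) {
    tab <- table(samples)
    unassigned[names(tab)] <- as.integer(tab)
  }
  out <- otus
  out@counts <- counts
  out@unassigned <- unassigned
  attr(out, "assignments") <- assign
  out
}

#' Write centroids as FASTA with otu id and size headers
#' @param otus An [OtuSet-class].
#' @param path Output path.
#' @export
writeCentroidsFasta <- function(otus, path) {
  x <- centroids(otus)
  names(x) <- sprintf("%s;size=%d", names(x), otus@sizes)
  writeFasta(x, path)
}

#' Write the OTU x sample count table as TSV
#' @param otus An [OtuSet-class] with counts filled.
#' @param path Output path.
#' @export
writeOtuTable <- function(otus, path) {
  df <- data.frame(otu = rownames(otuCounts(otus)), otuCounts(otus),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
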