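# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / enumeration, not by calling the code paths they
# check.

# --- exhaustive alignment enumeration (short sequences) ---------------------

# all global alignment column paths of a vs b as op strings (M/X/Y)
.enumOps <- function(n, m) {
  out <- list()
  rec <- function(i, j, ops) {
    if (i == n && j == m) {
      out[[length(out) + 1L]] <<- ops
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, c(ops, "M"))
    if (i < n) rec(i + 1L, j, c(ops, "X"))
    if (j < m) rec(i, j + 1L, c(ops, "Y"))
  }
  rec(0L, 0L, character(0))
  out
}

# score one alignment with affine interior gaps and free terminal gaps.
# Free terminal gaps mean an unaligned prefix of ONE sequence and an
# unaligned suffix of ONE sequence (the overlap convention): the leading
# run of gap columns must all gap the same row, ditto the trailing run.
# Returns c(score, identity); identity is NA when the core is empty (the
# null alignment with every residue in a free overhang, score 0).
.scoreAlignment <- function(a, b, ops, match = 1, mismatch = -2,
                            open = -4, ext = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  i <- 0L; j <- 0L
  n <- length(ops)
  colA <- character(n); colB <- character(n)
  for (k in seq_len(n)) {
    if (ops[k] == "M") { i <- i + 1L; j <- j + 1L
      colA[k] <- av[i]; colB[k] <- bv[j] }
    else if (ops[k] == "X") { i <- i + 1L; colA[k] <- av[i]; colB[k] <- "-" }
    else { j <- j + 1L; colA[k] <- "-"; colB[k] <- bv[j] }
  }
  isGap <- ops != "M"
  core <- which(!isGap)
  if (!length(core)) {
    # a pure-overhang alignment is valid iff it is one leading run from
    # one sequence followed by one trailing run from the other
    r <- rle(ops)
    if (length(r$values) <= 2) return(c(score = 0, identity = NA))
    return(NULL)
  }
  lead <- seq_len(core[1] - 1L)
  trail <- if (core[length(core)] < n) (core[length(core)] + 1L):n else
    integer(0)
  # free overhang at an end must come from a single sequence
  if (length(lead) && length(unique(ops[lead])) > 1) return(NULL)
  if (length(trail) && length(unique(ops[trail])) > 1) return(NULL)
  inner <- seq(core[1], core[length(core)])
  matches <- sum(colA[inner] == colB[inner] & !isGap[inner])
  mismatches <- sum(colA[inner] != colB[inner] & !isGap[inner])
  gapCols <- sum(isGap[inner])
  score <- matches * match + mismatches * mismatch
  r <- rle(ops[inner])
  for (q in seq_along(r$lengths))
    if (r$values[q] != "M")
      score <- score + open + (r$lengths[q] - 1L) * ext
  c(score = score, identity = matches / (matches + mismatches + gapCols))
}

# best score over all alignments plus the identities of all co-optimal ones
oracleAlign <- function(a, b, ...) {
  ops <- .enumOps(nchar(a), nchar(b))
  res <- lapply(ops, function(o) .scoreAlignment(a, b, o, ...))
  res <- res[!vapply(res, is.null, logical(1))]
  scores <- vapply(res, `[[`, numeric(1), "score")
  best <- max(scores)
  ids <- unique(vapply(res[scores == best], `[[`, numeric(1), "identity"))
  ids[is.na(ids)] <- 0  # empty-core optimum: identity reported as 0
  list(score = best, identities = unique(ids))
}

# --- straight-line greedy clustering (the Methods sentence, literally) ------

oracleGreedy <- function(seqs, threshold = 0.97) {
  centroids <- character(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    if (length(centroids)) {
      ids <- vapply(centroids, function(ce) pairwiseIdentity(seqs[i], ce),
                    numeric(1))
      if (max(ids) >= threshold) {
        assign[i] <- min(which(ids == max(ids)))
        next
      }
    }
    centroids <- c(centroids, seqs[i])
    assign[i] <- length(centroids)
  }
  list(centroids = centroids, assign = assign)
}

# --- brute-force average-linkage agglomeration ------------------------------

oracleAvgLink <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        better <- avg < bestd - 1e-12 ||
          (abs(avg - bestd) <= 1e-12 &&
             min(clusters[[i]]) < min(clusters[[best[1]]]))
        if (better) { bestd <- avg; best <- c(i, j) }
      }
    }
    if (bestd > cutoff) break
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
  }
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  membership
}

# compare two flat partitions ignoring labels
samePartition <- function(p1, p2) {
  canon <- function(p) {
    grp <- split(seq_along(p), p)
    paste(sort(vapply(grp, function(g) paste(g, collapse = ","),
                      character(1))), collapse = ";")
  }
  identical(canon(p1), canon(p2))
}

# --- small sequence utilities for fixtures ----------------------------------

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

mutateSeq <- function(seq, nSubs) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), nSubs)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# cached small reference set shared by slow tests (built once per run)
.fixtureEnv <- new.env()
smallRefSet <- function() {
  if (is.null(.fixtureEnv$rs))
    .fixtureEnv$rs <- makeReferenceSet(6L, 900L, minDivergence = 0.05,
                                       seed = 301L)
  .fixtureEnv$rs
}
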