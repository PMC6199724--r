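#' Centroid-anchored alignment matrix
#'
#' Aligns every member read to the OTU centroid and projects it into
#' centroid coordinates: member bases occupying centroid columns are kept,
#' insertions relative to the centroid are dropped (counted in attribute
#' "droppedInsertions"), deletions become "-". The result is a rectangular
#' character matrix whose width is the centroid length, a deterministic
#' linear-cost stand-in for a full multiple alignment that is adequate for
#' members within 3% of the centroid. Externally aligned FASTA can be
#' supplied directly to [medDecompose()] instead.
#'
#' @param members A [CcsReadSet-class], DNAStringSet or named character
#'   vector of member reads.
#' @param centroid Centroid sequence (character).
#' @param maxDivergence Members further than this from the centroid are
#'   rejected with tag "too_divergent" (default 0.03).
#' @return Character matrix (rows = member ids, columns = centroid
#'   positions), attributes "droppedInsertions" (named counts) and
#'   "rejected" (ids).
#' @export
centroidAnchoredAlignment <- function(members, centroid,
                                      maxDivergence = 0.03) {
  if (is(members, "CcsReadSet")) {
    ids <- readIds(members); members <- as.character(readSequences(members))
  } else {
    members <- .asChar(members)
    ids <- if (!is.null(names(members))) names(members) else
      paste0("read", seq_along(members))
  }
  centroid <- toupper(as.character(centroid))
  L <- nchar(centroid)
  rows <- list(); dropped <- integer(0); rejected <- character(0)
  for (i in seq_along(members)) {
    al <- globalAlignIdentity(members[i], centroid)
    if (1 - al@identity > maxDivergence) {
      rejected <- c(rejected, ids[i]); next
    }
    a <- strsplit(al@aligned_a, "")[[1]]  # member
    b <- strsplit(al@aligned_b, "")[[1]]  # centroid
    inCent <- b != "-"
    row <- a[inCent]
    ins <- sum(!inCent & a != "-")
    rows[[ids[i]]] <- row
    dropped[ids[i]] <- ins
  }
  m <- if (length(rows))
    matrix(unlist(rows), nrow = length(rows), ncol = L, byrow = TRUE,
           dimnames = list(names(rows), NULL))
  else matrix(character(0), 0, L)
  attr(m, "droppedInsertions") <- dropped
  attr(m, "rejected") <- rejected
  m
}

#' Per-column Shannon entropy of an alignment matrix
#'
#' H(col) = -sum_r f_r ln f_r in nats, over residues {A, C, G, T, -} with
#' frequencies f_r within the column.
#'
#' @param matrix Character matrix from [centroidAnchoredAlignment()] (or an
#'   external MSA in the same shape).
#' @return Numeric entropy per column.
#' @export
positionalEntropy <- function(matrix) {
  if (!nrow(matrix)) stop("empty matrix")
  apply(matrix, 2, function(col) {
    f <- table(col) / length(col)
    -sum(f * log(f))
  })
}

#' Minimum entropy decomposition into ASV nodes
#'
#' Recursively partitions the aligned reads: while a node's maximum column
#' entropy exceeds `entropyThreshold`, its members are split by their joint
#' residues at the top `maxComponents` highest-entropy columns. After the
#' recursion, nodes smaller than `minSubstantive` are dissolved and their
#' members reassigned to the surviving node with the most similar
#' representative (fewest row differences). Every input read ends in exactly
#' one final node.
#'
#' @param matrix Character matrix (rows = reads).
#' @param entropyThreshold Maximum residual column entropy in nats (default
#'   0.2).
#' @param maxComponents Number of high-entropy discriminant columns per
#'   split (default 4).
#' @param minSubstantive Minimum final node size; default
#'   max(2, 0.1% of input reads).
#' @return List of nodes: each a list with `node_id`, `members` (row ids),
#'   `path` (data.frame column/residue describing the decomposition), and
#'   `representative` (most abundant exact member sequence, ties
#'   lexicographic).
#' @export
medDecompose <- function(matrix, entropyThreshold = 0.2, maxComponents = 4L,
                         minSubstantive = NULL) {
  n <- nrow(matrix)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("read", seq_len(n))
  if (is.null(minSubstantive))
    minSubstantive <- max(2L, ceiling(0.001 * n))
  if (n == 0) return(list())

  recurse <- function(rows, path) {
    sub <- matrix[rows, , drop = FALSE]
    if (length(rows) < 2L) return(list(list(members = rows, path = path)))
    H <- positionalEntropy(sub)
    if (max(H) <= entropyThreshold)
      return(list(list(members = rows, path = path)))
    cols <- order(H, decreasing = TRUE)
    cols <- cols[H[cols] > entropyThreshold]
    cols <- sort(head(cols, maxComponents))
    keyOf <- apply(sub[, cols, drop = FALSE], 1, paste, collapse = "")
    groups <- split(rows, keyOf)
    if (length(groups) == 1L)  # degenerate: no split possible
      return(list(list(members = rows, path = path)))
    out <- list()
    for (key in sort(names(groups))) {
      res <- strsplit(key, "")[[1]]
      step <- data.frame(column = cols, residue = res)
      out <- c(out, recurse(groups[[key]], rbind(path, step)))
    }
    out
  }

  nodes <- recurse(rownames(matrix),
                   data.frame(column = integer(0), residue = character(0)))
  sizes <- lengths(lapply(nodes, `[[`, "members"))
  keep <- sizes >= minSubstantive
  if (!any(keep)) keep[which.max(sizes)] <- TRUE  # always retain a survivor
  survivors <- nodes[keep]
  reps <- vapply(survivors, function(nd)
    .nodeRepresentative(matrix[nd$members, , drop = FALSE]), character(1))
  # dissolve small nodes: members rejoin the most similar survivor
  for (nd in nodes[!keep]) {
    for (r in nd$members) {
      row <- paste(matrix[r, ], collapse = "")
      diffs <- vapply(reps, function(rep)
        sum(strsplit(rep, "")[[1]] != matrix[r, ]), numeric(1))
      tgt <- which.min(diffs)
      survivors[[tgt]]$members <- c(survivors[[tgt]]$members, r)
    }
  }
  lapply(seq_along(survivors), function(i) {
    nd <- survivors[[i]]
    list(node_id = sprintf("node_%d", i), members = nd$members,
         path = nd$path,
         representative = .nodeRepresentative(
           matrix[nd$members, , drop = FALSE]))
  })
}

# most abundant exact member sequence; ties broken lexicographically
.nodeRepresentative <- function(sub) {
  seqs <- apply(sub, 1, paste, collapse = "")
  tab <- table(seqs)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1]
}

#' Per-node representative sequences as FASTA
#'
#' Headers carry the node id and size ("node_1;size=60"); gap characters
#' from the alignment frame are removed so the output is plain sequence,
#' suitable as input to external tree building.
#'
#' @param nodes List from [medDecompose()].
#' @param path Optional FASTA output path.
#' @return A named [Biostrings::DNAStringSet] (invisibly written to `path`
#'   when given).
#' @export
nodeRepresentatives <- function(nodes, path = NULL) {
  if (!length(nodes)) return(Biostrings::DNAStringSet())
  seqs <- vapply(nodes, function(nd) gsub("-", "", nd$representative),
                 character(1))
  names(seqs) <- vapply(nodes, function(nd)
    sprintf("%s;size=%d", nd$node_id, length(nd$members)), character(1))
  x <- Biostrings::DNAStringSet(seqs)
  if (!is.null(path)) writeFasta(x, path)
  x
}
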