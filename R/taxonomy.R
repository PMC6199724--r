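#' Build a species-level taxonomy database
#'
#' Joins reference sequences with a 7-rank lineage table; sequences whose
#' accession cannot be resolved to a lineage are dropped (the count is
#' recorded in attribute "dropped").
#'
#' @param sequences A named [Biostrings::DNAStringSet], character vector, or
#'   FASTA path; names are accessions (must be unique).
#' @param lineage data.frame with column `accession` plus the rank columns
#'   domain, phylum, class, order, family, genus, species (NA allowed from
#'   the tail; species names in "Genus_species" token form).
#' @return A [TaxDb-class] with attribute "dropped".
#' @export
buildTaxDb <- function(sequences, lineage) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- readFasta(sequences)
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences))) stop("database sequences must be named")
  if (anyDuplicated(names(sequences)))
    stop(sprintf("duplicate accession '%s'",
                 names(sequences)[duplicated(names(sequences))][1]))
  if (!"accession" %in% names(lineage))
    stop("lineage table needs an 'accession' column")
  missing <- setdiff(RANKS, names(lineage))
  if (length(missing))
    stop(sprintf("lineage table lacks rank column(s): %s",
                 paste(missing, collapse = ", ")))
  bad <- !nzchar(trimws(as.character(lineage$accession)))
  if (any(bad))
    stop(sprintf("malformed lineage row %d: empty accession", which(bad)[1]))
  keep <- names(sequences) %in% lineage$accession
  dropped <- sum(!keep)
  sequences <- sequences[keep]
  li <- lineage[match(names(sequences), lineage$accession), RANKS,
                drop = FALSE]
  li[] <- lapply(li, function(col) {
    col <- as.character(col)
    col[!is.na(col) & !nzchar(trimws(col))] <- NA
    col
  })
  rownames(li) <- names(sequences)
  db <- new("TaxDb", sequences = sequences, lineage = li)
  attr(db, "dropped") <- dropped
  db
}

RANK_LETTERS <- c(domain = "d", phylum = "p", class = "c", order = "o",
                  family = "f", genus = "g", species = "s")

#' Write / read a taxonomy database as utax-dialect FASTA
#'
#' Headers carry the lineage as `;tax=d:...,p:...,...,s:...` with ranks
#' filled from domain down to the last annotated rank.
#'
#' @param db A [TaxDb-class].
#' @param path FASTA path.
#' @export
writeTaxDbFasta <- function(db, path) {
  li <- dbLineage(db)
  tax <- vapply(seq_len(nrow(li)), function(i) {
    f <- !is.na(unlist(li[i, ]))
    paste(paste0(RANK_LETTERS[RANKS[f]], ":", unlist(li[i, f])),
          collapse = ",")
  }, character(1))
  x <- dbSequences(db)
  names(x) <- sprintf("%s;tax=%s;", names(x), tax)
  writeFasta(x, path)
}

#' @rdname writeTaxDbFasta
#' @return `readTaxDbFasta`: the parsed [TaxDb-class].
#' @export
readTaxDbFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  acc <- sub(";.*$", "", hdr)
  taxpart <- sub("^.*;tax=", "", hdr)
  taxpart <- sub(";.*$", "", taxpart)
  li <- as.data.frame(matrix(NA_character_, nrow = length(x),
                             ncol = length(RANKS),
                             dimnames = list(acc, RANKS)))
  for (i in seq_along(taxpart)) {
    fields <- strsplit(taxpart[i], ",")[[1]]
    for (f in fields) {
      letter <- sub(":.*$", "", f)
      rank <- RANKS[match(letter, RANK_LETTERS)]
      if (!is.na(rank)) li[i, rank] <- sub("^[a-z]:", "", f)
    }
  }
  names(x) <- acc
  new("TaxDb", sequences = x, lineage = li)
}

#' Train the k-mer bootstrap classifier
#'
#' Builds a deterministic presence index mapping every `wordSize`-mer to the
#' database entries containing it (an RDP-style word index exposed through
#' the utax-like per-rank-confidence interface).
#'
#' @param db A [TaxDb-class].
#' @param wordSize K-mer word size, in [4, 16] (default 8).
#' @return A list of class "KmerClassifier".
#' @export
trainClassifier <- function(db, wordSize = 8L) {
  if (wordSize < 4L || wordSize > 16L)
    stop("wordSize must be between 4 and 16")
  if (!length(db)) stop("empty database")
  seqs <- as.character(dbSequences(db))
  P <- matrix(0, nrow = 4L^wordSize, ncol = length(seqs))
  for (i in seq_along(seqs)) P[.kmerCodes(seqs[i], wordSize), i] <- 1
  structure(list(P = P, accession = names(seqs), lineage = dbLineage(db),
                 word = as.integer(wordSize)),
            class = "KmerClassifier")
}

#' Classify a query with per-rank bootstrap confidence
#'
#' Extracts the query's distinct k-mer set (W k-mers) and runs `bootstraps`
#' rounds, each sampling ceiling(W/8) k-mers with replacement and scoring
#' every reference by shared sampled k-mers. The round's winner is the
#' top-scoring reference (ties to the lowest accession); a round abstains
#' ("unclassified") when the winner shares fewer than `minHitFrac` of the
#' sampled k-mers, which keeps non-16S (e.g. host) queries at near-zero
#' confidence even at the domain rank. The assigned name at each rank is the
#' most frequent winner's name at that rank and its confidence is that
#' frequency over all bootstraps.
#'
#' @param query Sequence (character), length >= word size.
#' @param classifier From [trainClassifier()].
#' @param bootstraps Bootstrap rounds (default 100).
#' @param minHitFrac Minimum shared fraction of sampled k-mers for a vote to
#'   count (default 1/8).
#' @param seed Optional integer seed for reproducible bootstraps (the global
#'   RNG is used when NULL).
#' @return data.frame with columns rank, name, confidence (7 rows).
#' @export
classifyWithConfidence <- function(query, classifier, bootstraps = 100L,
                                   minHitFrac = 1 / 8, seed = NULL) {
  query <- toupper(as.character(query))
  if (nchar(query) < classifier$word)
    stop("query shorter than classifier word size")
  if (!is.null(seed)) set.seed(seed)
  q <- .kmerCodes(query, classifier$word)
  W <- length(q)
  draws <- max(1L, as.integer(ceiling(W / 8)))
  nref <- length(classifier$accession)
  accOrder <- order(classifier$accession)
  winners <- integer(bootstraps)  # 0 = unclassified
  Pq <- classifier$P[q, , drop = FALSE]
  for (b in seq_len(bootstraps)) {
    s <- sample.int(W, draws, replace = TRUE)
    score <- colSums(Pq[s, , drop = FALSE])
    mx <- max(score)
    if (mx < minHitFrac * draws) next
    ties <- which(score == mx)
    winners[b] <- ties[which.min(match(ties, accOrder))]
  }
  out <- data.frame(rank = RANKS, name = NA_character_, confidence = 0)
  voted <- winners[winners > 0L]
  if (length(voted)) {
    for (ri in seq_along(RANKS)) {
      nm <- classifier$lineage[voted, RANKS[ri]]
      nm <- nm[!is.na(nm)]
      if (!length(nm)) next
      tab <- sort(table(nm), decreasing = TRUE)
      out$name[ri] <- names(tab)[1]
      out$confidence[ri] <- as.numeric(tab[1]) / bootstraps
    }
  }
  out
}

#' Classify many reads / centroids
#'
#' @param queries Named character vector, DNAStringSet or
#'   [CcsReadSet-class].
#' @inheritParams classifyWithConfidence
#' @return data.frame: one row per query, columns `id`, `<rank>` and
#'   `<rank>_conf` for the 7 ranks.
#' @export
classifyReads <- function(queries, classifier, bootstraps = 100L,
                          minHitFrac = 1 / 8, seed = NULL) {
  if (is(queries, "CcsReadSet")) {
    ids <- readIds(queries); queries <- as.character(readSequences(queries))
  } else {
    queries <- .asChar(queries)
    ids <- if (!is.null(names(queries))) names(queries) else
      paste0("query", seq_along(queries))
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(queries), function(i) {
    cl <- classifyWithConfidence(queries[i], classifier,
                                 bootstraps = bootstraps,
                                 minHitFrac = minHitFrac)
    row <- c(list(id = ids[i]),
             setNames(as.list(cl$name), cl$rank),
             setNames(as.list(cl$confidence), paste0(cl$rank, "_conf")))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster database entries into dbOTUs (average linkage at 3% divergence)
#'
#' All-vs-all pairwise distances (1 - global alignment identity) are
#' agglomerated by average linkage; every merge with linkage distance <=
#' `cutoff` is applied, so 3% difference separates clusters only when
#' exceeded. Species sharing a dbOTU are mutually hard to tell apart at
#' full-length 16S resolution.
#'
#' @param db A [TaxDb-class].
#' @param cutoff Linkage distance within which entries merge (default 0.03).
#' @return data.frame with columns `accession`, `species`, `dbotu`.
#' @export
dbotuCluster <- function(db, cutoff = 0.03) {
  n <- length(db)
  acc <- names(dbSequences(db))
  if (n == 1L)
    return(data.frame(accession = acc,
                      species = dbLineage(db)$species, dbotu = "dbOTU_1"))
  seqs <- as.character(dbSequences(db))
  d <- matrix(0, n, n, dimnames = list(acc, acc))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - pairwiseIdentity(seqs[i], seqs[j])
  }
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, h = cutoff)
  # deterministic ids: order clusters by their lowest member accession
  first <- vapply(split(acc, cl), function(a) min(a), character(1))
  ids <- setNames(sprintf("dbOTU_%d", rank(first, ties.method = "first")),
                  names(first))
  data.frame(accession = acc, species = dbLineage(db)$species,
             dbotu = unname(ids[as.character(cl)]), row.names = NULL)
}

#' Cross-reference classified centroids to dbOTU "nearly best hits"
#'
#' For each centroid's assigned species, reports every other species that
#' shares the assigned species' dbOTU (species that a best hit could almost
#' equally well have been), plus the dbOTU's species count. Assigned species
#' absent from the database are flagged with an empty co-member list.
#'
#' @param classifications data.frame from [classifyReads()] (needs `id` and
#'   `species` columns).
#' @param dbotus data.frame from [dbotuCluster()].
#' @return data.frame: id, species, dbotu, n_species, co_members
#'   (comma-separated), in_db.
#' @export
crossrefCentroidDbotu <- function(classifications, dbotus) {
  bySpecies <- split(dbotus, dbotus$species)
  rows <- lapply(seq_len(nrow(classifications)), function(i) {
    sp <- classifications$species[i]
    hit <- if (!is.na(sp) && sp %in% dbotus$species)
      dbotus$dbotu[match(sp, dbotus$species)] else NA_character_
    if (is.na(hit))
      return(data.frame(id = classifications$id[i], species = sp,
                        dbotu = NA_character_, n_species = 0L,
                        co_members = "", in_db = FALSE))
    memberSp <- unique(dbotus$species[dbotus$dbotu == hit])
    memberSp <- memberSp[!is.na(memberSp)]
    co <- setdiff(memberSp, sp)
    data.frame(id = classifications$id[i], species = sp, dbotu = hit,
               n_species = length(memberSp),
               co_members = paste(sort(co), collapse = ","), in_db = TRUE)
  })
  do.call(rbind, rows)
}
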