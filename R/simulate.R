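#' Generate a synthetic 16S reference set with a divergence plan
#'
#' Builds nSpecies ~1.5 kb full-length 16S-like references sharing conserved
#' primer-binding termini (F27 / R1492 sites) and internal conserved V3/V5
#' anchor blocks, so that primer matching and in-silico truncation behave as
#' on real amplicons. Pairwise divergences are controlled: designated pairs
#' hit a target divergence (within +/- 0.2 percentage points, verified by
#' global alignment) and all remaining pairs are at least `minDivergence`
#' apart.
#'
#' @param nSpecies Number of species (default 20).
#' @param length Approximate reference length in bp (default 1500).
#' @param pairDivergence Optional list of c(i, j, d) triples forcing species
#'   i and j to diverge by fraction d (e.g. one pair at 0.014, emulating two
#'   staphylococci distinguishable below the 3% OTU cutoff).
#' @param minDivergence Minimum divergence for all other pairs (default
#'   0.05).
#' @param seed Optional RNG seed.
#' @return List with `references` (DNAStringSet named by species) and
#'   `lineage` (7-rank data.frame; forced pairs share a genus).
#' @export
makeReferenceSet <- function(nSpecies = 20L, length = 1500L,
                             pairDivergence = NULL, minDivergence = 0.05,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nSpecies < 1) stop("nSpecies must be >= 1")
  for (pd in pairDivergence) {
    if (pd[1] == pd[2] || pd[1] > nSpecies || pd[2] > nSpecies)
      stop("infeasible divergence plan: bad species pair")
    if (pd[3] >= minDivergence && nSpecies > 2)
      stop("infeasible divergence plan: pair target exceeds background")
  }
  anchors <- list(
    fwd = "AGAGTTTGATCCTGGCTCAG",          # F27 site
    v3f = "CCTACGGGAGGCAGCAG",             # V3 forward site (357F)
    v5r = "ACTCAAAGGAATTGACGG",            # V5 reverse site (926R, fwd strand)
    rev = "AAGTCGTAACAAGGTAACCGTA")        # R1492 site (fwd strand)
  fixedLen <- sum(nchar(unlist(anchors)))
  varTotal <- length - fixedLen
  if (varTotal < 300) stop("length too short for the anchor layout")
  varLens <- c(round(varTotal * 0.22), round(varTotal * 0.34),
               varTotal - round(varTotal * 0.22) - round(varTotal * 0.34))
  assemble <- function(vars) paste0(anchors$fwd, vars[1], anchors$v3f,
                                    vars[2], anchors$v5r, vars[3],
                                    anchors$rev)
  randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  mutate <- function(seq, k) {
    v <- strsplit(seq, "")[[1]]
    pos <- sample(seq_along(v), min(k, base::length(v)))
    for (p in pos)
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }
  ancestor <- lapply(varLens, randSeq)
  # background species: independent mutation of the variable blocks at a
  # rate giving expected pairwise divergence ~ 1.3x minDivergence
  f <- min(0.45, 0.65 * minDivergence * length / varTotal)
  derived <- as.integer(seq_len(nSpecies))
  special <- unique(unlist(lapply(pairDivergence, function(pd) pd[2])))
  vars <- vector("list", nSpecies)
  for (i in setdiff(derived, special))
    vars[[i]] <- lapply(ancestor, function(a)
      mutate(a, stats::rbinom(1, nchar(a), f)))
  for (pd in pairDivergence) {
    src <- vars[[pd[1]]]
    k <- round(pd[3] * length)
    ks <- round(k * varLens / sum(varLens))
    ks[1] <- k - sum(ks[-1])
    vars[[pd[2]]] <- mapply(function(a, kk) mutate(a, kk), src, ks,
                            SIMPLIFY = FALSE)
  }
  refs <- vapply(vars, assemble, character(1))
  # verify and repair the plan
  for (iter in 1:25) {
    ok <- TRUE
    forced <- if (is.null(pairDivergence)) matrix(numeric(0), 0, 2) else
      do.call(rbind, lapply(pairDivergence, function(pd) sort(pd[1:2])))
    for (i in seq_len(nSpecies - 1)) for (j in (i + 1):nSpecies) {
      isForced <- nrow(forced) > 0 &&
        any(forced[, 1] == i & forced[, 2] == j)
      if (isForced) next
      d <- 1 - pairwiseIdentity(refs[i], refs[j])
      if (d < minDivergence) {
        ok <- FALSE
        vars[[j]] <- lapply(vars[[j]], function(a)
          mutate(a, ceiling(0.02 * nchar(a))))
        refs[j] <- assemble(vars[[j]])
      }
    }
    if (ok) break
  }
  for (pd in pairDivergence) {
    d <- 1 - pairwiseIdentity(refs[pd[1]], refs[pd[2]])
    if (abs(d - pd[3]) > 0.002)
      warning(sprintf("pair (%d,%d) realized divergence %.4f vs target %.4f",
                      pd[1], pd[2], d, pd[3]))
  }
  genus <- sprintf("Genus%02d", seq_len(nSpecies))
  for (pd in pairDivergence) genus[pd[2]] <- genus[pd[1]]
  species <- sprintf("%s_sp%02d", genus, seq_len(nSpecies))
  lineage <- data.frame(
    domain = "Bacteria",
    phylum = sprintf("Phylum%02d", (seq_len(nSpecies) - 1) %/% 8 + 1),
    class = sprintf("Class%02d", (seq_len(nSpecies) - 1) %/% 6 + 1),
    order = sprintf("Order%02d", (seq_len(nSpecies) - 1) %/% 4 + 1),
    family = sprintf("Family%02d", (seq_len(nSpecies) - 1) %/% 2 + 1),
    genus = genus, species = species, row.names = species)
  names(refs) <- species
  list(references = Biostrings::DNAStringSet(refs), lineage = lineage)
}

#' Derive intragenomic 16S copies from one reference
#'
#' Emulates a multi-copy 16S operon family (e.g. the seven E. coli copies,
#' two identical and the rest slightly different).
#'
#' @param reference One reference sequence.
#' @param nCopies Number of copies (default 7).
#' @param maxSubs Maximum substitutions per derived copy (default 3).
#' @param seed Optional seed.
#' @return Named character vector (copy1..copyN); copy1 and copy2 are
#'   identical to the input.
#' @export
makeCopyVariants <- function(reference, nCopies = 7L, maxSubs = 3L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reference <- as.character(reference)
  out <- character(nCopies)
  out[1] <- reference
  if (nCopies >= 2) out[2] <- reference
  if (nCopies >= 3) for (i in 3:nCopies) {
    v <- strsplit(reference, "")[[1]]
    for (p in sample(seq_along(v), sample.int(maxSubs, 1)))
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    out[i] <- paste(v, collapse = "")
  }
  setNames(out, paste0("copy", seq_len(nCopies)))
}

#' Define a simulated community
#'
#' @param references DNAStringSet (or character) named by species; extra
#'   intragenomic copies may be named "species|copyN".
#' @param lineage data.frame of 7-rank lineages (rownames = species).
#' @param weights Abundance weights per species (default even).
#' @param copyNumber 16S copies per genome per species (default 1).
#' @param errorRates Named per-base rates at the reference pass count of 10:
#'   substitution, insertion, deletion. Defaults 2e-4 / 2.5e-5 / 2.5e-5,
#'   i.e. EE around 0.5 for a 1.5 kb read (the high-quality CCS regime).
#' @param artifactRates Named fractions: chimera, host, dimer (defaults 0).
#' @param hostGenome DNAStringSet for host reads (required iff host > 0).
#' @param passRange Integer CCS pass counts to draw from (default 5:25).
#' @return A [CommunitySpec-class].
#' @export
communitySpec <- function(references, lineage,
                          weights = NULL, copyNumber = 1,
                          errorRates = c(substitution = 2e-4,
                                         insertion = 2.5e-5,
                                         deletion = 2.5e-5),
                          artifactRates = c(chimera = 0, host = 0,
                                            dimer = 0),
                          hostGenome = NULL, passRange = 5:25) {
  if (!is(references, "DNAStringSet"))
    references <- Biostrings::DNAStringSet(references)
  species <- rownames(lineage)
  if (is.null(weights)) weights <- rep(1, length(species))
  if (length(copyNumber) == 1L) copyNumber <- rep(copyNumber,
                                                  length(species))
  host <- if (is.null(hostGenome)) Biostrings::DNAStringSet() else
    if (is(hostGenome, "DNAStringSet")) hostGenome else
      Biostrings::DNAStringSet(hostGenome)
  new("CommunitySpec", references = references, lineage = lineage,
      weights = as.numeric(weights), copyNumber = as.numeric(copyNumber),
      errorRates = errorRates, artifactRates = artifactRates,
      hostGenome = host, passRange = as.integer(passRange))
}

#' Simulate CCS reads from a community with ground truth
#'
#' Source species are drawn proportional to weight x copy number; errors
#' are planted at per-base rates scaled by 10/passes (fewer passes, more
#' errors, mirroring the empirical EE-vs-passes relation); the quality
#' string encodes exactly the planted per-base error probability, so EE is
#' consistent with the realized error count in expectation. Chimeras join
#' two drawn parents at a uniform breakpoint in the middle 80%; host reads
#' are substrings of the host genome; dimer artifacts concatenate two
#' amplicons (~3 kb).
#'
#' @param spec A [CommunitySpec-class].
#' @param nReads Number of reads (> 0).
#' @param seed Optional seed (same seed, same reads).
#' @param sample Sample label attached to the reads.
#' @return List with `reads` (a [CcsReadSet-class]) and `truth`
#'   (data.frame: id, type, source, parent_a, parent_b, breakpoint,
#'   substitutions, insertions, deletions, passes).
#' @export
simulateReads <- function(spec, nReads, seed = NULL, sample = "sample1") {
  if (nReads <= 0) stop("nReads must be > 0")
  if (!is.null(seed)) set.seed(seed)
  species <- rownames(spec@lineage)
  refNames <- names(spec@references)
  refSpecies <- sub("\\|copy.*$", "", refNames)
  w <- spec@weights * spec@copyNumber
  ar <- spec@artifactRates
  if (ar["host"] > 0 && !length(spec@hostGenome))
    stop("host artifact rate > 0 but no host genome supplied")
  types <- sample(c("chimera", "host", "dimer", "read"), nReads,
                  replace = TRUE,
                  prob = c(ar["chimera"], ar["host"], ar["dimer"],
                           1 - sum(ar)))
  passProb <- stats::dnorm(spec@passRange, mean = 12, sd = 5)
  passes <- spec@passRange[sample.int(length(spec@passRange), nReads,
                                      replace = TRUE, prob = passProb)]
  er <- spec@errorRates

  drawRef <- function() {
    sp <- sample(species, 1, prob = w)
    cand <- which(refSpecies == sp)
    pick <- cand[sample.int(length(cand), 1)]
    list(species = sp, seq = as.character(spec@references[[pick]]))
  }

  seqs <- character(nReads); quals <- character(nReads)
  truth <- vector("list", nReads)
  for (i in seq_len(nReads)) {
    scale <- 10 / passes[i]
    s <- er[["substitution"]] * scale
    ins <- er[["insertion"]] * scale
    del <- er[["deletion"]] * scale
    if (types[i] == "read") {
      src <- drawRef()
      template <- src$seq
      meta <- list(type = src$species, source = src$species,
                   parent_a = NA, parent_b = NA, breakpoint = NA)
    } else if (types[i] == "chimera") {
      a <- drawRef(); b <- drawRef()
      while (b$species == a$species) b <- drawRef()
      fbp <- runif(1, 0.1, 0.9)
      bpA <- round(fbp * nchar(a$seq)); bpB <- round(fbp * nchar(b$seq))
      template <- paste0(substr(a$seq, 1, bpA),
                         substr(b$seq, bpB + 1, nchar(b$seq)))
      meta <- list(type = "chimera",
                   source = paste(a$species, b$species, sep = "|"),
                   parent_a = a$species, parent_b = b$species,
                   breakpoint = bpA)
    } else if (types[i] == "host") {
      hseq <- as.character(spec@hostGenome[[
        sample.int(length(spec@hostGenome), 1)]])
      len <- min(nchar(hseq), round(mean(Biostrings::width(
        spec@references))))
      start <- sample.int(max(1L, nchar(hseq) - len + 1L), 1)
      template <- substr(hseq, start, start + len - 1L)
      meta <- list(type = "host", source = "host", parent_a = NA,
                   parent_b = NA, breakpoint = NA)
    } else {  # dimer
      a <- drawRef(); b <- drawRef()
      template <- paste0(a$seq, b$seq)
      meta <- list(type = "dimer",
                   source = paste(a$species, b$species, sep = "|"),
                   parent_a = a$species, parent_b = b$species,
                   breakpoint = nchar(a$seq))
    }
    mut <- .plantErrors(template, s, ins, del)
    seqs[i] <- mut$seq
    pErr <- s + ins + del
    q <- if (pErr <= 0) 93L else
      max(2L, min(93L, as.integer(round(-10 * log10(pErr)))))
    quals[i] <- paste(rep(intToUtf8(q + 33L), nchar(mut$seq)),
                      collapse = "")
    truth[[i]] <- data.frame(
      id = sprintf("sim%06d", i), type = meta$type, source = meta$source,
      parent_a = as.character(meta$parent_a),
      parent_b = as.character(meta$parent_b),
      breakpoint = as.integer(meta$breakpoint),
      substitutions = mut$subs, insertions = mut$ins, deletions = mut$del,
      passes = passes[i], stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  reads <- ccsReadSet(setNames(Biostrings::DNAStringSet(seqs), truth$id),
                      quality = quals, passes = passes, sample = sample)
  list(reads = reads, truth = truth)
}

# plant substitutions / insertions / deletions at the given per-base rates
.plantErrors <- function(template, s, ins, del) {
  v <- strsplit(template, "")[[1]]
  n <- length(v)
  if (s + ins + del <= 0)
    return(list(seq = template, subs = 0L, ins = 0L, del = 0L))
  u <- runif(n)
  subPos <- which(u < s)
  delPos <- which(u >= s & u < s + del)
  insPos <- which(runif(n) < ins)
  for (p in subPos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  insMap <- character(n)
  insMap[insPos] <- vapply(insPos, function(p)
    sample(c("A", "C", "G", "T"), 1), character(1))
  keep <- rep(TRUE, n); keep[delPos] <- FALSE
  out <- paste0(v, insMap)[keep]
  list(seq = paste(out, collapse = ""), subs = length(subPos),
       ins = length(insPos), del = length(delPos))
}

#' Write a simulation truth table as TSV
#' @param truth data.frame from [simulateReads()].
#' @param path Output path.
#' @export
writeTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' BEI-like even mock community preset
#'
#' 20 species, one pair at 1.4% divergence and all other pairs >= 5%
#' apart, even weights, high-quality CCS error regime.
#'
#' @param readsPerSpecies Reads per species (default 200).
#' @param seed RNG seed.
#' @return List with `references`, `lineage`, `spec`, `reads`, `truth`.
#' @export
simulateBeiLike <- function(readsPerSpecies = 200L, seed = 1L) {
  set.seed(seed)
  rs <- makeReferenceSet(20L, 1500L,
                         pairDivergence = list(c(19, 20, 0.014)),
                         minDivergence = 0.05)
  spec <- communitySpec(rs$references, rs$lineage)
  sim <- simulateReads(spec, readsPerSpecies * 20L)
  c(rs, list(spec = spec), sim)
}
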