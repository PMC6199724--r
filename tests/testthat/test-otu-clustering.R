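test_that("dereplication counts, sorts and tie-breaks deterministically", {
  u <- dereplicate(c(a = "AAA", b = "AAA", c = "AAC"))
  expect_equal(u$bases, c("AAA", "AAC"))
  expect_equal(u$size, c(2L, 1L))
  expect_equal(u$ids[[1]], c("a", "b"))
  # all distinct -> sizes 1, lexicographic order
  u2 <- dereplicate(c(x = "TTT", y = "AAA", z = "CCC"))
  expect_equal(u2$bases, c("AAA", "CCC", "TTT"))
  expect_equal(u2$size, rep(1L, 3))
  expect_equal(nrow(dereplicate(character(0))), 0)
})

test_that("greedy clustering follows the abundance-sorted 97% rule", {
  set.seed(101)
  A <- randomSeq(400)
  B <- mutateSeq(A, 8)    # 2% from A -> joins A's OTU
  C <- mutateSeq(A, 20)   # 5% from A -> new OTU
  reads <- c(rep(A, 5), rep(C, 3), rep(B, 2))
  names(reads) <- paste0("r", seq_along(reads))
  otus <- greedyCluster(dereplicate(reads))
  expect_equal(length(otus), 2)
  expect_equal(as.character(centroids(otus)[[1]]), A)
  expect_equal(as.character(centroids(otus)[[2]]), C)
  expect_equal(otus@sizes, c(7L, 3L))
  # all reads identical -> one OTU
  expect_equal(length(greedyCluster(dereplicate(rep("ACGTACGTACGT", 5)))), 1)
})

test_that("greedy clustering matches the straight-line oracle on small sets", {
  set.seed(103)
  for (rep_i in 1:5) {
    base1 <- randomSeq(300); base2 <- mutateSeq(base1, 30)
    base3 <- mutateSeq(base1, 60)
    pool <- c(base1, base2, base3,
              vapply(1:7, function(i)
                mutateSeq(sample(c(base1, base2, base3), 1),
                          sample(c(2, 5, 12), 1)), character(1)))
    sizes <- sample(1:20, length(pool), TRUE)
    reads <- rep(pool, sizes)
    names(reads) <- paste0("r", seq_along(reads))
    u <- dereplicate(reads)
    got <- greedyCluster(u, chimeraCheck = FALSE)
    ora <- oracleGreedy(u$bases)
    expect_equal(unname(as.character(centroids(got))),
                 unname(ora$centroids))
    sizesOra <- vapply(seq_along(ora$centroids), function(k)
      sum(u$size[ora$assign == k]), integer(1))
    expect_equal(got@sizes, sizesOra)
  }
})

test_that("de novo chimera check flags crossovers and spares clean reads", {
  set.seed(107)
  rs <- smallRefSet()
  refs <- as.character(rs$references)
  L <- nchar(refs[1])
  chi <- paste0(substr(refs[1], 1, 450), substr(refs[2], 451, L))
  cc <- chimeraDenovoCheck(chi, refs, candidateId = "chi")
  expect_true(cc$verdict)
  expect_gte(cc$model_identity, cc$best_single_identity)
  # the inferred breakpoint can slide within the run of columns where the
  # two parents agree, so only approximate recovery is guaranteed
  expect_lt(abs(cc$breakpoint - 450), 80)
  # candidate identical to a centroid -> clean
  expect_false(chimeraDenovoCheck(refs[3], refs)$verdict)
  # 5% from everything with no crossover gain -> clean
  far <- mutateSeq(refs[1], round(0.05 * L))
  expect_false(chimeraDenovoCheck(far, refs)$verdict)
  # fewer than two parents -> vacuously clean
  expect_false(chimeraDenovoCheck(chi, refs[1])$verdict)
})

test_that("CHIM2 removes hybrid centroids against a reference set", {
  rs <- smallRefSet()
  refs <- as.character(rs$references)
  L <- nchar(refs[1])
  hybrid <- paste0(substr(refs[3], 1, 400), substr(refs[4], 401, L))
  reads <- c(rep(refs[1], 6), rep(hybrid, 3))
  names(reads) <- paste0("r", seq_along(reads))
  otus <- greedyCluster(dereplicate(reads), chimeraCheck = FALSE)
  expect_equal(length(otus), 2)
  out <- chimeraRefCheck(otus, rs$references)
  expect_equal(length(out), 1)
  expect_equal(length(out@chim2), 1)
  expect_equal(unname(as.character(centroids(out)[[1]])), unname(refs[1]))
})

test_that("read mapping quantifies per-sample counts and conserves reads", {
  set.seed(109)
  rs <- smallRefSet()
  refs <- as.character(rs$references)
  otus <- greedyCluster(dereplicate(setNames(refs, names(refs))),
                        chimeraCheck = FALSE)
  expect_equal(length(otus), 6)
  reads <- c(refs[1], mutateSeq(refs[1], 5), mutateSeq(refs[2], 3),
             randomSeq(900))
  x <- ccsReadSet(setNames(Biostrings::DNAStringSet(unname(reads)),
                           paste0("r", 1:4)),
                  sample = c("sA", "sA", "sB", "sB"))
  m <- mapReadsToCentroids(x, otus)
  counts <- otuCounts(m)
  expect_equal(sum(counts) + sum(m@unassigned), 4)
  # dereplication orders all-distinct sequences lexicographically, so look
  # the OTUs up by centroid sequence
  otu1 <- names(centroids(m))[match(refs[1], as.character(centroids(m)))]
  otu2 <- names(centroids(m))[match(refs[2], as.character(centroids(m)))]
  expect_equal(unname(counts[otu1, "sA"]), 2L)
  expect_equal(unname(counts[otu2, "sB"]), 1L)
  expect_equal(unname(m@unassigned[["sB"]]), 1L)
  asg <- attr(m, "assignments")
  expect_equal(unname(asg[["r1"]]), otu1)
  expect_true(is.na(asg[["r4"]]))
})

test_that("EE-failed reads are still counted in abundances", {
  rs <- smallRefSet()
  refs <- as.character(rs$references)[1:3]
  goodQ <- lapply(nchar(refs), function(w) rep(40L, w))
  badQ <- lapply(nchar(refs), function(w) rep(10L, w))  # EE >> 1
  x <- ccsReadSet(setNames(Biostrings::DNAStringSet(c(refs, refs)),
                           paste0("r", 1:6)),
                  quality = c(goodQ, badQ), sample = "s1")
  otus <- runClustering(x)
  expect_equal(length(otus), 3)
  expect_equal(sum(otuCounts(otus)), 6)   # the EE>1 copies still map
  expect_equal(attr(otus, "eeReport")$pass, 3)
})

test_that("centroid FASTA and count-table writers round-trip", {
  rs <- smallRefSet()
  refs <- as.character(rs$references)[1:2]
  reads <- setNames(rep(refs, c(3, 2)), paste0("r", 1:5))
  otus <- greedyCluster(dereplicate(reads), chimeraCheck = FALSE)
  x <- ccsReadSet(setNames(Biostrings::DNAStringSet(unname(reads)),
                           names(reads)), sample = "s1")
  otus <- mapReadsToCentroids(x, otus)
  fa <- tempfile(fileext = ".fasta")
  writeCentroidsFasta(otus, fa)
  back <- readFasta(fa)
  expect_equal(names(back), c("OTU_1;size=3", "OTU_2;size=2"))
  tsv <- tempfile(fileext = ".tsv")
  writeOtuTable(otus, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$s1, c(3L, 2L))
})
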