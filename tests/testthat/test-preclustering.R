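test_that("expected error follows the Phred sum and per-kb scaling", {
  expect_equal(expectedError(rep(20, 10)), 0.1)
  expect_equal(expectedError(10), 0.1)
  expect_equal(expectedError(rep(30, 1400)), 1.4)
  x <- ccsReadSet(c(r = randomSeq(1400)),
                  quality = list(rep(30L, 1400)))
  expect_equal(unname(expectedErrors(x)), 1.4)
  expect_equal(unname(expectedErrorsPerKb(x)), 1.0)
  expect_error(expectedError(integer(0)), "missing")
})

test_that("pass-count filter keeps >= 5 passes and fails closed", {
  x <- ccsReadSet(setNames(Biostrings::DNAStringSet(rep("ACGTACGT", 4)),
                           paste0("r", 1:4)),
                  passes = c(5L, 4L, 0L, NA))
  res <- filterByPasses(x)
  expect_equal(readIds(res$pass), "r1")
  expect_equal(unname(res$tags[c("r2", "r3")]),
               c("low_passes", "low_passes"))
  expect_equal(unname(res$tags[["r4"]]), "no_pass_info")
})

test_that("EE filter boundary is inclusive and monotone in the cutoff", {
  mkread <- function(id, ee, L = 100) {
    q <- as.integer(round(-10 * log10(ee / L)))
    ccsReadSet(setNames(Biostrings::DNAStringSet(randomSeq(L)), id),
               quality = list(rep(q, L)))
  }
  set.seed(5)
  # exact boundary: Q20 over 100 bases -> EE exactly 1.0
  x <- mkread("b", 1.0)
  expect_equal(unname(expectedErrors(x)), 1.0)
  expect_equal(length(filterByEE(x, 1.0)$pass), 1)
  expect_equal(length(filterByEE(x, 1.0, inclusive = FALSE)$pass), 0)
  # monotonicity: tightening maxEE never adds reads
  n <- 60
  qs <- lapply(seq_len(n), function(i) sample(10:45, 150, TRUE))
  xx <- ccsReadSet(setNames(Biostrings::DNAStringSet(
    vapply(seq_len(n), function(i) randomSeq(150), character(1))),
    paste0("r", 1:n)), quality = qs)
  prev <- readIds(xx)
  for (cut in c(Inf, 8, 4, 2, 1, 0.5, 0.25)) {
    cur <- readIds(filterByEE(xx, cut)$pass)
    expect_true(all(cur %in% prev), info = paste("cut", cut))
    prev <- cur
  }
  expect_equal(length(filterByEE(xx, Inf)$pass), n)
})

test_that("length filter bounds are inclusive", {
  w <- c(499, 500, 1450, 2000, 3000)
  x <- ccsReadSet(setNames(Biostrings::DNAStringSet(
    vapply(w, randomSeq, character(1))), paste0("r", w)))
  res <- filterByLength(x)
  expect_setequal(readIds(res$pass), c("r500", "r1450", "r2000"))
  expect_setequal(readIds(res$fail), c("r499", "r3000"))
  expect_error(filterByLength(x, min = 10, max = 5), "min > max")
})

test_that("host screen separates host substrings from 16S reads", {
  set.seed(31)
  host <- randomSeq(30000)
  rs <- smallRefSet()
  spec <- communitySpec(rs$references, rs$lineage)
  sim <- simulateReads(spec, 30, seed = 32)
  idx <- hostKmerIndex(host)
  hostReads <- ccsReadSet(setNames(Biostrings::DNAStringSet(c(
    substr(host, 101, 1100), substr(host, 5000, 6200))), c("h1", "h2")))
  res <- hostScreen(hostReads, idx)
  expect_equal(length(res$host), 2)        # 100% recall on pure host reads
  res2 <- hostScreen(sim$reads, idx)
  expect_equal(length(res2$host), 0)       # 0 false positives on 16S reads
  # junction read at exactly the threshold fraction counts as host
  half <- substr(host, 101, 600)
  ref <- as.character(rs$references[[1]])
  junction <- paste0(half, substr(ref, 1, 500))
  jr <- ccsReadSet(c(j = junction))
  frac <- hostScreen(jr, idx)$sharedFraction[["j"]]
  res3 <- hostScreen(jr, idx, screenFraction = frac)
  expect_equal(length(res3$host), 1)
  res4 <- hostScreen(jr, idx, screenFraction = frac + 1e-9)
  expect_equal(length(res4$host), 0)
  expect_error(hostKmerIndex(character(0)), "empty")
})

test_that("demultiplexing assigns, trims, orients; ties stay unassigned", {
  set.seed(41)
  bc <- data.frame(sample = c("s1", "s2"),
                   forward = c("ACGTACGT", "TTGGCCAA"),
                   reverse = c("GGTTCCAA", "AACCGGTT"))
  amp <- vapply(1:3, function(i) randomSeq(200), character(1))
  raw <- c(
    r1 = paste0("ACGTACGT", amp[1], revComp("GGTTCCAA")),
    r2 = revComp(paste0("TTGGCCAA", amp[2], revComp("AACCGGTT"))),
    r3 = paste0("GGGGGGGG", amp[3], "CCCCCCCC"))
  x <- ccsReadSet(setNames(Biostrings::DNAStringSet(unname(raw)),
                           names(raw)))
  res <- demultiplex(x, bc, maxMismatches = 1)
  expect_equal(unname(sampleLabels(res$assigned)[c("r1", "r2")]),
               c("s1", "s2"))
  expect_equal(unname(as.character(readSequences(res$assigned))),
               amp[1:2])
  expect_equal(unname(res$tags[["r3"]]), "barcode_unmatched")
  # ambiguous: both samples match at equal distance -> unassigned
  bc2 <- data.frame(sample = c("s1", "s2"),
                    forward = c("ACGTACGT", "ACGTACGA"),
                    reverse = c("GGTTCCAA", "GGTTCCAT"))
  res2 <- demultiplex(x[1], bc2, maxMismatches = 1)
  expect_equal(length(res2$assigned), 0)
  expect_equal(unname(res2$tags[["r1"]]), "barcode_ambiguous")
  expect_error(demultiplex(x, rbind(bc, bc[1, ])), "duplicate")
})

test_that("primer matching orients, trims and tags failures", {
  set.seed(51)
  rs <- smallRefSet()
  spec <- communitySpec(rs$references, rs$lineage)
  sim <- simulateReads(spec, 12, seed = 52)
  pm <- matchAndTrimPrimers(sim$reads)
  expect_equal(length(pm$pass), 12)
  # forward layout trimmed: no primer site remains
  expect_false(any(grepl("AGAGTTTGATC", as.character(readSequences(pm$pass))[1:3])))
  # a read and its reverse complement yield identical trimmed output
  rc <- ccsReadSet(setNames(Biostrings::DNAStringSet(
    revComp(as.character(readSequences(sim$reads))[1:4])), paste0("x", 1:4)))
  pm2 <- matchAndTrimPrimers(rc)
  expect_equal(unname(as.character(readSequences(pm2$pass))),
               unname(as.character(readSequences(pm$pass))[1:4]))
  # duplicated forward primer -> fail("multiple")
  ref <- as.character(rs$references[[1]])
  dup <- paste0("AGAGTTTGATCCTGGCTCAG", ref)
  res <- matchAndTrimPrimers(ccsReadSet(c(d = dup)))
  expect_equal(unname(res$tags[["d"]]), "multiple")
  # no primers at all -> fail("absent")
  res2 <- matchAndTrimPrimers(ccsReadSet(c(n = randomSeq(800))))
  expect_equal(unname(res2$tags[["n"]]), "absent")
})

test_that("region truncation extracts V3-V5 and is deliberately
           non-idempotent", {
  rs <- smallRefSet()
  spec <- communitySpec(rs$references, rs$lineage)
  sim <- simulateReads(spec, 6, seed = 61)
  pm <- matchAndTrimPrimers(sim$reads)
  tr <- truncateToRegion(pm$pass, "V3-V5")
  expect_equal(length(tr$miss), 0)
  w <- Biostrings::width(readSequences(tr$pass))
  expect_true(all(w > 100 & w < Biostrings::width(readSequences(pm$pass))))
  # primers already removed -> second truncation misses everything
  tr2 <- truncateToRegion(tr$pass, "V3-V5")
  expect_equal(length(tr2$pass), 0)
  expect_equal(length(tr2$miss), length(tr$pass))
  # quality strings are truncated alongside
  expect_equal(nchar(tr$pass@quality),
               Biostrings::width(readSequences(tr$pass)))
})

test_that("filter cascade conserves reads: one terminal bin each", {
  set.seed(71)
  rs <- smallRefSet()
  host <- randomSeq(20000)
  spec <- communitySpec(rs$references, rs$lineage,
                        artifactRates = c(chimera = 0, host = 0.15,
                                          dimer = 0.1),
                        hostGenome = Biostrings::DNAStringSet(host),
                        passRange = 3:25)
  sim <- simulateReads(spec, 80, seed = 72)
  res <- runPreclustering(sim$reads, host = host)
  # every read passed or carries exactly one fail tag
  expect_equal(sum(is.na(res$tags)), length(res$reads))
  expect_equal(length(res$tags), length(sim$reads))
  # report stage arithmetic: input = pass + fail, chained
  rep <- res$report
  expect_true(all(rep$input == rep$pass + rep$fail))
  expect_equal(rep$input[1], length(sim$reads))
  expect_equal(rep$input[-1], rep$pass[-length(rep$pass)])
  expect_equal(rep$pass[nrow(rep)], length(res$reads))
  # dimers are always removed: over-length when the amplicon is long
  # enough, otherwise at primer matching (each primer present twice);
  # host reads die at the host screen — unless already removed upstream
  # for low pass counts
  truthType <- setNames(sim$truth$type, sim$truth$id)
  lowPass <- names(passCounts(sim$reads))[passCounts(sim$reads) < 5]
  dimers <- setdiff(names(truthType)[truthType == "dimer"], lowPass)
  expect_true(all(res$tags[dimers] %in% c("bad_length", "multiple")))
  hostIds <- setdiff(names(truthType)[truthType == "host"], lowPass)
  expect_true(all(res$tags[hostIds] == "host"))
})
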