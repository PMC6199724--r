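cnTable <- data.frame(
  domain = "Bacteria", phylum = "P1", class = "C1", order = "O1",
  family = c("F1", "F1", "F1", "F2", "F2", "F2"),
  genus = c("G1", "G2", "G2", "G3", "G3", "G3"),
  species = c("G1_a", "G2_b", "G2_c", "G3_d", "G3_e", "G3_f"),
  copies = c(7, 3, 5, 2, 4, 6))

test_that("copy-number lookup walks up ranks and averages members", {
  expect_equal(copyNumberLookup(c(species = "G1_a"), cnTable), 7)
  # species absent, genus members {3, 5} -> 4
  expect_equal(copyNumberLookup(c(genus = "G2", species = "G2_zz"),
                                cnTable), 4)
  # genus absent, family members {2, 4, 6} -> 4
  expect_equal(copyNumberLookup(c(family = "F2", genus = "GX",
                                  species = "GX_q"), cnTable), 4)
  expect_error(copyNumberLookup(c(domain = "Archaea"), cnTable), "no rank")
})

test_that("expected abundances follow (m/g)*c with scale invariance", {
  p <- expectedAbundance(c(0.5, 0.5), c(2e6, 4e6), c(2, 1))$expected
  expect_equal(p, c(0.8, 0.2))
  expect_equal(expectedAbundance(1, 3e6, 4)$expected, 1)
  expect_equal(expectedAbundance(rep(2, 5), rep(3e6, 5), rep(4, 5))$expected,
               rep(0.2, 5))
  set.seed(401)
  m <- runif(8); g <- runif(8, 1e6, 9e6); cc <- sample(1:10, 8, TRUE)
  expect_equal(expectedAbundance(m, g, cc)$expected,
               expectedAbundance(m * 37.5, g, cc)$expected)
  expect_error(expectedAbundance(1, 0, 1), "genome size")
})

test_that("zero-read probability equals the exact binomial mass at zero", {
  expect_lt(probZeroReads(24 / 6878, 6878), 1e-10)
  expect_equal(probZeroReads(0, 1000), 1)
  expect_equal(probZeroReads(0.001, 1000), dbinom(0, 1000, 0.001))
  set.seed(403)
  for (i in 1:1000) {
    p <- runif(1); n <- sample(0:5000, 1)
    expect_equal(probZeroReads(p, n), dbinom(0, n, p))
  }
})

test_that("observed-vs-expected fit recovers proportionality and nulls", {
  set.seed(407)
  exp_p <- expectedAbundance(runif(50), runif(50, 1e6, 8e6),
                             sample(1:12, 50, TRUE))$expected
  fit <- suppressWarnings(fitObservedExpected(exp_p * 5000, exp_p))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1, tolerance = 1e-8)
  # permuted observations decorrelate
  fitNull <- fitObservedExpected(sample(exp_p * 5000), exp_p)
  expect_lt(fitNull$r_squared, 0.3)
  # multinomial draws at n = 5000 keep a strong fit
  obs <- as.numeric(rmultinom(1, 5000, exp_p))
  fitM <- fitObservedExpected(obs, exp_p)
  expect_gt(fitM$r_squared, 0.9)
  expect_error(fitObservedExpected(1:2, c(0.5, 0.5)), "3 matched")
})

test_that("slope is recovered within 3 SE from multinomial counts at 1e4", {
  set.seed(409)
  exp_p <- expectedAbundance(runif(40), runif(40, 1e6, 8e6),
                             sample(1:12, 40, TRUE))$expected
  obs <- as.numeric(rmultinom(1, 1e4, exp_p))
  fit <- fitObservedExpected(obs, exp_p)
  se <- summary(fit$fit)$coefficients[2, 2]
  expect_lt(abs(fit$slope - 1), 3 * se)
})

test_that("error-rate estimation picks the closest copy and stratifies by
           EE", {
  set.seed(411)
  ref <- randomSeq(900)
  copies <- makeCopyVariants(ref, nCopies = 7, seed = 413)
  # error-free reads from each copy match their source exactly
  x <- ccsReadSet(setNames(Biostrings::DNAStringSet(unname(copies)),
                           paste0("r_", names(copies))),
                  quality = lapply(rep(900, 7), function(w) rep(40L, w)))
  res <- estimateErrorRates(x, copies)
  expect_true(all(res$perRead$mismatches == 0 & res$perRead$gaps == 0))
  expect_equal(res$perRead$closest[3:7], names(copies)[3:7])
  # 2 substitutions + 1 deletion -> (2, 1), with a low-quality stratum
  v <- strsplit(copies[["copy4"]], "")[[1]]
  v[50] <- setdiff(c("A", "C", "G", "T"), v[50])[1]
  v[300] <- setdiff(c("A", "C", "G", "T"), v[300])[1]
  mutant <- paste(v[-600], collapse = "")
  y <- ccsReadSet(c(m1 = mutant), quality = list(rep(15L, 899)))
  res2 <- estimateErrorRates(y, copies)
  expect_equal(res2$perRead$mismatches, 2)
  expect_equal(res2$perRead$gaps, 1)
  expect_equal(unname(res2$byStratum["EE>cut", "n"]), 1)
})

test_that("diversity summaries match closed forms", {
  d1 <- diversityStats(c(10, 0, 0))
  expect_equal(d1$shannon, 0); expect_equal(d1$effective_species, 1)
  d4 <- diversityStats(c(25, 25, 25, 25))
  expect_equal(d4$shannon, log(4))
  expect_equal(d4$effective_species, 4)
  d <- diversityStats(c(70, 20, 10))
  expect_equal(d$shannon, 0.8018, tolerance = 1e-4)
  expect_equal(d$effective_species, 2.2296, tolerance = 1e-4)
  # effective number <= richness, equality iff uniform
  set.seed(417)
  for (i in 1:25) {
    ct <- sample(0:50, 8, TRUE)
    if (sum(ct) == 0) next
    dd <- diversityStats(ct)
    expect_lte(dd$effective_species, dd$richness + 1e-9)
  }
  expect_error(diversityStats(c(0, 0)), "all-zero")
  # agrees with vegan as an independent implementation
  skip_if_not_installed("vegan")
  ct <- c(70, 20, 10, 5)
  expect_equal(diversityStats(ct)$shannon,
               unname(vegan::diversity(ct, index = "shannon")))
})

test_that("count-table filtering applies sample-then-OTU minima inclusively", {
  tab <- matrix(c(450, 40, 10, 495, 5, 0, 600, 4, 41),
                nrow = 3,
                dimnames = list(paste0("OTU", 1:3), paste0("s", 1:3)))
  # totals: s1 = 500, s2 = 500, s3 = 645 -> all kept at the boundary
  ft <- filterCountTable(tab, minSample = 500, minOtu = 50)
  expect_equal(ncol(ft), 3)
  # OTU totals: 1545, 49, 51 -> OTU2 dropped, OTU3 kept at the boundary
  expect_setequal(rownames(ft), c("OTU1", "OTU3"))
  # sample below threshold dropped before OTU totals are formed
  tab2 <- tab; tab2[, "s3"] <- c(499, 0, 0)
  ft2 <- filterCountTable(tab2, minSample = 500, minOtu = 50)
  expect_equal(colnames(ft2), c("s1", "s2"))
  # untouched table passes through unchanged
  expect_equal(unclass(filterCountTable(tab, minSample = 1, minOtu = 1)),
               tab, ignore_attr = TRUE)
  # relative + log transform with 1/sample-total pseudocount; sample
  # totals are recomputed after filtering, matching normalization "after
  # first removing low yield samples and rare taxa"
  res <- filterCountTable(tab, 500, 50, relative = TRUE,
                          logTransform = TRUE)
  expect_equal(colSums(res$relative), rep(1, 3), ignore_attr = TRUE)
  expect_equal(res$logRelative[1, 1],
               log(450 / 460 + 1 / 460))
})

test_that("core taxa require presence in every subject", {
  tab <- matrix(c(5, 0, 2, 3, 1, 0, 0, 4, 9), nrow = 3,
                dimnames = list(paste0("OTU", 1:3), c("a1", "a2", "b1")))
  subj <- c(a1 = "A", a2 = "A", b1 = "B")
  core <- coreTaxa(tab, subj)
  # OTU1: present in A (a1) and B? b1 = 0 -> not core
  expect_setequal(core, c("OTU2", "OTU3"))
  expect_error(coreTaxa(tab, subj[1:2]), "unmapped")
})
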