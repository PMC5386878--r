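test_that("GC and GC3 are exact base counts", {
  expect_equal(gcContent("ATGC"), 0.5)
  expect_equal(gcContent("GGCC"), 1.0)
  expect_equal(gcContent("ATGGCCTAA"), 4 / 9)
  # N excluded from numerator and denominator
  expect_equal(gcContent("ATGCNN"), 0.5)
  expect_error(gcContent("NNN"), "undefined")
  expect_error(gcContent(""), "empty")

  expect_equal(gc3("ATG"), 1.0)
  expect_equal(gc3("ATGAAAGGG"), 2 / 3)
  expect_equal(gc3("ATAAGTCGT"), 0)      # all codons end A or T
  expect_error(gc3("ATGA"), "frame")
})

test_that("codon usage table derives Sharp & Li adaptiveness weights", {
  tab <- codonUsageTable(c("TTTTTTTTC"))   # Phe: 2x TTT, 1x TTC
  w <- relAdaptiveness(tab)
  expect_equal(unname(w["TTT"]), 1)
  expect_equal(unname(w["TTC"]), 0.5)
  # zero-count codons receive the 0.5 pseudo-count before the ratio
  expect_equal(unname(w["AAA"]), 1)   # whole Lys family unobserved -> all 1
  counts <- codonCounts(tab)
  expect_equal(sum(counts), 3)
  fam <- split(names(w), Biostrings::GENETIC_CODE[names(w)])
  expect_true(all(vapply(fam, function(cc) max(w[cc]), numeric(1)) == 1))
})

test_that("CAI matches a log-domain brute-force recomputation", {
  # toy usage table printed by hand: skewed Phe and Lys usage
  ref <- codonUsageTable(c(
    paste(rep("TTT", 6), collapse = ""),
    paste(rep("TTC", 2), collapse = ""),
    paste(rep("AAA", 8), collapse = ""),
    paste(rep("AAG", 4), collapse = ""),
    "GGTGGAGGG"
  ))
  gene <- "TTTAAGGGTTTCAAA"   # 5 codons
  expect_equal(cai(gene, ref),
               oracleCai(gene, codonCounts(ref)), tolerance = 1e-12)
  # every codon the family's preferred one -> exactly 1
  expect_equal(cai("TTTAAAGGT", ref), 1)
  # only Met/Trp codons -> empty-product convention
  expect_equal(cai("ATGTGGATG", ref), 1)
})

test_that("ENC hits Wright's analytic extremes and matches a brute-force", {
  # one codon per amino acid, each family observed twice -> exactly 20
  oneEach <- paste(rep(c("TTT", "ATT", "GTT", "CCT", "ACT", "GCT", "TAT",
                         "CAT", "CAA", "AAT", "AAA", "GAT", "GAA", "TGT",
                         "CGT", "AGT", "GGT", "CTT"), 3), collapse = "")
  expect_equal(enc(oneEach), 20)
  # uniform synonymous usage at large sample -> the 61 limit
  seqs <- simulateCodingSequences(60, "sp", seed = 11, lengthMeanCodons = 400,
                                  gc3Target = NA, biasStrength = 0)
  expect_equal(enc(paste(as.character(seqs), collapse = "")), 61,
               tolerance = 0.02)
  expect_true(enc(as.character(seqs[[1]])) <= 61)
  # 60-codon toy gene equals the independent spreadsheet-style recomputation
  set.seed(5)
  toy <- paste(sample(lgtaudit:::senseCodons(), 60, replace = TRUE),
               collapse = "")
  expect_equal(enc(toy), oracleEnc(toy), tolerance = 1e-12)
})

test_that("codon metrics are invariant to synonymous codon reordering", {
  seqs <- simulateCodingSequences(3, "sp", seed = 21, lengthMeanCodons = 200,
                                  gc3Target = 0.5, biasStrength = 1)
  ref <- codonUsageTable(seqs)
  for (s in as.character(seqs)) {
    cod <- lgtaudit:::splitCodons(s)
    perm <- paste(c(cod[1], sample(cod[-c(1, length(cod))]), cod[length(cod)]),
                  collapse = "")
    expect_equal(cai(perm, ref), cai(s, ref), tolerance = 1e-12)
    expect_equal(enc(perm), enc(s), tolerance = 1e-12)
  }
})

test_that("tetranucleotide frequencies equal hand counts", {
  f <- tetranucleotideFrequencies("AAAA")
  expect_equal(unname(f["AAAA"]), 1)
  expect_equal(sum(f), 1)
  expect_equal(unname(tetranucleotideFrequencies("AAAAA")["AAAA"]), 1)
  # exhaustive: every single-4-mer input puts all mass on itself
  kmers <- names(f)
  hits <- vapply(kmers, function(k) {
    unname(tetranucleotideFrequencies(k)[k]) == 1
  }, logical(1))
  expect_true(all(hits))
  # windows containing N are dropped
  fN <- tetranucleotideFrequencies("AAAANTTTT")
  expect_equal(unname(fN["AAAA"] + fN["TTTT"]), 1)
  expect_error(tetranucleotideFrequencies("ACG"), "invalid")
  expect_equal(sum(tetranucleotideFrequencies("ACGTACGGTTAC")), 1)
})

test_that("low-variance tetranucleotide selection matches an oracle sort", {
  set.seed(9)
  tetra <- matrix(runif(20 * 256), 20,
                  dimnames = list(NULL, names(tetranucleotideFrequencies("AAAA"))))
  tetra[, "ACGT"] <- 0.004   # engineered constant column
  expect_equal(selectLowVarianceTetranucs(tetra, 1), "ACGT")
  expect_equal(length(selectLowVarianceTetranucs(tetra, 256)), 256)
  v <- apply(tetra, 2, var)
  expect_equal(selectLowVarianceTetranucs(tetra, 10),
               colnames(tetra)[order(v, colnames(tetra))][1:10])
  expect_error(selectLowVarianceTetranucs(tetra, 0), "range")
})

test_that("discriminative tetranucleotide selection ranks the planted signal first", {
  set.seed(10)
  nm <- names(tetranucleotideFrequencies("AAAA"))
  a <- matrix(rnorm(30 * 256, 10), 30, dimnames = list(NULL, nm))
  b <- a + matrix(rnorm(30 * 256, 0, 0.01), 30)
  b[, "AAAA"] <- b[, "AAAA"] + 5
  expect_equal(selectDiscriminativeTetranucs(a, b, 1), "AAAA")
  # identical sets: all scores zero -> lexicographic prefix
  expect_equal(selectDiscriminativeTetranucs(a, a, 3), sort(nm)[1:3])
  # degenerate: both sets constant and identical
  z <- matrix(1, 3, 256, dimnames = list(NULL, nm))
  expect_error(selectDiscriminativeTetranucs(z, z, 1), "degenerate")
})

test_that("tail flagging is rank-based and matches sort-and-slice", {
  set.seed(11)
  v <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  fl <- flagTailOutliers(v)
  expect_length(fl$lower, 25)
  expect_length(fl$upper, 25)
  srt <- names(sort(v))
  expect_setequal(fl$lower, srt[1:25])
  expect_setequal(fl$upper, rev(srt)[1:25])
  # n = 200 against the brute-force slice
  v2 <- setNames(rnorm(200), sprintf("h%03d", 1:200))
  fl2 <- flagTailOutliers(v2)
  expect_setequal(fl2$flagged,
                  c(names(sort(v2))[1:5], rev(names(sort(v2)))[1:5]))
  # degenerate: identical values flag nothing
  expect_length(flagTailOutliers(setNames(rep(1, 100), 1:100))$flagged, 0)
  expect_error(flagTailOutliers(v, alpha = 0.7), "alpha")
  expect_error(flagTailOutliers(v[1:20]), "at least")
})

test_that("composition profiles exclude bad genes and round-trip through TSV", {
  seqs <- simulateCodingSequences(12, "spA", seed = 31)
  raw <- as.character(seqs)
  raw <- c(raw, bad1 = paste(rep("N", 300), collapse = ""),
           bad2 = "ATGAA")
  expect_warning(prof <- compositionProfiles(raw, "spA"), "excluded")
  expect_equal(nrow(metricsTable(prof)), 12)
  expect_true(all(abs(rowSums(tetraMatrix(prof)) - 1) < 1e-9))
  path <- tempfile(fileext = ".tsv")
  writeCompositionTsv(prof, path)
  back <- readCompositionTsv(path)
  expect_equal(metricsTable(back)$gc, metricsTable(prof)$gc, tolerance = 1e-9)
  expect_equal(dim(tetraMatrix(back)), dim(tetraMatrix(prof)))
})

test_that("randomized sequences drift to GC 0.5 in expectation", {
  seqs <- simulateCodingSequences(1, "sp", seed = 41, lengthMeanCodons = 1000,
                                  lengthSdCodons = 0, gc3Target = 0.6,
                                  biasStrength = 2)
  gcs <- vapply(1:50, function(i) {
    gcContent(randomizeSequence(seqs[[1]], seed = i))
  }, numeric(1))
  expect_equal(mean(gcs), 0.5, tolerance = 0.02)
})
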