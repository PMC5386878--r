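test_that("species tree simulation yields rooted binary Yule trees, deterministically", {
  tr <- simulateSpeciesTree(3, seed = 1)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_true(ape::is.rooted(tr) && ape::is.binary(tr))
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(simulateSpeciesTree(8, 1)),
                   ape::write.tree(simulateSpeciesTree(8, 1)))
  expect_error(simulateSpeciesTree(2, 1), "invalid")
  # different seeds give topologically different trees most of the time
  rfs <- vapply(1:40, function(s) {
    normalizedRF(simulateSpeciesTree(8, s), simulateSpeciesTree(8, s + 1000))
  }, numeric(1))
  expect_gt(mean(rfs > 0), 0.8)
})

test_that("gene-tree discordance scales with the number of regraft moves", {
  sp <- simulateSpeciesTree(8, seed = 2)
  expect_equal(normalizedRF(simulateGeneTree(sp, 0, seed = 3), sp), 0)
  moved <- vapply(1:60, function(s) {
    normalizedRF(simulateGeneTree(sp, 1, seed = s), sp)
  }, numeric(1))
  expect_gt(mean(moved > 0), 0.9)
  meanRfn <- vapply(c(0, 1, 3, 5), function(k) {
    mean(vapply(1:40, function(s) {
      normalizedRF(simulateGeneTree(sp, k, seed = s, stream = paste0("mono/", k)), sp)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanRfn) > 0))
  # supports attached and in range
  gt <- simulateGeneTree(sp, 1, seed = 4, support = 90, supportSd = 10)
  supp <- as.numeric(gt$node.label)
  expect_true(all(supp >= 0 & supp <= 100))
})

test_that("simulated coding sequences respect ORF constraints and GC3 control", {
  seqs <- simulateCodingSequences(300, "spX", seed = 5, lengthMeanCodons = 200,
                                  gc3Target = 0.5)
  chars <- as.character(seqs)
  expect_true(all(nchar(chars) %% 3 == 0))
  expect_true(all(substr(chars, 1, 3) == "ATG"))
  stops <- substring(chars, nchar(chars) - 2, nchar(chars))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  expect_true(all(nchar(chars) >= 30))
  internalStops <- vapply(chars, function(s) {
    cod <- lgtaudit:::splitCodons(s)
    any(cod[-length(cod)] %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(internalStops))
  # realized mean GC3 tracks the target
  g3 <- vapply(chars, gc3, numeric(1))
  expect_equal(mean(g3), 0.5, tolerance = 0.03)
  seqs65 <- simulateCodingSequences(300, "spY", seed = 6, lengthMeanCodons = 200,
                                    gc3Target = 0.65)
  expect_equal(mean(vapply(as.character(seqs65), gc3, numeric(1))), 0.65,
               tolerance = 0.03)
  # infeasible target errors out explicitly
  expect_error(simulateCodingSequences(5, "spZ", seed = 7, gc3Target = 0.02),
               "infeasible")
  # determinism
  expect_identical(as.character(simulateCodingSequences(5, "spX", seed = 5)),
                   as.character(simulateCodingSequences(5, "spX", seed = 5)))
})

test_that("sequence randomization keeps frame ends and uniform interior", {
  seqs <- simulateCodingSequences(1, "sp", seed = 8, lengthMeanCodons = 1000,
                                  lengthSdCodons = 0)
  s <- as.character(seqs[[1]])
  r <- randomizeSequence(s, seed = 9)
  expect_equal(nchar(r), nchar(s))
  expect_equal(substr(r, 1, 3), "ATG")
  expect_equal(substring(r, nchar(r) - 2), substring(s, nchar(s) - 2))
  # interior base frequencies approach 1/4 over many randomizations
  freqs <- rowMeans(vapply(1:30, function(i) {
    ri <- randomizeSequence(s, seed = i, stream = "freqcheck")
    interior <- substr(ri, 4, nchar(ri) - 3)
    b <- strsplit(interior, "")[[1]]
    c(mean(b == "A"), mean(b == "C"), mean(b == "G"), mean(b == "T"))
  }, numeric(4)))
  expect_true(all(abs(freqs - 0.25) < 0.01))
  expect_error(randomizeSequence("ATGAAATTT", seed = 1), "stop")
  expect_error(randomizeSequence("ATG", seed = 1), "multiple of 3|>= 6")
})

test_that("planted LGT events modify exactly what the truth records claim", {
  sp <- simulateSpeciesTree(6, seed = 10)
  ids <- sprintf("g%04d", 1:20)
  trees <- lapply(ids, function(g) simulateGeneTree(sp, 0, seed = 10,
                                                    stream = paste0("t/", g)))
  names(trees) <- ids
  seqs <- lapply(sp$tip.label, function(s)
    simulateCodingSequences(20, s, seed = 10, ids = ids))
  names(seqs) <- sp$tip.label
  res <- plantLgt(seqs, trees, donor = "sp06", recipient = "sp01",
                  nEvents = 10, mode = "both", seed = 11)
  expect_equal(nrow(res$truth), 10)
  expect_equal(anyDuplicated(res$truth$gene_id), 0)
  for (g in res$truth$gene_id) {
    # sequence swap: recipient now carries the donor sequence
    expect_identical(as.character(res$sequences$sp01[[g]]),
                     as.character(res$sequences$sp06[[g]]))
    # leaf regraft: donor and recipient form a cherry
    gt <- res$geneTrees[[g]]
    tipIdx <- match(c("sp01", "sp06"), gt$tip.label)
    parents <- gt$edge[match(tipIdx, gt$edge[, 2]), 1]
    expect_equal(parents[1], parents[2])
  }
  # untouched genes keep their sequences
  untouched <- setdiff(ids, res$truth$gene_id)
  expect_identical(as.character(res$sequences$sp01[untouched]),
                   as.character(seqs$sp01[untouched]))
  expect_error(plantLgt(seqs, trees, "sp01", "sp01", 1, "both", 1), "differ")
  expect_error(plantLgt(seqs, trees, "sp06", "sp01", 50, "both", 1), "exceeds")
})

test_that("hit tables round-trip the planted orthology and noise stays one-way", {
  truth <- data.frame(a = sprintf("a%03d", 1:100), b = sprintf("b%03d", 1:100),
                      stringsAsFactors = FALSE)
  clean <- generateHitTable(truth, noiseRate = 0, seed = 1)
  rb <- reciprocalBestHits(bestHits(clean$ab), bestHits(clean$ba))
  expect_identical(rb$a, truth$a)
  expect_identical(rb$b, truth$b)
  # noisy tables never produce reciprocal false positives
  for (s in 1:5) {
    noisy <- generateHitTable(truth, noiseRate = 0.2, seed = s)
    rbn <- reciprocalBestHits(bestHits(noisy$ab), bestHits(noisy$ba))
    expect_true(all(paste(rbn$a, rbn$b) %in% paste(truth$a, truth$b)))
  }
  empty <- generateHitTable(truth[0, ], noiseRate = 0, seed = 1)
  expect_equal(nrow(empty$ab), 0)
  # files parse back identically through the 12-column dialect
  path <- tempfile()
  writeHitTable(clean$ab, path)
  back <- readHitTable(path)
  expect_equal(nrow(back), nrow(clean$ab))
  expect_equal(back$evalue, clean$ab$evalue, tolerance = 1e-12)
})

test_that("leaf shuffling preserves shape and randomizes labels", {
  tr <- ape::rtree(20)
  sh <- shuffleTreeLeaves(tr, seed = 1)
  expect_setequal(sh$tip.label, tr$tip.label)
  expect_identical(sh$edge.length, tr$edge.length)
  expect_identical(sh$edge, tr$edge)
  expect_error(shuffleTreeLeaves(ape::rtree(3), 1), "invalid")
  # caterpillar null: shuffled trees sit near the RFn ceiling
  cat20 <- ape::stree(20, type = "left")
  cat20$edge.length <- rep(1, nrow(cat20$edge))
  rfn <- vapply(1:200, function(i) {
    normalizedRF(shuffleTreeLeaves(cat20, seed = i), cat20)
  }, numeric(1))
  expect_gt(mean(rfn), 0.8)
})

test_that("the assembled dataset is internally consistent and deterministic", {
  cfg <- demoConfig(genes_per_species = 15L, n_lgt_events = 4L)
  sim <- simulateLgtDataset(cfg)
  expect_s4_class(sim, "LgtSimulation")
  expect_length(geneTrees(sim), 15)
  expect_equal(nrow(lgtTruth(sim)), 4)
  expect_setequal(names(speciesSequences(sim)), speciesTree(sim)$tip.label)
  sim2 <- simulateLgtDataset(cfg)
  expect_identical(lapply(geneTrees(sim), ape::write.tree),
                   lapply(geneTrees(sim2), ape::write.tree))
  expect_identical(as.character(speciesSequences(sim)$sp01),
                   as.character(speciesSequences(sim2)$sp01))
})
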