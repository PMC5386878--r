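test_that("model construction validates and scales rates to one", {
  jc <- substitutionModel("JC69")
  Q <- rateMatrix(jc)
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(-sum(jc@baseFreq * diag(Q)), 1, tolerance = 1e-12)
  hky <- substitutionModel("HKY85", kappa = 3, baseFreq = c(0.3, 0.2, 0.3, 0.2))
  Qh <- rateMatrix(hky)
  expect_equal(rowSums(Qh), rep(0, 4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(-sum(hky@baseFreq * diag(Qh)), 1, tolerance = 1e-12)
  # detailed balance and stationarity for the reversible model
  pi <- unname(hky@baseFreq)
  bal <- diag(pi) %*% unname(Qh)
  expect_equal(bal, t(bal), tolerance = 1e-12)
  expect_true(all(abs(pi %*% Qh) < 1e-12))
  expect_error(substitutionModel("HKY85", kappa = -1), "kappa")
})

test_that("alignment evolution honors the closed-form JC divergence", {
  t0 <- ape::read.tree(text = "(A:0,B:0);")
  a0 <- evolveAlignment(t0, 500, seed = 1)
  expect_identical(as.character(a0[["A"]]), as.character(a0[["B"]]))
  t1 <- ape::read.tree(text = "(A:0.05,B:0.05);")
  a1 <- evolveAlignment(t1, 60000, seed = 2)
  m <- do.call(rbind, strsplit(as.character(a1), ""))
  expect_equal(mean(m[1, ] != m[2, ]), 3 / 4 * (1 - exp(-4 * 0.1 / 3)),
               tolerance = 0.01)
  expect_identical(as.character(evolveAlignment(t1, 100, seed = 3)),
                   as.character(evolveAlignment(t1, 100, seed = 3)))
  expect_error(evolveAlignment(ape::read.tree(text = "(A,B);"), 10), "branch")
  # gamma heterogeneity runs and keeps dimensions
  g <- evolveAlignment(t1, 100, substitutionModel("JC69", gammaShape = 0.5),
                       seed = 4)
  expect_equal(unique(nchar(as.character(g))), 100)
})

test_that("pruning likelihood equals closed forms and the exhaustive oracle", {
  # zero-length two-taxon tree: only the root frequency remains
  expect_equal(logLikelihood(c(A = "A", B = "A"),
                             ape::read.tree(text = "(A:0,B:0);")),
               log(1 / 4))
  # two-taxon JC closed form, matching and mismatching site
  d <- 0.07
  tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", d / 2, d / 2))
  expect_equal(logLikelihood(c(A = "A", B = "A"), tr),
               log(1 / 4 * (1 / 4 + 3 / 4 * exp(-4 * d / 3))), tolerance = 1e-12)
  expect_equal(logLikelihood(c(A = "A", B = "C"), tr),
               log(1 / 4 * (1 / 4 - 1 / 4 * exp(-4 * d / 3))), tolerance = 1e-12)
  # exhaustive sum over internal states, JC and HKY, 4-5 taxa
  skipOracle <- FALSE
  set.seed(31)
  for (i in 1:4) {
    nt <- sample(4:5, 1)
    t5 <- ape::rtree(nt)
    t5$edge.length <- runif(nrow(t5$edge), 0.01, 0.6)
    mod <- if (i %% 2) substitutionModel("JC69") else
      substitutionModel("HKY85", kappa = 2.5, baseFreq = c(0.3, 0.2, 0.26, 0.24))
    aln <- evolveAlignment(t5, 40, mod, seed = i, stream = "oracle")
    expect_equal(logLikelihood(aln, t5, mod), unname(oracleLnL(aln, t5, mod)),
                 tolerance = 40 * 1e-9)
  }
  # N treated as full ambiguity
  expect_equal(logLikelihood(c(A = "N", B = "N"), tr), log(1),
               tolerance = 1e-12)
  expect_error(logLikelihood(c(A = "A", B = "-"), tr), "parse")
  expect_error(logLikelihood(c(A = "A"), tr), "missing|leaf")
})

test_that("likelihood is invariant to rerooting under reversible models", {
  set.seed(32)
  t5 <- ape::rtree(5)
  t5$edge.length <- runif(8, 0.05, 0.3)
  mod <- substitutionModel("HKY85", kappa = 2, baseFreq = c(0.28, 0.22, 0.26, 0.24))
  aln <- evolveAlignment(t5, 150, mod, seed = 5)
  vals <- vapply(t5$tip.label, function(o) {
    logLikelihood(aln, ape::root(ape::unroot(t5), o, resolve.root = TRUE), mod)
  }, numeric(1))
  expect_lt(diff(range(vals)), 1e-8)
})

test_that("branch-length optimization ascends and recovers the truth", {
  tr <- ape::unroot(simulateSpeciesTree(5, seed = 33))
  # keep every branch long enough that a 10% relative error is several
  # standard errors at 10,000 sites
  tr$edge.length <- pmax(tr$edge.length * 0.15, 0.05)
  aln <- evolveAlignment(tr, 10000, seed = 6)
  fit <- optimizeBranchLengths(aln, tr)
  expect_true(fit@converged)
  expect_gte(fitLnL(fit), logLikelihood(aln, tr))
  rel <- abs(fitTree(fit)$edge.length - tr$edge.length) / tr$edge.length
  expect_lt(max(rel), 0.10)
  # AIC bookkeeping is exact
  expect_equal(aicOf(fit), 2 * fit@nFreeParameters - 2 * fitLnL(fit))
  expect_equal(fit@nFreeParameters, length(tr$edge.length))
  # zero-variation alignment drives all branches to the lower bound
  flat <- setNames(rep(strrep("A", 60), 5), tr$tip.label)
  fit0 <- optimizeBranchLengths(flat, tr)
  expect_true(all(fitTree(fit0)$edge.length <= 1e-4))
})

test_that("the constrained test is null on identical topologies and bookkeeps AIC", {
  sp <- simulateSpeciesTree(6, seed = 34)
  sp$edge.length <- sp$edge.length * 0.15
  aln <- evolveAlignment(sp, 400, seed = 7)
  cmp <- constrainedTest(aln, sp, sp)
  expect_equal(deltaAic(cmp), 0, tolerance = 2e-4)
  expect_identical(verdict(cmp), "no_signal")
  expect_equal(cmp@aicConstrained - cmp@aicUnconstrained, deltaAic(cmp))
  expect_equal(cmp@internalBranchCount, 3L)  # unrooted 6-taxon topology
  expect_lt(abs(cmp@lnLConstrained - cmp@lnLUnconstrained), 1e-3)
  expect_error(constrainedTest(aln[1:3], sp, sp), "4")
})

test_that("the power experiment reports calibrated rates", {
  expect_error(powerExperiment(0), "invalid")
  tab <- powerExperiment(4, seed = 8, nSpecies = 6, nSites = 600)
  expect_setequal(tab$scenario, c("congruent", "planted_lgt"))
  expect_true(all(tab$rate >= tab$ci_lo - 1e-9 & tab$rate <= tab$ci_hi + 1e-9))
  expect_true(all(tab$n == 4))
  congruent <- tab$rate[tab$scenario == "congruent"]
  expect_lte(congruent, 0.5)
})
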