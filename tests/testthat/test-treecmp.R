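test_that("support collapsing contracts exactly the weak edges", {
  t1 <- ape::read.tree(text = "((a:1,b:1)x:1,(c:1,d:1)y:1)r;")
  t1$node.label <- c("", "100", "100")
  expect_equal(normalizedRF(collapseLowSupport(t1), t1), 0)
  expect_equal(collapseLowSupport(t1)$Nnode, t1$Nnode)
  t1$node.label <- c("", "50", "50")
  star <- collapseLowSupport(t1)
  expect_equal(star$Nnode, 1)
  expect_setequal(star$tip.label, t1$tip.label)
  # support exactly 75 is retained (inclusive)
  t1$node.label <- c("", "75", "74.9")
  kept <- collapseLowSupport(t1)
  expect_equal(kept$Nnode, 2)
  t1$node.label <- NULL
  expect_error(collapseLowSupport(t1), "support")
  t1$node.label <- c("", "90", NA)
  expect_error(collapseLowSupport(t1), "missing")
})

test_that("collapsing a deeper tree keeps leaves and strong bipartitions", {
  sp <- simulateSpeciesTree(10, seed = 3)
  gt <- simulateGeneTree(sp, 2, seed = 4, support = 85, supportSd = 15)
  col <- collapseLowSupport(gt, 75)
  expect_setequal(col$tip.label, gt$tip.label)
  # every surviving bipartition existed before collapsing
  expect_true(all(lgtaudit:::.splitSet(col) %in% lgtaudit:::.splitSet(gt)))
})

test_that("polytomy resolution is binary, deterministic, and idempotent", {
  star <- ape::read.tree(text = "(a,b,c,d);")
  r <- resolvePolytomies(star)
  expect_true(ape::is.binary(r))
  expect_equal(r$Nnode, 3)
  bin <- ape::rtree(6)
  expect_identical(ape::write.tree(resolvePolytomies(bin)), ape::write.tree(bin))
  expect_identical(ape::write.tree(resolvePolytomies(star)),
                   ape::write.tree(resolvePolytomies(star)))
  expect_identical(ape::write.tree(resolvePolytomies(resolvePolytomies(star))),
                   ape::write.tree(resolvePolytomies(star)))
  # seeded random mode is reproducible and binary
  r1 <- resolvePolytomies(star, seed = 7)
  expect_true(ape::is.binary(r1))
  expect_identical(ape::write.tree(resolvePolytomies(star, seed = 7)),
                   ape::write.tree(r1))
  # resolution never destroys an existing bipartition
  multi <- collapseLowSupport(simulateGeneTree(simulateSpeciesTree(8, 5), 1,
                                               seed = 6, support = 70,
                                               supportSd = 20), 75)
  res <- resolvePolytomies(multi)
  expect_true(all(lgtaudit:::.splitSet(multi) %in% lgtaudit:::.splitSet(res)))
})

test_that("normalized RF matches the brute-force bipartition oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(normalizedRF(t1, t1), 0)
  expect_equal(normalizedRF(t1, t2), 1)
  expect_error(normalizedRF(ape::rtree(3), ape::rtree(3)), "4")
  set.seed(12)
  for (i in 1:60) {
    a <- randomRootedTree(8)
    b <- randomRootedTree(8)
    expect_equal(normalizedRF(a, b), oracleRfn(a, b))
  }
  # symmetry and cross-check against an independent library implementation
  a <- randomRootedTree(10); b <- randomRootedTree(10)
  expect_equal(normalizedRF(a, b), normalizedRF(b, a))
  expect_equal(normalizedRF(a, b) * (2 * 10 - 6),
               as.numeric(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))))
})

test_that("unnormalized RF satisfies the triangle inequality on random triples", {
  set.seed(13)
  rfRaw <- function(x, y) {
    sx <- lgtaudit:::.splitSet(x); sy <- lgtaudit:::.splitSet(y)
    length(setdiff(sx, sy)) + length(setdiff(sy, sx))
  }
  for (i in 1:40) {
    t1 <- randomRootedTree(7); t2 <- randomRootedTree(7); t3 <- randomRootedTree(7)
    expect_lte(rfRaw(t1, t3), rfRaw(t1, t2) + rfRaw(t2, t3))
  }
})

test_that("pruning to the shared leaf set is order-independent", {
  set.seed(14)
  a <- randomRootedTree(10, labels = paste0("t", 1:10))
  b <- randomRootedTree(8, labels = paste0("t", 3:10))
  expect_equal(normalizedRF(a, b), normalizedRF(b, a))
})

test_that("bipartition frequencies count compatible gene trees", {
  sp <- simulateSpeciesTree(8, seed = 21)
  same <- lapply(1:6, function(i) sp)
  bf <- bipartitionFrequencies(sp, same)
  expect_true(all(bf$percent == 100))
  # a node present in 2 of 4 discordant-or-not trees scores 50%
  t0 <- ape::read.tree(text = "((a,b),(c,d),e);")
  alt <- ape::read.tree(text = "((a,c),(b,d),e);")
  bf2 <- bipartitionFrequencies(ape::read.tree(text = "(((a,b),(c,d)),e);"),
                                list(t0, t0, alt, alt))
  ab <- bf2[bf2$split %in% c("a;b", "c;d;e"), ]
  expect_true(all(ab$percent == 50))
  # more rearrangements depress the mean frequency
  mk <- function(k) lapply(1:25, function(i)
    simulateGeneTree(sp, k, seed = i, stream = paste0("bf/", k)))
  m1 <- mean(bipartitionFrequencies(sp, mk(1))$percent)
  m4 <- mean(bipartitionFrequencies(sp, mk(4))$percent)
  expect_gt(m1, m4)
  expect_error(bipartitionFrequencies(sp, list()), "invalid")
})

test_that("exact-match fraction recovers the planted mixture", {
  sp <- simulateSpeciesTree(8, seed = 22)
  trees <- c(lapply(1:10, function(i) simulateGeneTree(sp, 0, seed = i)),
             lapply(1:10, function(i)
               simulateGeneTree(sp, 3, seed = i, stream = "mix")))
  frac <- exactMatchFraction(trees, sp)
  expect_gte(frac, 0.5)    # the 3-regraft half almost never matches
  expect_lte(frac, 0.65)
  expect_equal(exactMatchFraction(lapply(1:5, function(i) sp), sp), 1)
  expect_equal(exactMatchFraction(lapply(1:5, function(i)
    simulateGeneTree(sp, 4, seed = i, stream = "nomatch")), sp), 0)
})

test_that("supertree bootstrap recovers concordant branches with high support", {
  sp <- simulateSpeciesTree(7, seed = 23)
  trees <- c(lapply(1:16, function(i) sp),
             lapply(1:4, function(i)
               simulateGeneTree(sp, 2, seed = i, stream = "boot")))
  st <- supertreeBootstrap(trees, nReplicates = 40, seed = 5)
  expect_equal(normalizedRF(st, sp), 0)
  supp <- as.numeric(st$node.label[nzchar(st$node.label)])
  expect_gt(mean(supp), 90)
  # identical inputs give all supports exactly 100
  st2 <- supertreeBootstrap(lapply(1:12, function(i) sp), nReplicates = 20, seed = 1)
  supp2 <- as.numeric(st2$node.label[nzchar(st2$node.label)])
  expect_true(all(supp2 == 100))
  # a single replicate can only produce 0 or 100
  st3 <- supertreeBootstrap(trees, nReplicates = 1, seed = 2)
  supp3 <- as.numeric(st3$node.label[nzchar(st3$node.label)])
  expect_true(all(supp3 %in% c(0, 100)))
  expect_error(supertreeBootstrap(trees[1:5]), "10")
})

test_that("the leaf-shuffle null is reproducible and sits above concordant RFn", {
  sp <- simulateSpeciesTree(8, seed = 24)
  trees <- lapply(1:15, function(i)
    simulateGeneTree(sp, 1, seed = i, stream = "null"))
  obs <- vapply(trees, normalizedRF, numeric(1), treeB = sp)
  null1 <- rfNullDistribution(trees, sp, nShuffles = 2, seed = 9)
  null2 <- rfNullDistribution(trees, sp, nShuffles = 2, seed = 9)
  expect_identical(null1, null2)
  expect_length(null1, 30)
  expect_gt(mean(null1), mean(obs))
})
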