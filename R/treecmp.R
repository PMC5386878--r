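# Topology hygiene and distance statistics: support collapsing, polytomy
# resolution, normalized Robinson-Foulds distance, bipartition frequencies,
# supertree bootstrap, and the leaf-shuffle null.

# Leaf sets descending from every node (indexed by ape node id).
.nodeTipSets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  post <- reorder(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

.splitKey <- function(side, universe) {
  # canonical side: the one NOT containing the overall smallest label
  if (min(universe) %in% side) side <- setdiff(universe, side)
  paste(sort(side), collapse = ";")
}

# Canonical keys of the non-trivial bipartitions of a tree (unrooted view);
# returns a named character vector, names = internal node ids.
.splitSet <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  universe <- tree$tip.label
  sets <- .nodeTipSets(tree)
  root <- ntip + 1L
  keys <- character(0)
  for (nd in setdiff(seq_len(tree$Nnode) + ntip, root)) {
    side <- sets[[nd]]
    if (length(side) >= 2 && length(side) <= ntip - 2) {
      keys[as.character(nd)] <- .splitKey(side, universe)
    }
  }
  keys
}

#' Normalized Robinson-Foulds distance between two trees
#'
#' Both trees are pruned to their shared leaf set, and the symmetric
#' difference of their non-trivial bipartition sets is divided by its
#' maximum (the total number of non-trivial bipartitions in both pruned
#' trees, which accommodates polytomies).  0 means identical topologies,
#' 1 maximal disagreement.
#'
#' @param treeA,treeB `phylo` objects sharing >= 4 leaves.
#' @param outgroup optional leaf label; if present in both trees they are
#'   rooted on it first (the unrooted bipartition set is unchanged).
#' @return RFn in `[0, 1]`.
#' @export
normalizedRF <- function(treeA, treeB, outgroup = NULL) {
  shared <- intersect(treeA$tip.label, treeB$tip.label)
  .assert(length(shared) >= 4, "trees share fewer than 4 leaves (invalid-argument)")
  a <- ape::keep.tip(treeA, shared)
  b <- ape::keep.tip(treeB, shared)
  if (!is.null(outgroup) && outgroup %in% shared) {
    a <- ape::root(a, outgroup, resolve.root = TRUE)
    b <- ape::root(b, outgroup, resolve.root = TRUE)
  }
  sa <- .splitSet(a); sb <- .splitSet(b)
  rf <- length(setdiff(sa, sb)) + length(setdiff(sb, sa))
  maxRF <- length(sa) + length(sb)
  if (maxRF == 0) return(0)
  rf / maxRF
}

#' Collapse poorly supported internal edges
#'
#' Contracts every internal edge whose child-node support is below
#' `threshold` (the conventional bootstrap filter keeps supports >= 75,
#' inclusive), producing polytomies.  The leaf set never changes.  Trees
#' without support values are rejected rather than silently passed through.
#'
#' @param tree a `phylo` whose `node.label` holds supports in `[0, 100]`
#'   (the root label may be empty).
#' @param threshold minimum support retained (default 75, inclusive).
#' @return a `phylo`, possibly multifurcating.
#' @export
collapseLowSupport <- function(tree, threshold = 75) {
  ntip <- length(tree$tip.label)
  .assert(!is.null(tree$node.label), "tree has no support values (missing supports)")
  supp <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  internal <- seq_len(tree$Nnode) + ntip
  nonRoot <- setdiff(internal, root)
  .assert(!anyNA(supp[nonRoot - ntip]),
          "missing or non-numeric support on an internal node")
  drop <- nonRoot[supp[nonRoot - ntip] < threshold]
  if (!length(drop)) return(tree)
  edge <- tree$edge; len <- tree$edge.length
  for (nd in drop) {
    ein <- which(edge[, 2] == nd)
    p <- edge[ein, 1]
    edge[edge[, 1] == nd, 1] <- p
    edge <- edge[-ein, , drop = FALSE]
    if (!is.null(len)) len <- len[-ein]
  }
  keep <- sort(setdiff(unique(edge[, 1]), seq_len(ntip)))
  map <- integer(max(keep))
  map[root] <- ntip + 1L
  map[setdiff(keep, root)] <- ntip + 1L + seq_along(setdiff(keep, root))
  newEdge <- edge
  newEdge[edge > ntip] <- map[edge[edge > ntip]]
  out <- list(edge = newEdge, tip.label = tree$tip.label,
              Nnode = length(keep),
              node.label = tree$node.label[keep - ntip])
  if (!is.null(len)) out$edge.length <- len
  class(out) <- "phylo"
  reorder(out, "cladewise")
}

# Newick with children of every node sorted by their smallest descendant
# label; used for deterministic polytomy resolution.
.sortedNewick <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  lens <- if (is.null(tree$edge.length)) NULL else
    setNames(tree$edge.length, tree$edge[, 2])
  rec <- function(nd) {
    if (nd <= ntip) {
      base <- tree$tip.label[nd]
      m <- base
    } else {
      subs <- lapply(kids[[as.character(nd)]], rec)
      subs <- subs[order(vapply(subs, `[[`, character(1), "min"))]
      base <- paste0("(", paste(vapply(subs, `[[`, character(1), "str"),
                                collapse = ","), ")")
      m <- subs[[1]]$min
    }
    str <- if (!is.null(lens) && as.character(nd) %in% names(lens) &&
               !is.na(lens[as.character(nd)]))
      paste0(base, ":", format(lens[as.character(nd)], digits = 15)) else base
    list(str = str, min = m)
  }
  paste0(rec(ntip + 1L)$str, ";")
}

#' Resolve polytomies into a binary tree
#'
#' Deterministic by default: children of every node are first put in sorted
#' order (by smallest descendant label) and polytomies are then resolved in
#' that order with zero-length branches; `seed > 0` switches to a seeded
#' random resolution order for sensitivity checks.  Idempotent on binary
#' input.
#'
#' @param tree a `phylo`.
#' @param seed 0 for the deterministic canonical order (default), otherwise
#'   a seed for random resolution.
#' @return a binary `phylo`.
#' @export
resolvePolytomies <- function(tree, seed = 0) {
  tree <- ape::collapse.singles(tree)
  if (ape::is.binary(tree)) return(tree)
  if (seed == 0) {
    sorted <- ape::read.tree(text = .sortedNewick(tree))
    ape::multi2di(sorted, random = FALSE)
  } else {
    withSubstream(seed, "resolve_polytomies", ape::multi2di(tree, random = TRUE))
  }
}

#' Frequency of species-tree bipartitions among gene trees
#'
#' For every internal bipartition of the species tree, the percentage of
#' gene trees containing an identical (compatible) bipartition after each
#' gene tree is pruned to its leaves shared with the species tree.  Gene
#' trees with no leaf on one side of a bipartition are not counted for it;
#' bipartitions that become trivial after restriction count as present.
#'
#' @param speciesTree a `phylo`.
#' @param geneTrees list or `multiPhylo` of gene trees sharing >= 4 leaves
#'   with the species tree.
#' @return data.frame with columns `split`, `percent`, `n_present`,
#'   `n_applicable`.
#' @export
bipartitionFrequencies <- function(speciesTree, geneTrees) {
  .assert(length(geneTrees) > 0, "empty gene-tree list (invalid-argument)")
  spUnrooted <- ape::unroot(speciesTree)
  spLeaves <- spUnrooted$tip.label
  sets <- .nodeTipSets(spUnrooted)
  ntip <- length(spLeaves)
  root <- ntip + 1L
  splitSides <- list()
  for (nd in setdiff(seq_len(spUnrooted$Nnode) + ntip, root)) {
    side <- sets[[nd]]
    if (length(side) >= 2 && length(side) <= ntip - 2)
      splitSides[[.splitKey(side, spLeaves)]] <- side
  }
  geneInfo <- lapply(geneTrees, function(gt) {
    shared <- intersect(gt$tip.label, spLeaves)
    if (length(shared) < 4) return(NULL)
    list(shared = shared, splits = .splitSet(ape::keep.tip(gt, shared)))
  })
  geneInfo <- Filter(Negate(is.null), geneInfo)
  .assert(length(geneInfo) > 0, "no gene tree shares >= 4 leaves with the species tree")
  out <- lapply(names(splitSides), function(key) {
    side <- splitSides[[key]]
    pres <- 0L; appl <- 0L
    for (gi in geneInfo) {
      a <- intersect(side, gi$shared)
      b <- setdiff(gi$shared, a)
      if (length(a) < 1 || length(b) < 1) next
      appl <- appl + 1L
      ok <- if (length(a) < 2 || length(b) < 2) TRUE
      else .splitKey(a, gi$shared) %in% gi$splits
      if (ok) pres <- pres + 1L
    }
    data.frame(split = key,
               percent = if (appl > 0) 100 * pres / appl else NA_real_,
               n_present = pres, n_applicable = appl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of gene trees exactly matching the species tree
#'
#' @param geneTrees list or `multiPhylo` of gene trees.
#' @param speciesTree a `phylo`.
#' @param outgroup optional outgroup passed to [normalizedRF()].
#' @return fraction in `[0, 1]` of gene trees with RFn = 0.
#' @export
exactMatchFraction <- function(geneTrees, speciesTree, outgroup = NULL) {
  rfn <- vapply(geneTrees, normalizedRF, numeric(1),
                treeB = speciesTree, outgroup = outgroup)
  mean(rfn == 0)
}

#' Majority-rule consensus supertree with gene-tree bootstrap supports
#'
#' Builds a majority-rule consensus of the gene trees as the supertree, then
#' resamples the gene-tree population with replacement `nReplicates` times,
#' rebuilding the consensus for each sample; each branch's support is the
#' percentage of replicate supertrees containing that branch.
#'
#' @param geneTrees list or `multiPhylo` (>= 10 trees); trees are pruned to
#'   their common leaf set.
#' @param nReplicates number of bootstrap resamples (default 500).
#' @param seed master seed.
#' @return a `phylo` whose `node.label` holds branch supports in `[0, 100]`.
#' @export
supertreeBootstrap <- function(geneTrees, nReplicates = 500, seed = 1) {
  .assert(length(geneTrees) >= 10, "need >= 10 gene trees (invalid-argument)")
  common <- Reduce(intersect, lapply(geneTrees, `[[`, "tip.label"))
  .assert(length(common) >= 4, "gene trees share fewer than 4 leaves")
  trees <- lapply(geneTrees, ape::keep.tip, tip = common)
  class(trees) <- "multiPhylo"
  main <- ape::consensus(trees, p = 0.5, rooted = FALSE)
  repSplits <- withSubstream(seed, "supertree_bootstrap", {
    lapply(seq_len(nReplicates), function(r) {
      idx <- sample.int(length(trees), replace = TRUE)
      sub <- trees[idx]
      class(sub) <- "multiPhylo"
      .splitSet(ape::consensus(sub, p = 0.5, rooted = FALSE))
    })
  })
  mainSplits <- .splitSet(main)
  ntip <- length(main$tip.label)
  labels <- rep("", main$Nnode)
  for (i in seq_along(mainSplits)) {
    nd <- as.integer(names(mainSplits)[i])
    pct <- 100 * mean(vapply(repSplits, function(s) mainSplits[i] %in% s,
                             logical(1)))
    labels[nd - ntip] <- format(pct, digits = 4)
  }
  main$node.label <- labels
  main
}

#' Leaf-shuffle null distribution of RFn
#'
#' For each replicate, every gene tree's leaves are shuffled (shape and
#' branch lengths kept) and its RFn to the species tree recorded, giving a
#' null sample of distances expected from tree shape alone.
#'
#' @param geneTrees list or `multiPhylo` of gene trees (>= 4 leaves each).
#' @param speciesTree a `phylo`.
#' @param nShuffles number of shuffle replicates over the whole set.
#' @param seed master seed.
#' @param outgroup optional outgroup passed to [normalizedRF()].
#' @return numeric vector of pooled null RFn values
#'   (`nShuffles * length(geneTrees)` long).
#' @export
rfNullDistribution <- function(geneTrees, speciesTree, nShuffles = 1, seed = 1,
                               outgroup = NULL) {
  .assert(nShuffles >= 1, "nShuffles must be >= 1")
  unlist(lapply(seq_len(nShuffles), function(r) {
    vapply(seq_along(geneTrees), function(i) {
      sh <- shuffleTreeLeaves(geneTrees[[i]], seed,
                              stream = sprintf("rf_null/%d/%d", r, i))
      normalizedRF(sh, speciesTree, outgroup = outgroup)
    }, numeric(1))
  }))
}
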