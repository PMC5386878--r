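#' Simulate a rooted binary species tree (Yule process)
#'
#' @param nSpecies number of species (>= 3); tips are labeled `sp01`, `sp02`, ...
#' @param seed master seed; the tree is drawn from its own substream.
#' @return a rooted binary `phylo` with positive branch lengths.
#' @export
#' @examples
#' simulateSpeciesTree(8, seed = 1)
simulateSpeciesTree <- function(nSpecies, seed) {
  .assert(nSpecies >= 3, "nSpecies must be >= 3 (invalid-argument)")
  tree <- withSubstream(seed, paste0("species_tree/", nSpecies), {
    ape::rphylo(nSpecies, birth = 1, death = 0)
  })
  tree$tip.label <- sprintf("sp%02d", seq_len(nSpecies))
  tree
}

#' Simulate a gene tree by random prune-and-regraft moves
#'
#' Starts from the species tree (one gene per species) and applies exactly
#' `rearrangements` random subtree-prune-and-regraft (SPR) moves, the single
#' tunable knob for gene-tree/species-tree discordance.  Internal nodes
#' receive bootstrap-style supports (default 100, with optional Gaussian
#' noise truncated to `[0, 100]`).
#'
#' @param speciesTree binary `phylo`.
#' @param rearrangements number of SPR moves (>= 0).
#' @param seed master seed.
#' @param support mean support assigned to internal nodes (default 100).
#' @param supportSd standard deviation of support noise (default 0: all
#'   nodes get exactly `support`).
#' @param stream substream suffix, so each gene gets an independent draw.
#' @return a `phylo` with the same leaf set and `node.label` supports.
#' @export
simulateGeneTree <- function(speciesTree, rearrangements, seed,
                             support = 100, supportSd = 0,
                             stream = "gene_tree") {
  .assert(inherits(speciesTree, "phylo"), "speciesTree must be a phylo")
  .assert(ape::is.binary(speciesTree), "speciesTree must be binary")
  .assert(rearrangements >= 0, "rearrangements must be >= 0")
  withSubstream(seed, stream, {
    tree <- speciesTree
    for (mv in seq_len(rearrangements)) {
      # one move at a time; an occasional degenerate draw is redrawn
      for (attempt in 1:25) {
        cand <- tryCatch(ape::collapse.singles(phangorn::rSPR(tree, moves = 1)),
                         error = function(e) NULL)
        if (!is.null(cand) && ape::is.binary(cand) &&
            length(cand$tip.label) == length(tree$tip.label)) {
          tree <- cand
          break
        }
        cand <- NULL
      }
      .assert(!is.null(cand), "could not apply a regraft move")
    }
    if (!ape::is.rooted(tree)) {
      # SPR can leave a basal trifurcation; re-root deterministically on a
      # leaf edge (the unrooted topology is unchanged)
      tree <- ape::root(tree, outgroup = sort(tree$tip.label)[1],
                        resolve.root = TRUE)
    }
    n <- tree$Nnode
    supp <- if (supportSd > 0) {
      pmin(100, pmax(0, round(rnorm(n, support, supportSd))))
    } else rep(support, n)
    tree$node.label <- as.character(supp)
    tree
  })
}

#' Shuffle the leaf labels of a tree
#'
#' Keeps the unlabeled shape and all branch lengths, permuting only the
#' leaf labels uniformly at random — the null model used to ask whether
#' observed gene-tree/species-tree distances could arise from tree shape
#' alone.
#'
#' @param tree a `phylo` with >= 4 leaves.
#' @param seed master seed.
#' @param stream substream suffix.
#' @return a `phylo` with permuted `tip.label`.
#' @export
shuffleTreeLeaves <- function(tree, seed, stream = "leaf_shuffle") {
  .assert(inherits(tree, "phylo"), "tree must be a phylo")
  .assert(length(tree$tip.label) >= 4, "tree must have >= 4 leaves (invalid-argument)")
  withSubstream(seed, stream, {
    # permute over the sorted label set so the draw does not depend on the
    # tree's internal tip-storage order
    labs <- sort(tree$tip.label)
    perm <- sample(labs)
    tree$tip.label <- perm[match(tree$tip.label, labs)]
    tree
  })
}

# Prune `tip` and re-attach it as the sister of `sister` (midway along the
# sister's pendant edge), producing a (sister, tip) cherry.
regraftLeafAsSister <- function(tree, tip, sister) {
  .assert(all(c(tip, sister) %in% tree$tip.label), "tip and sister must be leaves")
  .assert(tip != sister, "tip and sister must differ")
  pruned <- ape::drop.tip(tree, tip)
  where <- which(pruned$tip.label == sister)
  edge <- which(pruned$edge[, 2] == where)
  len <- if (is.null(pruned$edge.length)) NULL else pruned$edge.length[edge]
  out <- phytools::bind.tip(pruned, tip,
                            edge.length = if (is.null(len)) NULL else len / 2,
                            where = where,
                            position = if (is.null(len)) NULL else len / 2)
  out
}
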