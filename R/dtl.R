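# Parsimony duplication-transfer-loss (DTL) reconciliation of a rooted
# binary gene tree against a rooted binary species tree, undated model
# (transfers may land on any incomparable species branch), with a
# deterministic most-conservative backtracking and the transfer-cost sweep.

#' @rdname costScheme
#' @export
setClass("CostScheme",
         representation(dup = "numeric", transfer = "numeric", loss = "numeric"),
         validity = function(object) {
           if (any(c(object@dup, object@loss) < 0) || object@transfer < 0)
             return("event costs must be >= 0")
           if (!all(is.finite(c(object@dup, object@loss))))
             return("dup and loss costs must be finite")
           TRUE
         })

#' DTL event cost scheme
#'
#' Defaults follow the parsimony reconciliation tools' documented defaults:
#' duplication 2, transfer 3, loss 1.  `transfer = Inf` forbids transfers,
#' reducing the optimum to a pure duplication-loss reconciliation.
#'
#' @param dup,transfer,loss non-negative event costs.
#' @return a `CostScheme`.
#' @export
costScheme <- function(dup = 2, transfer = 3, loss = 1) {
  methods::new("CostScheme", dup = dup, transfer = transfer, loss = loss)
}

setMethod("show", "CostScheme", function(object) {
  cat(sprintf("CostScheme: duplication %g, transfer %g, loss %g\n",
              object@dup, object@transfer, object@loss))
})

#' @rdname reconcile
#' @export
setClass("Reconciliation",
         representation(minCost = "numeric", speciations = "integer",
                        duplications = "integer", transfers = "integer",
                        losses = "integer", mapping = "integer",
                        costs = "CostScheme"),
         validity = function(object) {
           expected <- object@costs@dup * object@duplications +
             object@costs@transfer * object@transfers +
             object@costs@loss * object@losses
           if (object@transfers == 0 && is.infinite(object@costs@transfer))
             expected <- object@costs@dup * object@duplications +
               object@costs@loss * object@losses
           if (abs(object@minCost - expected) > 1e-9)
             return("minCost must equal the cost of the reported scenario")
           TRUE
         })

#' @describeIn reconcile minimum reconciliation cost.
#' @param x a `Reconciliation`.
#' @export
minCost <- function(x) x@minCost

#' @describeIn reconcile named event counts.
#' @export
eventCounts <- function(x) {
  c(speciations = x@speciations, duplications = x@duplications,
    transfers = x@transfers, losses = x@losses)
}

#' @describeIn reconcile TRUE iff the reported optimal scenario contains at
#'   least one transfer.
#' @export
hasTransfer <- function(x) x@transfers >= 1L

setMethod("show", "Reconciliation", function(object) {
  cat(sprintf(paste0("Reconciliation: cost %g (%d speciations, %d duplications, ",
                     "%d transfers, %d losses)\n"),
              object@minCost, object@speciations, object@duplications,
              object@transfers, object@losses))
})

# Species-tree bookkeeping: children, descendants-or-self matrix, edge-count
# distance from each node to its descendants.
.speciesIndex <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  ntip <- length(tree$tip.label)
  kids <- matrix(0L, n, 2)
  for (p in unique(tree$edge[, 1])) {
    ch <- tree$edge[tree$edge[, 1] == p, 2]
    .assert(length(ch) == 2, "species tree must be binary (resolve first)")
    kids[p, ] <- ch
  }
  post <- unique(reorder(tree, "postorder")$edge[, 1])
  postNodes <- c(seq_len(ntip), post) # tips first, then internals children-first
  desc <- matrix(FALSE, n, n)
  depth <- matrix(NA_real_, n, n) # edge count from row (ancestor) to col
  for (s in postNodes) {
    desc[s, s] <- TRUE
    depth[s, s] <- 0
    if (kids[s, 1] > 0) {
      for (c2 in kids[s, ]) {
        desc[s, desc[c2, ]] <- TRUE
        depth[s, desc[c2, ]] <- depth[c2, desc[c2, ]] + 1
      }
    }
  }
  list(n = n, ntip = ntip, kids = kids, post = postNodes, desc = desc,
       depth = depth, root = ntip + 1L)
}

#' Most parsimonious DTL reconciliation
#'
#' Dynamic program over (gene node, species node) in the undated DTL model:
#' a gene node mapped to species `s` is explained by a speciation (children
#' split into the two species subtrees), a duplication (both children stay
#' in the subtree of `s`), or a transfer (one child stays, the other enters
#' a species subtree incomparable to `s`), with losses charged per skipped
#' species edge through an enter-subtree table.  One optimal scenario is
#' reconstructed by deterministic backtracking that prefers speciation over
#' duplication over transfer at equal cost, then the lowest species-node
#' index — the most conservative composition, minimizing spurious transfer
#' calls.
#'
#' @param geneTree rooted binary `phylo`.
#' @param speciesTree rooted binary `phylo`.
#' @param leafMap named character vector gene leaf -> species leaf; by
#'   default gene leaves named `"species|gene"` are mapped to `species`,
#'   and leaves whose label is itself a species leaf map to themselves.
#' @param costs a [costScheme()].
#' @return a `Reconciliation`.
#' @export
reconcile <- function(geneTree, speciesTree, leafMap = NULL,
                      costs = costScheme()) {
  .assert(ape::is.binary(geneTree) && ape::is.rooted(geneTree),
          "gene tree must be rooted and binary (resolve first)")
  .assert(ape::is.binary(speciesTree) && ape::is.rooted(speciesTree),
          "species tree must be rooted and binary (resolve first)")
  if (is.null(leafMap)) {
    leafMap <- setNames(sub("\\|.*$", "", geneTree$tip.label), geneTree$tip.label)
  }
  .assert(all(geneTree$tip.label %in% names(leafMap)),
          "unmapped gene leaf (invalid-argument)")
  sp <- .speciesIndex(speciesTree)
  sigma <- match(leafMap[geneTree$tip.label], speciesTree$tip.label)
  .assert(!anyNA(sigma), "gene leaf mapped to an unknown species (invalid-argument)")

  gtip <- length(geneTree$tip.label)
  gn <- gtip + geneTree$Nnode
  gkids <- matrix(0L, gn, 2)
  for (p in unique(geneTree$edge[, 1])) {
    gkids[p, ] <- geneTree$edge[geneTree$edge[, 1] == p, 2]
  }
  gpost <- c(seq_len(gtip), unique(reorder(geneTree, "postorder")$edge[, 1]))

  BIG <- Inf
  C <- matrix(BIG, gn, sp$n)    # cost with g mapped exactly to s
  IN <- matrix(BIG, gn, sp$n)   # enter above s: min over s' below of C + loss * dist
  CMIN <- matrix(BIG, gn, sp$n) # min of C over the subtree of s (transfer landing)
  OUT <- matrix(BIG, gn, sp$n)  # min of C over species nodes incomparable to s
  EV <- matrix(0L, gn, sp$n)    # event chosen at (g, s): 1 spec, 2 dup, 3 transfer

  spPost <- sp$post
  spPre <- rev(spPost)
  for (g in gpost) {
    if (g <= gtip) {
      C[g, sigma[g]] <- 0
    } else {
      g1 <- gkids[g, 1]; g2 <- gkids[g, 2]
      for (s in spPost) {
        cand <- c(Inf, Inf, Inf) # speciation, duplication, transfer
        if (sp$kids[s, 1] > 0) {
          s1 <- sp$kids[s, 1]; s2 <- sp$kids[s, 2]
          cand[1] <- min(IN[g1, s1] + IN[g2, s2], IN[g1, s2] + IN[g2, s1])
        }
        cand[2] <- costs@dup + IN[g1, s] + IN[g2, s]
        if (is.finite(costs@transfer)) {
          cand[3] <- costs@transfer +
            min(IN[g1, s] + OUT[g2, s], IN[g2, s] + OUT[g1, s])
        }
        C[g, s] <- min(cand)
        EV[g, s] <- which.min(cand) # ties: speciation > duplication > transfer
      }
    }
    for (s in spPost) {
      IN[g, s] <- C[g, s]
      CMIN[g, s] <- C[g, s]
      if (sp$kids[s, 1] > 0) {
        IN[g, s] <- min(IN[g, s],
                        costs@loss + IN[g, sp$kids[s, 1]],
                        costs@loss + IN[g, sp$kids[s, 2]])
        CMIN[g, s] <- min(CMIN[g, s],
                          CMIN[g, sp$kids[s, 1]], CMIN[g, sp$kids[s, 2]])
      }
    }
    OUT[g, sp$root] <- BIG
    for (s in spPre) {
      if (sp$kids[s, 1] > 0) {
        s1 <- sp$kids[s, 1]; s2 <- sp$kids[s, 2]
        OUT[g, s1] <- min(OUT[g, s], CMIN[g, s2])
        OUT[g, s2] <- min(OUT[g, s], CMIN[g, s1])
      }
    }
  }

  groot <- gtip + 1L
  best <- min(C[groot, ])
  .assert(is.finite(best), "reconciliation infeasible under the given costs")
  rootS <- which(C[groot, ] == best)[1] # lowest species index on ties

  # -- backtracking -------------------------------------------------------
  counts <- c(spec = 0L, dup = 0L, transfer = 0L, loss = 0L)
  mapping <- integer(gn)
  # descend the IN chain from s to the species node where C is realized
  resolveIn <- function(g, s) {
    while (IN[g, s] != C[g, s]) {
      k1 <- sp$kids[s, 1]; k2 <- sp$kids[s, 2]
      counts["loss"] <<- counts["loss"] + 1L
      s <- if (k1 > 0 && IN[g, s] == costs@loss + IN[g, k1]) k1 else k2
    }
    s
  }
  walk <- function(g, s) walkAt(g, resolveIn(g, s))
  # g is mapped exactly to s (C[g, s] realized)
  walkAt <- function(g, s) {
    mapping[g] <<- s
    if (g <= gtip) return(invisible())
    g1 <- gkids[g, 1]; g2 <- gkids[g, 2]
    ev <- EV[g, s]
    if (ev == 1L) {
      counts["spec"] <<- counts["spec"] + 1L
      s1 <- sp$kids[s, 1]; s2 <- sp$kids[s, 2]
      if (IN[g1, s1] + IN[g2, s2] <= IN[g1, s2] + IN[g2, s1]) {
        walk(g1, s1); walk(g2, s2)
      } else {
        walk(g1, s2); walk(g2, s1)
      }
    } else if (ev == 2L) {
      counts["dup"] <<- counts["dup"] + 1L
      walk(g1, s); walk(g2, s)
    } else {
      counts["transfer"] <<- counts["transfer"] + 1L
      stay1 <- IN[g1, s] + OUT[g2, s] <= IN[g2, s] + OUT[g1, s]
      stay <- if (stay1) g1 else g2
      move <- if (stay1) g2 else g1
      target <- min(which(!sp$desc[s, ] & !sp$desc[, s] &
                            C[move, ] == OUT[move, s]))
      walk(stay, s); walkAt(move, target)
    }
    invisible()
  }
  walkAt(groot, rootS)

  methods::new("Reconciliation", minCost = best,
               speciations = counts[["spec"]], duplications = counts[["dup"]],
               transfers = counts[["transfer"]], losses = counts[["loss"]],
               mapping = mapping, costs = costs)
}

#' Transfer-cost sweep over a gene-tree set
#'
#' For each transfer cost, the fraction of gene trees whose optimal
#' reconciliation against the species tree contains at least one transfer
#' (duplication and loss costs held at their defaults).  Plotted against
#' cost this reproduces the characteristic inverse-like decay of
#' parsimony-DTL transfer calls.
#'
#' @param geneTrees list or `multiPhylo` of rooted binary gene trees.
#' @param speciesTree rooted binary `phylo`.
#' @param transferCosts vector of transfer costs (default `3:30`).
#' @param dup,loss duplication and loss costs (defaults 2 and 1).
#' @param leafMap optional leaf map passed to [reconcile()].
#' @return data.frame: transfer_cost, n_trees, n_with_transfer, fraction.
#' @export
costSweep <- function(geneTrees, speciesTree, transferCosts = 3:30,
                      dup = 2, loss = 1, leafMap = NULL) {
  .assert(length(geneTrees) >= 1, "need at least one gene tree")
  out <- lapply(transferCosts, function(tc) {
    hits <- vapply(geneTrees, function(gt) {
      hasTransfer(reconcile(gt, speciesTree, leafMap,
                            costScheme(dup = dup, transfer = tc, loss = loss)))
    }, logical(1))
    data.frame(transfer_cost = tc, n_trees = length(hits),
               n_with_transfer = sum(hits), fraction = mean(hits))
  })
  do.call(rbind, out)
}
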