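# Constrained-vs-unconstrained topology test: pruning-algorithm likelihood
# under a nucleotide model, per-branch likelihood optimization on a fixed
# topology, and AIC comparison.

.CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

# alignment -> integer matrix (taxa x sites), 5 = fully ambiguous
.alnMatrix <- function(aln) {
  rows <- if (is.character(aln)) aln else as.character(aln)
  rows <- setNames(toupper(rows), names(rows))
  .assert(!is.null(names(rows)), "alignment rows must be named by taxon")
  .assert(length(unique(nchar(rows))) == 1L, "alignment rows differ in length")
  chars <- strsplit(rows, "", fixed = TRUE)
  bad <- vapply(chars, function(x) any(!x %in% names(.CODE)), logical(1))
  if (any(bad)) {
    stop(sprintf("parse error: non-ACGT/N character in row '%s'",
                 names(rows)[which(bad)[1]]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(chars, function(x) unname(.CODE[x])))
  rownames(m) <- names(rows)
  m
}

# Pattern-compressed pruning-likelihood engine bound to one (alignment,
# topology, model).  Returns a function lnL(edgeLengths, kappa = NULL).
.likelihoodEngine <- function(aln, tree, model) {
  m <- .alnMatrix(aln)
  .assert(all(tree$tip.label %in% rownames(m)),
          "leaf name missing from the alignment (invalid-argument)")
  m <- m[tree$tip.label, , drop = FALSE]
  # pattern compression via an exact base-5 column hash (taxa <= 22 keeps
  # the double exact); larger alignments fall back to string keys
  patt <- if (nrow(m) <= 22) {
    as.vector(crossprod(m, 5^(seq_len(nrow(m)) - 1)))
  } else {
    apply(m, 2, paste, collapse = "\r")
  }
  uniq <- which(!duplicated(patt))
  weights <- as.vector(table(factor(patt, levels = patt[uniq]))[])
  sites <- m[, uniq, drop = FALSE]
  npat <- ncol(sites)
  ntip <- length(tree$tip.label)
  post <- reorder(tree, "postorder")
  edge <- post$edge
  nnode <- ntip + post$Nnode
  # edgeLengths arrive in the caller's original edge order
  edgeOfChild <- integer(nnode)
  edgeOfChild[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parents <- unique(edge[, 1]) # postorder guarantees children first
  childrenOf <- lapply(seq_len(nnode), function(p) edge[edge[, 1] == p, 2])
  root <- edge[nrow(edge), 1]
  eigCached <- .modelEigen(model)
  ones <- rep(1, npat)
  # partials are kept as lists of four per-pattern vectors to keep the hot
  # loop in fast vectorized arithmetic
  function(edgeLengths, kappa = NULL) {
    if (!is.null(kappa) && model@name == "HKY85") {
      mod <- model
      mod@kappa <- kappa
      eig <- .modelEigen(mod)
      pi <- mod@baseFreq
    } else {
      eig <- eigCached
      pi <- model@baseFreq
    }
    partial <- vector("list", nnode)
    logScale <- 0
    for (p in parents) {
      L1 <- L2 <- L3 <- L4 <- NULL
      for (ch in childrenOf[[p]]) {
        P <- .transitionProb(eig, edgeLengths[edgeOfChild[ch]])
        if (ch <= ntip) {
          s <- sites[ch, ] # state 5 (N) -> all-ones partial
          c1 <- c(P[1, ], 1)[s]; c2 <- c(P[2, ], 1)[s]
          c3 <- c(P[3, ], 1)[s]; c4 <- c(P[4, ], 1)[s]
        } else {
          M <- partial[[ch]]
          c1 <- P[1, 1] * M[[1]] + P[1, 2] * M[[2]] + P[1, 3] * M[[3]] + P[1, 4] * M[[4]]
          c2 <- P[2, 1] * M[[1]] + P[2, 2] * M[[2]] + P[2, 3] * M[[3]] + P[2, 4] * M[[4]]
          c3 <- P[3, 1] * M[[1]] + P[3, 2] * M[[2]] + P[3, 3] * M[[3]] + P[3, 4] * M[[4]]
          c4 <- P[4, 1] * M[[1]] + P[4, 2] * M[[2]] + P[4, 3] * M[[3]] + P[4, 4] * M[[4]]
        }
        if (is.null(L1)) {
          L1 <- c1; L2 <- c2; L3 <- c3; L4 <- c4
        } else {
          L1 <- L1 * c1; L2 <- L2 * c2; L3 <- L3 * c3; L4 <- L4 * c4
        }
      }
      sc <- pmax.int(pmax.int(L1, L2), pmax.int(L3, L4))
      sc[sc <= 0] <- 1
      inv <- 1 / sc
      partial[[p]] <- list(L1 * inv, L2 * inv, L3 * inv, L4 * inv)
      logScale <- logScale + sum(weights * log(sc))
    }
    rootL <- partial[[root]]
    siteL <- pi[1] * rootL[[1]] + pi[2] * rootL[[2]] +
      pi[3] * rootL[[3]] + pi[4] * rootL[[4]]
    sum(weights * log(siteL)) + logScale
  }
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Site-independent likelihood under a reversible nucleotide model with the
#' root state drawn at the equilibrium frequencies; identical site patterns
#' are compressed and per-node scaling guards against underflow.
#'
#' @param aln named `DNAStringSet` or character vector (ungapped, equal
#'   lengths; `N` allowed as full ambiguity).
#' @param tree `phylo` with branch lengths; its leaves must all appear in
#'   `aln`.
#' @param model a [substitutionModel()].
#' @return the log-likelihood.
#' @export
logLikelihood <- function(aln, tree, model = substitutionModel("JC69")) {
  .assert(!is.null(tree$edge.length), "tree has no branch lengths (invalid-argument)")
  .assert(all(tree$edge.length >= 0), "negative branch length")
  .likelihoodEngine(aln, tree, model)(tree$edge.length)
}

#' Empirical base frequencies of an alignment
#'
#' @param aln named `DNAStringSet` or character vector.
#' @return length-4 frequency vector (A, C, G, T), summing to 1.
#' @export
empiricalBaseFreq <- function(aln) {
  m <- .alnMatrix(aln)
  counts <- tabulate(m[m != 5L], nbins = 4L)
  setNames(counts / sum(counts), c("A", "C", "G", "T"))
}

#' @rdname optimizeBranchLengths
#' @export
setClass("LikelihoodFit",
         representation(topologyId = "character", lnL = "numeric",
                        tree = "ANY", nFreeParameters = "integer",
                        converged = "logical", model = "character",
                        kappa = "numeric"),
         validity = function(object) {
           if (!inherits(object@tree, "phylo")) return("tree must be a phylo")
           if (!is.finite(object@lnL)) return("lnL must be finite")
           expected <- length(object@tree$edge.length) +
             if (object@model == "HKY85") 4L else 0L
           if (object@nFreeParameters != expected)
             return("nFreeParameters must equal #branches + #model parameters")
           TRUE
         })

#' @describeIn optimizeBranchLengths fitted log-likelihood.
#' @param x a `LikelihoodFit`.
#' @export
fitLnL <- function(x) x@lnL

#' @describeIn optimizeBranchLengths tree with optimized branch lengths.
#' @export
fitTree <- function(x) x@tree

#' @describeIn optimizeBranchLengths AIC = `2k - 2 lnL`.
#' @export
aicOf <- function(x) 2 * x@nFreeParameters - 2 * x@lnL

setMethod("show", "LikelihoodFit", function(object) {
  cat(sprintf("LikelihoodFit [%s, %s]: lnL = %.4f, k = %d, %s\n",
              object@topologyId, object@model, object@lnL,
              object@nFreeParameters,
              if (object@converged) "converged" else "NOT converged"))
})

#' Optimize branch lengths (and rate parameters) on a fixed topology
#'
#' Coordinate-wise univariate maximization: each branch in turn is
#' optimized by Brent's bounded method on `[1e-8, 10]` (and, for HKY85,
#' kappa on a log scale), sweeping in a fixed postorder until the
#' log-likelihood improves by less than `tol` or `maxSweeps` is reached.
#' A proposed branch value is only accepted if it does not decrease the
#' log-likelihood, so the trace is monotone by construction.
#'
#' @param aln alignment as in [logLikelihood()].
#' @param topology `phylo`; existing branch lengths are used as the start
#'   (missing lengths start at 0.1).
#' @param model a [substitutionModel()].
#' @param topologyId label stored in the fit.
#' @param tol convergence tolerance on lnL (default 1e-6).
#' @param maxSweeps maximum optimization sweeps (default 50).
#' @return a `LikelihoodFit`.
#' @export
optimizeBranchLengths <- function(aln, topology, model = substitutionModel("JC69"),
                                  topologyId = "topology", tol = 1e-6,
                                  maxSweeps = 50) {
  lower <- 1e-8; upper <- 10
  lens <- topology$edge.length %||% rep(0.1, nrow(topology$edge))
  lens <- pmin(pmax(lens, lower), upper)
  engine <- .likelihoodEngine(aln, topology, model)
  kappa <- if (model@name == "HKY85") model@kappa else NULL
  cur <- engine(lens, kappa)
  converged <- FALSE
  for (sweep in seq_len(maxSweeps)) {
    prev <- cur
    for (i in seq_along(lens)) {
      # full interval on the first sweep, then refine locally
      lo <- if (sweep == 1) lower else max(lower, lens[i] / 5)
      hi <- if (sweep == 1) upper else min(upper, lens[i] * 5 + 1e-4)
      opt <- optimize(function(x) engine(replace(lens, i, x), kappa),
                      c(lo, hi), maximum = TRUE, tol = 1e-5)
      if (opt$objective > cur) {
        lens[i] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (!is.null(kappa)) {
      opt <- optimize(function(lk) engine(lens, exp(lk)),
                      log(c(0.02, 100)), maximum = TRUE, tol = 1e-6)
      if (opt$objective > cur) {
        kappa <- exp(opt$maximum)
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("branch-length optimization did not converge; returning best so far")
  fitted <- topology
  fitted$edge.length <- lens
  methods::new("LikelihoodFit", topologyId = topologyId, lnL = cur,
               tree = fitted,
               nFreeParameters = length(lens) + model@nParams,
               converged = converged, model = model@name,
               kappa = kappa %||% 1)
}

#' @rdname constrainedTest
#' @export
setClass("AicComparison",
         representation(lnLUnconstrained = "numeric", lnLConstrained = "numeric",
                        aicUnconstrained = "numeric", aicConstrained = "numeric",
                        deltaAic = "numeric", internalBranchCount = "integer",
                        verdict = "character", threshold = "numeric"),
         validity = function(object) {
           if (!identical(object@deltaAic,
                          object@aicConstrained - object@aicUnconstrained))
             return("deltaAic must equal aicConstrained - aicUnconstrained")
           if (!object@verdict %in% c("no_signal", "candidate_lgt"))
             return("verdict must be no_signal or candidate_lgt")
           TRUE
         })

#' @describeIn constrainedTest AIC difference (constrained - unconstrained).
#' @param x an `AicComparison`.
#' @export
deltaAic <- function(x) x@deltaAic

#' @describeIn constrainedTest `"candidate_lgt"` or `"no_signal"`.
#' @export
verdict <- function(x) x@verdict

setMethod("show", "AicComparison", function(object) {
  cat(sprintf(paste0("AicComparison: lnL(unconstrained) = %.3f, ",
                     "lnL(constrained) = %.3f, dAIC = %.3f (threshold %g), ",
                     "%d internal branches -> %s\n"),
              object@lnLUnconstrained, object@lnLConstrained,
              object@deltaAic, object@threshold,
              object@internalBranchCount, object@verdict))
})

#' Constrained-vs-unconstrained topology AIC test for one gene
#'
#' Fits branch lengths on the gene's own (unconstrained) topology and on
#' the species-tree (constrained) topology — both pruned to the gene's taxa
#' and treated unrooted — and compares the two fits by AIC (`2k - 2 lnL`).
#' A gene is a `candidate_lgt` when the constrained fit is worse by more
#' than `deltaThreshold` AIC units.  The number of internal branches of the
#' pruned species topology (the degrees of freedom of the comparison) is
#' reported alongside.
#'
#' @param aln alignment of the gene's taxa.
#' @param geneTopology `phylo`: the unconstrained topology (e.g. an
#'   independently estimated gene tree).
#' @param speciesTopology `phylo`: the species tree.
#' @param model a [substitutionModel()].
#' @param deltaThreshold AIC difference called a candidate (default 10).
#' @return an `AicComparison`.
#' @export
constrainedTest <- function(aln, geneTopology, speciesTopology,
                            model = substitutionModel("JC69"),
                            deltaThreshold = 10) {
  taxa <- intersect(geneTopology$tip.label, speciesTopology$tip.label)
  alnNames <- if (is.character(aln)) names(aln) else names(as.character(aln))
  taxa <- intersect(taxa, alnNames)
  .assert(length(taxa) >= 4, "fewer than 4 shared taxa (invalid-argument)")
  # least-squares starting branch lengths from JC distances speed up the
  # per-branch likelihood sweeps considerably
  bin <- ape::as.DNAbin(Biostrings::DNAStringSet(
    setNames(as.character(aln), alnNames)))
  dm <- as.matrix(ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE))
  dm[!is.finite(dm)] <- 1
  dm <- dm[taxa, taxa]
  prep <- function(tree) {
    tree <- ape::keep.tip(tree, taxa)
    tree$node.label <- NULL
    tree <- ape::unroot(resolvePolytomies(ape::unroot(tree)))
    tree <- phangorn::nnls.phylo(tree, as.matrix(dm))
    tree$edge.length[!is.finite(tree$edge.length) | tree$edge.length < 1e-8] <- 1e-8
    tree
  }
  gene <- prep(geneTopology)
  spec <- prep(speciesTopology)
  fitU <- optimizeBranchLengths(aln, gene, model, topologyId = "unconstrained")
  fitC <- optimizeBranchLengths(aln, spec, model, topologyId = "constrained")
  aicU <- aicOf(fitU); aicC <- aicOf(fitC)
  delta <- aicC - aicU
  nInternal <- nrow(spec$edge) - length(taxa)
  methods::new("AicComparison",
               lnLUnconstrained = fitU@lnL, lnLConstrained = fitC@lnL,
               aicUnconstrained = aicU, aicConstrained = aicC,
               deltaAic = delta, internalBranchCount = as.integer(nInternal),
               verdict = if (delta > deltaThreshold) "candidate_lgt" else "no_signal",
               threshold = deltaThreshold)
}

# NJ topology from JC-corrected distances: the "externally estimated"
# unconstrained gene tree used in the power experiment.
.estimateGeneTopology <- function(aln) {
  bin <- ape::as.DNAbin(Biostrings::DNAStringSet(as.character(aln)))
  d <- ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 0.75) + 0.1
  ape::nj(d)
}

#' Type-I error and power of the constrained-topology AIC test
#'
#' Monte-Carlo experiment: per replicate a Yule species tree is drawn,
#' an alignment is evolved either on the species topology (`congruent`
#' scenario: flags are false positives) or on a topology with the recipient
#' leaf re-grafted next to the most distant donor (`planted_lgt`: flags are
#' true positives); the unconstrained topology is re-estimated from the
#' alignment by neighbor joining and the AIC test applied.  Rates come with
#' exact binomial confidence intervals.
#'
#' @param nReplicates replicates per scenario (>= 1).
#' @param seed master seed.
#' @param nSpecies taxa per tree (default 8).
#' @param nSites alignment length (default 1000).
#' @param branchScale multiplier applied to the Yule branch lengths
#'   (default 0.15, giving desk-scale divergences).
#' @param model a [substitutionModel()].
#' @param deltaThreshold AIC cutoff (default 10).
#' @param scenarios subset of `c("congruent", "planted_lgt")`.
#' @return data.frame: scenario, n, n_flagged, rate, ci_lo, ci_hi.
#' @export
powerExperiment <- function(nReplicates, seed = 1, nSpecies = 8, nSites = 1000,
                            branchScale = 0.15,
                            model = substitutionModel("JC69"),
                            deltaThreshold = 10,
                            scenarios = c("congruent", "planted_lgt")) {
  .assert(nReplicates >= 1, "nReplicates must be >= 1 (invalid-argument)")
  runOne <- function(scenario, r) {
    sp <- simulateSpeciesTree(nSpecies, seed = substreamSeed(seed, sprintf("power/%s/%d", scenario, r)))
    sp$edge.length <- sp$edge.length * branchScale
    trueTree <- sp
    if (scenario == "planted_lgt") {
      D <- ape::cophenetic.phylo(sp)
      ij <- which(D == max(D), arr.ind = TRUE)[1, ]
      trueTree <- regraftLeafAsSister(sp, rownames(D)[ij[1]], colnames(D)[ij[2]])
    }
    aln <- evolveAlignment(trueTree, nSites, model,
                           seed = seed, stream = sprintf("power_aln/%s/%d", scenario, r))
    gene <- .estimateGeneTopology(aln)
    cmp <- constrainedTest(aln, gene, sp, model, deltaThreshold)
    verdict(cmp) == "candidate_lgt"
  }
  out <- lapply(scenarios, function(sc) {
    flags <- vapply(seq_len(nReplicates), function(r) runOne(sc, r), logical(1))
    ci <- binom.test(sum(flags), nReplicates)$conf.int
    data.frame(scenario = sc, n = nReplicates, n_flagged = sum(flags),
               rate = mean(flags), ci_lo = ci[1], ci_hi = ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
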