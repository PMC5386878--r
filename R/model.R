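# Nucleotide substitution models (JC69, HKY85) shared by the alignment
# simulator and the likelihood engine.  Rate matrices are scaled to one
# expected substitution per site per unit branch length.

.NUC <- c("A", "C", "G", "T")

#' @rdname substitutionModel
#' @export
setClass("SubstitutionModel",
         representation(name = "character", kappa = "numeric",
                        baseFreq = "numeric", gammaShape = "numeric",
                        nCategories = "integer", nParams = "integer"),
         validity = function(object) {
           if (!object@name %in% c("JC69", "HKY85")) return("unknown model")
           if (abs(sum(object@baseFreq) - 1) > 1e-12) return("base frequencies must sum to 1")
           if (any(object@baseFreq <= 0)) return("base frequencies must be positive")
           if (object@kappa <= 0) return("kappa must be > 0")
           TRUE
         })

#' Nucleotide substitution model
#'
#' @param name `"JC69"` (equal rates and frequencies) or `"HKY85"`
#'   (transition/transversion ratio `kappa`, arbitrary base frequencies).
#' @param kappa transition/transversion rate ratio (HKY85 only; > 0).
#' @param baseFreq equilibrium frequencies in A, C, G, T order, summing to 1.
#' @param gammaShape optional shape of discrete-gamma rate heterogeneity
#'   used by [evolveAlignment()] (`NA` = homogeneous rates).
#' @param nCategories number of discrete gamma categories.
#' @return a `SubstitutionModel` object.
#' @export
substitutionModel <- function(name = c("JC69", "HKY85"), kappa = 2,
                              baseFreq = rep(0.25, 4), gammaShape = NA_real_,
                              nCategories = 4L) {
  name <- match.arg(name)
  if (name == "JC69") {
    kappa <- 1
    baseFreq <- rep(0.25, 4)
  }
  baseFreq <- setNames(baseFreq / sum(baseFreq), .NUC)
  # free parameters counted for AIC: none for JC69; kappa + 3 frequencies
  # for HKY85 (frequencies are taken from the data)
  nParams <- if (name == "JC69") 0L else 4L
  methods::new("SubstitutionModel", name = name, kappa = kappa,
               baseFreq = baseFreq, gammaShape = as.numeric(gammaShape),
               nCategories = as.integer(nCategories), nParams = nParams)
}

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf("SubstitutionModel %s (kappa = %.3g; pi = %s%s)\n",
              object@name, object@kappa,
              paste(sprintf("%.3f", object@baseFreq), collapse = "/"),
              if (is.na(object@gammaShape)) ""
              else sprintf("; gamma alpha = %.3g x %d categories",
                           object@gammaShape, object@nCategories)))
})

#' @describeIn substitutionModel the scaled 4x4 rate matrix (rows sum to 0,
#'   mean rate 1).
#' @param model a `SubstitutionModel`.
#' @export
rateMatrix <- function(model) {
  pi <- model@baseFreq
  Q <- matrix(0, 4, 4, dimnames = list(.NUC, .NUC))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    k <- if (any(transitions[, 1] == .NUC[i] & transitions[, 2] == .NUC[j]))
      model@kappa else 1
    Q[i, j] <- k * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Spectral decomposition of the reversible rate matrix; P(t) follows by
# exponentiating eigenvalues.
.modelEigen <- function(model) {
  pi <- model@baseFreq
  Q <- rateMatrix(model)
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(U = diag(1 / d) %*% e$vectors,
       Uinv = t(e$vectors) %*% diag(d),
       lambda = e$values)
}

.transitionProb <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve an ungapped alignment along a tree
#'
#' Simulates site-independent nucleotide evolution under the chosen model:
#' the root state is drawn from the equilibrium frequencies and each branch
#' applies its transition matrix `P(t) = exp(Qt)`.  Optional discrete-gamma
#' rate heterogeneity uses category means normalized to 1.
#'
#' @param tree a `phylo` with branch lengths (expected substitutions/site).
#' @param nSites number of sites (>= 1).
#' @param model a [substitutionModel()].
#' @param seed master seed.
#' @param stream substream suffix.
#' @return a named `DNAStringSet`, one ungapped row of length `nSites` per leaf.
#' @export
evolveAlignment <- function(tree, nSites, model = substitutionModel("JC69"),
                            seed = 1, stream = "evolve") {
  .assert(inherits(tree, "phylo"), "tree must be a phylo")
  .assert(!is.null(tree$edge.length), "tree has no branch lengths (invalid-argument)")
  .assert(nSites >= 1, "nSites must be >= 1")
  eig <- .modelEigen(model)
  withSubstream(seed, stream, {
    rates <- if (is.na(model@gammaShape)) rep(1, nSites) else {
      k <- model@nCategories
      cats <- qgamma((seq_len(k) - 0.5) / k, shape = model@gammaShape,
                     rate = model@gammaShape)
      cats <- cats / mean(cats)
      sample(cats, nSites, replace = TRUE)
    }
    uniqRates <- sort(unique(rates))
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    states <- matrix(0L, nnode, nSites)
    root <- ntip + 1L
    states[root, ] <- sample.int(4L, nSites, replace = TRUE, prob = model@baseFreq)
    tr <- reorder(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      len <- tr$edge.length[e]
      childState <- states[par, ]
      if (len > 0) {
        for (r in uniqRates) {
          P <- .transitionProb(eig, len * r)
          for (s in 1:4) {
            idx <- which(states[par, ] == s & rates == r)
            if (length(idx))
              childState[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                            prob = P[s, ])
          }
        }
      }
      states[child, ] <- childState
    }
    rows <- apply(states[seq_len(ntip), , drop = FALSE], 1,
                  function(s) paste(.NUC[s], collapse = ""))
    Biostrings::DNAStringSet(setNames(rows, tree$tip.label))
  })
}
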