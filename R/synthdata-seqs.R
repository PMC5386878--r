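# Coding-sequence simulation: codons are resampled from a per-species usage
# table.  Codon bias concentrates usage on one preferred codon per amino
# acid (softmax); a third-position exponential tilt is solved numerically so
# the realized GC3 matches the requested target.

.thirdIsGC <- function(codons) substr(codons, 3, 3) %in% c("G", "C")

# Per-codon sampling distribution over the 61 sense codons.
# preferred: named character, one codon per multi-codon family (families
# absent default to their first codon).
.codonDistribution <- function(gc3Target = NA, biasStrength = 0, preferred = NULL) {
  fams <- codonFamilies()
  if (is.null(preferred)) preferred <- vapply(fams, `[`, character(1), 1L)
  aaProb <- 1 / length(fams)
  baseW <- lapply(names(fams), function(aa) {
    cod <- fams[[aa]]
    w <- exp(biasStrength * (cod == preferred[[aa]]))
    w / sum(w)
  })
  names(baseW) <- names(fams)
  tilt <- function(theta) {
    q <- unlist(lapply(names(fams), function(aa) {
      cod <- fams[[aa]]
      w <- baseW[[aa]] * ifelse(.thirdIsGC(cod), theta, 1)
      aaProb * w / sum(w)
    }))
    names(q) <- unlist(fams, use.names = FALSE)
    q
  }
  gc3Of <- function(theta) {
    q <- tilt(theta)
    sum(q[.thirdIsGC(names(q))])
  }
  if (is.na(gc3Target)) return(tilt(1))
  .assert(gc3Target >= 0 && gc3Target <= 1, "gc3_target must lie in [0,1]")
  lo <- gc3Of(exp(-25)); hi <- gc3Of(exp(25))
  if (gc3Target < lo || gc3Target > hi) {
    stop(sprintf("gc3_target %.3f infeasible under this codon table (reachable range %.3f-%.3f)",
                 gc3Target, lo, hi), call. = FALSE)
  }
  root <- stats::uniroot(function(lt) gc3Of(exp(lt)) - gc3Target,
                         lower = -25, upper = 25, tol = 1e-10)
  tilt(exp(root$root))
}

#' Simulate ORF-like coding sequences with controlled composition
#'
#' Every gene starts with ATG, ends with a stop codon, contains no internal
#' in-frame stop (interior codons are drawn from a sense-codon usage table),
#' and has its length (in codons) drawn from a normal distribution truncated
#' at 10 codons.  Codon bias concentrates usage on one randomly chosen
#' preferred codon per amino-acid family; the third-position composition is
#' tilted so the expected GC3 equals `gc3Target`.
#'
#' @param n number of genes.
#' @param speciesTag species label, also used to seed the species' preferred
#'   codons.
#' @param seed master seed.
#' @param lengthMeanCodons,lengthSdCodons length distribution in codons.
#' @param gc3Target target GC3 in `[0, 1]`, or `NA` for no third-position
#'   tilt (uniform synonymous usage when `biasStrength = 0`).
#' @param biasStrength codon-bias concentration (>= 0; 0 = no bias).
#' @param gc3Sd per-gene Gaussian jitter of the GC3 target (default 0.04),
#'   emulating the wide within-genome GC3 spread of real genomes; 0
#'   disables it.  Jittered targets are clamped to the feasible range.
#' @param biasSdLog per-gene log-normal spread of the bias strength
#'   (default 0.5), emulating expression-driven codon-bias heterogeneity;
#'   0 gives every gene the same bias.
#' @param ids gene ids (default `g0001`, `g0002`, ...).
#' @param preferred optional named vector (amino acid -> preferred codon);
#'   by default each species draws its own.  Passing one shared vector to
#'   several species emulates the conserved codon preferences of closely
#'   related genomes.
#' @return a named `DNAStringSet`.
#' @export
simulateCodingSequences <- function(n, speciesTag, seed,
                                    lengthMeanCodons = 300, lengthSdCodons = 50,
                                    gc3Target = NA, biasStrength = 0,
                                    gc3Sd = 0.04, biasSdLog = 0.5,
                                    ids = NULL, preferred = NULL) {
  .assert(n >= 1, "n must be >= 1")
  .assert(biasStrength >= 0, "biasStrength must be >= 0")
  ids <- ids %||% sprintf("g%04d", seq_len(n))
  .assert(length(ids) == n, "ids must have length n")
  withSubstream(seed, paste0("codseq/", speciesTag), {
    fams <- codonFamilies()
    if (is.null(preferred)) {
      preferred <- vapply(fams, function(cod) cod[sample.int(length(cod), 1L)],
                          character(1))
    }
    # the species-level target must be feasible; per-gene jitter is clamped
    baseQ <- .codonDistribution(gc3Target, biasStrength, preferred)
    stops <- stopCodons()
    seqs <- vapply(seq_len(n), function(i) {
      q <- baseQ
      if (!is.na(gc3Target) && (gc3Sd > 0 || biasSdLog > 0)) {
        tgt <- min(0.97, max(0.15, rnorm(1, gc3Target, gc3Sd)))
        b <- biasStrength * exp(rnorm(1, 0, biasSdLog))
        q <- tryCatch(.codonDistribution(tgt, b, preferred),
                      error = function(e) baseQ)
      }
      L <- max(10L, as.integer(round(rnorm(1, lengthMeanCodons, lengthSdCodons))))
      interior <- sample(names(q), L - 2L, replace = TRUE, prob = q)
      paste0("ATG", paste(interior, collapse = ""), sample(stops, 1L))
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, ids))
  })
}

#' Randomize a coding sequence, keeping start and stop codons
#'
#' Replaces everything between the first codon (forced to ATG) and the
#' original stop codon with uniform i.i.d. nucleotides.  Used to build
#' random ORF-like null sequences with the same length distribution as real
#' genes.
#'
#' @param seq in-frame coding sequence ending in a stop codon (length >= 6,
#'   multiple of 3).
#' @param seed master seed.
#' @param stream substream suffix.
#' @return a character string of the same length.
#' @export
randomizeSequence <- function(seq, seed, stream = "randomize") {
  seq <- .asSeqChar(seq)
  n <- nchar(seq)
  .assert(n >= 6 && n %% 3 == 0, "length must be >= 6 and a multiple of 3")
  stop <- substr(seq, n - 2, n)
  .assert(stop %in% stopCodons(),
          "input lacks a terminal stop codon (invalid-argument)")
  withSubstream(seed, stream, {
    interior <- sample(c("A", "C", "G", "T"), n - 6L, replace = TRUE)
    paste0("ATG", paste(interior, collapse = ""), stop)
  })
}

#' Plant lateral gene transfer events with ground truth
#'
#' For each planted event the recipient's coding sequence is replaced by the
#' donor's ortholog (`sequence_swap`), and/or the recipient leaf of that
#' gene's tree is pruned and re-grafted as the sister of the donor leaf
#' (`leaf_regraft`).  One truth record is returned per event.
#'
#' @param sequences named list (species -> `DNAStringSet` with shared gene ids).
#' @param geneTrees named list or `multiPhylo` of gene trees (names are gene
#'   ids; tips are species labels).
#' @param donor,recipient species names (must differ and be present).
#' @param nEvents number of events; must not exceed the shared gene set.
#' @param mode one of `"both"`, `"sequence_swap"`, `"leaf_regraft"`.
#' @param seed master seed.
#' @return list with elements `sequences`, `geneTrees`, and `truth`
#'   (data.frame gene_id, donor_species, recipient_species, mode).
#' @export
plantLgt <- function(sequences, geneTrees, donor, recipient, nEvents,
                     mode = c("both", "sequence_swap", "leaf_regraft"), seed) {
  mode <- match.arg(mode)
  .assert(donor != recipient, "donor and recipient must differ (invalid-argument)")
  .assert(all(c(donor, recipient) %in% names(sequences)),
          "donor and recipient must be present in the sequence sets")
  shared <- intersect(names(sequences[[donor]]), names(sequences[[recipient]]))
  .assert(nEvents <= length(shared),
          "nEvents exceeds the available orthologous genes (invalid-argument)")
  genes <- withSubstream(seed, "plant_lgt", sample(shared, nEvents))
  for (g in genes) {
    if (mode %in% c("both", "sequence_swap")) {
      sequences[[recipient]][[g]] <- sequences[[donor]][[g]]
    }
    if (mode %in% c("both", "leaf_regraft")) {
      .assert(g %in% names(geneTrees), "gene tree missing for planted gene")
      hadSupport <- !is.null(geneTrees[[g]]$node.label)
      gt <- regraftLeafAsSister(geneTrees[[g]], recipient, donor)
      # the regrafted placement is treated as fully supported
      if (hadSupport) gt$node.label <- rep("100", gt$Nnode)
      geneTrees[[g]] <- gt
    }
  }
  truth <- data.frame(gene_id = genes,
                      donor_species = donor,
                      recipient_species = recipient,
                      mode = mode,
                      stringsAsFactors = FALSE)
  list(sequences = sequences, geneTrees = geneTrees, truth = truth)
}

#' Generate noisy reciprocal similarity hit tables for one species pair
#'
#' Emits the two directed 12-column tabular hit files (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) implied by a planted ortholog truth set.  Every true pair
#' appears as mutual best hits with E-value well below 1e-5 unless
#' perturbed: with probability `noiseRate` a pair's A->B best hit is stolen
#' by a spurious, strictly one-way decoy hit (so noise can only lose true
#' pairs, never create reciprocal false positives), and an additional weak
#' one-way hit above the E-value threshold is added to exercise filtering.
#'
#' @param truth data.frame with columns `a` and `b` (gene ids in species A
#'   and B); may have zero rows.
#' @param noiseRate perturbation probability in `[0, 1)`.
#' @param seed master seed.
#' @return list of two data.frames, `ab` and `ba`.
#' @export
generateHitTable <- function(truth, noiseRate = 0, seed = 1) {
  .assert(noiseRate >= 0 && noiseRate < 1, "noiseRate must lie in [0, 1)")
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  emptyTab <- function() {
    tab <- c(setNames(rep(list(character(0)), 2), cols[1:2]),
             setNames(rep(list(numeric(0)), 10), cols[3:12]))
    as.data.frame(tab, stringsAsFactors = FALSE)
  }
  if (nrow(truth) == 0) return(list(ab = emptyTab(), ba = emptyTab()))
  withSubstream(seed, "hit_table", {
    n <- nrow(truth)
    row <- function(q, s, evalue, bits) {
      len <- as.integer(round(runif(length(q), 200, 900)))
      data.frame(qseqid = q, sseqid = s,
                 pident = round(runif(length(q), 80, 100), 2),
                 length = len,
                 mismatch = as.integer(round(runif(length(q), 0, 40))),
                 gapopen = as.integer(round(runif(length(q), 0, 5))),
                 qstart = 1L, qend = len, sstart = 1L, send = len,
                 evalue = evalue,
                 bitscore = bits,
                 stringsAsFactors = FALSE)
    }
    ev <- 10^-runif(n, 20, 60)
    bits <- round(runif(n, 200, 900), 1)
    ab <- row(truth$a, truth$b, ev, bits)
    ba <- row(truth$b, truth$a, 10^-runif(n, 20, 60), round(runif(n, 200, 900), 1))
    hit <- runif(n) < noiseRate
    if (any(hit)) {
      for (i in which(hit)) {
        decoy <- truth$b[sample(setdiff(seq_len(n), i), 1L)]
        ab <- rbind(ab, row(truth$a[i], decoy, ev[i] * 1e-5, bits[i] + 50))
      }
      weak <- which(hit)
      ab <- rbind(ab, row(truth$a[weak],
                          truth$b[(weak %% n) + 1L],
                          10^-runif(length(weak), 1, 4.9),
                          round(runif(length(weak), 30, 60), 1)))
    }
    list(ab = ab[order(ab$qseqid, ab$evalue), ],
         ba = ba[order(ba$qseqid, ba$evalue), ])
  })
}
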