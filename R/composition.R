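#' @include codons.R utils-rng.R
NULL

.asSeqChar <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  .assert(is.character(seq) && length(seq) == 1L, "expected a single sequence")
  toupper(seq)
}

.baseCounts <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  c(A = sum(b == "A"), C = sum(b == "C"), G = sum(b == "G"), T = sum(b == "T"))
}

#' GC content of a nucleotide sequence
#'
#' Fraction of G+C among unambiguous bases; `N` (and any other ambiguity
#' code) is excluded from both numerator and denominator.
#'
#' @param seq a nucleotide string, `DNAString`, or length-1 `DNAStringSet`.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' gcContent("ATGC") # 0.5
gcContent <- function(seq) {
  seq <- .asSeqChar(seq)
  .assert(nchar(seq) > 0, "empty sequence")
  n <- .baseCounts(seq)
  tot <- sum(n)
  .assert(tot > 0, "GC content undefined: no unambiguous bases")
  unname((n["G"] + n["C"]) / tot)
}

#' GC content at third codon positions (GC3)
#'
#' @param seq an in-frame nucleotide string (length a multiple of 3).
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' gc3("ATGAAAGGG") # 2/3
gc3 <- function(seq) {
  seq <- .asSeqChar(seq)
  .assert(nchar(seq) %% 3 == 0 && nchar(seq) > 0,
          "sequence length is not a positive multiple of 3 (frame error)")
  thirds <- paste(substring(seq, seq(3L, nchar(seq), 3L), seq(3L, nchar(seq), 3L)),
                  collapse = "")
  gcContent(thirds)
}

# ---------------------------------------------------------------------------
# Codon usage reference table and CAI

#' @rdname codonUsageTable
#' @export
setClass("CodonUsageTable",
         representation(counts = "numeric", w = "numeric", pseudocount = "numeric"),
         validity = function(object) {
           if (!identical(names(object@counts), senseCodons()))
             return("counts must cover the 61 sense codons")
           if (any(object@w <= 0) || any(object@w > 1 + 1e-12))
             return("relative adaptiveness w must lie in (0, 1]")
           fam <- codonFamilies()
           mx <- vapply(fam, function(cod) max(object@w[cod]), numeric(1))
           if (any(abs(mx - 1) > 1e-12))
             return("every amino-acid family must have max(w) == 1")
           TRUE
         })

#' Codon usage reference table with relative adaptiveness weights
#'
#' Counts usage of the 61 sense codons over a set of coding sequences and
#' derives the Sharp & Li relative adaptiveness `w_c = n_c / max(n)` within
#' each synonymous family.  Codons never observed receive a pseudo-count
#' (default 0.5) before the ratio is taken, so `log(w)` is always finite.
#'
#' @param seqs character vector or `DNAStringSet` of in-frame coding sequences.
#' @param pseudocount value substituted for zero counts (default 0.5).
#' @return a `CodonUsageTable` object.
#' @export
codonUsageTable <- function(seqs, pseudocount = 0.5) {
  .assert(length(seqs) > 0, "empty reference set (invalid-argument)")
  counts <- countCodons(seqs)
  .assert(sum(counts) > 0, "reference contains no countable codons (invalid-argument)")
  adj <- counts
  if (any(adj == 0)) adj[adj == 0] <- pseudocount
  w <- adj
  for (cod in codonFamilies()) w[cod] <- adj[cod] / max(adj[cod])
  methods::new("CodonUsageTable", counts = counts, w = w, pseudocount = pseudocount)
}

#' @describeIn codonUsageTable relative adaptiveness vector `w` (named by codon).
#' @param object,x a `CodonUsageTable`.
#' @export
relAdaptiveness <- function(x) x@w

#' @describeIn codonUsageTable raw codon counts.
#' @export
codonCounts <- function(x) x@counts

setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable:", sum(object@counts), "codons counted;",
      sum(object@counts == 0), "zero-count codons (pseudo-count",
      object@pseudocount, ")\n")
})

#' Codon Adaptation Index (Sharp & Li)
#'
#' Geometric mean of the relative adaptiveness `w` of the gene's codons.
#' Stop codons and single-codon families (Met, Trp) are excluded; if no
#' countable codon remains the conventional value 1 is returned.
#'
#' @param seq in-frame coding sequence.
#' @param reference a [codonUsageTable()].
#' @return CAI in `(0, 1]`.
#' @export
cai <- function(seq, reference) {
  .assert(methods::is(reference, "CodonUsageTable"),
          "reference must be a CodonUsageTable (invalid-argument)")
  seq <- .asSeqChar(seq)
  cod <- splitCodons(seq)
  single <- unlist(codonFamilies()[lengths(codonFamilies()) == 1L], use.names = FALSE)
  cod <- cod[cod %in% senseCodons() & !(cod %in% single)]
  if (!length(cod)) return(1)
  exp(mean(log(reference@w[cod])))
}

#' Effective number of codons (Wright's ENC)
#'
#' Wright's statistic `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is
#' the mean codon homozygosity of the synonymous families with degeneracy
#' `k`, each family's homozygosity being `F = (n * sum(p^2) - 1) / (n - 1)`
#' for `n` observed codons with within-family proportions `p`.  Families
#' observed fewer than twice, or with non-positive homozygosity, are
#' skipped; a degeneracy class with no usable family borrows the mean
#' homozygosity of the observed classes.  The result is clamped at 61
#' (uniform synonymous usage); 20 means one codon per amino acid.
#'
#' @param seq in-frame coding sequence (stop codon, if present, is ignored).
#' @return ENC in `[20, 61]`.
#' @export
enc <- function(seq) {
  seq <- .asSeqChar(seq)
  counts <- countCodons(seq)
  fam <- codonFamilies()
  fam <- fam[lengths(fam) > 1L] # Met/Trp contribute the constant 2
  degeneracy <- lengths(fam)
  Fhat <- rep(NA_real_, length(fam))
  for (i in seq_along(fam)) {
    n_c <- counts[fam[[i]]]
    n <- sum(n_c)
    if (n < 2) next
    p <- n_c / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f > 0) Fhat[i] <- f
  }
  classes <- c(2, 3, 4, 6)
  nFam <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  Fbar <- vapply(classes, function(k) {
    vals <- Fhat[degeneracy == k & !is.na(Fhat)]
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
  .assert(any(!is.na(Fbar)), "ENC undefined: no synonymous family observed twice")
  Fbar[is.na(Fbar)] <- mean(Fbar, na.rm = TRUE)
  value <- 2 + sum(nFam / Fbar)
  min(value, 61)
}

#' Overlapping tetranucleotide frequencies
#'
#' Counts the 256 overlapping 4-mers on the given strand (windows containing
#' ambiguity codes are dropped) and normalizes to sum 1.
#'
#' @param seq nucleotide string of length >= 4.
#' @return named numeric vector of length 256, lexicographic order, sum 1.
#' @export
tetranucleotideFrequencies <- function(seq) {
  seq <- .asSeqChar(seq)
  .assert(nchar(seq) >= 4, "sequence shorter than 4 (invalid-argument)")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = 4)
  tot <- sum(counts)
  .assert(tot > 0, "no unambiguous 4-mer window (degenerate input)")
  counts / tot
}

#' Tetranucleotides with the smallest across-gene variance
#'
#' @param tetra matrix of per-gene tetranucleotide frequencies (genes in
#'   rows, 256 named columns), or a [CompositionProfiles] object.
#' @param k number of 4-mers to return (1..256).
#' @return character vector of `k` 4-mers, ties broken lexicographically.
#' @export
selectLowVarianceTetranucs <- function(tetra, k) {
  tetra <- .asTetraMatrix(tetra)
  .assert(nrow(tetra) >= 2, "need at least 2 profiles")
  .assert(k >= 1 && k <= ncol(tetra), "k out of range (invalid-argument)")
  v <- apply(tetra, 2, var)
  colnames(tetra)[order(v, colnames(tetra))][seq_len(k)]
}

#' Tetranucleotides that best separate two gene sets
#'
#' Ranks 4-mers by the absolute standardized mean difference
#' `|mean_a - mean_b| / pooled_sd` between the two sets (a simplified,
#' deterministic stand-in for signature-scanning feature selection).
#'
#' @param tetraA,tetraB per-gene tetranucleotide frequency matrices (or
#'   [CompositionProfiles]) for the two sets.
#' @param k number of 4-mers to return.
#' @return character vector of `k` 4-mers, ties broken lexicographically.
#' @export
selectDiscriminativeTetranucs <- function(tetraA, tetraB, k) {
  a <- .asTetraMatrix(tetraA); b <- .asTetraMatrix(tetraB)
  .assert(nrow(a) >= 1 && nrow(b) >= 1, "both sets must be non-empty")
  .assert(k >= 1 && k <= ncol(a), "k out of range (invalid-argument)")
  na <- nrow(a); nb <- nrow(b)
  va <- if (na > 1) apply(a, 2, var) else rep(0, ncol(a))
  vb <- if (nb > 1) apply(b, 2, var) else rep(0, ncol(b))
  pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / max(na + nb - 2, 1))
  dm <- abs(colMeans(a) - colMeans(b))
  .assert(any(pooled > 0) || any(dm > 0),
          "zero pooled sd and zero difference for every 4-mer (degenerate input)")
  score <- ifelse(pooled > 0, dm / pooled, ifelse(dm > 0, Inf, 0))
  colnames(a)[order(-score, colnames(a))][seq_len(k)]
}

.asTetraMatrix <- function(x) {
  if (methods::is(x, "CompositionProfiles")) x <- tetraMatrix(x)
  .assert(is.matrix(x) && !is.null(colnames(x)), "expected a tetranucleotide matrix")
  x
}

#' Flag genes in the two distribution tails
#'
#' Flags the `floor(alpha * n)` smallest and largest values (rank-based,
#' ties broken by id).  If the two empirical quantiles coincide (no spread)
#' nothing is flagged.
#'
#' @param values named numeric vector (names are gene ids).
#' @param alpha tail mass per side, in `(0, 0.5)`; default 0.025.
#' @return list with `lower`, `upper`, and their union `flagged`.
#' @export
flagTailOutliers <- function(values, alpha = 0.025) {
  .assert(alpha > 0 && alpha < 0.5, "alpha must lie in (0, 0.5) (invalid-argument)")
  n <- length(values)
  ids <- names(values) %||% as.character(seq_len(n))
  m <- floor(alpha * n)
  .assert(m >= 1, sprintf("need at least %d values for alpha = %g", ceiling(1 / alpha), alpha))
  qlo <- unname(quantile(values, alpha, type = 1))
  qhi <- unname(quantile(values, 1 - alpha, type = 1))
  if (qlo >= qhi) {
    return(list(lower = character(0), upper = character(0), flagged = character(0)))
  }
  lower <- ids[order(values, ids)][seq_len(m)]
  upper <- ids[order(-values, ids)][seq_len(m)]
  list(lower = lower, upper = upper, flagged = sort(union(lower, upper)))
}

# ---------------------------------------------------------------------------
# Per-gene profile container

#' @rdname compositionProfiles
#' @export
setClass("CompositionProfiles",
         representation(metrics = "data.frame", tetra = "matrix"),
         validity = function(object) {
           need <- c("gene_id", "species", "gc", "gc3", "cai", "enc")
           if (!all(need %in% names(object@metrics)))
             return("metrics must have columns gene_id, species, gc, gc3, cai, enc")
           if (nrow(object@metrics) != nrow(object@tetra))
             return("metrics and tetra must describe the same genes")
           if (ncol(object@tetra) != 256)
             return("tetra must have 256 columns")
           if (nrow(object@tetra) &&
               any(abs(rowSums(object@tetra) - 1) > 1e-9))
             return("tetranucleotide rows must sum to 1")
           with(object@metrics, {
             if (any(gc < 0 | gc > 1 | gc3 < 0 | gc3 > 1)) return("gc/gc3 out of [0,1]")
             if (any(enc > 61 + 1e-9)) return("enc above 61")
             TRUE
           })
         })

#' Per-gene composition profiles
#'
#' Computes GC, GC3, CAI, ENC and tetranucleotide frequencies for every gene
#' in a coding-sequence set.  Genes with >= 10% ambiguous bases, or whose
#' length is below 6 or not a multiple of 3 (codon metrics undefined), are
#' excluded with a warning.  The CAI reference defaults to the pooled codon
#' usage of the (kept) input set itself.
#'
#' @param seqs named character vector or `DNAStringSet` of coding sequences.
#' @param species species tag stored with every gene.
#' @param reference optional [codonUsageTable()] for CAI (default: built
#'   from `seqs`).
#' @return a `CompositionProfiles` object.
#' @seealso [metricsTable()], [tetraMatrix()], [writeCompositionTsv()]
#' @export
compositionProfiles <- function(seqs, species, reference = NULL) {
  seqs <- setNames(toupper(as.character(seqs)),
                   names(seqs) %||% paste0("gene", seq_along(seqs)))
  nfrac <- 1 - vapply(seqs, function(s) sum(.baseCounts(s)), numeric(1)) / nchar(seqs)
  bad <- nfrac >= 0.10 | nchar(seqs) < 6 | nchar(seqs) %% 3 != 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) excluded (ambiguity fraction >= 10% or out of frame)")
    seqs <- seqs[!bad]
  }
  .assert(length(seqs) > 0, "no usable gene after exclusions")
  if (is.null(reference)) reference <- codonUsageTable(seqs)
  metrics <- data.frame(
    gene_id = names(seqs),
    species = species,
    gc  = vapply(seqs, gcContent, numeric(1)),
    gc3 = vapply(seqs, gc3, numeric(1)),
    cai = vapply(seqs, cai, numeric(1), reference = reference),
    enc = vapply(seqs, enc, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tetra <- t(vapply(seqs, tetranucleotideFrequencies,
                    numeric(256)))
  rownames(tetra) <- names(seqs)
  methods::new("CompositionProfiles", metrics = metrics, tetra = tetra)
}

#' @describeIn compositionProfiles data frame of gene_id, species, gc, gc3, cai, enc.
#' @param x a `CompositionProfiles` object.
#' @export
metricsTable <- function(x) {
  .assert(methods::is(x, "CompositionProfiles"), "not a CompositionProfiles")
  x@metrics
}

#' @describeIn compositionProfiles genes-by-256 tetranucleotide frequency matrix.
#' @export
tetraMatrix <- function(x) {
  .assert(methods::is(x, "CompositionProfiles"), "not a CompositionProfiles")
  x@tetra
}

setMethod("show", "CompositionProfiles", function(object) {
  m <- object@metrics
  cat("CompositionProfiles:", nrow(m), "genes from",
      length(unique(m$species)), "species\n")
  cat(sprintf("  mean GC %.3f  GC3 %.3f  CAI %.3f  ENC %.1f\n",
              mean(m$gc), mean(m$gc3), mean(m$cai), mean(m$enc)))
})

#' Write / read the per-gene metrics table
#'
#' Fixed-header TSV: gene_id, species, gc, gc3, cai, enc, then the 256
#' tetranucleotide columns in lexicographic order.
#'
#' @param profiles a [compositionProfiles()] result.
#' @param path output file.
#' @return `path`, invisibly (`readCompositionTsv` returns a
#'   `CompositionProfiles`).
#' @export
writeCompositionTsv <- function(profiles, path) {
  tab <- cbind(metricsTable(profiles), as.data.frame(tetraMatrix(profiles)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCompositionTsv
#' @export
readCompositionTsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  tetra <- as.matrix(tab[, -(1:6), drop = FALSE])
  rownames(tetra) <- tab$gene_id
  methods::new("CompositionProfiles", metrics = tab[, 1:6], tetra = tetra)
}
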