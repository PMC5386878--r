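# Codon bookkeeping shared by the composition metrics and the sequence
# simulator.  The standard genetic code is taken from Biostrings.

.codonEnv <- new.env(parent = emptyenv())

geneticCode <- function() Biostrings::GENETIC_CODE

stopCodons <- function() names(geneticCode())[geneticCode() == "*"]

senseCodons <- function() names(geneticCode())[geneticCode() != "*"]

# named list: amino acid -> its synonymous codons (sense codons only)
codonFamilies <- function() {
  if (is.null(.codonEnv$families)) {
    gc <- geneticCode()
    gc <- gc[gc != "*"]
    .codonEnv$families <- split(names(gc), gc)
  }
  .codonEnv$families
}

# split an in-frame nucleotide string into codons
splitCodons <- function(seq) {
  n <- nchar(seq)
  .assert(n %% 3 == 0, "sequence length is not a multiple of 3 (frame error)")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# codon counts over the 61 sense codons (stop codons dropped); codons
# containing N or other ambiguity codes are ignored
countCodons <- function(seqs) {
  seqs <- as.character(seqs)
  counts <- setNames(numeric(length(senseCodons())), senseCodons())
  for (s in seqs) {
    cod <- splitCodons(s)
    cod <- cod[cod %in% names(counts)]
    if (length(cod)) {
      tab <- table(cod)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts
}
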