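# Reciprocal best hit (RBBH) orthology from 12-column tabular similarity
# files (the classic blast outfmt-6 dialect).

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12-column tabular hit file
#'
#' Parses the tab-separated pairwise-similarity dialect (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore).  Malformed rows are reported with their line number.
#'
#' @param path file path.
#' @return data.frame with the 12 standard columns.
#' @export
readHitTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    tab <- c(setNames(rep(list(character(0)), 2), .HIT_COLS[1:2]),
             setNames(rep(list(numeric(0)), 10), .HIT_COLS[3:12]))
    return(as.data.frame(tab, stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: expected 12 tab-separated fields, got %d",
                 bad[1], lengths(fields)[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      stop(sprintf("parse error at line %d: non-numeric %s field",
                   which(is.na(v))[1], .HIT_COLS[j]), call. = FALSE)
    }
    out[[.HIT_COLS[j]]] <- v
  }
  out
}

#' @rdname readHitTable
#' @param hits a 12-column hit data.frame.
#' @export
writeHitTable <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Best hit per query under an E-value threshold
#'
#' Multiple HSPs for the same query-subject pair are first collapsed to
#' their best row.  Per query, the subject with the smallest E-value at or
#' below `evalueMax` wins; ties are broken by higher bitscore, then by
#' lexicographic subject id.  Queries with no passing hit are dropped.
#'
#' @param hits data.frame from [readHitTable()] (or a path to one).
#' @param evalueMax inclusive E-value cutoff (default `1e-5`).
#' @return named character vector, query id -> best subject id.
#' @export
bestHits <- function(hits, evalueMax = 1e-5) {
  if (is.character(hits) && length(hits) == 1L) hits <- readHitTable(hits)
  .assert(all(c("qseqid", "sseqid", "evalue", "bitscore") %in% names(hits)),
          "hits must have qseqid, sseqid, evalue, bitscore")
  hits <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  if (!nrow(hits)) return(setNames(character(0), character(0)))
  # best row per (query, subject), then best subject per query
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("qseqid", "sseqid")]), , drop = FALSE]
  hits <- hits[order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid), ,
               drop = FALSE]
  best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  setNames(best$sseqid, best$qseqid)
}

#' Reciprocal best hits between two species
#'
#' A pair `(g1, g2)` is accepted iff `g2` is the best hit of `g1` in the
#' A->B direction and `g1` is the best hit of `g2` in the B->A direction.
#'
#' @param bestAB,bestBA named vectors from [bestHits()].
#' @return data.frame with columns `a` and `b`, sorted by `a`.
#' @export
reciprocalBestHits <- function(bestAB, bestBA) {
  keep <- names(bestAB)[!is.na(bestBA[bestAB]) & bestBA[bestAB] == names(bestAB)]
  out <- data.frame(a = keep, b = unname(bestAB[keep]), stringsAsFactors = FALSE)
  out[order(out$a), , drop = FALSE]
}

#' Assemble reference-anchored ortholog groups
#'
#' One group per reference gene, containing the RBBH partner from every
#' species in which one exists.  Groups covering fewer than `minSpecies`
#' species (reference included) are flagged as too small for tree-based
#' tests.
#'
#' @param referenceSpecies name of the anchor species.
#' @param rbbhMaps named list (other species -> data.frame from
#'   [reciprocalBestHits()] with the reference genes in column `a`).
#' @param minSpecies minimum group size before flagging (default 4).
#' @return data.frame: `ref_gene`, one column per other species (NA where
#'   absent), `n_species`, `too_small`.
#' @export
buildGroups <- function(referenceSpecies, rbbhMaps, minSpecies = 4) {
  .assert(length(rbbhMaps) >= 1, "need at least one RBBH map")
  refGenes <- sort(unique(unlist(lapply(rbbhMaps, `[[`, "a"))))
  out <- data.frame(ref_gene = refGenes, stringsAsFactors = FALSE)
  for (sp in names(rbbhMaps)) {
    mp <- rbbhMaps[[sp]]
    if (anyDuplicated(mp$a)) {
      stop(sprintf("consistency error: reference gene mapped twice in %s", sp),
           call. = FALSE)
    }
    out[[sp]] <- mp$b[match(refGenes, mp$a)]
  }
  out$n_species <- 1L + rowSums(!is.na(as.matrix(out[names(rbbhMaps)])))
  out$too_small <- out$n_species < minSpecies
  attr(out, "reference_species") <- referenceSpecies
  out
}
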