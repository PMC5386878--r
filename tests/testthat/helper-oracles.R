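# Independent brute-force oracles used to pin down expected values.  These
# deliberately re-derive each quantity from first principles, sharing no
# code with the package implementation.

# --- composition ------------------------------------------------------------

# ENC recomputed "spreadsheet style" from a codon string
oracleEnc <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  codons <- codons[gc[codons] != "*" & !is.na(gc[codons])]
  aa <- gc[codons]
  fam <- split(codons, aa)
  famSize <- vapply(names(fam), function(a) sum(gc == a & gc != "*"), numeric(1))
  Fhat <- rep(NA_real_, length(fam))
  for (i in seq_along(fam)) {
    n <- length(fam[[i]])
    if (n < 2) next
    p <- as.numeric(table(fam[[i]])) / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f > 0) Fhat[i] <- f
  }
  classes <- c(2, 3, 4, 6); terms <- c(9, 1, 5, 3)
  Fbar <- sapply(classes, function(k) {
    v <- Fhat[famSize[names(fam)] == k & !is.na(Fhat)]
    if (length(v)) mean(v) else NA
  })
  Fbar[is.na(Fbar)] <- mean(Fbar, na.rm = TRUE)
  min(2 + sum(terms / Fbar), 61)
}

# CAI recomputed in the log domain from a usage table of raw counts
oracleCai <- function(seq, counts) {
  gc <- Biostrings::GENETIC_CODE
  counts[counts == 0] <- 0.5
  w <- counts
  for (a in unique(gc[names(counts)])) {
    idx <- names(counts)[gc[names(counts)] == a]
    w[idx] <- counts[idx] / max(counts[idx])
  }
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  aa <- gc[codons]
  keep <- !is.na(aa) & aa != "*" & !(aa %in% c("M", "W"))
  if (!any(keep)) return(1)
  exp(mean(log(w[codons[keep]])))
}

# --- trees ------------------------------------------------------------------

# bipartition set of a tree as canonical strings, derived by splitting the
# leaf set at every internal edge of the unrooted tree
oracleSplits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  labs <- tree$tip.label
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    below <- ape::extract.clade(tree, child)$tip.label
    if (length(below) < 2 || length(below) > ntip - 2) next
    side <- if (min(labs) %in% below) setdiff(labs, below) else below
    out <- c(out, paste(sort(side), collapse = ";"))
  }
  unique(out)
}

oracleRfn <- function(a, b) {
  shared <- intersect(a$tip.label, b$tip.label)
  a <- ape::keep.tip(a, shared); b <- ape::keep.tip(b, shared)
  sa <- oracleSplits(a); sb <- oracleSplits(b)
  denom <- length(sa) + length(sb)
  if (denom == 0) return(0)
  (length(setdiff(sa, sb)) + length(setdiff(sb, sa))) / denom
}

# --- likelihood -------------------------------------------------------------

# log-likelihood by exhaustive summation over all internal-node state
# assignments (feasible for <= 3 internal nodes)
oracleLnL <- function(aln, tree, model) {
  Q <- rateMatrix(model)
  pi <- model@baseFreq
  P <- lapply(tree$edge.length, function(t) {
    e <- eigen(Q)
    Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  })
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  rows <- if (is.character(aln)) aln else as.character(aln)
  m <- do.call(rbind, strsplit(toupper(rows[tree$tip.label]), ""))
  code <- c(A = 1, C = 2, G = 3, T = 4, N = 5)
  m <- matrix(code[m], nrow(m))
  internals <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  total <- 0
  for (site in seq_len(ncol(m))) {
    siteL <- 0
    for (r in seq_len(nrow(grid))) {
      st <- integer(nnode)
      st[internals] <- grid[r, ]
      pr <- pi[st[ntip + 1]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pr <- pr * if (ch <= ntip) {
          if (m[ch, site] == 5) 1 else P[[e]][st[p], m[ch, site]]
        } else P[[e]][st[p], st[ch]]
      }
      siteL <- siteL + pr
    }
    total <- total + log(siteL)
  }
  total
}

# --- DTL --------------------------------------------------------------------

# minimum DTL cost by enumerating every mapping of internal gene nodes to
# species nodes and costing it from first principles
oracleDtl <- function(geneTree, speciesTree, leafMap, dup, trans, loss) {
  sn <- length(speciesTree$tip.label) + speciesTree$Nnode
  parent <- rep(NA_integer_, sn)
  for (e in seq_len(nrow(speciesTree$edge)))
    parent[speciesTree$edge[e, 2]] <- speciesTree$edge[e, 1]
  ancPath <- lapply(seq_len(sn), function(s) {
    out <- s
    while (!is.na(parent[s])) { s <- parent[s]; out <- c(out, s) }
    out
  })
  isAnc <- function(a, d) a %in% ancPath[[d]]
  edist <- function(a, d) which(ancPath[[d]] == a) - 1L
  gntip <- length(geneTree$tip.label)
  gn <- gntip + geneTree$Nnode
  gkids <- lapply(seq_len(gn), function(p)
    geneTree$edge[geneTree$edge[, 1] == p, 2])
  sigma <- match(leafMap[geneTree$tip.label], speciesTree$tip.label)
  internals <- (gntip + 1):gn
  grid <- as.matrix(expand.grid(rep(list(seq_len(sn)), length(internals))))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    m <- integer(gn); m[seq_len(gntip)] <- sigma; m[internals] <- grid[r, ]
    cost <- 0; ok <- TRUE
    for (g in internals) {
      s <- m[g]; s1 <- m[gkids[[g]][1]]; s2 <- m[gkids[[g]][2]]
      in1 <- isAnc(s, s1); in2 <- isAnc(s, s2)
      cands <- numeric(0)
      if (in1 && in2) {
        sk <- speciesTree$edge[speciesTree$edge[, 1] == s, 2]
        if (length(sk) == 2 &&
            ((isAnc(sk[1], s1) && isAnc(sk[2], s2)) ||
             (isAnc(sk[2], s1) && isAnc(sk[1], s2))))
          cands <- c(cands, loss * (edist(s, s1) - 1) + loss * (edist(s, s2) - 1))
        cands <- c(cands, dup + loss * edist(s, s1) + loss * edist(s, s2))
      } else if (in1 && !isAnc(s2, s)) {
        cands <- c(cands, trans + loss * edist(s, s1))
      } else if (in2 && !isAnc(s1, s)) {
        cands <- c(cands, trans + loss * edist(s, s2))
      }
      if (!length(cands)) { ok <- FALSE; break }
      cost <- cost + min(cands)
    }
    if (ok && cost < best) best <- cost
  }
  best
}

# duplication/loss-only reconciliation by the classic LCA mapping
oracleDlCost <- function(geneTree, speciesTree, leafMap, dup, loss) {
  sn <- length(speciesTree$tip.label) + speciesTree$Nnode
  parent <- rep(NA_integer_, sn)
  for (e in seq_len(nrow(speciesTree$edge)))
    parent[speciesTree$edge[e, 2]] <- speciesTree$edge[e, 1]
  ancPath <- lapply(seq_len(sn), function(s) {
    out <- s
    while (!is.na(parent[s])) { s <- parent[s]; out <- c(out, s) }
    out
  })
  lca <- function(a, b) ancPath[[a]][ancPath[[a]] %in% ancPath[[b]]][1]
  depth <- vapply(seq_len(sn), function(s) length(ancPath[[s]]), numeric(1))
  gntip <- length(geneTree$tip.label)
  gn <- gntip + geneTree$Nnode
  sigma <- match(leafMap[geneTree$tip.label], speciesTree$tip.label)
  mp <- integer(gn); mp[seq_len(gntip)] <- sigma
  post <- unique(reorder(geneTree, "postorder")$edge[, 1])
  gkids <- lapply(seq_len(gn), function(p)
    geneTree$edge[geneTree$edge[, 1] == p, 2])
  dups <- 0; losses <- 0
  for (g in post) {
    c1 <- gkids[[g]][1]; c2 <- gkids[[g]][2]
    mp[g] <- lca(mp[c1], mp[c2])
    isDup <- mp[g] == mp[c1] || mp[g] == mp[c2]
    if (isDup) dups <- dups + 1
    for (ch in c(c1, c2)) {
      d <- depth[mp[ch]] - depth[mp[g]]
      losses <- losses + if (isDup) d else max(d - 1, 0)
    }
  }
  dup * dups + loss * losses
}

# --- misc -------------------------------------------------------------------

randomRootedTree <- function(ntip, labels = paste0("t", seq_len(ntip))) {
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$tip.label <- labels
  tr
}

# partition-identity comparison that ignores label values
samePartition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
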