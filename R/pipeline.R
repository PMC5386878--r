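# End-to-end audit: simulate -> composition -> overlap/cluster -> RBBH ->
# tree comparison -> AIC test -> DTL sweep, with a reproducible manifest.

.writeTsv <- function(x, path, rowNames = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = rowNames)
  path
}

.writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60)
  path
}

.writeTreesTsv <- function(trees, path) {
  txt <- vapply(trees, ape::write.tree, character(1))
  writeLines(paste(names(trees), txt, sep = "\t"), path)
  path
}

.readTreesTsv <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  trees <- lapply(parts, function(p) ape::read.tree(text = p[2]))
  names(trees) <- vapply(parts, `[`, character(1), 1)
  trees
}

#' Score detector flags against the planted truth
#'
#' For each detection method, counts true positives, false positives and
#' false negatives among the genes the method examined.
#'
#' @param flags named list: method -> character vector of flagged gene ids.
#' @param truthIds gene ids of the planted LGT events.
#' @param universes named list: method -> the gene ids the method examined
#'   (truth is intersected with the universe before scoring).
#' @return data.frame: method, n_examined, tp, fp, fn, precision, recall.
#' @export
evaluateAgainstTruth <- function(flags, truthIds, universes) {
  if (is.null(truthIds) || !length(truthIds)) {
    warning("no truth records available: all flags count as false positives")
    truthIds <- character(0)
  }
  out <- lapply(names(flags), function(m) {
    uni <- universes[[m]]
    fl <- intersect(flags[[m]], uni)
    tr <- intersect(truthIds, uni)
    tp <- length(intersect(fl, tr))
    fp <- length(setdiff(fl, tr))
    fn <- length(setdiff(tr, fl))
    data.frame(method = m, n_examined = length(uni), tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full synthetic LGT-detection audit
#'
#' Executes every stage in dependency order, writing plain-text outputs
#' (FASTA, Newick, TSV) plus a JSON run manifest whose per-file digests
#' make reruns verifiable: identical configuration and seed reproduce
#' byte-identical outputs.  With `resume = TRUE` a stage whose outputs all
#' exist is loaded from disk instead of recomputed.
#'
#' @param config configuration list (see [demoConfig()]) or path to a YAML
#'   file of overrides.
#' @param outDir output directory (created if needed).
#' @param resume reuse existing stage outputs (default FALSE).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
runAudit <- function(config = demoConfig(), outDir, resume = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- demoConfig()
  cfg[names(config)] <- config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  manifest <- list(package = "lgtaudit",
                   version = as.character(packageVersion("lgtaudit")),
                   seed = seed, stages = list())
  p <- function(...) file.path(outDir, ...)

  cfgPath <- p("config_resolved.yaml")
  yaml::write_yaml(cfg, cfgPath)
  manifest$config_hash <- unname(md5sum(cfgPath))

  stageFiles <- list()
  note <- function(stage, files) {
    stageFiles[[stage]] <<- files
  }
  done <- function(files) resume && all(file.exists(files))

  ## stage 1: simulate ------------------------------------------------------
  spPath <- p("species_tree.nwk"); gtPath <- p("gene_trees.tsv")
  truthPath <- p("lgt_truth.tsv")
  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  seqPaths <- p(sprintf("seqs_%s.fasta", species))
  simFiles <- c(spPath, gtPath, truthPath, seqPaths)
  if (done(simFiles)) {
    sp <- ape::read.tree(spPath)
    trees <- .readTreesTsv(gtPath)
    truth <- read.table(truthPath, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, colClasses = "character")
    seqs <- lapply(seqPaths, Biostrings::readDNAStringSet)
    names(seqs) <- species
  } else {
    sim <- simulateLgtDataset(cfg)
    sp <- speciesTree(sim); trees <- geneTrees(sim)
    seqs <- speciesSequences(sim); truth <- lgtTruth(sim)
    ape::write.tree(sp, spPath)
    .writeTreesTsv(trees, gtPath)
    .writeTsv(truth, truthPath)
    for (i in seq_along(species)) .writeFasta(seqs[[species[i]]], seqPaths[i])
  }
  note("simulate", simFiles)
  geneIds <- names(trees)
  ref <- cfg$reference_species
  others <- setdiff(species, ref)

  ## stage 2: hit tables ----------------------------------------------------
  hitPaths <- c(p(sprintf("hits_%s_%s.tsv", ref, others)),
                p(sprintf("hits_%s_%s.tsv", others, ref)))
  if (!done(hitPaths)) {
    for (i in seq_along(others)) {
      truthPairs <- data.frame(a = geneIds, b = geneIds,
                               stringsAsFactors = FALSE)
      ht <- generateHitTable(truthPairs, noiseRate = cfg$hit_noise_rate,
                             seed = substreamSeed(seed, paste0("hits/", others[i])))
      writeHitTable(ht$ab, hitPaths[i])
      writeHitTable(ht$ba, hitPaths[length(others) + i])
    }
  }
  note("hit_tables", hitPaths)

  ## stage 3: composition ---------------------------------------------------
  compPaths <- p(sprintf("composition_%s.tsv", species))
  randPath <- p("composition_random.tsv")
  if (done(c(compPaths, randPath))) {
    profiles <- lapply(compPaths, readCompositionTsv)
    names(profiles) <- species
    randProf <- readCompositionTsv(randPath)
  } else {
    profiles <- lapply(species, function(s)
      compositionProfiles(seqs[[s]], s))
    names(profiles) <- species
    for (i in seq_along(species)) writeCompositionTsv(profiles[[i]], compPaths[i])
    randSeqs <- vapply(seq_along(seqs[[ref]]), function(i) {
      randomizeSequence(seqs[[ref]][[i]], seed,
                        stream = paste0("randomize/", names(seqs[[ref]])[i]))
    }, character(1))
    names(randSeqs) <- paste0("rand_", names(seqs[[ref]]))
    randProf <- compositionProfiles(randSeqs, "random")
    writeCompositionTsv(randProf, randPath)
  }
  note("composition", c(compPaths, randPath))

  ## stage 4: overlap + clustering ------------------------------------------
  ovPath <- p("overlap_table.tsv"); clPath <- p("clusters.tsv")
  if (done(c(ovPath, clPath))) {
    overlap <- read.table(ovPath, sep = "\t", header = TRUE, row.names = 1)
    clusters <- read.table(clPath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  } else {
    cmp <- c(profiles[others], list(random = randProf))
    overlap <- overlapTable(profiles[[ref]], cmp)
    .writeTsv(overlap, ovPath, rowNames = TRUE)
    feats <- featureMatrix(profiles[[ref]])
    ms <- clusterModeSeeking(feats)
    db <- clusterDensity(feats, eps = suggestDensityEps(feats))
    clusters <- data.frame(gene_id = metricsTable(profiles[[ref]])$gene_id,
                           modeseek = clusterLabels(ms),
                           density = clusterLabels(db),
                           stringsAsFactors = FALSE)
    .writeTsv(clusters, clPath)
  }
  note("overlap_cluster", c(ovPath, clPath))

  ## stage 5: orthology (RBBH) ----------------------------------------------
  rbbhPath <- p("rbbh_pairs.tsv"); groupPath <- p("ortholog_groups.tsv")
  if (done(c(rbbhPath, groupPath))) {
    groups <- read.table(groupPath, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  } else {
    rbbhMaps <- list()
    pairRows <- list()
    for (i in seq_along(others)) {
      ab <- bestHits(readHitTable(hitPaths[i]), cfg$evalue_max)
      ba <- bestHits(readHitTable(hitPaths[length(others) + i]), cfg$evalue_max)
      rb <- reciprocalBestHits(ab, ba)
      rbbhMaps[[others[i]]] <- rb
      if (nrow(rb)) pairRows[[others[i]]] <- cbind(species = others[i], rb)
    }
    .writeTsv(do.call(rbind, pairRows), rbbhPath)
    groups <- buildGroups(ref, rbbhMaps)
    .writeTsv(groups, groupPath)
  }
  note("orthology", c(rbbhPath, groupPath))

  ## stage 6: tree comparison -----------------------------------------------
  statsPath <- p("tree_stats.tsv"); nullPath <- p("null_rfn.tsv")
  if (done(c(statsPath, nullPath))) {
    treeStats <- read.table(statsPath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    nullRfn <- read.table(nullPath, sep = "\t", header = TRUE)$rfn
  } else {
    cleaned <- lapply(trees, function(gt) {
      resolvePolytomies(collapseLowSupport(gt, cfg$support_min))
    })
    rfn <- vapply(cleaned, normalizedRF, numeric(1), treeB = sp)
    treeStats <- data.frame(gene_id = geneIds,
                            n_leaves = vapply(trees, function(t)
                              length(t$tip.label), integer(1)),
                            rfn = rfn, stringsAsFactors = FALSE)
    .writeTsv(treeStats, statsPath)
    nullRfn <- rfNullDistribution(cleaned, sp, nShuffles = cfg$n_null_shuffles,
                                  seed = seed)
    .writeTsv(data.frame(rfn = nullRfn), nullPath)
  }
  note("treecmp", c(statsPath, nullPath))

  ## stage 7: constrained-topology AIC test ----------------------------------
  aicPath <- p("aic_results.tsv")
  aicGenes <- unique(c(truth$gene_id,
                       setdiff(geneIds, truth$gene_id)))[seq_len(min(cfg$aic_n_genes,
                                                                     length(geneIds)))]
  alnPaths <- p(sprintf("aln_%s.fasta", aicGenes))
  if (done(c(aicPath, alnPaths))) {
    aicTab <- read.table(aicPath, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  } else {
    model <- substitutionModel("JC69")
    rows <- lapply(seq_along(aicGenes), function(i) {
      g <- aicGenes[i]
      gt <- trees[[g]]
      gt$edge.length <- gt$edge.length * cfg$branch_scale
      aln <- evolveAlignment(gt, cfg$aic_n_sites, model, seed = seed,
                             stream = paste0("aic_aln/", g))
      .writeFasta(aln, alnPaths[i])
      est <- .estimateGeneTopology(aln)
      cmpv <- constrainedTest(aln, est, sp, model, cfg$delta_aic)
      data.frame(gene_id = g, planted = g %in% truth$gene_id,
                 lnl_unconstrained = cmpv@lnLUnconstrained,
                 lnl_constrained = cmpv@lnLConstrained,
                 delta_aic = deltaAic(cmpv), verdict = verdict(cmpv),
                 stringsAsFactors = FALSE)
    })
    aicTab <- do.call(rbind, rows)
    .writeTsv(aicTab, aicPath)
  }
  note("aic_test", c(aicPath, alnPaths))

  ## stage 8: DTL sweep -------------------------------------------------------
  dtlPath <- p("dtl_sweep.tsv"); dtlGenePath <- p("dtl_default_cost.tsv")
  if (done(c(dtlPath, dtlGenePath))) {
    sweep <- read.table(dtlPath, sep = "\t", header = TRUE)
    dtlGene <- read.table(dtlGenePath, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  } else {
    rootedTrees <- lapply(trees, function(gt) {
      gt$node.label <- NULL
      resolvePolytomies(gt)
    })
    sweep <- costSweep(rootedTrees, sp, transferCosts = cfg$transfer_costs,
                       dup = cfg$dup_cost, loss = cfg$loss_cost)
    .writeTsv(sweep, dtlPath)
    defCost <- costScheme(cfg$dup_cost, min(cfg$transfer_costs), cfg$loss_cost)
    dtlGene <- data.frame(
      gene_id = geneIds,
      has_transfer = vapply(rootedTrees, function(gt)
        hasTransfer(reconcile(gt, sp, costs = defCost)), logical(1)),
      stringsAsFactors = FALSE)
    .writeTsv(dtlGene, dtlGenePath)
  }
  note("dtl", c(dtlPath, dtlGenePath))

  ## stage 9: detection scoring ----------------------------------------------
  detPath <- p("detection.tsv")
  refMetrics <- metricsTable(profiles[[ref]])
  tailFlags <- unique(unlist(lapply(c("gc", "gc3", "cai", "enc"), function(met) {
    flagTailOutliers(setNames(refMetrics[[met]], refMetrics$gene_id),
                     cfg$tail_alpha)$flagged
  })))
  minority <- function(labels, ids) {
    tab <- table(labels[labels != -1])
    main <- names(tab)[which.max(tab)]
    ids[labels == -1 | labels != main]
  }
  flags <- list(
    composition_tail = tailFlags,
    clustering = minority(clusters$modeseek, clusters$gene_id),
    aic_test = aicTab$gene_id[aicTab$verdict == "candidate_lgt"],
    dtl = dtlGene$gene_id[dtlGene$has_transfer]
  )
  universes <- list(composition_tail = refMetrics$gene_id,
                    clustering = clusters$gene_id,
                    aic_test = aicTab$gene_id,
                    dtl = dtlGene$gene_id)
  detection <- evaluateAgainstTruth(flags, truth$gene_id, universes)
  .writeTsv(detection, detPath)
  note("detection", detPath)

  ## manifest ----------------------------------------------------------------
  manifest$stage_order <- names(stageFiles)
  manifest$stages <- lapply(stageFiles, function(files) {
    as.list(setNames(unname(md5sum(files)), basename(files)))
  })
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
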