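# The synthetic study: a species tree, one gene tree and one ortholog per
# species per gene, per-species composition-controlled coding sequences,
# and planted LGT events with ground truth.

#' @rdname simulateLgtDataset
#' @export
setClass("LgtSimulation",
         representation(speciesTree = "ANY", geneTrees = "list",
                        sequences = "list", truth = "data.frame",
                        config = "list"),
         validity = function(object) {
           if (!inherits(object@speciesTree, "phylo")) return("speciesTree must be a phylo")
           if (!all(vapply(object@geneTrees, inherits, logical(1), "phylo")))
             return("geneTrees must all be phylo")
           sp <- object@speciesTree$tip.label
           if (!all(names(object@sequences) %in% sp))
             return("sequence sets must be named by species")
           if (nrow(object@truth) &&
               !all(object@truth$recipient_species %in% sp))
             return("truth records must reference known species")
           TRUE
         })

#' @describeIn simulateLgtDataset the species tree (`phylo`).
#' @param x an `LgtSimulation`.
#' @export
speciesTree <- function(x) x@speciesTree

#' @describeIn simulateLgtDataset named list of gene trees (tips are species).
#' @export
geneTrees <- function(x) x@geneTrees

#' @describeIn simulateLgtDataset named list (species -> `DNAStringSet`).
#' @export
speciesSequences <- function(x) x@sequences

#' @describeIn simulateLgtDataset planted-event truth records.
#' @export
lgtTruth <- function(x) x@truth

#' @describeIn simulateLgtDataset the resolved simulation configuration.
#' @export
simConfig <- function(x) x@config

setMethod("show", "LgtSimulation", function(object) {
  cat(sprintf(paste0("LgtSimulation: %d species, %d genes/species, ",
                     "%d planted LGT event(s) (%s -> %s), seed %s\n"),
              length(object@speciesTree$tip.label), length(object@geneTrees),
              nrow(object@truth),
              object@config$donor_species %||% "-",
              object@config$recipient_species %||% "-",
              format(object@config$seed)))
})

#' Default demo configuration for the synthetic audit
#'
#' Eight species, 200 orthologous genes per species with species-specific
#' GC3 targets and moderate codon bias, one prune-and-regraft move per gene
#' tree, and ten planted LGT events from the most distant species into the
#' reference.  All thresholds default to the conventional values: E-value
#' 1e-5, bootstrap support 75, tails 2.5%, dAIC 10, transfer costs 3-30.
#'
#' @param ... named overrides of any configuration key.
#' @return named list of configuration values.
#' @export
demoConfig <- function(...) {
  cfg <- list(
    n_species = 8L,
    genes_per_species = 200L,
    length_mean_codons = 300,
    length_sd_codons = 50,
    gc3_targets = c(0.52, 0.55, 0.48, 0.58, 0.50, 0.56, 0.45, 0.60),
    codon_bias_strength = 1.0,
    discordance_rearrangements = 1L,
    support_mean = 95, support_sd = 8,
    n_lgt_events = 10L,
    lgt_mode = "both",
    reference_species = "sp01",
    recipient_species = "sp01",
    donor_species = "sp08",
    evalue_max = 1e-5,
    hit_noise_rate = 0.10,
    support_min = 75,
    tail_alpha = 0.025,
    delta_aic = 10,
    transfer_costs = seq(3L, 30L, by = 3L),
    dup_cost = 2, loss_cost = 1,
    aic_n_genes = 12L,
    aic_n_sites = 500L,
    branch_scale = 0.15,
    n_null_shuffles = 1L,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate the full synthetic study with planted LGT events
#'
#' Generates the species tree, one gene tree per gene (with the configured
#' number of prune-and-regraft moves and noisy supports), per-species
#' coding sequences under species-specific GC3 targets and codon bias, and
#' plants the configured LGT events (sequence swap and/or leaf regraft)
#' from donor to recipient, returning ground-truth records.
#'
#' @param config configuration list, see [demoConfig()].
#' @return an `LgtSimulation`.
#' @export
simulateLgtDataset <- function(config = demoConfig()) {
  cfg <- demoConfig()
  cfg[names(config)] <- config
  seed <- cfg$seed
  sp <- simulateSpeciesTree(cfg$n_species, seed)
  geneIds <- sprintf("g%04d", seq_len(cfg$genes_per_species))
  trees <- lapply(geneIds, function(g) {
    simulateGeneTree(sp, cfg$discordance_rearrangements, seed,
                     support = cfg$support_mean,
                     supportSd = cfg$support_sd,
                     stream = paste0("gene_tree/", g))
  })
  names(trees) <- geneIds
  gc3 <- rep_len(cfg$gc3_targets, cfg$n_species)
  seqs <- lapply(seq_len(cfg$n_species), function(i) {
    simulateCodingSequences(cfg$genes_per_species, sp$tip.label[i], seed,
                            lengthMeanCodons = cfg$length_mean_codons,
                            lengthSdCodons = cfg$length_sd_codons,
                            gc3Target = gc3[i],
                            biasStrength = cfg$codon_bias_strength,
                            ids = geneIds)
  })
  names(seqs) <- sp$tip.label
  truth <- data.frame(gene_id = character(0), donor_species = character(0),
                      recipient_species = character(0), mode = character(0),
                      stringsAsFactors = FALSE)
  if (cfg$n_lgt_events > 0) {
    planted <- plantLgt(seqs, trees, cfg$donor_species, cfg$recipient_species,
                        cfg$n_lgt_events, cfg$lgt_mode, seed)
    seqs <- planted$sequences
    trees <- planted$geneTrees
    truth <- planted$truth
  }
  methods::new("LgtSimulation", speciesTree = sp, geneTrees = trees,
               sequences = seqs, truth = truth, config = cfg)
}
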