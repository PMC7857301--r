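#' Simulation configuration
#'
#' Complete parameter set for one simulation scenario: demography, genome
#' structure, distribution of fitness effects (DFE), dominance model,
#' ecological stochasticity, genetic-rescue settings and run control.
#' Construct with [simulationConfig()] or [loadConfig()]; all fields have
#' defaults reproducing the canine-exome parameterization (20,000 genes of
#' 1500 bp on 38 autosomes, mutation rate 1e-8/bp, deleterious:neutral
#' ratio 2.31:1, hmix dominance, OU carrying capacity with phi = 0.9 and
#' sigma = log10(1.3), Beta(0.5, 8) catastrophes).
#'
#' @slot scenario character; one of `"contraction"`, `"gradual_contraction"`,
#'   `"genetic_rescue"`, `"neutral_ecology"`.
#' @slot demography,genome,dfe,dominance,ecology,rescue,run named lists of
#'   parameters; see [simulationConfig()] for every field and default.
#' @seealso [simulationConfig()], [loadConfig()], [runReplicates()]
#' @export
setClass("SimulationConfig",
  representation(
    scenario  = "character",
    demography = "list",
    genome    = "list",
    dfe       = "list",
    dominance = "list",
    ecology   = "list",
    rescue    = "list",
    run       = "list"
  )
)

#' Genome coordinate map
#'
#' Physical layout of the simulated coding genome: genes of fixed length
#' laid end-to-end within each chromosome (gene k of a chromosome occupies
#' bp ((k-1)*L + 1) .. k*L of that chromosome's coding coordinate). Only
#' coding sequence is represented, so runs of homozygosity are measured on
#' this coding-contiguous coordinate system.
#'
#' @slot genes a [GenomicRanges::GRanges] with one range per gene
#'   (seqnames chr1..chrN, coding-coordinate start/end) and a `gene_id`
#'   metadata column giving the global gene index.
#' @slot geneLength integer, gene length in bp.
#' @slot interGeneRecombRate numeric, recombination fraction between
#'   adjacent genes on the same chromosome.
#' @slot chromGeneCounts integer vector, genes per chromosome.
#' @slot totalCodingBp numeric, n_genes * gene_length_bp.
#' @seealso [buildGenomeMap()]
#' @export
setClass("GenomeMap",
  representation(
    genes = "GRanges",
    geneLength = "integer",
    interGeneRecombRate = "numeric",
    chromGeneCounts = "integer",
    totalCodingBp = "numeric"
  )
)

#' Simulated population
#'
#' A set of diploid individuals plus a carrying capacity, a generation
#' counter and the multiplicative fitness contribution of fixed deleterious
#' mutations. The individual genotypes live in compiled code behind an
#' external pointer; use the accessors ([popSize()], [individualFitness()],
#' [mutationTable()], [getGenotypes()], ...) rather than the slots.
#' Populations cloned from a common ancestor within one replicate share a
#' mutation table, which is what allows migrants to be copied between them.
#'
#' Note the external pointer does not survive serialization; populations
#' are run-time objects, not data to be saved.
#'
#' @slot ptr external pointer to the engine state.
#' @slot label character, population label (e.g. "ancestral", "endangered").
#' @slot map the [GenomeMap-class] the population evolves on.
#' @seealso [newPopulation()], [stepGeneration()], [runBurnIn()]
#' @export
setClass("Population",
  representation(
    ptr = "externalptr",
    label = "character",
    map = "GenomeMap"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- validateConfigParts(object@scenario, object@demography,
                             object@genome, object@dfe, object@dominance,
                             object@ecology, object@rescue, object@run)
  if (length(msg)) msg else TRUE
})

setValidity("GenomeMap", function(object) {
  msg <- character()
  if (sum(object@chromGeneCounts) != length(object@genes))
    msg <- c(msg, "chromGeneCounts must sum to the number of genes")
  if (object@totalCodingBp !=
      length(object@genes) * as.numeric(object@geneLength))
    msg <- c(msg, "totalCodingBp must equal n_genes * gene_length_bp")
  if (length(msg)) msg else TRUE
})
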