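# One-generation update and its phases. Each phase is exposed on its own
# for testing and for building custom scenarios; stepGeneration() chains
# them in the canonical order.

#' Individual absolute fitness
#'
#' Fitness is multiplicative across sites:
#' `w = fixed_load * prod(1 + s)` over homozygous mutations
#' `* prod(1 + h s)` over heterozygous mutations, clamped to `[0, 1]`.
#' A mutation is homozygous when the same mutation id is present on both
#' haplotypes.
#'
#' @param pop a [Population-class].
#' @return numeric vector of fitness values, one per individual.
#' @export
individualFitness <- function(pop) .eng_fitness(pop@ptr)

#' Reproduction phase
#'
#' Every individual, in turn, draws a mate uniformly from the other
#' individuals (selfing excluded; an individual may be chosen as mate
#' repeatedly) and produces one offspring. Each parental gamete is formed
#' by [makeGamete()]-style recombination and then mutated. Offspring join
#' the population with age 0; with fewer than two individuals no offspring
#' are produced.
#'
#' @param pop a [Population-class] (modified in place).
#' @return `pop`, invisibly.
#' @export
reproduce <- function(pop) {
  .eng_reproduce(pop@ptr)
  invisible(pop)
}

#' Catastrophe mortality phase
#'
#' Each individual dies independently with probability `p`.
#'
#' @param pop a [Population-class] (modified in place).
#' @param p per-individual mortality probability in `[0, 1]`.
#' @return `pop`, invisibly.
#' @export
catastropheMortality <- function(pop, p) {
  stopifnot(p >= 0, p <= 1)
  .eng_catastrophe(pop@ptr, as.numeric(p))
  invisible(pop)
}

#' Fixed-mutation pruning phase
#'
#' Removes every mutation present on all 2N haplotypes from the genotypes
#' and folds its fitness factor (1 + s) into the population's fixed load.
#' Neutral fixations are removed with no load change. Idempotent, and
#' exactly fitness-preserving: pruning never changes any individual's w.
#'
#' @param pop a [Population-class] (modified in place).
#' @return `pop`, invisibly.
#' @export
pruneFixed <- function(pop) {
  .eng_prune_fixed(pop@ptr)
  invisible(pop)
}

#' Viability-selection phase
#'
#' Each individual survives an independent Bernoulli trial with probability
#' `min(1, w * K / n_ref)`, the density-dependent rescaling of absolute
#' fitness. `n_ref` is the post-reproduction population size (parents plus
#' offspring); survivors' ages increment.
#'
#' @param pop a [Population-class] (modified in place).
#' @param n_ref reference population size for the K/N rescale; defaults to
#'   the current size.
#' @return `pop`, invisibly.
#' @export
viabilitySelection <- function(pop, n_ref = popSize(pop)) {
  .eng_viability(pop@ptr, as.integer(n_ref))
  invisible(pop)
}

#' Advance one generation
#'
#' Ordered phases: (1) set this generation's carrying capacity; (2)
#' reproduction; (3) catastrophe mortality (fitness-independent, applied to
#' parents and offspring alike); (4) fixed-mutation pruning; (5) viability
#' selection with the K/N ratio computed against the post-reproduction
#' count; (6) generation counter increment. An empty or single-individual
#' result is a valid terminal (extinct) state.
#'
#' @param pop a [Population-class] (modified in place).
#' @param K_next carrying capacity for this generation.
#' @param catastrophe_p per-individual catastrophe mortality probability.
#' @return the surviving population size, invisibly.
#' @export
stepGeneration <- function(pop, K_next = carryingCapacity(pop),
                           catastrophe_p = 0) {
  invisible(.eng_step(pop@ptr, as.integer(K_next), as.numeric(catastrophe_p)))
}

#' Form one gamete from a parent
#'
#' Per chromosome a starting parental haplotype is chosen uniformly;
#' between each pair of adjacent genes the copying haplotype switches with
#' probability `inter_gene_recomb_rate`; chromosomes assort independently
#' (free recombination). There is no recombination within genes.
#'
#' @param pop a [Population-class].
#' @param ind index of the parent individual.
#' @return integer vector of mutation ids (rows of [mutationTable()]).
#' @export
makeGamete <- function(pop, ind) .eng_gamete(pop@ptr, as.integer(ind))

#' Add new mutations to a gamete
#'
#' Draws Poisson(mutation_rate_per_bp * total_coding_bp) new mutations at
#' uniform coding positions, each with a selection coefficient from the
#' DFE and the corresponding dominance coefficient. There is no reverse
#' mutation; repeat hits at one bp are distinct mutations.
#'
#' @param pop a [Population-class] (its mutation table grows).
#' @param haplotype integer vector of mutation ids.
#' @return the mutated haplotype (mutation ids).
#' @export
mutateGamete <- function(pop, haplotype) {
  .eng_mutate_gamete(pop@ptr, as.integer(haplotype))
}
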