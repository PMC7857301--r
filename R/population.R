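# Population construction and accessors. The individual-level state lives
# in compiled code; these wrappers are the supported surface.

#' Create a new population of mutation-free founders
#'
#' @param config a [SimulationConfig-class].
#' @param n number of founder individuals.
#' @param K carrying capacity.
#' @param label population label.
#' @param map optional pre-built [GenomeMap-class] (rebuilt from `config`
#'   when omitted).
#' @return a [Population-class].
#' @export
newPopulation <- function(config, n, K = n, label = "population",
                          map = buildGenomeMap(config)) {
  ptr <- .eng_new(engineParams(config), as.integer(n), as.integer(K))
  new("Population", ptr = ptr, label = label, map = map)
}

#' Build a population from explicit genotypes
#'
#' Intended for constructing small populations with known genotypes (tests,
#' worked examples). `mutations` defines the mutation table; each genotype
#' is a list with integer vectors `h1` and `h2` of row indices into it.
#'
#' @param config a [SimulationConfig-class].
#' @param genotypes list of `list(h1 = ..., h2 = ...)` per individual.
#' @param mutations data.frame with columns `pos` (global coding bp,
#'   1-based), `s`, `h`.
#' @param fixed_load multiplicative fitness contribution of fixed mutations.
#' @param K carrying capacity.
#' @param label population label.
#' @return a [Population-class].
#' @export
populationFromGenotypes <- function(config, genotypes, mutations,
                                    fixed_load = 1, K = length(genotypes),
                                    label = "population") {
  stopifnot(is.list(genotypes),
            all(c("pos", "s", "h") %in% names(mutations)))
  ptr <- .eng_from_genotypes(engineParams(config), genotypes,
                             as.data.frame(mutations),
                             as.numeric(fixed_load), as.integer(K))
  new("Population", ptr = ptr, label = label, map = buildGenomeMap(config))
}

#' Clone a population
#'
#' Deep-copies the individuals; the mutation table is shared with the
#' original so that individuals remain transferable between the two (the
#' mechanism behind source-population splits and translocation).
#'
#' @param pop a [Population-class].
#' @param label label for the clone.
#' @return a new [Population-class].
#' @export
clonePopulation <- function(pop, label = pop@label) {
  new("Population", ptr = .eng_clone(pop@ptr), label = label, map = pop@map)
}

#' Keep a subset of individuals
#'
#' @param pop a [Population-class] (modified in place).
#' @param keep integer indices of individuals to keep (1-based).
#' @return `pop`, invisibly.
#' @export
subsetPopulation <- function(pop, keep) {
  .eng_subset(pop@ptr, as.integer(keep))
  invisible(pop)
}

#' Copy individuals between populations
#'
#' Both populations must descend from one replicate (shared mutation
#' table). The copied individuals receive new ids and age 0 in the
#' destination; the source population is unchanged.
#'
#' @param from,to [Population-class] objects.
#' @param idx indices of individuals in `from` to copy.
#' @return `to`, invisibly.
#' @export
transferIndividuals <- function(from, to, idx) {
  .eng_transfer(from@ptr, to@ptr, as.integer(idx))
  invisible(to)
}

#' @rdname Population-accessors
#' @export
setGeneric("popSize", function(pop) standardGeneric("popSize"))

#' Population accessors
#'
#' @param pop a [Population-class].
#' @param value replacement value.
#' @return `popSize`: number of living individuals; `currentGeneration`:
#'   generation counter; `carryingCapacity`: this generation's realized K;
#'   `fixedLoad`: multiplicative fitness contribution of fixed deleterious
#'   mutations; `individualAges`/`individualIds`: per-individual vectors;
#'   `mutationTable`: data.frame of every mutation ever drawn (id, chrom,
#'   gene, pos, s, h, origin_generation); `getGenotypes`: list of
#'   `list(h1, h2)` mutation-id vectors per individual;
#'   `individualMetrics`: data.frame with per-individual heterozygous-site
#'   and strongly-deleterious-allele counts and fitness.
#' @name Population-accessors
#' @aliases popSize
#' @export
setMethod("popSize", "Population", function(pop) .eng_size(pop@ptr))

#' @rdname Population-accessors
#' @export
setGeneric("currentGeneration", function(pop) standardGeneric("currentGeneration"))

#' @rdname Population-accessors
#' @export
setMethod("currentGeneration", "Population",
          function(pop) .eng_generation(pop@ptr))

#' @rdname Population-accessors
#' @export
setGeneric("carryingCapacity", function(pop) standardGeneric("carryingCapacity"))

#' @rdname Population-accessors
#' @export
setMethod("carryingCapacity", "Population", function(pop) .eng_K(pop@ptr))

#' @rdname Population-accessors
#' @export
setGeneric("carryingCapacity<-",
           function(pop, value) standardGeneric("carryingCapacity<-"))

#' @rdname Population-accessors
#' @export
setMethod("carryingCapacity<-", "Population", function(pop, value) {
  .eng_set_K(pop@ptr, as.integer(value))
  pop
})

#' @rdname Population-accessors
#' @export
setGeneric("fixedLoad", function(pop) standardGeneric("fixedLoad"))

#' @rdname Population-accessors
#' @export
setMethod("fixedLoad", "Population", function(pop) .eng_fixed_load(pop@ptr))

#' @rdname Population-accessors
#' @export
setGeneric("mutationTable", function(pop) standardGeneric("mutationTable"))

#' @rdname Population-accessors
#' @export
setMethod("mutationTable", "Population",
          function(pop) .eng_mutation_table(pop@ptr))

#' @rdname Population-accessors
#' @export
getGenotypes <- function(pop) .eng_genotypes(pop@ptr)

#' @rdname Population-accessors
#' @export
individualAges <- function(pop) .eng_ages(pop@ptr)

#' @rdname Population-accessors
#' @export
individualIds <- function(pop) .eng_ids(pop@ptr)

#' @rdname Population-accessors
#' @export
individualMetrics <- function(pop) .eng_individual_metrics(pop@ptr)

setMethod("show", "Population", function(object) {
  n <- .eng_size(object@ptr)
  cat(sprintf("Population '%s': N=%d, K=%d, generation=%d\n",
              object@label, n, .eng_K(object@ptr),
              .eng_generation(object@ptr)))
  cat(sprintf("  fixed-mutation load %.6g; %d mutations ever drawn\n",
              .eng_fixed_load(object@ptr), .eng_table_size(object@ptr)))
  invisible(NULL)
})
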