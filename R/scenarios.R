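# Scenario orchestration: burn-in, contraction (instantaneous and gradual),
# genetic rescue with source populations, replicate management.
#
# Each replicate derives five independent RNG streams (endangered genetics,
# source genetics, ecology, migrant selection, stats sampling) from its
# replicate seed. Keeping subsystems on separate streams makes, e.g., a
# rescue run with n_translocations = 0 bit-identical to the plain
# contraction under the same master seed.

burnInGenerations <- function(config) {
  if (identical(config@demography$burn_in_mode, "fixed_30000")) 30000L
  else 10L * config@demography$K_ancestral
}

#' Run the ancestral burn-in
#'
#' Evolves a population of mutation-free founders at constant
#' `K = K_ancestral` (no environmental stochasticity, no catastrophes) for
#' `10 * K_ancestral` generations (or 30,000 under `burn_in_mode =
#' "fixed_30000"`), letting segregating variation approach
#' mutation-selection-drift balance. Fixed mutations are retained in the
#' population's fixed load (there is no reverse mutation), so absolute
#' fitness declines slowly throughout. Summary statistics are recorded
#' every 1000 generations and at the final burn-in generation.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer seed (default: replicate 1 of the configured master
#'   seed).
#' @param map optional pre-built [GenomeMap-class].
#' @return a [Population-class] with attribute `"stats"` (the burn-in
#'   GenStats data.frame).
#' @export
runBurnIn <- function(config,
                      seed = deriveReplicateSeed(config@run$master_seed, 1),
                      map = buildGenomeMap(config)) {
  streams <- makeStreams(seed)
  res <- .burnIn(config, map, streams, replicate = 1L)
  attr(res$pop, "stats") <- res$stats
  res$pop
}

makeStreams <- function(replicate_seed) {
  seeds <- deriveStreamSeeds(replicate_seed)
  lapply(seeds, newStream)
}

.burnIn <- function(config, map, streams, replicate) {
  K <- config@demography$K_ancestral
  gens <- burnInGenerations(config)
  pop <- newPopulation(config, n = K, K = K, label = "ancestral", map = map)
  rows <- list()
  for (g in seq_len(gens)) {
    n <- withStream(streams$endangered, stepGeneration(pop, K, 0))
    if (n < 2)
      stop("population went extinct during burn-in (generation ", g,
           "); this should not happen under the configured parameters",
           call. = FALSE)
    if (g %% 1000L == 0L || g == gens) {
      idx <- withStream(streams$stats,
                        sampleForStats(pop, config@run$stats_sample_size))
      rows[[length(rows) + 1L]] <- genStatsRow(pop, idx, replicate, "burn_in")
    }
  }
  list(pop = pop, stats = do.call(rbind, rows))
}

sourceSpec <- function(config) {
  switch(config@rescue$source_kind,
    K10000 = list(K = config@demography$K_ancestral, isolation = 0L,
                  label = "K10000"),
    K1000_1000gen = list(K = 1000L, isolation = 1000L, label = "K1000_1000gen"),
    K100_100gen = list(K = 100L, isolation = 100L, label = "K100_100gen"),
    K25_10gen = list(K = 25L, isolation = 10L, label = "K25_10gen"))
}

#' Split off and age a source population for genetic rescue
#'
#' The source is a copy-split of the burn-in ancestral population,
#' downsampled to its carrying capacity and evolved at constant K (no
#' endangered-population ecology) for its pre-contraction isolation time:
#' K = 10,000 (the ancestral population continuing unchanged), K = 1000
#' for 1000 generations, K = 100 for 100 generations, or K = 25 for 10
#' generations. After the contraction the source keeps evolving in
#' parallel with the endangered population until translocation.
#'
#' @param config a [SimulationConfig-class] whose `rescue$source_kind`
#'   selects the source demography.
#' @param ancestral the burn-in [Population-class].
#' @return a [Population-class] labelled with the source kind.
#' @export
prepareSourcePopulation <- function(config, ancestral) {
  spec <- sourceSpec(config)
  if (identical(config@rescue$source_kind, "K10000")) {
    src <- ancestral
    src@label <- spec$label
    return(src)
  }
  if (spec$K > popSize(ancestral))
    stop("source carrying capacity exceeds the ancestral population size",
         call. = FALSE)
  src <- clonePopulation(ancestral, label = spec$label)
  subsetPopulation(src, sample.int(popSize(src), spec$K))
  carryingCapacity(src) <- spec$K
  for (g in seq_len(spec$isolation)) {
    if (stepGeneration(src, spec$K, 0) < 2)
      stop("source population went extinct during isolation", call. = FALSE)
  }
  src
}

#' Select migrants from a source population
#'
#' Strategies: `"random"` (uniform without replacement),
#' `"min_strong_load"` (the n individuals carrying the fewest strongly
#' deleterious allele copies, s < -0.01, heterozygous = 1 and homozygous =
#' 2), `"max_heterozygosity"` (the n individuals with the most heterozygous
#' sites). Screening ties are broken by lower individual id, so selection
#' is deterministic given the population.
#'
#' @param source a [Population-class].
#' @param n number of migrants.
#' @param strategy one of the three strategy names.
#' @return integer indices of the selected individuals in `source`.
#' @export
selectMigrants <- function(source, n, strategy = "random") {
  N <- popSize(source)
  if (N < n) stop("source population smaller than the number of migrants",
                  call. = FALSE)
  strategy <- match.arg(strategy, configEnums$migrant_strategy)
  if (strategy == "random") return(sample.int(N, n))
  m <- individualMetrics(source)
  ord <- switch(strategy,
    min_strong_load = order(m$n_strong_alleles, m$id),
    max_heterozygosity = order(-m$n_het, m$id))
  ord[seq_len(n)]
}

# The post-contraction endangered loop shared by all scenarios: full
# ecology (OU carrying capacity + catastrophes), per-generation stats,
# optional genetic rescue. Returns the extinction record and stats rows.
.endangeredLoop <- function(pop, config, streams, replicate,
                            source = NULL, scenario_label = config@scenario) {
  run <- config@run
  rsc <- config@rescue
  maxg <- run$max_generations
  eco <- withStream(streams$ecology, ecologySeries(config, maxg))
  rows <- list()
  events <- list()
  pending <- FALSE
  translocations_left <-
    if (is.null(source)) 0L else rsc$n_translocations

  ext_gen <- NA_integer_
  for (t in seq_len(maxg)) {
    if (pending) {
      if (popSize(source$pop) < rsc$n_migrants) {
        message("replicate ", replicate, ": source population exhausted (N=",
                popSize(source$pop), " < ", rsc$n_migrants,
                "); skipping rescue event at generation ", t)
      } else {
        sel <- withStream(streams$rescue,
                          selectMigrants(source$pop, rsc$n_migrants,
                                         rsc$migrant_strategy))
        transferIndividuals(source$pop, pop, sel)
        translocations_left <- translocations_left - 1L
        events[[length(events) + 1L]] <- data.frame(
          replicate = replicate, generation = t,
          n_migrants = rsc$n_migrants, source_label = source$label,
          strategy = rsc$migrant_strategy)
      }
      pending <- FALSE
    }
    if (!is.null(source) && translocations_left > 0L)
      withStream(streams$source, stepGeneration(source$pop, source$K, 0))

    n <- withStream(streams$endangered,
                    stepGeneration(pop, eco$K[t], eco$catastrophe_p[t]))
    if (n >= 1) {
      idx <- withStream(streams$stats,
                        sampleForStats(pop, run$stats_sample_size))
      rows[[length(rows) + 1L]] <-
        genStatsRow(pop, idx, replicate, "post_contraction")
    }
    if (n < 2) { ext_gen <- t; break }
    if (translocations_left > 0L && n <= rsc$trigger_threshold)
      pending <- TRUE
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(replicate = integer(), generation = integer(),
               n_migrants = integer(), source_label = character(),
               strategy = character())
  record <- data.frame(
    replicate = replicate, scenario = scenario_label,
    extinction_generation = if (is.na(ext_gen)) maxg else ext_gen,
    censored = is.na(ext_gen),
    n_rescue_events = nrow(events))
  list(extinction = record, stats = do.call(rbind, rows),
       rescue_events = events)
}

# seed the endangered population and, for the gradual scenario, run the
# intermediate phase (constant K_intermediate, no endangered ecology)
.seedEndangered <- function(config, ancestral, streams, replicate) {
  d <- config@demography
  rows <- list()
  if (identical(config@scenario, "gradual_contraction")) {
    if (d$K_intermediate > popSize(ancestral))
      stop("K_intermediate exceeds the ancestral population size",
           call. = FALSE)
    inter <- clonePopulation(ancestral, label = "intermediate")
    withStream(streams$endangered,
               subsetPopulation(inter,
                                sample.int(popSize(inter), d$K_intermediate)))
    carryingCapacity(inter) <- d$K_intermediate
    for (g in seq_len(d$generations_intermediate)) {
      n <- withStream(streams$endangered,
                      stepGeneration(inter, d$K_intermediate, 0))
      if (n < 2)
        stop("population went extinct during the intermediate phase",
             call. = FALSE)
      idx <- withStream(streams$stats,
                        sampleForStats(inter, config@run$stats_sample_size))
      rows[[length(rows) + 1L]] <-
        genStatsRow(inter, idx, replicate, "post_contraction")
    }
    ancestral <- inter
  }
  if (d$K_endangered > popSize(ancestral))
    stop("K_endangered exceeds the ancestral population size", call. = FALSE)
  pop <- clonePopulation(ancestral, label = "endangered")
  withStream(streams$endangered,
             subsetPopulation(pop, sample.int(popSize(pop), d$K_endangered)))
  carryingCapacity(pop) <- d$K_endangered
  list(pop = pop, stats = if (length(rows)) do.call(rbind, rows) else NULL)
}

# one full replicate of any scenario
runReplicate <- function(config, replicate = 1L,
                         map = buildGenomeMap(config)) {
  seed <- deriveReplicateSeed(config@run$master_seed, replicate)
  streams <- makeStreams(seed)
  scn <- config@scenario

  if (identical(scn, "neutral_ecology")) {
    K <- config@demography$K_endangered
    pop <- newPopulation(config, n = K, K = K, label = "endangered",
                         map = map)
    out <- .endangeredLoop(pop, config, streams, replicate)
    return(out)
  }

  bi <- .burnIn(config, map, streams, replicate)

  source <- NULL
  if (identical(scn, "genetic_rescue")) {
    spec <- sourceSpec(config)
    src <- withStream(streams$source,
                      prepareSourcePopulation(config, bi$pop))
    source <- list(pop = src, K = spec$K, label = spec$label)
  }

  seeded <- .seedEndangered(config, bi$pop, streams, replicate)
  out <- .endangeredLoop(seeded$pop, config, streams, replicate,
                         source = source)
  out$stats <- rbind(bi$stats, seeded$stats, out$stats)
  out
}

#' Run one contraction replicate
#'
#' Burn-in at `K_ancestral`, then the endangered population is seeded with
#' `K_endangered` individuals sampled uniformly without replacement and
#' evolved under the full endangered-population ecology until extinction
#' (population size below 2) or `max_generations` (censored). The gradual
#' variant first contracts to `K_intermediate` for
#' `generations_intermediate` generations (constant K, no endangered
#' ecology) before the final contraction.
#'
#' @param config a [SimulationConfig-class] with scenario `"contraction"`,
#'   `"gradual_contraction"` or `"neutral_ecology"`.
#' @param replicate replicate index (determines the derived seed).
#' @return list with `extinction` (one-row data.frame), `stats`
#'   (per-generation GenStats) and `rescue_events` (empty).
#' @export
runContraction <- function(config, replicate = 1L) {
  stopifnot(config@scenario %in% c("contraction", "gradual_contraction",
                                   "neutral_ecology"))
  runReplicate(config, replicate)
}

#' Run one genetic-rescue replicate
#'
#' As [runContraction()], but a source population is split off before the
#' contraction and evolves in parallel; whenever the endangered population
#' falls to `trigger_threshold` or fewer individuals (evaluated after that
#' generation's mortality) and translocations remain, `n_migrants`
#' individuals chosen by the configured strategy are copied into the
#' endangered population at the start of the next generation. At most one
#' rescue event fires per generation; with `n_translocations = 0` the run
#' is bit-identical to the plain contraction under the same seeds.
#'
#' @param config a [SimulationConfig-class] with scenario
#'   `"genetic_rescue"`.
#' @param replicate replicate index.
#' @return list with `extinction`, `stats` and `rescue_events`.
#' @export
runGeneticRescue <- function(config, replicate = 1L) {
  stopifnot(identical(config@scenario, "genetic_rescue") ||
              config@rescue$n_translocations == 0L)
  runReplicate(config, replicate)
}

#' Run all replicates of a scenario
#'
#' Executes `n_replicates` independent replicates (each with its own
#' derived seed) and aggregates the per-replicate outputs. A failing
#' replicate is reported and skipped without aborting the others.
#'
#' @param config a [SimulationConfig-class].
#' @param quiet suppress per-replicate progress messages.
#' @return list with `extinctions`, `stats` and `rescue_events`
#'   data.frames.
#' @examples
#' \donttest{
#' cfg <- simulationConfig("neutral_ecology",
#'   genome = list(mutation_rate_per_bp = 0),
#'   run = list(n_replicates = 2, max_generations = 200))
#' res <- runReplicates(cfg, quiet = TRUE)
#' res$extinctions
#' }
#' @export
runReplicates <- function(config, quiet = FALSE) {
  validObject(config)
  map <- buildGenomeMap(config)
  ext <- list(); st <- list(); ev <- list()
  for (r in seq_len(config@run$n_replicates)) {
    t0 <- Sys.time()
    res <- tryCatch(runReplicate(config, r, map = map), error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    ext[[r]] <- res$extinction
    st[[r]] <- res$stats
    ev[[r]] <- res$rescue_events
    if (!quiet) {
      dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      message(sprintf(
        "replicate %d/%d: %s at generation %d%s [%.1fs]",
        r, config@run$n_replicates,
        if (res$extinction$censored) "censored" else "extinct",
        res$extinction$extinction_generation,
        if (res$extinction$n_rescue_events > 0)
          sprintf(" (%d rescue event(s))", res$extinction$n_rescue_events)
        else "",
        dt))
    }
  }
  list(extinctions = do.call(rbind, ext),
       stats = do.call(rbind, st),
       rescue_events = do.call(rbind, ev))
}
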