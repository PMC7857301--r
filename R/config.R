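# Configuration schema, defaults, validation, file I/O and seeding.

configDefaults <- function() {
  list(
    demography = list(
      K_ancestral = 10000L,
      K_endangered = 25L,
      K_intermediate = 1000L,
      generations_intermediate = 200L,
      burn_in_mode = "proportional"
    ),
    genome = list(
      n_genes = 20000L,
      gene_length_bp = 1500L,
      n_chromosomes = 38L,
      per_chromosome_gene_counts = NULL,   # NULL -> dog-autosome proportional
      inter_gene_recomb_rate = 1e-3,
      mutation_rate_per_bp = 1e-8
    ),
    dfe = list(
      deleterious_to_neutral_ratio = 2.31,
      gamma_shape = 0.186,
      gamma_mean_abs_s = 0.01314833,
      truncation = "none"
    ),
    dominance = list(
      model = "hmix",
      fixed_h = 0.0,
      hs_scale_constant = 7071.07,
      hmix_strong_threshold = -0.01,
      hmix_weak_h = 0.25,
      hmix_strong_h = 0.0
    ),
    ecology = list(
      ou_phi = 0.9,
      ou_sigma = log10(1.3),
      catastrophe_alpha = 0.5,
      catastrophe_beta = 8,
      apply_to = "endangered_only"
    ),
    rescue = list(
      source_kind = "K10000",
      n_migrants = 5L,
      n_translocations = 1L,
      trigger_threshold = NULL,            # NULL -> 5 (K_end=25) / 15 (K_end=50)
      migrant_strategy = "random"
    ),
    run = list(
      n_replicates = 25L,
      master_seed = 1L,
      stats_sample_size = 30L,
      max_generations = 5000L
    )
  )
}

configEnums <- list(
  scenario = c("contraction", "gradual_contraction", "genetic_rescue",
               "neutral_ecology"),
  burn_in_mode = c("proportional", "fixed_30000"),
  truncation = c("none", "strong_only", "weak_moderate_only"),
  dominance_model = c("hs_relationship", "hmix", "fixed"),
  source_kind = c("K10000", "K1000_1000gen", "K100_100gen", "K25_10gen"),
  migrant_strategy = c("random", "min_strong_load", "max_heterozygosity"),
  apply_to = "endangered_only"
)

# integer-valued fields, coerced on construction
.intFields <- c("K_ancestral", "K_endangered", "K_intermediate",
                "generations_intermediate", "n_genes", "gene_length_bp",
                "n_chromosomes", "per_chromosome_gene_counts", "n_migrants",
                "n_translocations", "trigger_threshold", "n_replicates",
                "master_seed", "stats_sample_size", "max_generations")

checkPositiveInt <- function(value, field, min = 1L) {
  if (length(value) != 1 || is.na(value) || value < min)
    sprintf("'%s' must be a single integer >= %d", field, min)
  else character()
}

validateConfigParts <- function(scenario, demography, genome, dfe, dominance,
                                ecology, rescue, run) {
  msg <- character()
  chk <- function(cond, text) if (!isTRUE(cond)) msg <<- c(msg, text)

  chk(length(scenario) == 1 && scenario %in% configEnums$scenario,
      sprintf("'scenario' must be one of: %s",
              paste(configEnums$scenario, collapse = ", ")))

  msg <- c(msg,
    checkPositiveInt(demography$K_ancestral, "K_ancestral"),
    checkPositiveInt(demography$K_endangered, "K_endangered"),
    checkPositiveInt(demography$K_intermediate, "K_intermediate"),
    checkPositiveInt(demography$generations_intermediate,
                     "generations_intermediate", min = 0L))
  chk(demography$burn_in_mode %in% configEnums$burn_in_mode,
      "'burn_in_mode' must be 'proportional' or 'fixed_30000'")

  msg <- c(msg,
    checkPositiveInt(genome$n_genes, "n_genes"),
    checkPositiveInt(genome$gene_length_bp, "gene_length_bp"),
    checkPositiveInt(genome$n_chromosomes, "n_chromosomes"))
  chk(is.numeric(genome$inter_gene_recomb_rate) &&
        genome$inter_gene_recomb_rate >= 0 &&
        genome$inter_gene_recomb_rate <= 0.5,
      "'inter_gene_recomb_rate' must lie in [0, 0.5]")
  chk(is.numeric(genome$mutation_rate_per_bp) &&
        genome$mutation_rate_per_bp >= 0,
      "'mutation_rate_per_bp' must be >= 0")
  if (!is.null(genome$per_chromosome_gene_counts)) {
    chk(length(genome$per_chromosome_gene_counts) == genome$n_chromosomes,
        "'per_chromosome_gene_counts' must have length n_chromosomes")
    chk(sum(genome$per_chromosome_gene_counts) == genome$n_genes,
        "'per_chromosome_gene_counts' must sum to n_genes")
    chk(all(genome$per_chromosome_gene_counts >= 0),
        "'per_chromosome_gene_counts' must be non-negative")
  }

  chk(is.numeric(dfe$deleterious_to_neutral_ratio) &&
        dfe$deleterious_to_neutral_ratio >= 0,
      "'deleterious_to_neutral_ratio' must be >= 0")
  chk(is.numeric(dfe$gamma_shape) && dfe$gamma_shape > 0,
      "'gamma_shape' must be > 0")
  chk(is.numeric(dfe$gamma_mean_abs_s) && dfe$gamma_mean_abs_s > 0,
      "'gamma_mean_abs_s' must be > 0")
  chk(dfe$truncation %in% configEnums$truncation,
      sprintf("'truncation' must be one of: %s",
              paste(configEnums$truncation, collapse = ", ")))

  chk(dominance$model %in% configEnums$dominance_model,
      sprintf("dominance 'model' must be one of: %s",
              paste(configEnums$dominance_model, collapse = ", ")))
  chk(is.numeric(dominance$fixed_h) && dominance$fixed_h >= 0 &&
        dominance$fixed_h <= 1,
      "'fixed_h' must lie in [0, 1]")
  chk(is.numeric(dominance$hs_scale_constant) &&
        dominance$hs_scale_constant >= 0,
      "'hs_scale_constant' must be >= 0")
  chk(is.numeric(dominance$hmix_strong_threshold) &&
        dominance$hmix_strong_threshold <= 0,
      "'hmix_strong_threshold' must be <= 0")

  chk(is.numeric(ecology$ou_phi) && ecology$ou_phi >= 0 && ecology$ou_phi < 1,
      "'ou_phi' must lie in [0, 1)")
  chk(is.numeric(ecology$ou_sigma) && ecology$ou_sigma >= 0,
      "'ou_sigma' must be >= 0")
  chk(is.numeric(ecology$catastrophe_alpha) && ecology$catastrophe_alpha > 0,
      "'catastrophe_alpha' must be > 0")
  chk(is.numeric(ecology$catastrophe_beta) && ecology$catastrophe_beta > 0,
      "'catastrophe_beta' must be > 0")
  chk(identical(ecology$apply_to, "endangered_only"),
      "'apply_to' only supports 'endangered_only'")

  chk(rescue$source_kind %in% configEnums$source_kind,
      sprintf("'source_kind' must be one of: %s",
              paste(configEnums$source_kind, collapse = ", ")))
  msg <- c(msg,
    checkPositiveInt(rescue$n_migrants, "n_migrants"),
    checkPositiveInt(rescue$n_translocations, "n_translocations", min = 0L),
    checkPositiveInt(rescue$trigger_threshold, "trigger_threshold"))
  chk(rescue$migrant_strategy %in% configEnums$migrant_strategy,
      sprintf("'migrant_strategy' must be one of: %s",
              paste(configEnums$migrant_strategy, collapse = ", ")))

  msg <- c(msg,
    checkPositiveInt(run$n_replicates, "n_replicates"),
    checkPositiveInt(run$master_seed, "master_seed", min = 0L),
    checkPositiveInt(run$stats_sample_size, "stats_sample_size"),
    checkPositiveInt(run$max_generations, "max_generations"))

  msg
}

mergeGroup <- function(defaults, override, group) {
  if (is.null(override)) return(defaults)
  if (!is.list(override))
    stop(sprintf("config group '%s' must be a list", group), call. = FALSE)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown key(s) in '%s': %s", group,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (k in names(override)) defaults[[k]] <- override[[k]]
  defaults
}

coerceInts <- function(group) {
  for (k in intersect(names(group), .intFields)) {
    if (!is.null(group[[k]])) {
      v <- group[[k]]
      if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)))
        stop(sprintf("'%s' must be integer-valued", k), call. = FALSE)
      group[[k]] <- as.integer(v)
    }
  }
  group
}

#' Create a simulation configuration
#'
#' Builds a validated [SimulationConfig-class] from the default
#' parameterization, overriding any field supplied in the per-group lists.
#' Unknown keys are rejected.
#'
#' Defaults (per group):
#' \describe{
#'   \item{demography}{`K_ancestral = 10000`, `K_endangered = 25`,
#'     `K_intermediate = 1000`, `generations_intermediate = 200`,
#'     `burn_in_mode = "proportional"` (burn-in lasts 10 * K_ancestral
#'     generations; `"fixed_30000"` runs 30,000 regardless of K).}
#'   \item{genome}{`n_genes = 20000`, `gene_length_bp = 1500`,
#'     `n_chromosomes = 38`, `per_chromosome_gene_counts = NULL` (genes
#'     allocated proportionally to dog autosome lengths),
#'     `inter_gene_recomb_rate = 1e-3`, `mutation_rate_per_bp = 1e-8`.}
#'   \item{dfe}{`deleterious_to_neutral_ratio = 2.31`,
#'     `gamma_shape = 0.186`, `gamma_mean_abs_s = 0.01314833`,
#'     `truncation = "none"` (`"strong_only"` turns deleterious draws with
#'     s >= -0.01 neutral; `"weak_moderate_only"` the converse).}
#'   \item{dominance}{`model = "hmix"` (alternatives `"hs_relationship"`,
#'     `"fixed"`), `fixed_h = 0`, `hs_scale_constant = 7071.07`,
#'     `hmix_strong_threshold = -0.01`, `hmix_weak_h = 0.25`,
#'     `hmix_strong_h = 0`.}
#'   \item{ecology}{`ou_phi = 0.9`, `ou_sigma = log10(1.3)`,
#'     `catastrophe_alpha = 0.5`, `catastrophe_beta = 8`,
#'     `apply_to = "endangered_only"`.}
#'   \item{rescue}{`source_kind = "K10000"`, `n_migrants = 5`,
#'     `n_translocations = 1`, `trigger_threshold = NULL` (5 when
#'     `K_endangered = 25`, 15 when 50), `migrant_strategy = "random"`.}
#'   \item{run}{`n_replicates = 25`, `master_seed = 1`,
#'     `stats_sample_size = 30`, `max_generations = 5000`.}
#' }
#'
#' @param scenario one of `"contraction"`, `"gradual_contraction"`,
#'   `"genetic_rescue"`, `"neutral_ecology"`.
#' @param demography,genome,dfe,dominance,ecology,rescue,run named lists of
#'   overrides for the corresponding group.
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig("contraction",
#'                         demography = list(K_ancestral = 1000))
#' cfg
#' @export
simulationConfig <- function(scenario,
                             demography = list(), genome = list(),
                             dfe = list(), dominance = list(),
                             ecology = list(), rescue = list(),
                             run = list()) {
  if (missing(scenario) || is.null(scenario) || !nzchar(scenario[1]))
    stop("'scenario' must be given", call. = FALSE)
  d <- configDefaults()
  demography <- coerceInts(mergeGroup(d$demography, demography, "demography"))
  genome     <- coerceInts(mergeGroup(d$genome, genome, "genome"))
  dfe        <- mergeGroup(d$dfe, dfe, "dfe")
  dominance  <- mergeGroup(d$dominance, dominance, "dominance")
  ecology    <- mergeGroup(d$ecology, ecology, "ecology")
  rescue     <- coerceInts(mergeGroup(d$rescue, rescue, "rescue"))
  run        <- coerceInts(mergeGroup(d$run, run, "run"))

  # fill derived defaults
  if (is.null(genome$per_chromosome_gene_counts))
    genome$per_chromosome_gene_counts <-
      defaultChromosomeGeneCounts(genome$n_genes, genome$n_chromosomes)
  if (is.null(rescue$trigger_threshold)) {
    rescue$trigger_threshold <-
      if (demography$K_endangered == 50L) 15L
      else if (demography$K_endangered == 25L) 5L
      else if (identical(scenario, "genetic_rescue"))
        stop("no default 'trigger_threshold' for K_endangered = ",
             demography$K_endangered, "; set rescue$trigger_threshold",
             call. = FALSE)
      else 5L
  }

  new("SimulationConfig", scenario = scenario, demography = demography,
      genome = genome, dfe = dfe, dominance = dominance, ecology = ecology,
      rescue = rescue, run = run)
}

#' Load a simulation configuration from a YAML file
#'
#' The file holds the same group/key structure documented in
#' [simulationConfig()], plus a top-level `scenario` key. Every omitted key
#' takes its default; unknown groups or keys are an error naming the
#' offender.
#'
#' @param path path to a YAML configuration file.
#' @return a validated [SimulationConfig-class].
#' @seealso [dumpConfig()] for the inverse.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  groups <- c("scenario", "demography", "genome", "dfe", "dominance",
              "ecology", "rescue", "run")
  unknown <- setdiff(names(raw), groups)
  if (length(unknown))
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$scenario) || !nzchar(raw$scenario[1]))
    stop("config must set 'scenario'", call. = FALSE)
  counts <- raw$genome$per_chromosome_gene_counts
  if (!is.null(counts)) raw$genome$per_chromosome_gene_counts <- unlist(counts)
  simulationConfig(scenario = raw$scenario,
                   demography = raw$demography %||% list(),
                   genome = raw$genome %||% list(),
                   dfe = raw$dfe %||% list(),
                   dominance = raw$dominance %||% list(),
                   ecology = raw$ecology %||% list(),
                   rescue = raw$rescue %||% list(),
                   run = raw$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration to a YAML file
#'
#' Writes every (default-filled) field, so `loadConfig(dumpConfig(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param config a [SimulationConfig-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dumpConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  out <- list(scenario = config@scenario,
              demography = config@demography, genome = config@genome,
              dfe = config@dfe, dominance = config@dominance,
              ecology = config@ecology, rescue = config@rescue,
              run = config@run)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Derive a replicate seed from a master seed
#'
#' Deterministic and injective in the replicate index (for a fixed master
#' seed) over the full 31-bit seed space, so replicate seeds within a run
#' never collide and are independent of execution order.
#'
#' @param master_seed integer master seed.
#' @param replicate_index integer replicate index, >= 0.
#' @return a positive integer seed suitable for [set.seed()].
#' @export
deriveReplicateSeed <- function(master_seed, replicate_index) {
  stopifnot(length(master_seed) == 1, length(replicate_index) == 1,
            replicate_index >= 0)
  .eng_mix_seed(as.numeric(master_seed), as.numeric(replicate_index))
}

# Independent per-subsystem RNG streams for one replicate. Keeping the
# ecology, genetics (endangered and source), rescue-selection and
# stats-sampling draws on separate streams makes the dynamics of one
# subsystem invariant to the presence of another (e.g. a rescue run with
# n_translocations = 0 is bit-identical to the plain contraction).
deriveStreamSeeds <- function(replicate_seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(replicate_seed)
  s <- sample.int(.Machine$integer.max, 5L)
  names(s) <- c("endangered", "source", "ecology", "rescue", "stats")
  s
}

# minimal RNG-stream objects: an environment holding a .Random.seed state
newStream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  env
}

withStream <- function(stream, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

#' @describeIn simulationConfig show method
#' @param object a `SimulationConfig`
#' @export
setMethod("show", "SimulationConfig", function(object) {
  d <- object@demography
  cat("SimulationConfig:", object@scenario, "\n")
  cat(sprintf("  K_ancestral=%d K_endangered=%d burn_in=%s\n",
              d$K_ancestral, d$K_endangered, d$burn_in_mode))
  cat(sprintf("  genome: %d genes x %d bp on %d chromosomes\n",
              object@genome$n_genes, object@genome$gene_length_bp,
              object@genome$n_chromosomes))
  cat(sprintf("  dfe: gamma(shape=%.3g, mean|s|=%.4g), del:neu=%.3g, %s\n",
              object@dfe$gamma_shape, object@dfe$gamma_mean_abs_s,
              object@dfe$deleterious_to_neutral_ratio, object@dfe$truncation))
  cat(sprintf("  dominance: %s\n", object@dominance$model))
  if (identical(object@scenario, "genetic_rescue"))
    cat(sprintf("  rescue: %s, %d migrant(s) x %d event(s), strategy=%s\n",
                object@rescue$source_kind, object@rescue$n_migrants,
                object@rescue$n_translocations,
                object@rescue$migrant_strategy))
  cat(sprintf("  run: %d replicate(s), master_seed=%d\n",
              object@run$n_replicates, object@run$master_seed))
  invisible(NULL)
})
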