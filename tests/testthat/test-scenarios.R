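test_that("burn-in duration follows the configured mode", {
  cfg <- tinyConfig(demography = list(K_ancestral = 30),
                    genome = list(mutation_rate_per_bp = 0))
  pop <- runBurnIn(cfg, seed = 1)
  expect_equal(currentGeneration(pop), 300L)  # 10 * K_ancestral
  expect_equal(popSize(pop) > 1, TRUE)
  # with no mutation the population stays genetically empty
  expect_equal(nrow(mutationTable(pop)), 0L)
  expect_equal(fixedLoad(pop), 1)
  st <- attr(pop, "stats")
  expect_equal(st$phase, "burn_in")
  expect_equal(st$generation[nrow(st)], 300L)

  cfgF <- tinyConfig(demography = list(K_ancestral = 12,
                                       burn_in_mode = "fixed_30000"),
                     genome = list(mutation_rate_per_bp = 0))
  popF <- runBurnIn(cfgF, seed = 1)
  expect_equal(currentGeneration(popF), 30000L)  # ignores K
})

test_that("burn-in accumulates segregating variation and fixed load", {
  # elevated mutation rate so weakly deleterious fixations are certain to
  # accumulate within the short 10 * K burn-in of this small population
  cfg <- tinyConfig(demography = list(K_ancestral = 60),
                    genome = list(mutation_rate_per_bp = 1e-7),
                    run = list(stats_sample_size = 20L))
  pop <- runBurnIn(cfg, seed = 3)
  expect_gt(nrow(mutationTable(pop)), 0)
  expect_lt(fixedLoad(pop), 1)          # weak fixations accumulate
  expect_gt(fixedLoad(pop), 0.9)
  expect_gt(meanHeterozygosity(pop), 0)
})

test_that("burn-in heterozygosity increases with carrying capacity", {
  het <- vapply(c(25, 100, 500), function(K) {
    cfg <- tinyConfig(demography = list(K_ancestral = K),
                      run = list(stats_sample_size = 25L))
    pop <- runBurnIn(cfg, seed = 17)
    meanHeterozygosity(pop, sampleForStats(pop, 25))
  }, numeric(1))
  expect_identical(order(het), 1:3)  # rank correlation 1 with K
})

test_that("contraction seeds the endangered population and records outcomes", {
  cfg <- tinyConfig(
    demography = list(K_ancestral = 50, K_endangered = 6),
    run = list(max_generations = 250L, stats_sample_size = 6L,
               master_seed = 2L))
  res <- runContraction(cfg, replicate = 1)
  expect_equal(nrow(res$extinction), 1L)
  expect_true(res$extinction$extinction_generation >= 1)
  expect_equal(res$extinction$n_rescue_events, 0L)
  expect_equal(nrow(res$rescue_events), 0L)
  post <- res$stats[res$stats$phase == "post_contraction", ]
  expect_gt(nrow(post), 0)
  # stats recorded every generation after the contraction
  expect_equal(diff(post$generation), rep(1L, nrow(post) - 1))
  if (!res$extinction$censored)
    expect_equal(nrow(post), res$extinction$extinction_generation)
})

test_that("gradual contraction inserts a constant-K intermediate phase", {
  cfg <- tinyConfig(
    scenario = "gradual_contraction",
    demography = list(K_ancestral = 50, K_intermediate = 30,
                      generations_intermediate = 12, K_endangered = 6),
    run = list(max_generations = 60L, stats_sample_size = 6L,
               master_seed = 4L))
  res <- runContraction(cfg, replicate = 1)
  post <- res$stats[res$stats$phase == "post_contraction", ]
  # first 12 recorded post rows are the intermediate phase at K = 30
  expect_equal(post$K[1:12], rep(30L, 12))
  expect_true(all(post$K[13:min(20, nrow(post))] != 30L |
                    post$N[13:min(20, nrow(post))] <= 30L))
})

test_that("a censored run reports max_generations and the censoring flag", {
  cfg <- tinyConfig(
    demography = list(K_ancestral = 40, K_endangered = 30),
    genome = list(mutation_rate_per_bp = 0),
    ecology = list(ou_sigma = 0, catastrophe_alpha = 1e-6),
    run = list(max_generations = 50L, stats_sample_size = 10L,
               master_seed = 3L))
  res <- runContraction(cfg, replicate = 1)
  expect_true(res$extinction$censored)
  expect_equal(res$extinction$extinction_generation, 50L)
})

test_that("source populations follow their split specifications", {
  cfg <- tinyConfig(
    demography = list(K_ancestral = 60),
    rescue = list(source_kind = "K25_10gen"),
    run = list(stats_sample_size = 10L))
  pop <- runBurnIn(cfg, seed = 9)
  gen0 <- currentGeneration(pop)
  set.seed(31)
  src <- prepareSourcePopulation(cfg, pop)
  expect_equal(carryingCapacity(src), 25L)
  expect_equal(currentGeneration(src), gen0 + 10L)
  expect_lte(popSize(src), 60L)
  # the ancestral population is untouched by the split
  expect_equal(currentGeneration(pop), gen0)

  cfgBig <- tinyConfig(rescue = list(source_kind = "K10000"))
  srcBig <- prepareSourcePopulation(cfgBig, pop)
  expect_equal(currentGeneration(srcBig), gen0)  # continues unchanged

  cfgTooBig <- tinyConfig(demography = list(K_ancestral = 60),
                          rescue = list(source_kind = "K1000_1000gen"))
  expect_error(prepareSourcePopulation(cfgTooBig, pop), "exceeds")
})

test_that("migrant selection honours the screening strategy and tie-break", {
  cfg <- simulationConfig("genetic_rescue",
    genome = list(n_genes = 10L, n_chromosomes = 1L,
                  mutation_rate_per_bp = 0))
  muts <- data.frame(pos = c(100L, 3000L, 6000L, 9000L, 12000L),
                     s = c(-0.02, -0.02, -0.001, 0, 0),
                     h = c(0, 0, 0.25, 0.5, 0.5))
  pop <- makePop(cfg, muts, list(
    list(h1 = c(1L, 2L), h2 = c(1L, 2L)),   # 4 strong alleles, 0 het
    list(h1 = integer(), h2 = integer()),   # 0 strong, 0 het
    list(h1 = c(3L, 4L, 5L), h2 = integer()),  # 0 strong, 3 het
    list(h1 = 1L, h2 = integer())))         # 1 strong, 1 het
  expect_equal(selectMigrants(pop, 1, "min_strong_load"), 2L)
  expect_equal(selectMigrants(pop, 2, "min_strong_load"), c(2L, 3L))
  expect_equal(selectMigrants(pop, 1, "max_heterozygosity"), 3L)
  # tie between individuals 2 and 3 on strong load: lower id wins first
  expect_equal(selectMigrants(pop, 4, "min_strong_load")[1:2], c(2L, 3L))
  set.seed(601)
  r <- selectMigrants(pop, 4, "random")
  expect_equal(sort(r), 1:4)
  expect_error(selectMigrants(pop, 5, "random"), "smaller")
})

test_that("translocated migrants mask fixed load in their offspring", {
  cfg <- simulationConfig("genetic_rescue",
    genome = list(n_genes = 10L, n_chromosomes = 1L,
                  mutation_rate_per_bp = 0, inter_gene_recomb_rate = 0))
  muts <- data.frame(pos = c(100L, 9000L), s = c(-0.5, -0.5), h = c(0, 0))
  # endangered population homozygous for deleterious mutation 1, source
  # homozygous for a different one: F1 offspring are het at both (masked)
  endangered <- makePop(cfg, muts,
                        lapply(1:4, function(i) list(h1 = 1L, h2 = 1L)),
                        K = 8)
  w_before <- mean(individualFitness(endangered))
  expect_equal(w_before, 0.5, tolerance = 1e-6)
  # population right after translocation: residents plus two migrants
  # fixed for a different deleterious mutation
  mixed <- makePop(cfg, muts, c(
    lapply(1:4, function(i) list(h1 = 1L, h2 = 1L)),
    lapply(1:2, function(i) list(h1 = 2L, h2 = 2L))), K = 12)
  set.seed(602)
  reproduce(mixed)
  w <- individualFitness(mixed)
  kids_w <- w[7:length(w)]
  # resident x migrant offspring are fully masked (w = 1); mean offspring
  # fitness exceeds the pre-rescue resident mean
  expect_gt(mean(kids_w), w_before)
  expect_true(any(kids_w == 1))
})

test_that("a rescue run with zero translocations reduces to the contraction", {
  base <- list(
    demography = list(K_ancestral = 50, K_endangered = 6),
    genome = list(n_genes = 500L, n_chromosomes = 10L),
    run = list(max_generations = 150L, stats_sample_size = 6L,
               master_seed = 8L))
  cfg_c <- do.call(simulationConfig, c(list(scenario = "contraction"), base))
  cfg_r <- do.call(simulationConfig,
                   c(list(scenario = "genetic_rescue"), base,
                     list(rescue = list(n_translocations = 0L,
                                        trigger_threshold = 3L,
                                        source_kind = "K25_10gen"))))
  res_c <- runContraction(cfg_c, replicate = 1)
  res_r <- runGeneticRescue(cfg_r, replicate = 1)
  expect_identical(res_c$stats, res_r$stats)
  expect_identical(res_c$extinction$extinction_generation,
                   res_r$extinction$extinction_generation)
  expect_identical(res_c$extinction$censored, res_r$extinction$censored)
  expect_equal(res_r$extinction$n_rescue_events, 0L)
})

test_that("rescue events fire after the population falls to the trigger", {
  cfg <- simulationConfig("genetic_rescue",
    demography = list(K_ancestral = 40, K_endangered = 5),
    genome = list(n_genes = 300L, n_chromosomes = 10L),
    rescue = list(source_kind = "K25_10gen", n_migrants = 3L,
                  n_translocations = 2L, trigger_threshold = 3L),
    run = list(max_generations = 400L, stats_sample_size = 5L,
               master_seed = 21L))
  res <- runGeneticRescue(cfg, replicate = 1)
  expect_gte(res$extinction$n_rescue_events, 1L)
  if (nrow(res$rescue_events) > 1) {
    # at most one event per generation, later events in later generations
    expect_true(all(diff(res$rescue_events$generation) >= 1))
  }
  expect_equal(res$rescue_events$n_migrants,
               rep(3L, nrow(res$rescue_events)))
  expect_equal(res$rescue_events$source_label,
               rep("K25_10gen", nrow(res$rescue_events)))
})

test_that("replicates are independent, seeded and aggregated", {
  cfg <- simulationConfig("neutral_ecology",
    demography = list(K_endangered = 6),
    genome = list(n_genes = 100L, n_chromosomes = 5L,
                  mutation_rate_per_bp = 0),
    run = list(n_replicates = 3L, max_generations = 300L,
               master_seed = 10L, stats_sample_size = 6L))
  res1 <- runReplicates(cfg, quiet = TRUE)
  expect_equal(nrow(res1$extinctions), 3L)
  expect_equal(res1$extinctions$replicate, 1:3)
  res2 <- runReplicates(cfg, quiet = TRUE)
  expect_identical(res1$extinctions, res2$extinctions)
  expect_identical(res1$stats, res2$stats)
  # distinct replicate seeds give distinct trajectories
  per_rep <- split(res1$stats$N, res1$stats$replicate)
  expect_false(identical(per_rep[[1]], per_rep[[2]]))
})

test_that("a gradual contraction purges strongly deleterious alleles
           during the intermediate phase", {
  # the mechanism behind the longer persistence of gradually contracted
  # populations: an intermediate phase at moderate K exposes recessive
  # strong alleles to selection before the final contraction
  cfg <- simulationConfig("gradual_contraction",
    demography = list(K_ancestral = 300, K_intermediate = 40,
                      generations_intermediate = 250, K_endangered = 25),
    genome = list(n_genes = 1000L),
    run = list(n_replicates = 12L, master_seed = 31L,
               max_generations = 1L, stats_sample_size = 30L))
  res <- runReplicates(cfg, quiet = TRUE)
  pre <- post <- numeric(12)
  for (r in 1:12) {
    d <- res$stats[res$stats$replicate == r, ]
    burn <- d[d$phase == "burn_in", ]
    inter <- d[d$phase == "post_contraction", ]
    pre[r] <- burn$n_strong[which.max(burn$generation)]
    post[r] <- inter$n_strong[250]  # end of the intermediate phase
  }
  expect_lt(t.test(post, pre, paired = TRUE,
                   alternative = "less")$p.value, 0.05)
})
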