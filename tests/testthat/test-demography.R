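test_that("fitness is multiplicative across sites with dominance masking", {
  cfg <- simulationConfig("contraction",
    genome = list(n_genes = 10L, n_chromosomes = 1L,
                  mutation_rate_per_bp = 0))
  muts <- data.frame(pos = c(100L, 3000L, 7000L),
                     s = c(-0.1, -0.1, -0.1),
                     h = c(0, 0.25, 0))
  # no mutations
  p0 <- makePop(cfg, muts, list(list(h1 = integer(), h2 = integer())))
  expect_equal(individualFitness(p0), 1)
  # fully recessive heterozygote is completely masked
  p1 <- makePop(cfg, muts, list(list(h1 = 1L, h2 = integer())))
  expect_equal(individualFitness(p1), 1)
  # two homozygous s = -0.1: w = 0.9 * 0.9
  p2 <- makePop(cfg, muts, list(list(h1 = c(1L, 3L), h2 = c(1L, 3L))))
  expect_equal(individualFitness(p2), 0.81, tolerance = 1e-6)
  # heterozygous s = -0.1, h = 0.25: w = 1 + 0.25 * (-0.1)
  p3 <- makePop(cfg, muts, list(list(h1 = 2L, h2 = integer())))
  expect_equal(individualFitness(p3), 0.975, tolerance = 1e-6)
  # fixed load multiplies in and w is clamped to [0, 1]
  p4 <- makePop(cfg, muts, list(list(h1 = c(1L, 3L), h2 = c(1L, 3L))),
                fixed_load = 0.5)
  expect_equal(individualFitness(p4), 0.5 * 0.81, tolerance = 1e-6)
})

test_that("reproduction pairs every focal individual with another", {
  cfg <- simulationConfig("contraction",
    genome = list(n_genes = 4L, n_chromosomes = 1L,
                  mutation_rate_per_bp = 0, inter_gene_recomb_rate = 0))
  muts <- data.frame(pos = c(500L, 2000L, 3500L, 5000L),
                     s = 0, h = 0.5)
  # two parents with disjoint homozygous mutation sets
  pop <- makePop(cfg, muts, list(list(h1 = 1:2, h2 = 1:2),
                                 list(h1 = 3:4, h2 = 3:4)))
  set.seed(201)
  reproduce(pop)
  expect_equal(popSize(pop), 4L)  # 2 parents + 2 offspring
  genos <- getGenotypes(pop)[3:4]
  # each offspring has one gamete from each adult (self excluded)
  expect_equal(sort(genos[[1]]$h1), 1:2)
  expect_equal(sort(genos[[1]]$h2), 3:4)
  expect_equal(sort(genos[[2]]$h1), 3:4)
  expect_equal(sort(genos[[2]]$h2), 1:2)

  # a single individual cannot mate
  p1 <- makePop(cfg, muts, list(list(h1 = 1L, h2 = 1L)))
  reproduce(p1)
  expect_equal(popSize(p1), 1L)
})

test_that("offspring genotypes are closed under the parental mutation set", {
  cfg <- simulationConfig("contraction",
    genome = list(n_genes = 50L, n_chromosomes = 5L,
                  mutation_rate_per_bp = 0))
  set.seed(202)
  muts <- data.frame(pos = sort(sample.int(50L * 1500L, 40)), s = 0, h = 0.5)
  genos <- lapply(1:6, function(i)
    list(h1 = sample.int(40, 8), h2 = sample.int(40, 8)))
  pop <- makePop(cfg, muts, genos)
  parental <- sort(unique(unlist(lapply(genos, unlist))))
  reproduce(pop)
  kids <- getGenotypes(pop)[7:12]
  for (k in kids) {
    expect_true(all(k$h1 %in% parental))
    expect_true(all(k$h2 %in% parental))
  }
})

test_that("viability selection applies the K/N-rescaled fitness", {
  cfg <- oneLocusConfig()
  n <- 4000
  muts <- data.frame(pos = 1L, s = -1, h = 0.5)
  empty <- lapply(seq_len(n), function(i) list(h1 = integer(), h2 = integer()))

  # w = 1 and N <= K: certain survival
  popA <- makePop(cfg, muts, empty[1:100], K = 200)
  set.seed(203)
  viabilitySelection(popA, n_ref = 100)
  expect_equal(popSize(popA), 100L)
  expect_true(all(individualAges(popA) == 1L))

  # w = 1, N = 2K: survival probability 1/2
  popB <- makePop(cfg, muts, empty, K = n / 2)
  viabilitySelection(popB, n_ref = n)
  expect_equal(popSize(popB) / n, 0.5, tolerance = 0.05)

  # w = 0.5 (via fixed load), N = 2K: survival probability 1/4
  popC <- makePop(cfg, muts, empty, fixed_load = 0.5, K = n / 2)
  viabilitySelection(popC, n_ref = n)
  expect_equal(popSize(popC) / n, 0.25, tolerance = 0.05)
})

test_that("fixation pruning moves fitness into the fixed load exactly", {
  cfg <- simulationConfig("contraction",
    genome = list(n_genes = 10L, n_chromosomes = 2L,
                  mutation_rate_per_bp = 0))
  muts <- data.frame(pos = c(100L, 3000L, 9000L),
                     s = c(-0.001, 0, -0.1),
                     h = c(0.25, 0.5, 0))
  # mutation 1 fixed (hom in everyone), 2 fixed neutral, 3 segregating
  pop <- makePop(cfg, muts, list(list(h1 = c(1L, 2L), h2 = c(1L, 2L, 3L)),
                                 list(h1 = c(1L, 2L, 3L), h2 = c(1L, 2L))))
  w_before <- individualFitness(pop)
  pruneFixed(pop)
  expect_equal(fixedLoad(pop), 0.999)
  expect_equal(individualFitness(pop), w_before, tolerance = 1e-12)
  genos <- getGenotypes(pop)
  expect_false(any(c(1L, 2L) %in% unlist(genos)))
  expect_true(3L %in% unlist(genos))
  # idempotent
  pruneFixed(pop)
  expect_equal(fixedLoad(pop), 0.999)
  expect_equal(individualFitness(pop), w_before, tolerance = 1e-12)
})

test_that("one generation follows the reproduce/catastrophe/prune/viability order", {
  cfg <- tinyConfig(genome = list(mutation_rate_per_bp = 0))
  # catastrophe probability 1 wipes the population
  pop <- newPopulation(cfg, 20, 20)
  set.seed(204)
  expect_equal(stepGeneration(pop, 20, 1), 0L)
  expect_equal(popSize(pop), 0L)

  # lethal homozygotes (w = 0) die at viability
  cfg1 <- oneLocusConfig()
  muts <- data.frame(pos = 1L, s = -1, h = 0.5)
  genos <- lapply(1:10, function(i) list(h1 = 1L, h2 = 1L))
  popL <- makePop(cfg1, muts, genos, K = 10)
  stepGeneration(popL, 10, 0)
  expect_equal(popSize(popL), 0L)

  # neutral population hovers near K
  popN <- newPopulation(cfg, 100, 100)
  set.seed(205)
  sizes <- replicate(300, stepGeneration(popN, 100, 0))
  expect_equal(mean(sizes[101:300]), 100, tolerance = 0.1)
})

test_that("engine matches a brute-force single-locus simulator", {
  # N = 20, one locus at frequency 0.5, s = -0.1, h = 0.5 (additive);
  # compare the mean allele frequency after 3 generations against an
  # independent R implementation of the identical update rule
  cfg <- oneLocusConfig()
  muts <- data.frame(pos = 750L, s = -0.1, h = 0.5)
  n0 <- 20L; K <- 20L; n_gens <- 3L; n_rep <- 2500L

  set.seed(206)
  eng <- vapply(seq_len(n_rep), function(r) {
    genos <- lapply(seq_len(n0), function(i) {
      hp <- list(h1 = integer(), h2 = integer())
      if (runif(1) < 0.5) hp$h1 <- 1L
      if (runif(1) < 0.5) hp$h2 <- 1L
      hp
    })
    pop <- makePop(cfg, muts, genos, K = K)
    for (g in seq_len(n_gens)) stepGeneration(pop, K, 0)
    n <- popSize(pop)
    if (n == 0) return(NA_real_)
    carriers <- unlist(getGenotypes(pop))
    cnt <- length(carriers)
    if (fixedLoad(pop) < 1) 1 else cnt / (2 * n)  # pruned when fixed
  }, numeric(1))

  set.seed(207)
  orc <- vapply(seq_len(n_rep), function(r)
    oneLocusOracle(n0, 0.5, -0.1, 0.5, K, n_gens), numeric(1))

  m_eng <- mean(eng, na.rm = TRUE)
  m_orc <- mean(orc, na.rm = TRUE)
  se <- sqrt(var(eng, na.rm = TRUE) / sum(!is.na(eng)) +
             var(orc, na.rm = TRUE) / sum(!is.na(orc)))
  expect_lt(abs(m_eng - m_orc), 4 * se + 1e-12)
})

test_that("runs are bit-identical under a shared seed", {
  cfg <- tinyConfig(demography = list(K_ancestral = 40))
  run_once <- function() {
    pop <- newPopulation(cfg, 40, 40)
    set.seed(208)
    for (g in 1:150) stepGeneration(pop, 40, 0)
    list(n = popSize(pop), tab = mutationTable(pop),
         genos = getGenotypes(pop), w = individualFitness(pop))
  }
  expect_identical(run_once(), run_once())
})
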