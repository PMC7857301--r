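# Shared tiny configurations and independent brute-force oracles.

# small genome for fast unit runs: 500 genes of 1500 bp on 10 chromosomes
tinyConfig <- function(scenario = "contraction", ...) {
  args <- list(...)
  genome <- c(list(n_genes = 500L, n_chromosomes = 10L),
              args$genome %||% list())
  args$genome <- genome[!duplicated(names(genome), fromLast = TRUE)]
  do.call(simulationConfig, c(list(scenario = scenario), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-locus genome (one gene, one chromosome) for toy constructions
oneLocusConfig <- function(...) {
  simulationConfig("contraction",
                   genome = list(n_genes = 1L, n_chromosomes = 1L,
                                 mutation_rate_per_bp = 0,
                                 inter_gene_recomb_rate = 0),
                   ...)
}

# build a population from a list of c(h1 ids, h2 ids) pairs
makePop <- function(config, muts, genos, fixed_load = 1,
                    K = length(genos)) {
  populationFromGenotypes(config, genos, muts, fixed_load = fixed_load,
                          K = K)
}

# brute-force F_ROH oracle: explicit segment enumeration over heterozygous
# positions, independent of the engine implementation
frohOracle <- function(het_pos, chrom_len, min_len = 1e6) {
  bounds <- cumsum(c(0, chrom_len))
  roh <- 0
  for (c in seq_along(chrom_len)) {
    p <- sort(het_pos[het_pos > bounds[c] & het_pos <= bounds[c + 1]])
    cuts <- c(bounds[c], p, bounds[c + 1])
    seg <- diff(cuts)
    # the closing segment runs from the last het site to the chromosome
    # end; segments between consecutive het sites are their distances
    roh <- roh + sum(seg[seg > min_len])
  }
  roh / sum(chrom_len)
}

# brute-force single-locus simulator implementing the identical
# generation update (reproduction, no catastrophe, pruning-free counting,
# viability with the post-reproduction K/N rescale)
oneLocusOracle <- function(n0, freq0, s, h, K, n_gens) {
  geno <- matrix(rbinom(2 * n0, 1, freq0), ncol = 2)
  for (g in seq_len(n_gens)) {
    n <- nrow(geno)
    if (n < 2) break
    kids <- matrix(0L, n, 2)
    for (i in seq_len(n)) {
      j <- sample.int(n - 1, 1)
      if (j >= i) j <- j + 1
      kids[i, 1] <- geno[i, sample.int(2, 1)]
      kids[i, 2] <- geno[j, sample.int(2, 1)]
    }
    pool <- rbind(geno, kids)
    n2 <- nrow(pool)
    cnt <- rowSums(pool)
    w <- ifelse(cnt == 2, 1 + s, ifelse(cnt == 1, 1 + h * s, 1))
    p <- pmin(1, w * K / n2)
    keep <- runif(n2) < p
    geno <- pool[keep, , drop = FALSE]
  }
  if (nrow(geno) == 0) NA_real_ else mean(geno)
}
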