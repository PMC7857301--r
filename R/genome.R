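# Genome map, DFE sampling and dominance assignment.

# Approximate lengths (Mb) of the 38 dog autosomes (CanFam3.1 assembly),
# used only as ratios to apportion genes among chromosomes.
dogAutosomeMb <- c(122.7, 85.4, 91.9, 88.3, 88.9, 77.6, 80.9, 74.3, 61.1,
                   69.3, 74.4, 72.5, 63.4, 60.9, 64.2, 59.6, 64.3, 55.9,
                   53.5, 58.1, 50.9, 61.4, 52.3, 47.7, 51.6, 39.0, 45.9,
                   41.2, 41.6, 40.2, 39.2, 38.8, 31.4, 42.1, 26.5, 30.8,
                   30.9, 23.9)

#' Default per-chromosome gene counts
#'
#' Allocates genes to chromosomes proportionally to published dog autosome
#' lengths, rounded with the largest-remainder method so the counts sum
#' exactly to `n_genes`. With a chromosome count other than 38 the
#' allocation falls back to an even split (same rounding rule).
#'
#' @param n_genes total number of genes.
#' @param n_chromosomes number of chromosomes.
#' @return integer vector of length `n_chromosomes` summing to `n_genes`.
#' @export
defaultChromosomeGeneCounts <- function(n_genes, n_chromosomes = 38L) {
  w <- if (n_chromosomes == length(dogAutosomeMb)) dogAutosomeMb
       else rep(1, n_chromosomes)
  exact <- n_genes * w / sum(w)
  counts <- floor(exact)
  short <- n_genes - sum(counts)
  if (short > 0) {
    give <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

#' Build the genome coordinate map
#'
#' Lays genes end-to-end within each chromosome on a coding-only physical
#' coordinate (gene k of a chromosome spans bp ((k-1)*L+1)..(k*L)). The map
#' is deterministic given the configuration.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GenomeMap-class].
#' @examples
#' map <- buildGenomeMap(simulationConfig("contraction"))
#' totalCodingBp(map)  # 20000 * 1500 = 3e7
#' @export
buildGenomeMap <- function(config) {
  g <- config@genome
  counts <- g$per_chromosome_gene_counts
  if (sum(counts) != g$n_genes)
    stop("per_chromosome_gene_counts must sum to n_genes", call. = FALSE)
  L <- g$gene_length_bp
  chrom <- rep(paste0("chr", seq_len(g$n_chromosomes)), counts)
  within <- unlist(lapply(counts, seq_len), use.names = FALSE)
  starts <- (within - 1L) * L + 1L
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = paste0("chr", seq_len(g$n_chromosomes))),
    ranges = IRanges::IRanges(start = starts, width = L),
    gene_id = seq_len(g$n_genes))
  new("GenomeMap", genes = gr, geneLength = as.integer(L),
      interGeneRecombRate = g$inter_gene_recomb_rate,
      chromGeneCounts = as.integer(counts),
      totalCodingBp = as.numeric(g$n_genes) * L)
}

#' @rdname GenomeMap-accessors
#' @export
setGeneric("totalCodingBp", function(x) standardGeneric("totalCodingBp"))

#' Genome map accessors
#'
#' @param x a [GenomeMap-class].
#' @return `totalCodingBp`: total coding bp; `geneRanges`: the gene
#'   [GenomicRanges::GRanges]; `chromGeneCounts`: genes per chromosome.
#' @name GenomeMap-accessors
#' @aliases totalCodingBp
#' @export
setMethod("totalCodingBp", "GenomeMap", function(x) x@totalCodingBp)

#' @rdname GenomeMap-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GenomeMap-accessors
#' @export
setMethod("geneRanges", "GenomeMap", function(x) x@genes)

#' @rdname GenomeMap-accessors
#' @export
setGeneric("chromGeneCounts", function(x) standardGeneric("chromGeneCounts"))

#' @rdname GenomeMap-accessors
#' @export
setMethod("chromGeneCounts", "GenomeMap", function(x) x@chromGeneCounts)

setMethod("show", "GenomeMap", function(object) {
  cat(sprintf("GenomeMap: %d genes x %d bp on %d chromosomes (%.3g coding bp)\n",
              length(object@genes), object@geneLength,
              length(object@chromGeneCounts), object@totalCodingBp))
  cat(sprintf("  inter-gene recombination %.3g, free between chromosomes\n",
              object@interGeneRecombRate))
  invisible(NULL)
})

# engine parameter list shared by all compiled entry points
engineParams <- function(config) {
  g <- config@genome; f <- config@dfe; d <- config@dominance
  r <- f$deleterious_to_neutral_ratio
  list(
    n_genes = g$n_genes,
    gene_length_bp = g$gene_length_bp,
    n_chromosomes = g$n_chromosomes,
    per_chromosome_gene_counts = g$per_chromosome_gene_counts,
    inter_gene_recomb_rate = g$inter_gene_recomb_rate,
    mutation_rate_per_bp = g$mutation_rate_per_bp,
    p_deleterious = r / (1 + r),
    gamma_shape = f$gamma_shape,
    gamma_scale = f$gamma_mean_abs_s / f$gamma_shape,
    truncation_code = match(f$truncation, configEnums$truncation) - 1L,
    dominance_code = match(d$model, configEnums$dominance_model) - 1L,
    fixed_h = d$fixed_h,
    hs_scale_constant = d$hs_scale_constant,
    hmix_strong_threshold = d$hmix_strong_threshold,
    hmix_weak_h = d$hmix_weak_h,
    hmix_strong_h = d$hmix_strong_h
  )
}

#' Draw selection coefficients from the configured DFE
#'
#' With probability `1 - p_deleterious` (where `p_deleterious = r/(1+r)` for
#' deleterious:neutral ratio r) a draw is neutral (s = 0); otherwise
#' s = -min(1, X) with X gamma-distributed with the configured shape and
#' mean. Truncation modes convert the complementary severity class to
#' neutral: `"strong_only"` keeps only s < -0.01, `"weak_moderate_only"`
#' only s >= -0.01.
#'
#' @param n number of draws.
#' @param config a [SimulationConfig-class].
#' @return numeric vector of n selection coefficients in `[-1, 0]`.
#' @export
drawFitnessEffect <- function(n, config = simulationConfig("contraction")) {
  .eng_draw_s(engineParams(config), as.integer(n))
}

#' Assign dominance coefficients
#'
#' Under the hs relationship, `h(s) = 0.5 / (1 + C |s|)` with scale constant
#' C = 7071.07, so strongly deleterious mutations are nearly fully
#' recessive; under hmix, h = 0.25 for s >= -0.01 and h = 0 for s < -0.01;
#' under a fixed model every deleterious mutation gets the configured h.
#' Neutral mutations (s = 0) carry h = 0.5 as a bookkeeping value.
#'
#' @param s numeric vector of selection coefficients in `[-1, 0]`.
#' @param config a [SimulationConfig-class] (its `dominance` group is used).
#' @return numeric vector of dominance coefficients.
#' @examples
#' cfg <- simulationConfig("contraction",
#'                         dominance = list(model = "hs_relationship"))
#' assignDominance(c(0, -0.01, -1), cfg)
#' @export
assignDominance <- function(s, config = simulationConfig("contraction")) {
  .eng_assign_h(engineParams(config), as.numeric(s))
}
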