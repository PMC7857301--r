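# Per-generation population summaries and cross-replicate comparison.

#' Sample individuals for summary statistics
#'
#' Uniform sample without replacement of `min(n, N)` individuals.
#'
#' @param pop a [Population-class].
#' @param n target sample size (default 30).
#' @return integer vector of individual indices.
#' @export
sampleForStats <- function(pop, n = 30) {
  N <- popSize(pop)
  if (N < 1) stop("cannot sample from an empty population", call. = FALSE)
  if (N <= n) seq_len(N) else sample.int(N, n)
}

#' Mean per-bp heterozygosity of a sample
#'
#' Observed heterozygosity: mean over sampled individuals of (number of
#' heterozygous mutation sites) / total coding bp. Monomorphic sites are
#' included in the denominator, which makes the estimator invariant to
#' fixed-mutation pruning.
#'
#' @param pop a [Population-class].
#' @param idx individual indices (default: everyone).
#' @return mean heterozygosity per coding bp.
#' @export
meanHeterozygosity <- function(pop, idx = seq_len(popSize(pop))) {
  if (!length(idx)) stop("empty sample", call. = FALSE)
  mean(.eng_het_counts(pop@ptr, as.integer(idx))) / totalCodingBp(pop@map)
}

#' Inbreeding coefficient from runs of homozygosity
#'
#' On each chromosome the individual's heterozygous sites partition the
#' coding coordinate into maximal homozygous segments (chromosome ends
#' bound the outer segments); F_ROH is the summed length of segments
#' strictly longer than `min_length_bp`, divided by total coding bp. The
#' 1 Mb default captures inbreeding due to recent close-relative mating.
#' Note lengths are measured on the coding-contiguous coordinate (1 Mb of
#' which spans about 667 genes of 1500 bp).
#'
#' @param pop a [Population-class].
#' @param idx individual indices.
#' @param min_length_bp minimum segment length (exclusive), default 1e6.
#' @return numeric vector of F_ROH in `[0, 1]`, one per individual.
#' @export
fRoh <- function(pop, idx = seq_len(popSize(pop)), min_length_bp = 1e6) {
  .eng_froh(pop@ptr, as.integer(idx), as.numeric(min_length_bp))
}

#' Binned deleterious-allele counts
#'
#' Mean allele copies per sampled individual (heterozygous = 1 copy,
#' homozygous = 2) in the four severity classes: weakly
#' (-0.001 < s <= -0.00001), moderately (-0.01 < s <= -0.001), strongly
#' (s < -0.01) and very strongly (s < -0.05) deleterious. The strong and
#' very-strong classes overlap by construction (very strong is a subset).
#'
#' @param pop a [Population-class].
#' @param idx individual indices.
#' @return named numeric vector `n_weak`, `n_moderate`, `n_strong`,
#'   `n_very_strong`.
#' @export
deleteriousCounts <- function(pop, idx = seq_len(popSize(pop))) {
  if (!length(idx)) stop("empty sample", call. = FALSE)
  colMeans(.eng_del_counts(pop@ptr, as.integer(idx)))
}

# one GenStats row; sampling must already have happened (idx)
genStatsRow <- function(pop, idx, replicate, phase) {
  bins <- colMeans(.eng_del_counts(pop@ptr, as.integer(idx)))
  data.frame(
    replicate = replicate,
    generation = currentGeneration(pop),
    phase = phase,
    N = popSize(pop),
    K = carryingCapacity(pop),
    mean_het = mean(.eng_het_counts(pop@ptr, as.integer(idx))) /
      totalCodingBp(pop@map),
    mean_Froh = mean(.eng_froh(pop@ptr, as.integer(idx), 1e6)),
    mean_fitness = mean(.eng_fitness(pop@ptr)[idx]),
    n_weak = bins[["n_weak"]],
    n_moderate = bins[["n_moderate"]],
    n_strong = bins[["n_strong"]],
    n_very_strong = bins[["n_very_strong"]],
    row.names = NULL
  )
}

#' Compare extinction times between two groups of replicates
#'
#' Per group: number of uncensored replicates, mean, median and standard
#' deviation of the extinction generation. The treatment group is compared
#' with the baseline as a percent change in mean extinction time,
#' `100 * (mean - mean_baseline) / mean_baseline`, with a one-tailed Welch
#' t-test for an increase. Censored replicates (still extant at
#' max_generations) are excluded from the comparison and reported as a
#' count.
#'
#' @param records extinction table of the treatment group (as produced by
#'   [runReplicates()]), with columns `extinction_generation`, `censored`.
#' @param baseline_records extinction table of the baseline group.
#' @return a list with `summary` (per-group data.frame), `pct_change` and
#'   `p_value`.
#' @export
summarizeExtinctions <- function(records, baseline_records) {
  grab <- function(df, label) {
    t_ext <- df$extinction_generation[!df$censored]
    if (length(t_ext) < 2)
      stop("need at least 2 uncensored replicates in group '", label, "'",
           call. = FALSE)
    data.frame(group = label, n = length(t_ext), n_censored = sum(df$censored),
               mean = mean(t_ext), median = median(t_ext), sd = sd(t_ext))
  }
  s_trt <- grab(records, "treatment")
  s_bas <- grab(baseline_records, "baseline")
  t_trt <- records$extinction_generation[!records$censored]
  t_bas <- baseline_records$extinction_generation[!baseline_records$censored]
  pct <- 100 * (s_trt$mean - s_bas$mean) / s_bas$mean
  p <- if (isTRUE(all.equal(c(t_trt), c(t_bas))) &&
           length(t_trt) == length(t_bas)) 0.5
       else t.test(t_trt, t_bas, alternative = "greater")$p.value
  list(summary = rbind(s_trt, s_bas), pct_change = pct, p_value = p)
}
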