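# Environmental stochasticity and catastrophes. Applied only to the small
# endangered population; ancestral and source populations evolve at
# constant K with no catastrophes.

#' One Ornstein-Uhlenbeck update of the carrying capacity
#'
#' The endangered population's carrying capacity follows a mean-reverting
#' process on the log scale:
#' `log K[t+1] = (1 - phi) log(K_endangered) + phi log K[t] + e`,
#' with `e ~ Normal(0, sigma)`. The realized capacity is `exp(log K)`
#' rounded to the nearest integer with floor 1. With the defaults phi =
#' 0.9 and sigma = log10(1.3) ~= 0.114, the stationary standard deviation
#' of log K is `sigma / sqrt(1 - phi^2) ~= 0.261`, i.e. the realized K
#' fluctuates within roughly +/- 30% of its target (one sd).
#'
#' The log base deserves a note: the literature this process is drawn
#' from prints the innovation scale as log10(1.3) without fixing the base
#' of the process itself. This implementation runs the recursion in
#' natural log with that innovation scale, the only reading under which
#' the model's published neutral-ecology control (extinction of a K = 25
#' population remaining the exception over 10,000 generations, and never
#' observed at K = 50) and its load-driven extinction times are jointly
#' attainable; a uniformly base-10 reading more than doubles the
#' stationary variation and makes ecology alone drive nearly every small
#' population extinct.
#'
#' @param K_current current carrying capacity (the process state; pass
#'   the continuous `log_K` returned previously for an exact chain).
#' @param K_endangered mean-reversion target.
#' @param config a [SimulationConfig-class] (its `ecology` group is used).
#' @param log_K optional continuous process state; when given it
#'   supersedes `K_current` so rounding does not feed back into the chain.
#' @return list with `K` (integer, >= 1) and `log_K` (the continuous
#'   state to pass to the next update).
#' @export
updateCarryingCapacity <- function(K_current, K_endangered,
                                   config = simulationConfig("contraction"),
                                   log_K = NULL) {
  e <- config@ecology
  x <- if (is.null(log_K)) log(K_current) else log_K
  x <- (1 - e$ou_phi) * log(K_endangered) + e$ou_phi * x +
    stats::rnorm(1, 0, e$ou_sigma)
  list(K = max(1L, as.integer(round(exp(x)))), log_K = x)
}

#' Draw a catastrophe mortality probability
#'
#' Each generation an independent probability of mortality due to a
#' catastrophe is drawn from Beta(alpha, beta) (defaults alpha = 0.5,
#' beta = 8, mean ~= 0.059); deaths are then independent Bernoulli trials
#' per individual (see [catastropheMortality()]).
#'
#' @param n number of draws.
#' @param config a [SimulationConfig-class].
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
drawCatastropheProbability <- function(n = 1,
                                       config = simulationConfig("contraction")) {
  e <- config@ecology
  stats::rbeta(n, e$catastrophe_alpha, e$catastrophe_beta)
}

# Pre-draw the full ecology trajectory for one endangered run: realized K
# and catastrophe probability per generation. Drawing these on their own
# RNG stream keeps the genetic dynamics independent of ecology consumption.
ecologySeries <- function(config, n_generations,
                          K_target = config@demography$K_endangered) {
  e <- config@ecology
  K <- integer(n_generations)
  p <- stats::rbeta(n_generations, e$catastrophe_alpha, e$catastrophe_beta)
  x <- log(K_target)
  eps <- stats::rnorm(n_generations, 0, e$ou_sigma)
  for (t in seq_len(n_generations)) {
    x <- (1 - e$ou_phi) * log(K_target) + e$ou_phi * x + eps[t]
    K[t] <- max(1L, as.integer(round(exp(x))))
  }
  data.frame(generation = seq_len(n_generations), K = K, catastrophe_p = p)
}
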