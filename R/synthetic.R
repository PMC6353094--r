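# Synthetic-data generators: a plausible female life table and simulated
# elicitation raw data with known ground truth, so every pipeline stage is
# testable without external downloads.

#' Synthetic female all-cause mortality life table (Gompertz)
#'
#' Annual death probabilities follow a Gompertz hazard,
#' `q(age) = 1 - exp(-h0 * exp(slope * (age - 30)))`. The defaults give
#' `q_annual` between about 5e-4 and 3e-3 over ages 32-50 (cumulative
#' mortality ~2%), the right order of magnitude for women of this age:
#' the disease itself does not contribute to mortality, so the table only
#' has to carry a realistic, near-negligible background. The table is
#' illustrative and does not reproduce any national life table.
#'
#' @param h0 baseline annual hazard at age 30 (> 0).
#' @param slope log-hazard slope per year of age.
#' @param ages integer vector of ages to tabulate.
#' @return Data frame with columns `age`, `q_annual`.
#' @export
#' @examples
#' make_life_table()
make_life_table <- function(h0 = 4e-4, slope = 0.09, ages = 32:50) {
  if (h0 <= 0) stop("baseline hazard must be > 0", call. = FALSE)
  q <- 1 - exp(-h0 * exp(slope * (ages - 30)))
  data.frame(age = as.integer(ages), q_annual = q)
}

#' Validate a life table
#' @param life data frame with columns `age`, `q_annual`.
#' @param start_age,end_age required age coverage.
#' @return The life table, invisibly; errors on violation.
#' @export
validate_life_table <- function(life, start_age = NULL, end_age = NULL) {
  if (!all(c("age", "q_annual") %in% names(life)))
    stop("life table needs columns age, q_annual", call. = FALSE)
  if (any(life$q_annual < 0) || any(life$q_annual >= 1))
    stop("life table: every q_annual must be in [0, 1)", call. = FALSE)
  if (anyDuplicated(life$age))
    stop("life table: duplicated ages", call. = FALSE)
  if (!is.null(start_age)) {
    need <- seq(start_age, end_age - 1)
    if (!all(need %in% life$age))
      stop("life table must cover ages ", start_age, "..", end_age - 1,
           call. = FALSE)
  }
  invisible(life)
}

#' Simulate one month of hypothetical-patient transitions
#'
#' Emulates the elicitation exercise in which `n` hypothetical patients sit
#' in one origin state and their one-month destinations are counted: a
#' multinomial draw over (stay, destinations...) with known true monthly
#' probabilities, for recovery-testing the Beta/Dirichlet fits.
#'
#' @param probs named numeric vector of true monthly exit probabilities
#'   (sum < 1); the stay probability is the residual.
#' @param n cohort size (default 1000, as elicited).
#' @param seed optional integer seed for reproducibility.
#' @return Named numeric vector of counts `(stay, destinations...)` summing
#'   to `n`.
#' @export
simulate_transition_counts <- function(probs, n = 1000, seed = NULL) {
  if (any(probs < 0) || sum(probs) > 1)
    stop("exit probabilities must be >= 0 and sum to <= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- c(stay = 1 - sum(probs), probs)
  counts <- as.numeric(stats::rmultinom(1, size = n, prob = p))
  names(counts) <- names(p)
  counts
}

#' Simulate a roulette ("chips and bins") histogram from a known Beta
#'
#' Chips are allocated over equal-width bins by a multinomial draw with
#' probabilities equal to the Beta probability mass in each bin, emulating a
#' well-calibrated expert whose belief is exactly `Beta(alpha, beta)`.
#'
#' @param alpha,beta true Beta parameters (> 0).
#' @param bins number of equal-width bins over `support` (>= 2).
#' @param chips total chips to place (>= 1).
#' @param support interval to bin, default `c(0, 1)`.
#' @param seed optional integer seed.
#' @return Data frame with columns `bin_low`, `bin_high`, `chips`.
#' @export
simulate_roulette <- function(alpha, beta, bins = 20, chips = 50,
                              support = c(0, 1), seed = NULL) {
  if (alpha <= 0 || beta <= 0) stop("Beta parameters must be > 0", call. = FALSE)
  if (bins < 2) stop("need at least 2 bins", call. = FALSE)
  if (chips < 1) stop("need at least 1 chip", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  edges <- seq(support[1], support[2], length.out = bins + 1)
  mass <- diff(stats::pbeta(edges, alpha, beta))
  if (sum(mass) <= 0) stop("Beta mass is zero on the requested support", call. = FALSE)
  cnt <- as.numeric(stats::rmultinom(1, size = chips, prob = mass))
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1], chips = cnt)
}
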