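# Probabilistic sensitivity analysis: joint sampling of utilities,
# transition rows and unit costs from their elicited distributions, per-draw
# evaluation of both arms, cost-effectiveness plane summary and CEAC.

#' Build the PSA sampling distributions from the loaded inputs
#'
#' Utilities get Beta distributions from their elicited (alpha, beta);
#' transition rows get Beta (single exit) or Dirichlet (two exits, sampled
#' jointly with the stay mass) distributions from the hypothetical-patient
#' pseudo-counts; the GP visit and oral-contraceptive pack costs get Gamma
#' distributions with the published means and an assumed CV
#' ([gamma_from_mean_cv()]); analgesic unit costs are fixed. Utilities are
#' state properties, so one utility set is shared by both arms within a
#' draw.
#'
#' @param inputs an `ep_inputs` bundle.
#' @param precision_scale multiplier on every Beta/Dirichlet pseudo-count
#'   and Gamma shape; values > 1 shrink all sampling variances by roughly
#'   that factor while keeping the means, which is useful for degenerate
#'   limit checks. Default 1 (the elicited uncertainty).
#' @return A list of `ep_dist` objects: `utilities` (per state),
#'   `transitions` (per arm, per origin row) and `costs`.
#' @export
psa_distributions <- function(inputs, precision_scale = 1) {
  if (precision_scale <= 0) stop("precision_scale must be > 0", call. = FALSE)
  ps <- precision_scale
  alive <- ep_states(alive_only = TRUE)
  utilities <- lapply(inputs$utilities, function(u)
    ep_dist("beta", alpha = ps * u$alpha, beta = ps * u$beta))

  transitions <- lapply(ep_arms(), function(arm) {
    rows <- inputs$transitions[[paste0(arm, "_psa")]]
    lapply(rows, function(row) {
      a <- vapply(row, function(d) d$alpha, numeric(1))
      n <- row[[1]]$alpha + row[[1]]$beta
      if (length(a) == 1)
        ep_dist("beta", alpha = ps * a, beta = ps * (n - a))
      else
        ep_dist("dirichlet", alpha = ps * c(stay = n - sum(a), a))
    })
  })
  names(transitions) <- ep_arms()

  cv <- inputs$costs$cost_cv / sqrt(ps)
  list(utilities = utilities,
       transitions = transitions,
       costs = list(
         gp_visit = gamma_from_mean_cv(inputs$costs$gp_visit_cost, cv),
         oc_pack = gamma_from_mean_cv(inputs$costs$oc_pack_cost, cv)))
}

#' Sample one PSA parameter draw
#'
#' Consumes the current RNG state (seed management belongs to the caller,
#' see [run_psa()]). Each sampled transition row is returned as a full 4x4
#' matrix with the stay probability as the residual, so rows sum to 1 by
#' construction.
#'
#' @param dists distribution set from [psa_distributions()].
#' @return A list with `utilities` (named vector), `transitions` (per-arm
#'   4x4 matrices) and `costs` (`gp_visit`, `oc_pack`).
#' @export
sample_draw <- function(dists) {
  alive <- ep_states(alive_only = TRUE)
  u <- vapply(alive, function(s) ep_dist_sample(dists$utilities[[s]], 1),
              numeric(1))
  trans <- lapply(ep_arms(), function(arm) {
    P <- matrix(0, 4, 4, dimnames = list(alive, alive))
    for (origin in names(dists$transitions[[arm]])) {
      d <- dists$transitions[[arm]][[origin]]
      i <- match(origin, alive)
      dest <- names(.ep_exit_destinations(d, origin))
      if (d$family %in% c("beta", "fixed")) {
        P[i, dest] <- ep_dist_sample(d, 1)
      } else {
        x <- ep_dist_sample(d, 1)[1, ]
        P[i, dest] <- x[-1]  # drop the stay component
      }
    }
    diag(P) <- 1 - rowSums(P)
    P
  })
  names(trans) <- ep_arms()
  list(utilities = u,
       transitions = trans,
       costs = list(gp_visit = ep_dist_sample(dists$costs$gp_visit, 1),
                    oc_pack = ep_dist_sample(dists$costs$oc_pack, 1)))
}

# destination names for a row distribution: Beta rows keep their single
# destination in names(alpha)[?]; Dirichlet rows carry (stay, dest...)
.ep_exit_destinations <- function(d, origin) {
  if (d$family == "dirichlet") d$alpha[-1]
  else {
    # single-exit rows: the destination is the adjacent state recorded at
    # fit time; reconstruct from the origin (boundary states of the chain)
    dest <- switch(origin, no_pain = "mild", severe = "moderate",
                   stop("ambiguous single-exit origin: ", origin, call. = FALSE))
    stats::setNames(1, dest)
  }
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets, evaluates both arms through the cohort
#' engine for each, and records the incremental pair (delta QALY, delta
#' cost) per draw. Any single-draw engine failure is excluded and counted,
#' and the run continues. Fixed seeds give byte-identical outputs.
#'
#' @param inputs an `ep_inputs` bundle.
#' @param n_draws number of draws (default from the configuration).
#' @param seed integer seed (default from the configuration).
#' @param precision_scale see [psa_distributions()].
#' @return An object of class `ep_psa`: `draws` (data frame with per-draw
#'   arm totals, deltas and plane quadrant), `n_failed`, `seed` and
#'   `quadrants` (named proportions NE/NW/SE/SW).
#' @export
run_psa <- function(inputs, n_draws = NULL, seed = NULL, precision_scale = 1) {
  if (is.null(n_draws)) n_draws <- inputs$psa$n_draws
  if (is.null(seed)) seed <- inputs$psa$seed
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  dists <- psa_distributions(inputs, precision_scale)
  set.seed(seed)
  rows <- vector("list", n_draws)
  n_failed <- 0L
  for (i in seq_len(n_draws)) {
    rows[[i]] <- tryCatch({
      dr <- sample_draw(dists)
      res <- lapply(ep_arms(), function(arm)
        run_cohort(inputs, pars = arm_parameters(
          inputs, arm,
          transitions = dr$transitions[[arm]],
          utilities = dr$utilities,
          gp_visit_cost = dr$costs$gp_visit,
          oc_pack_cost = dr$costs$oc_pack))$result)
      names(res) <- ep_arms()
      data.frame(draw = i,
                 cost_nht = res$nht$cost, qaly_nht = res$nht$qaly,
                 cost_oc = res$oc$cost, qaly_oc = res$oc$qaly,
                 delta_cost = res$oc$cost - res$nht$cost,
                 delta_qaly = res$oc$qaly - res$nht$qaly)
    }, error = function(e) NULL)
    if (is.null(rows[[i]])) n_failed <- n_failed + 1L
  }
  draws <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(draws) || nrow(draws) == 0)
    stop("every PSA draw failed", call. = FALSE)
  if (n_failed > 0)
    warning(n_failed, " PSA draw(s) failed and were excluded")
  draws$quadrant <- ifelse(draws$delta_qaly > 0,
                           ifelse(draws$delta_cost < 0, "SE", "NE"),
                           ifelse(draws$delta_cost < 0, "SW", "NW"))
  quad <- vapply(c(NE = "NE", NW = "NW", SE = "SE", SW = "SW"),
                 function(q) mean(draws$quadrant == q), numeric(1))
  structure(list(draws = draws, n_failed = n_failed, seed = seed,
                 quadrants = quad),
            class = "ep_psa")
}

#' @export
print.ep_psa <- function(x, ...) {
  cat(sprintf("<ep_psa> %d draws (seed %s), quadrants: %s\n",
              nrow(x$draws), format(x$seed),
              paste(sprintf("%s %.1f%%", names(x$quadrants),
                            100 * x$quadrants), collapse = ", ")))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the probability that each arm has
#' the maximal net monetary benefit across the PSA draws; exact NMB ties are
#' split equally between the arms. The default grid is 0 to 50,000 GBP/QALY
#' in steps of 1,000 plus an unbounded sentinel (`Inf`, read "50,000+"),
#' where the comparison reduces to the sign of the QALY difference.
#'
#' @param psa an `ep_psa` object.
#' @param thresholds non-negative, sorted thresholds (GBP/QALY).
#' @return Data frame `threshold`, `p_oc`, `p_nht` with `p_oc + p_nht = 1`.
#' @export
ceac <- function(psa, thresholds = c(seq(0, 50000, by = 1000), Inf)) {
  stopifnot(inherits(psa, "ep_psa"))
  if (nrow(psa$draws) == 0) stop("empty PSA result", call. = FALSE)
  if (any(thresholds < 0) || is.unsorted(thresholds))
    stop("thresholds must be non-negative and sorted", call. = FALSE)
  dq <- psa$draws$delta_qaly
  dc <- psa$draws$delta_cost
  p_oc <- vapply(thresholds, function(l) {
    d <- if (is.finite(l)) l * dq - dc else sign(dq) + ifelse(dq == 0, sign(-dc), 0)
    mean(d > 0) + 0.5 * mean(d == 0)
  }, numeric(1))
  data.frame(threshold = thresholds, p_oc = p_oc, p_nht = 1 - p_oc)
}

#' Export PSA draws to CSV
#' @param psa an `ep_psa` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  utils::write.csv(
    psa$draws[, c("draw", "delta_cost", "delta_qaly", "quadrant")],
    path, row.names = FALSE)
  invisible(path)
}

#' Cost-effectiveness plane plot
#'
#' Scatter of the per-draw incremental pairs, effect difference on the
#' x-axis and cost difference on the y-axis, with the origin axes drawn.
#'
#' @param psa an `ep_psa` object.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "Incremental QALYs (OC - no hormonal treatment)",
                  y = "Incremental cost, £ (OC - no hormonal treatment)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#' @param curves data frame from [ceac()] (the `Inf` sentinel row is dropped).
#' @return A ggplot object.
#' @export
plot_ceac <- function(curves) {
  d <- curves[is.finite(curves$threshold), ]
  long <- data.frame(
    threshold = rep(d$threshold, 2),
    probability = c(d$p_oc, d$p_nht),
    arm = rep(c("Oral contraceptives", "No hormonal treatment"),
              each = nrow(d)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$probability,
                                     colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay threshold, £/QALY",
                  y = "Probability cost-effective", colour = NULL,
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}
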