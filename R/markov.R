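# The monthly cohort engine: per-arm parameter assembly, transition matrices
# with the all-cause mortality overlay, occupancy propagation, half-cycle
# correction, discounting and cost/QALY accrual.

#' Assemble the per-arm parameters for one model run
#'
#' Collects everything [run_cohort()] needs for one arm: the 4x4 monthly
#' pain-transition matrix, the per-state monthly cost components and the
#' per-state utilities. The override arguments exist so the PSA and the
#' sensitivity analyses can re-run the engine with perturbed values without
#' touching the loaded configuration.
#'
#' Monthly costs per alive state are
#' \itemize{
#'   \item drug: the oral-contraceptive pack cost divided by the months a
#'     pack covers, in the OC arm only;
#'   \item GP consultations: visit cost / visit interval (amortised mode,
#'     default), or the full visit cost charged in the cycles where a visit
#'     falls (lumped mode);
#'   \item analgesics: paracetamol and ibuprofen maximum-dose monthly costs
#'     scaled by the pain-state dose rule (none; half paracetamol; full
#'     paracetamol; full paracetamol + full ibuprofen).
#' }
#'
#' @param inputs an `ep_inputs` bundle from [load_config()].
#' @param arm `"nht"` or `"oc"`.
#' @param transitions optional replacement 4x4 monthly transition matrix
#'   (rows may carry exit probabilities only; the diagonal is recomputed).
#' @param utilities optional named vector of per-state utilities.
#' @param gp_visit_cost,oc_pack_cost optional cost overrides (GBP).
#' @return An object of class `ep_arm_parameters`.
#' @export
arm_parameters <- function(inputs, arm = c("nht", "oc"), transitions = NULL,
                           utilities = NULL, gp_visit_cost = NULL,
                           oc_pack_cost = NULL) {
  arm <- match.arg(arm)
  alive <- ep_states(alive_only = TRUE)
  cc <- inputs$costs

  P <- if (is.null(transitions)) inputs$transitions[[arm]] else {
    stopifnot(identical(dim(transitions), c(4L, 4L)))
    P <- transitions
    diag(P) <- 0
    diag(P) <- 1 - rowSums(P)
    if (any(diag(P) < 0)) stop("transition row exits sum to > 1", call. = FALSE)
    dimnames(P) <- list(alive, alive)
    P
  }

  u <- if (is.null(utilities)) {
    vapply(alive, function(s) inputs$utilities[[s]]$mean, numeric(1))
  } else utilities[alive]
  if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]", call. = FALSE)

  gp_cost <- if (is.null(gp_visit_cost)) cc$gp_visit_cost else gp_visit_cost
  pack <- if (is.null(oc_pack_cost)) cc$oc_pack_cost else oc_pack_cost
  drug_monthly <- if (arm == "oc") pack / cc$oc_pack_months else 0
  analgesic <- vapply(alive, function(s) {
    sc <- cc$analgesic_scaling[[s]]
    sc$paracetamol * cc$paracetamol_month_max + sc$ibuprofen * cc$ibuprofen_month_max
  }, numeric(1))

  structure(list(
    arm = arm,
    transitions = P,
    utilities = u,
    drug_monthly = drug_monthly,
    gp_visit_cost = gp_cost,
    gp_interval = cc$gp_interval_months[[arm]],
    gp_cost_mode = cc$gp_cost_mode,
    analgesic = analgesic
  ), class = "ep_arm_parameters")
}

#' Monthly transition matrix with the mortality overlay
#'
#' Death is cause-independent: the monthly death probability
#' `q_m = 1 - (1 - q_annual)^(1/12)` applies identically from every alive
#' state, the remaining mass `1 - q_m` is distributed over the arm's pain
#' transitions, and dead is absorbing. The disease itself contributes
#' nothing to mortality.
#'
#' @param pain 4x4 row-stochastic monthly matrix over the alive states.
#' @param q_annual annual all-cause death probability at the current age.
#' @return 5x5 row-stochastic matrix (fifth state: dead).
#' @export
build_transition_matrix <- function(pain, q_annual) {
  if (q_annual < 0 || q_annual > 1)
    stop("q_annual must be in [0, 1]", call. = FALSE)
  if (any(pain < 0) || any(abs(rowSums(pain) - 1) > 1e-9))
    stop("pain transition matrix must be row-stochastic", call. = FALSE)
  q_m <- 1 - (1 - q_annual)^(1 / 12)
  M <- matrix(0, 5, 5, dimnames = list(ep_states(), ep_states()))
  M[1:4, 1:4] <- pain * (1 - q_m)
  M[1:4, 5] <- q_m
  M[5, 5] <- 1
  M
}

#' Discount factor for a monthly cycle
#'
#' Converts the annual rate to cycles by compound interest:
#' `factor = (1 + rate)^(-cycle/12)` (default), or by the simple monthly
#' conversion `(1 + rate/12)^(-cycle)`. Accrual in cycle 0 is undiscounted.
#'
#' @param cycle cycle index (0-based); vectorised.
#' @param annual_rate annual discount rate (>= 0).
#' @param compounding `"compound"` or `"simple"`.
#' @return Numeric discount factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(12, 0.035)  # 1/1.035
discount_factor <- function(cycle, annual_rate, compounding = "compound") {
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  if (any(cycle < 0)) stop("cycle must be >= 0", call. = FALSE)
  switch(compounding,
    compound = (1 + annual_rate)^(-cycle / 12),
    simple = (1 + annual_rate / 12)^(-cycle),
    stop("unknown compounding mode", call. = FALSE))
}

# Per-cycle monthly cost rows (cycles x 4 alive states) for one arm.
# Amortised mode spreads GP visits uniformly; lumped mode charges the full
# visit cost in the cycles where a visit falls (end of each interval).
.ep_cost_matrix <- function(pars, n_cycles) {
  base <- pars$drug_monthly + pars$analgesic  # length 4
  cost <- matrix(rep(base, each = n_cycles), nrow = n_cycles)
  if (pars$gp_cost_mode == "amortised") {
    cost <- cost + pars$gp_visit_cost / pars$gp_interval
  } else {
    visit <- ((seq_len(n_cycles)) %% pars$gp_interval) == 0
    cost[visit, ] <- cost[visit, ] + pars$gp_visit_cost
  }
  cost
}

#' Run the monthly cohort model for one arm
#'
#' Propagates the cohort occupancy through `(end_age - start_age) * 12`
#' monthly cycles, refreshing the mortality overlay once per model year
#' from the life table. With half-cycle correction on (default), cycle
#' accrual is weighted by the trapezoidal effective occupancy, the mean of
#' the start- and end-of-cycle occupancy. QALYs accrue as
#' `effective occupancy x utility / 12` per cycle; costs accrue from the
#' per-state monthly cost rows. Both are discounted by [discount_factor()].
#'
#' @param inputs an `ep_inputs` bundle.
#' @param arm `"nht"` or `"oc"`; ignored when `pars` is given.
#' @param pars an [arm_parameters()] object, for running with overrides.
#' @param half_cycle_correction optional override of the configured flag.
#' @return A list of class `ep_cohort_run`:
#' \describe{
#'   \item{trace}{data frame, one row per cycle: `cycle`, `age`, the five
#'     occupancy fractions, `discount_factor`, the effective alive-state
#'     occupancies, and per-cycle discounted accrual `cost_accrued`,
#'     `qaly_accrued`.}
#'   \item{result}{`ep_arm_result`: totals `cost`, `qaly`, undiscounted
#'     counterparts and the discounted cost components `cost_drug`,
#'     `cost_gp`, `cost_analgesic`.}
#' }
#' @export
#' @examples
#' inputs <- load_config()
#' run <- run_cohort(inputs, "oc")
#' run$result$qaly
run_cohort <- function(inputs, arm = c("nht", "oc"), pars = NULL,
                       half_cycle_correction = NULL) {
  arm <- match.arg(arm)
  if (is.null(pars)) pars <- arm_parameters(inputs, arm)
  m <- inputs$model
  hcc <- if (is.null(half_cycle_correction)) m$half_cycle_correction else half_cycle_correction
  T_ <- m$n_cycles
  alive <- ep_states(alive_only = TRUE)

  q_of_age <- stats::setNames(inputs$life_table$q_annual, inputs$life_table$age)
  ages <- m$start_age + (0:(T_ - 1)) %/% 12
  M_by_year <- lapply(unique(ages), function(a)
    build_transition_matrix(pars$transitions, q_of_age[[as.character(a)]]))
  names(M_by_year) <- unique(ages)

  occ <- matrix(0, T_ + 1, 5, dimnames = list(NULL, ep_states()))
  occ[1, alive] <- m$initial_distribution
  for (t in seq_len(T_)) {
    occ[t + 1, ] <- occ[t, ] %*% M_by_year[[as.character(ages[t])]]
    if (abs(sum(occ[t + 1, ]) - 1) > 1e-9)
      stop("occupancy conservation breached at cycle ", t, call. = FALSE)
  }

  eff <- if (hcc) (occ[1:T_, alive] + occ[2:(T_ + 1), alive]) / 2 else occ[1:T_, alive]
  df <- discount_factor(0:(T_ - 1), m$annual_discount_rate, m$discount_compounding)
  cost_rows <- .ep_cost_matrix(pars, T_)

  qaly_cycle_undisc <- as.numeric(eff %*% (pars$utilities / 12))
  cost_cycle_undisc <- rowSums(eff * cost_rows)
  comp <- function(rows) sum(df * rowSums(eff * rows))
  n4 <- matrix(0, T_, 4)
  drug_rows <- n4 + rep(pars$drug_monthly, each = T_)
  gp_rows <- cost_rows - drug_rows - rep(pars$analgesic, each = T_)

  result <- structure(list(
    arm = pars$arm,
    cost = sum(df * cost_cycle_undisc),
    qaly = sum(df * qaly_cycle_undisc),
    cost_undiscounted = sum(cost_cycle_undisc),
    qaly_undiscounted = sum(qaly_cycle_undisc),
    cost_drug = comp(drug_rows),
    cost_gp = comp(gp_rows),
    cost_analgesic = comp(n4 + rep(pars$analgesic, each = T_))
  ), class = "ep_arm_result")

  trace <- data.frame(cycle = 0:(T_ - 1), age = ages, occ[1:T_, ],
                      discount_factor = df,
                      effective = I(eff),
                      cost_accrued = df * cost_cycle_undisc,
                      qaly_accrued = df * qaly_cycle_undisc)

  structure(list(trace = trace, occupancy = occ, result = result, pars = pars),
            class = "ep_cohort_run")
}

#' @export
print.ep_arm_result <- function(x, ...) {
  cat(sprintf("<ep_arm_result %s> cost £%.2f, %.4f QALYs (undiscounted £%.2f, %.4f)\n",
              x$arm, x$cost, x$qaly, x$cost_undiscounted, x$qaly_undiscounted))
  cat(sprintf("  components: drug £%.2f, GP £%.2f, analgesic £%.2f\n",
              x$cost_drug, x$cost_gp, x$cost_analgesic))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' Long format, one row per cycle and state:
#' `cycle,age,state,occupancy,effective_occupancy,discount_factor,cost_accrued,qaly_accrued`
#' (per-cycle accruals are repeated across the states of a cycle).
#'
#' @param run an `ep_cohort_run`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(run, path) {
  tr <- run$trace
  alive <- ep_states(alive_only = TRUE)
  long <- do.call(rbind, lapply(ep_states(), function(s) {
    data.frame(cycle = tr$cycle, age = tr$age, state = s,
               occupancy = tr[[s]],
               effective_occupancy = if (s %in% alive) tr$effective[, s] else NA,
               discount_factor = tr$discount_factor,
               cost_accrued = tr$cost_accrued, qaly_accrued = tr$qaly_accrued)
  }))
  long <- long[order(long$cycle), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
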