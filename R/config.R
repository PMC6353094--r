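# Loading and validation of all model inputs.
#
# One YAML file carries the run settings (sections: model, costs, utilities,
# transitions.nht, transitions.oc, psa) plus a pointer to a two-column
# life-table CSV (`age,q_annual`); "bundled" selects the synthetic table
# shipped with the package.

.ep_err <- function(...) stop(..., call. = FALSE)

#' Path to the bundled default configuration
#' @return File path of the YAML configuration that encodes the published
#'   base-case inputs.
#' @export
ep_default_config <- function() {
  system.file("extdata", "default_config.yaml", package = "endopain",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads the YAML configuration and the life table it references, checks
#' every structural invariant (state coverage, probability ranges, cost
#' signs, utility ordering, transition adjacency, life-table coverage) and
#' returns the validated input bundle used by every other function.
#'
#' @param path YAML configuration file; default the bundled base case.
#' @return An object of class `ep_inputs`: a list with elements `model`,
#'   `costs`, `utilities`, `transitions`, `life_table` and `path`.
#' @export
#' @examples
#' inputs <- load_config()
#' inputs$transitions$nht["moderate", "severe"]  # 0.003
load_config <- function(path = ep_default_config()) {
  if (!file.exists(path)) .ep_err("configuration file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) .ep_err("configuration parse failure in '",
                                              path, "': ", conditionMessage(e)))
  for (sec in c("model", "costs", "utilities", "transitions"))
    if (is.null(cfg[[sec]])) .ep_err("missing configuration section '", sec, "'")

  model <- .ep_validate_model(cfg$model)
  costs <- .ep_validate_costs(cfg$costs)
  utilities <- .ep_validate_utilities(cfg$utilities)
  transitions <- .ep_validate_transitions(cfg$transitions)

  lt_ref <- if (is.null(cfg$life_table)) "bundled" else cfg$life_table
  life <- .ep_load_life_table(lt_ref, dirname(path))
  validate_life_table(life, model$start_age, model$end_age)

  psa <- cfg$psa
  if (is.null(psa)) psa <- list()
  if (is.null(psa$n_draws)) psa$n_draws <- 1000
  if (is.null(psa$seed)) psa$seed <- 42L
  if (psa$n_draws < 1) .ep_err("psa.n_draws must be >= 1")

  structure(list(model = model, costs = costs, utilities = utilities,
                 transitions = transitions, life_table = life, psa = psa,
                 path = path),
            class = "ep_inputs")
}

.ep_validate_model <- function(m) {
  for (f in c("start_age", "end_age", "annual_discount_rate", "initial_distribution"))
    if (is.null(m[[f]])) .ep_err("model.", f, " is missing")
  if (m$end_age <= m$start_age) .ep_err("model.end_age must exceed model.start_age")
  if (m$annual_discount_rate < 0) .ep_err("model.annual_discount_rate must be >= 0")
  if (is.null(m$cycle_length_months)) m$cycle_length_months <- 1
  if (m$cycle_length_months != 1)
    .ep_err("model.cycle_length_months: only monthly cycles are supported")
  if (is.null(m$half_cycle_correction)) m$half_cycle_correction <- TRUE
  if (is.null(m$discount_compounding)) m$discount_compounding <- "compound"
  if (!m$discount_compounding %in% c("compound", "simple"))
    .ep_err("model.discount_compounding must be 'compound' or 'simple'")
  init <- unlist(m$initial_distribution)
  alive <- ep_states(alive_only = TRUE)
  if (!setequal(names(init), alive))
    .ep_err("model.initial_distribution must name exactly the states ",
            paste(alive, collapse = ", "))
  init <- init[alive]
  if (any(init < 0)) .ep_err("model.initial_distribution entries must be >= 0")
  if (abs(sum(init) - 1) > 1e-6)
    .ep_err("model.initial_distribution must sum to 1 (got ",
            format(sum(init)), ")")
  m$initial_distribution <- init / sum(init)
  m$n_cycles <- as.integer((m$end_age - m$start_age) * 12)
  m
}

.ep_validate_costs <- function(cc) {
  for (f in c("gp_visit_cost", "gp_interval_months", "oc_pack_cost",
              "oc_pack_months", "paracetamol_month_max", "ibuprofen_month_max",
              "analgesic_scaling"))
    if (is.null(cc[[f]])) .ep_err("costs.", f, " is missing")
  num <- c(cc$gp_visit_cost, cc$oc_pack_cost, cc$paracetamol_month_max,
           cc$ibuprofen_month_max)
  if (any(num < 0)) .ep_err("costs must be >= 0")
  for (arm in ep_arms())
    if (is.null(cc$gp_interval_months[[arm]]) || cc$gp_interval_months[[arm]] <= 0)
      .ep_err("costs.gp_interval_months.", arm, " must be a positive number of months")
  if (cc$oc_pack_months <= 0) .ep_err("costs.oc_pack_months must be > 0")
  if (is.null(cc$gp_cost_mode)) cc$gp_cost_mode <- "amortised"
  if (!cc$gp_cost_mode %in% c("amortised", "lumped"))
    .ep_err("costs.gp_cost_mode must be 'amortised' or 'lumped'")
  if (is.null(cc$cost_cv)) cc$cost_cv <- 0.2
  if (cc$cost_cv <= 0) .ep_err("costs.cost_cv must be > 0")
  alive <- ep_states(alive_only = TRUE)
  sc <- cc$analgesic_scaling
  if (!setequal(names(sc), alive))
    .ep_err("costs.analgesic_scaling must name exactly the alive states")
  for (s in alive)
    for (d in c("paracetamol", "ibuprofen")) {
      v <- sc[[s]][[d]]
      if (is.null(v) || v < 0)
        .ep_err("costs.analgesic_scaling.", s, ".", d, " must be >= 0")
    }
  cc
}

.ep_validate_utilities <- function(uu) {
  alive <- ep_states(alive_only = TRUE)
  if (!setequal(names(uu), alive))
    .ep_err("utilities must name exactly the alive states")
  mean_u <- vapply(alive, function(s) {
    u <- uu[[s]]
    for (f in c("mean", "alpha", "beta"))
      if (is.null(u[[f]])) .ep_err("utilities.", s, ".", f, " is missing")
    if (u$mean < 0 || u$mean > 1) .ep_err("utilities.", s, ".mean must be in [0, 1]")
    if (u$alpha <= 0 || u$beta <= 0) .ep_err("utilities.", s, ": Beta parameters must be > 0")
    u$mean
  }, numeric(1))
  if (any(diff(mean_u) >= 0))
    .ep_err("utilities must strictly decrease with pain severity")
  uu[alive]
}

# Transition section -> per-arm 4x4 monthly matrices over the alive states
# plus the per-row PSA pseudo-count structure.
.ep_validate_transitions <- function(tt) {
  alive <- ep_states(alive_only = TRUE)
  out <- list()
  for (arm in ep_arms()) {
    sec <- tt[[arm]]
    if (is.null(sec)) .ep_err("transitions.", arm, " is missing")
    P <- matrix(0, 4, 4, dimnames = list(alive, alive))
    psa_rows <- list()
    for (origin in names(sec)) {
      if (!origin %in% alive) .ep_err("transitions.", arm, ": unknown state '", origin, "'")
      row <- sec[[origin]]
      i <- match(origin, alive)
      for (dest in names(row)) {
        if (!dest %in% alive) .ep_err("transitions.", arm, ".", origin,
                                      ": unknown destination '", dest, "'")
        j <- match(dest, alive)
        if (abs(i - j) != 1)
          .ep_err("transitions.", arm, ".", origin, " -> ", dest,
                  ": only adjacent-severity transitions are permitted")
        p <- row[[dest]]$p
        if (is.null(p) || p < 0 || p > 1)
          .ep_err("transitions.", arm, ".", origin, ".", dest,
                  ".p must be a probability")
        P[i, j] <- p
      }
      if (sum(P[i, ]) >= 1)
        .ep_err("transitions.", arm, ".", origin,
                ": exit probabilities must sum to < 1")
      psa_rows[[origin]] <- row
    }
    diag(P) <- 1 - rowSums(P)
    out[[arm]] <- P
    out[[paste0(arm, "_psa")]] <- psa_rows
  }
  out
}

.ep_load_life_table <- function(ref, base_dir) {
  if (identical(ref, "bundled")) {
    path <- system.file("extdata", "life_table_synthetic.csv",
                        package = "endopain", mustWork = TRUE)
  } else {
    path <- if (file.exists(ref)) ref else file.path(base_dir, ref)
    if (!file.exists(path)) .ep_err("life table file not found: ", ref)
  }
  utils::read.csv(path)
}

#' Serialise inputs back to a configuration file
#'
#' Writes a YAML file that [load_config()] reads back to identical values
#' (round-trip contract). The life table is referenced, not embedded.
#'
#' @param inputs an `ep_inputs` object.
#' @param path output YAML path.
#' @param life_table_ref reference to store in the `life_table` key.
#' @return `path`, invisibly.
#' @export
write_config <- function(inputs, path, life_table_ref = "bundled") {
  stopifnot(inherits(inputs, "ep_inputs"))
  alive <- ep_states(alive_only = TRUE)
  tr <- list()
  for (arm in ep_arms()) tr[[arm]] <- inputs$transitions[[paste0(arm, "_psa")]]
  cfg <- list(
    model = list(
      start_age = inputs$model$start_age,
      end_age = inputs$model$end_age,
      cycle_length_months = inputs$model$cycle_length_months,
      annual_discount_rate = inputs$model$annual_discount_rate,
      discount_compounding = inputs$model$discount_compounding,
      half_cycle_correction = inputs$model$half_cycle_correction,
      initial_distribution = as.list(inputs$model$initial_distribution)),
    costs = inputs$costs[c("gp_visit_cost", "gp_interval_months", "gp_cost_mode",
                           "oc_pack_cost", "oc_pack_months",
                           "paracetamol_month_max", "ibuprofen_month_max",
                           "analgesic_scaling", "cost_cv")],
    utilities = inputs$utilities,
    transitions = tr,
    psa = inputs$psa[c("n_draws", "seed")],
    life_table = life_table_ref)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @export
print.ep_inputs <- function(x, ...) {
  m <- x$model
  cat("<ep_inputs> ", basename(x$path), "\n", sep = "")
  cat(sprintf("  cohort: ages %d-%d, %d monthly cycles, discount %.1f%%/yr (%s), HCC %s\n",
              m$start_age, m$end_age, m$n_cycles, 100 * m$annual_discount_rate,
              m$discount_compounding, if (m$half_cycle_correction) "on" else "off"))
  cat("  initial split:",
      paste(sprintf("%s %.3f", names(m$initial_distribution),
                    m$initial_distribution), collapse = ", "), "\n")
  invisible(x)
}
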