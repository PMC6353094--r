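# Deterministic economics: incremental comparison, dominance classification,
# ICER, net monetary benefit, and the one-way sensitivity analysis that
# removes GP consultation costs.

#' Incremental comparison of two arms
#'
#' Differences are intervention minus comparator. A strategy dominates when
#' it is at least as effective and at least as cheap with at least one
#' strict inequality; the ICER `delta_cost / delta_qaly` is reported only
#' when the signs do not already settle the decision (a negative ICER is
#' meaningless and is never printed).
#'
#' @param comparator,intervention `ep_arm_result` objects (comparator:
#'   no hormonal treatment; intervention: oral contraceptives).
#' @return An object of class `ep_incremental` with `delta_cost`,
#'   `delta_qaly`, `icer` (`NA` unless reported) and `verdict`, one of
#'   `"intervention_dominates"`, `"comparator_dominates"`,
#'   `"icer_reported"`, `"equivalent"`.
#' @export
#' @examples
#' nht <- structure(list(arm = "nht", cost = 1707, qaly = 9.88),
#'                  class = "ep_arm_result")
#' oc <- structure(list(arm = "oc", cost = 1113, qaly = 10.31),
#'                 class = "ep_arm_result")
#' compare_arms(nht, oc)$verdict  # "intervention_dominates"
compare_arms <- function(comparator, intervention) {
  stopifnot(inherits(comparator, "ep_arm_result"),
            inherits(intervention, "ep_arm_result"))
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qaly - comparator$qaly
  verdict <-
    if (dq == 0 && dc == 0) "equivalent"
    else if (dq >= 0 && dc <= 0) "intervention_dominates"
    else if (dq <= 0 && dc >= 0) "comparator_dominates"
    else "icer_reported"
  icer <- if (verdict == "icer_reported") dc / dq else NA_real_
  structure(list(comparator = comparator$arm, intervention = intervention$arm,
                 delta_cost = dc, delta_qaly = dq, icer = icer,
                 verdict = verdict),
            class = "ep_incremental")
}

#' @export
print.ep_incremental <- function(x, ...) {
  cat(sprintf("<ep_incremental %s vs %s> dCost £%.2f, dQALY %.4f: %s",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly,
              x$verdict))
  if (!is.na(x$icer)) cat(sprintf(" (ICER £%.2f/QALY)", x$icer))
  cat("\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = threshold x QALYs - cost`; the ranking statistic behind the
#' cost-effectiveness acceptability curve.
#'
#' @param result an `ep_arm_result` (or any list with `cost` and `qaly`).
#' @param threshold willingness to pay, GBP per QALY (>= 0).
#' @return NMB in GBP.
#' @export
nmb <- function(result, threshold) {
  if (any(threshold < 0)) stop("threshold must be >= 0", call. = FALSE)
  threshold * result$qaly - result$cost
}

#' One-way sensitivity analysis: exclude GP consultations
#'
#' Re-runs both arms with the GP visit cost set to zero and everything else
#' unchanged. Costs do not feed back into the trace, so the QALY totals are
#' bit-identical to the base case; only the cost side moves.
#'
#' @param inputs an `ep_inputs` bundle.
#' @return List with `nht`, `oc` (the re-run `ep_arm_result`s) and
#'   `incremental` (their [compare_arms()] summary).
#' @export
one_way_sa_exclude_gp <- function(inputs) {
  res <- lapply(ep_arms(), function(arm)
    run_cohort(inputs, pars = arm_parameters(inputs, arm, gp_visit_cost = 0))$result)
  names(res) <- ep_arms()
  list(nht = res$nht, oc = res$oc,
       incremental = compare_arms(res$nht, res$oc))
}

#' Export deterministic results in the published table layout
#'
#' Two arm rows (`arm,total_cost,total_qalys`) followed by a mean-difference
#' row with the ICER column carrying either the ratio or the dominance
#' verdict.
#'
#' @param nht,oc `ep_arm_result` objects.
#' @param path output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_results_csv <- function(nht, oc, path) {
  inc <- compare_arms(nht, oc)
  icer_txt <- switch(inc$verdict,
    intervention_dominates = "comparator dominated",
    comparator_dominates = "intervention dominated",
    equivalent = "equivalent",
    icer_reported = sprintf("%.2f", inc$icer))
  out <- data.frame(
    row = c("no_hormonal_treatment", "oral_contraceptives", "mean_difference"),
    total_cost = c(nht$cost, oc$cost, inc$delta_cost),
    total_qalys = c(nht$qaly, oc$qaly, inc$delta_qaly),
    icer = c("", "", icer_txt))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
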