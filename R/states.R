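# Health-state space shared by every module.

#' Health states of the pain model
#'
#' The model distinguishes four alive states defined by the numerical rating
#' scale (NRS) for pain, plus an absorbing all-cause-mortality state.
#'
#' @param alive_only if `TRUE`, drop the absorbing `dead` state.
#' @return Character vector of state names, in model order.
#' @export
#' @examples
#' ep_states()
ep_states <- function(alive_only = FALSE) {
  s <- c("no_pain", "mild", "moderate", "severe", "dead")
  if (alive_only) s[1:4] else s
}

#' NRS pain-score ranges defining the alive states
#'
#' No pain corresponds to an NRS of 0, mild pain to 1-3, moderate pain to
#' 4-6 and severe pain to 7-10. The ranges are disjoint and cover the whole
#' 0-10 scale; the dead state carries no NRS range.
#'
#' @return Data frame with columns `state`, `nrs_low`, `nrs_high`.
#' @export
ep_nrs_ranges <- function() {
  data.frame(
    state = ep_states(alive_only = TRUE),
    nrs_low = c(0L, 1L, 4L, 7L),
    nrs_high = c(0L, 3L, 6L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Arm identifiers
#'
#' `"nht"` is the comparator (no hormonal treatment, analgesics only);
#' `"oc"` is the intervention (combined oral contraceptives).
#'
#' @return Character vector of the two arm ids.
#' @export
ep_arms <- function() c("nht", "oc")
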