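# Year-1 decision tree: a five-branch chance node over the first-year
# clinical outcomes. Branches are mutually exclusive single outcomes (no
# within-year compounding); the residual branch is event-free.

#' Run the one-year decision tree for one treatment arm
#'
#' Distributes the cohort over the five first-year outcomes — event-free,
#' nonfatal MI, nonfatal stroke, nonfatal unstable angina, all-cause death —
#' using the arm's annual event probabilities as mutually exclusive
#' branches. The event-free fraction is the residual
#' `1 - (p_mi + p_stroke + p_ua + p_death)`. Deaths in year 1 enter the
#' Markov model directly in the dead state.
#'
#' @param arm One arm component of an [`acs_parameters`][default_parameters]
#'   object (e.g. `params$chm_arm`): a list of `(base, low, high)` triples
#'   `p_nonfatal_mi`, `p_nonfatal_stroke`, `p_nonfatal_ua`, `p_death`.
#' @return Named numeric vector of cohort fractions
#'   `c(event_free, new_mi, new_stroke, new_ua, dead)` summing to 1.
#' @export
#' @examples
#' run_decision_tree(default_parameters()$chm_arm)
run_decision_tree <- function(arm) {
  p <- vapply(arm[c("p_nonfatal_mi", "p_nonfatal_stroke", "p_nonfatal_ua",
                    "p_death")], `[[`, numeric(1), "base")
  if (any(p < 0) || any(p > 1))
    stop("year-1 event probabilities must lie in [0, 1]", call. = FALSE)
  if (sum(p) > 1)
    stop("year-1 event probabilities sum to ", sum(p),
         " > 1: no event-free residual remains", call. = FALSE)
  c(event_free = 1 - sum(p),
    new_mi     = p[["p_nonfatal_mi"]],
    new_stroke = p[["p_nonfatal_stroke"]],
    new_ua     = p[["p_nonfatal_ua"]],
    dead       = p[["p_death"]])
}

#' Map a year-1 outcome distribution onto the Markov state space
#'
#' @param outcome Output of [run_decision_tree()].
#' @return Named numeric vector over the 8 Markov states (see
#'   [health_states()]); post-event states start empty.
#' @export
entry_distribution <- function(outcome) {
  x <- stats::setNames(numeric(8), health_states())
  x[c("event_free", "new_mi", "new_stroke", "new_ua", "dead")] <-
    outcome[c("event_free", "new_mi", "new_stroke", "new_ua", "dead")]
  x
}
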