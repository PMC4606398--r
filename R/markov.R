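# Markov engine: 8-state annual-cycle cohort model with tunnel states.
#
# Tenure dependence ("1st year" vs "after 1st year" post-event risks) is
# encoded structurally: each nonfatal event sends the patient to a new_*
# tunnel state carrying the first-year probabilities; survivors without a
# further event move on to the matching post_* state carrying the
# later-year probabilities. With the age multiplier disabled the matrix is
# therefore time-homogeneous.

#' The 8 Markov health states
#'
#' `event_free`, the three one-cycle tunnel states `new_mi`, `new_stroke`,
#' `new_ua`, their long-term counterparts `post_mi`, `post_stroke`,
#' `post_ua`, and the absorbing `dead` state.
#'
#' @return Character vector of the 8 state names, in matrix order.
#' @export
health_states <- function() {
  c("event_free", "new_mi", "post_mi", "new_stroke", "post_stroke",
    "new_ua", "post_ua", "dead")
}

base_of <- function(group, fields)
  vapply(group[fields], `[[`, numeric(1), "base")

# Age-related MACE odds ratio applied as a hazard multiplier:
# probabilities -> rates, scaled by OR^((cycle-1)/10), -> probabilities.
age_scale <- function(p, or, cycle) {
  f <- or^((cycle - 1) / 10)
  1 - exp(log(1 - p) * f)
}

#' Build the per-cycle transition matrix
#'
#' Constructs the row-stochastic 8x8 transition matrix from the long-term
#' annual probabilities. Rows follow the tunnel construction: `new_*` rows
#' carry the first-year post-event probabilities and route survivors to the
#' matching `post_*` state; `post_*` rows carry the later-year
#' probabilities with the residual remaining in place. A recurrent event
#' re-enters the corresponding `new_*` state (tenure resets; the model has
#' no memory beyond the current state). Neither `post_mi` nor `post_stroke`
#' can enter `new_ua`, and unstable angina does not recur from `post_ua`.
#' `dead` is absorbing.
#'
#' @param long_term `long_term` component of an
#'   [`acs_parameters`][default_parameters] object.
#' @param cycle Cycle index (years since model entry), used only when
#'   `apply_age_or` is `TRUE`.
#' @param apply_age_or Apply the age-related MACE odds ratio per decade as
#'   a time-dependent hazard multiplier on all outgoing event and death
#'   probabilities of living states (default `FALSE`).
#' @return 8x8 numeric matrix with `dimnames` [health_states()]; rows sum
#'   to 1.
#' @export
#' @examples
#' M <- build_transition_matrix(default_parameters()$long_term)
#' rowSums(M)
build_transition_matrix <- function(long_term, cycle = 1L,
                                    apply_age_or = FALSE) {
  states <- health_states()
  M <- matrix(0, 8, 8, dimnames = list(states, states))
  or <- long_term$age_mace_or_per_10y[["base"]]
  adj <- function(p) if (apply_age_or) age_scale(p, or, cycle) else p

  fill <- function(from, p_mi, p_stroke, p_death, residual_state,
                   p_ua = 0) {
    p <- adj(c(p_mi, p_stroke, p_ua, p_death))
    if (sum(p) > 1)
      stop("outgoing transition probabilities of state '", from,
           "' sum to ", sum(p), " > 1", call. = FALSE)
    M[from, "new_mi"]     <<- M[from, "new_mi"] + p[1]
    M[from, "new_stroke"] <<- M[from, "new_stroke"] + p[2]
    M[from, "new_ua"]     <<- M[from, "new_ua"] + p[3]
    M[from, "dead"]       <<- M[from, "dead"] + p[4]
    M[from, residual_state] <<- M[from, residual_state] + (1 - sum(p))
  }

  ef <- base_of(long_term$event_free, ef_fields)
  fill("event_free", ef[["p_mi"]], ef[["p_stroke"]], ef[["p_death"]],
       "event_free", p_ua = ef[["p_ua"]])

  for (ev in c("mi", "stroke", "ua")) {
    g <- base_of(long_term[[paste0("post_", ev)]], post_fields)
    fill(paste0("new_", ev), g[["p_mi_y1"]], g[["p_stroke_y1"]],
         g[["p_death_y1"]], paste0("post_", ev))
    fill(paste0("post_", ev), g[["p_mi_later"]], g[["p_stroke_later"]],
         g[["p_death_later"]], paste0("post_", ev))
  }
  M["dead", "dead"] <- 1
  M
}

#' Propagate the cohort to the model horizon
#'
#' Runs the Markov chain from the end-of-year-1 entry distribution to the
#' horizon. Row `t` of the trace is the state occupancy at the end of year
#' `t`; row 1 is the decision-tree output and each subsequent row is the
#' previous row multiplied by the transition matrix.
#'
#' @param entry Year-1 outcome distribution from [run_decision_tree()] (or
#'   an 8-state occupancy vector from [entry_distribution()]).
#' @param long_term `long_term` component of the parameter set.
#' @param settings Run settings (see [default_settings()]); uses
#'   `horizon_years` and `apply_age_or`.
#' @return A `horizon_years` x 8 occupancy matrix (class `cohort_trace`)
#'   with rownames `"year_1"` ... and columns [health_states()]. Each row
#'   sums to 1.
#' @export
#' @examples
#' p <- default_parameters()
#' tr <- run_cohort(run_decision_tree(p$chm_arm), p$long_term, p$settings)
#' 1 - tr[, "dead"]   # survival curve
run_cohort <- function(entry, long_term, settings = default_settings()) {
  if (length(entry) == 5L) entry <- entry_distribution(entry)
  stopifnot(length(entry) == 8L)
  if (abs(sum(entry) - 1) > 1e-9)
    stop("entry distribution must sum to 1", call. = FALSE)
  h <- settings$horizon_years
  trace <- matrix(0, h, 8,
                  dimnames = list(paste0("year_", seq_len(h)), health_states()))
  trace[1, ] <- entry[health_states()]
  if (h > 1) {
    M <- build_transition_matrix(long_term, cycle = 2L,
                                 apply_age_or = settings$apply_age_or)
    for (t in 2:h) {
      if (settings$apply_age_or && t > 2)
        M <- build_transition_matrix(long_term, cycle = t,
                                     apply_age_or = TRUE)
      trace[t, ] <- trace[t - 1, ] %*% M
    }
  }
  structure(trace, class = c("cohort_trace", "matrix", "array"))
}

#' Export a cohort trace as a data frame
#'
#' @param x A `cohort_trace` matrix.
#' @param arm Optional arm label added as a column.
#' @param ... Unused.
#' @return Data frame with `cycle`, optional `arm`, and one column per
#'   state.
#' @export
as.data.frame.cohort_trace <- function(x, arm = NULL, ...) {
  df <- data.frame(cycle = seq_len(nrow(x)), unclass(x)[, , drop = FALSE],
                   row.names = NULL)
  if (!is.null(arm)) df <- cbind(arm = arm, df)
  df
}
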