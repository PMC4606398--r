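# Outcome layer: survival curves, utility-weighted rewards, discounted
# QALYs with half-cycle correction, per-cohort event counts, incremental
# comparisons.

#' Survival curve from a cohort trace
#'
#' @param trace A `cohort_trace` matrix from [run_cohort()].
#' @return Numeric vector: fraction alive (`1 - dead` occupancy) at the end
#'   of each year, with attribute `terminal_pct` (terminal survival as a
#'   percentage).
#' @export
compute_survival <- function(trace) {
  s <- 1 - trace[, "dead"]
  attr(s, "terminal_pct") <- 100 * unname(s[length(s)])
  s
}

#' Per-state annual utilities for one arm
#'
#' The event-free state earns the arm's event-free utility `u`; event and
#' post-event states earn `u` minus the event's disutility (MI, stroke, or
#' UA); `dead` earns 0. With `disutility_mode = "one-off"` the disutility
#' is applied only in the event year (the `new_*` tunnel state) and
#' post-event states earn the full `u`.
#'
#' @param utilities `utilities` component of the parameter set.
#' @param arm `"chm"` or `"conv"`.
#' @param disutility_mode `"persistent"` (default) or `"one-off"`.
#' @return Named numeric vector of 8 state utilities.
#' @export
state_utilities <- function(utilities, arm = c("chm", "conv"),
                            disutility_mode = c("persistent", "one-off")) {
  arm <- match.arg(arm)
  disutility_mode <- match.arg(disutility_mode)
  u <- utilities[[if (arm == "chm") "u_event_free_chm" else "u_event_free_conv"]][["base"]]
  d <- vapply(utilities[c("d_mi", "d_stroke", "d_ua")], `[[`, numeric(1), "base")
  post_d <- if (disutility_mode == "persistent") unname(d) else c(0, 0, 0)
  su <- c(event_free = u,
          new_mi = u - d[["d_mi"]], post_mi = u - post_d[1],
          new_stroke = u - d[["d_stroke"]], post_stroke = u - post_d[2],
          new_ua = u - d[["d_ua"]], post_ua = u - post_d[3],
          dead = 0)
  if (any(su < 0))
    stop("negative state utility for arm '", arm,
         "': disutility exceeds the event-free utility", call. = FALSE)
  su
}

#' Utility-weighted reward of one occupancy row
#'
#' @param occupancy One row of a cohort trace (8 state fractions summing
#'   to 1).
#' @param utilities `utilities` component of the parameter set.
#' @param arm `"chm"` or `"conv"`.
#' @param disutility_mode See [state_utilities()].
#' @return Expected utility earned per year at that occupancy (QALYs/year).
#' @export
#' @examples
#' p <- default_parameters()
#' occ <- entry_distribution(run_decision_tree(p$chm_arm))
#' cycle_reward(occ, p$utilities, "chm")
cycle_reward <- function(occupancy, utilities, arm = c("chm", "conv"),
                         disutility_mode = c("persistent", "one-off")) {
  if (abs(sum(occupancy) - 1) > 1e-9)
    stop("occupancy must sum to 1", call. = FALSE)
  su <- state_utilities(utilities, arm, disutility_mode)
  sum(occupancy[names(su)] * su)
}

# Per-cycle weights implementing the half-cycle conventions.
#  standard:   half reward in the first and the last cycle, full otherwise
#              (the classic half-cycle correction).
#  entry-half: half first-cycle reward; later cycles average the adjacent
#              end-of-cycle rewards (trapezoidal continuation).
#  none:       full end-of-cycle rewards.
qaly_terms <- function(rewards, discount_rate, half_cycle) {
  h <- length(rewards)
  disc <- (1 + discount_rate)^-(seq_len(h) - 1)
  eff <- switch(half_cycle,
    "standard" = {
      w <- rep(1, h); w[1] <- w[1] - 0.5; w[h] <- w[h] - 0.5
      if (h == 1L) w <- 0.5
      w * rewards
    },
    "entry-half" = {
      eff <- 0.5 * rewards
      if (h > 1)
        eff[2:h] <- (rewards[1:(h - 1)] + rewards[2:h]) / 2
      eff
    },
    "none" = rewards,
    stop("unknown half-cycle convention: ", half_cycle, call. = FALSE)
  )
  eff * disc
}

#' Discounted QALYs from a cohort trace
#'
#' Computes the per-cycle utility rewards of the trace, applies the
#' half-cycle convention and annual discounting (discount factor
#' `(1 + r)^-(t - 1)`, so the first cycle is undiscounted), and sums over
#' the horizon.
#'
#' @param trace A `cohort_trace` matrix.
#' @param utilities `utilities` component of the parameter set.
#' @param arm `"chm"` or `"conv"`.
#' @param settings Run settings; uses `discount_rate`, `half_cycle`,
#'   `disutility_mode`.
#' @return List with `total` (discounted QALYs over the horizon), `year1`
#'   (the cycle-1 term), and `per_cycle` (discounted per-cycle terms).
#' @export
compute_qalys <- function(trace, utilities, arm = c("chm", "conv"),
                          settings = default_settings()) {
  arm <- match.arg(arm)
  su <- state_utilities(utilities, arm, settings$disutility_mode)
  rewards <- as.vector(unclass(trace)[, names(su), drop = FALSE] %*% su)
  terms <- qaly_terms(rewards, settings$discount_rate, settings$half_cycle)
  list(total = sum(terms), year1 = terms[1], per_cycle = terms)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-cohort event differences between arms
#'
#' Counts, per `cohort_size` patients over the shared horizon, how many
#' more patients remain event-free, how many fewer die (both from terminal
#' occupancy), and how many incident nonfatal MIs, strokes, and UA episodes
#' are prevented (cumulative inflow into the tunnel states, which by the
#' tunnel property equals the summed `new_*` occupancy) in the CHM arm
#' relative to the conventional arm. Differences are rounded
#' half-away-from-zero to whole patients. `terminal_state_diff` additionally
#' reports the terminal occupancy difference of each event-state pair
#' (`new_* + post_*`), the alternative "patients prevented" reading.
#'
#' @param trace_chm,trace_conv Cohort traces of the two arms (same horizon).
#' @param cohort_size Cohort size (default 1000).
#' @return List with integer counts `event_free_gained`, `deaths_avoided`,
#'   `mi_prevented`, `stroke_prevented`, `ua_prevented`, and the unrounded
#'   `terminal_state_diff` vector.
#' @export
events_per_cohort <- function(trace_chm, trace_conv, cohort_size = 1000L) {
  if (nrow(trace_chm) != nrow(trace_conv))
    stop("traces have different horizons", call. = FALSE)
  h <- nrow(trace_chm)
  incident <- function(tr, st) sum(tr[, st])
  cnt <- function(x) as.integer(round_half_away(cohort_size * x))
  pair <- function(tr, ev) sum(tr[h, c(paste0("new_", ev), paste0("post_", ev))])
  list(
    event_free_gained = cnt(trace_chm[h, "event_free"] - trace_conv[h, "event_free"]),
    deaths_avoided    = cnt(trace_conv[h, "dead"] - trace_chm[h, "dead"]),
    mi_prevented      = cnt(incident(trace_conv, "new_mi") - incident(trace_chm, "new_mi")),
    stroke_prevented  = cnt(incident(trace_conv, "new_stroke") - incident(trace_chm, "new_stroke")),
    ua_prevented      = cnt(incident(trace_conv, "new_ua") - incident(trace_chm, "new_ua")),
    terminal_state_diff = cohort_size * c(
      mi = pair(trace_conv, "mi") - pair(trace_chm, "mi"),
      stroke = pair(trace_conv, "stroke") - pair(trace_chm, "stroke"),
      ua = pair(trace_conv, "ua") - pair(trace_chm, "ua"))
  )
}

#' Incremental comparison of two arms
#'
#' @param qalys_chm,qalys_conv Outputs of [compute_qalys()] for each arm.
#' @param survival_chm,survival_conv Outputs of [compute_survival()].
#' @return List with `qaly_total`, `qaly_year1` (QALY differences, CHM
#'   minus conventional) and `survival_pp` (terminal survival difference in
#'   percentage points).
#' @export
incremental <- function(qalys_chm, qalys_conv, survival_chm, survival_conv) {
  list(
    qaly_total = qalys_chm$total - qalys_conv$total,
    qaly_year1 = qalys_chm$year1 - qalys_conv$year1,
    survival_pp = attr(survival_chm, "terminal_pct") -
      attr(survival_conv, "terminal_pct")
  )
}
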