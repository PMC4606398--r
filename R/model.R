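# Top-level model: run both arms through the decision tree and Markov
# engine, attach outcome summaries, and expose the result as a classed
# object with print/summary/plot methods.

#' Run the two-component decision model
#'
#' Runs the one-year decision tree and the 8-state Markov cohort model for
#' both treatment arms (adjunctive CHM plus conventional treatment vs
#' conventional treatment alone) and derives all outcome summaries:
#' survival curves, discounted QALYs with half-cycle correction,
#' per-cohort event counts, and incremental comparisons.
#'
#' @param params An [`acs_parameters`][default_parameters] object. Use
#'   [validate_parameters()] (or [read_parameters()], which validates) on
#'   inputs of uncertain provenance; `run_model()` itself only enforces
#'   structural feasibility (rows summing to 1 etc.).
#' @param settings Optional run settings overriding `params$settings`.
#' @return An object of class `acs_model`: a list with components
#'   `parameters`, `decision_tree`, `trace`, `survival` (per-arm curves),
#'   `survival_10y` (terminal survival, percent, per arm), `qalys`
#'   (per-arm lists from [compute_qalys()]), `incremental`, and
#'   `events_per_1000`.
#' @export
#' @examples
#' m <- run_model(default_parameters())
#' m$survival_10y
#' m$incremental$qaly_total
#' summary(m)
run_model <- function(params, settings = NULL) {
  if (!is.null(settings)) params$settings <- settings
  st <- params$settings
  tree <- list(chm = run_decision_tree(params$chm_arm),
               conv = run_decision_tree(params$conv_arm))
  trace <- lapply(tree, run_cohort, long_term = params$long_term, settings = st)
  survival <- lapply(trace, compute_survival)
  qalys <- list(chm = compute_qalys(trace$chm, params$utilities, "chm", st),
                conv = compute_qalys(trace$conv, params$utilities, "conv", st))
  structure(list(
    parameters = params,
    decision_tree = tree,
    trace = trace,
    survival = survival,
    survival_10y = c(chm = attr(survival$chm, "terminal_pct"),
                     conv = attr(survival$conv, "terminal_pct")),
    qalys = qalys,
    incremental = incremental(qalys$chm, qalys$conv,
                              survival$chm, survival$conv),
    events_per_1000 = events_per_cohort(trace$chm, trace$conv,
                                        st$cohort_size)
  ), class = "acs_model")
}

#' @export
print.acs_model <- function(x, digits = 4, ...) {
  st <- x$parameters$settings
  cat("Two-component decision model: CHM + conventional vs conventional alone\n")
  cat(sprintf("  horizon %d y, discount %.3g, half-cycle '%s'\n",
              st$horizon_years, st$discount_rate, st$half_cycle))
  cat(sprintf("  %d-year survival:   CHM %.2f%%   conv %.2f%%   (+%.2f pp)\n",
              st$horizon_years, x$survival_10y[["chm"]],
              x$survival_10y[["conv"]], x$incremental$survival_pp))
  cat(sprintf("  discounted QALYs:   CHM %.*f   conv %.*f   (+%.*f)\n",
              digits, x$qalys$chm$total, digits, x$qalys$conv$total,
              digits, x$incremental$qaly_total))
  invisible(x)
}

#' @export
summary.acs_model <- function(object, ...) {
  structure(list(model = object), class = "summary.acs_model")
}

#' @export
print.summary.acs_model <- function(x, ...) {
  m <- x$model
  print(m)
  e <- m$events_per_1000
  cat(sprintf("  year-1 QALYs:       CHM %.4f   conv %.4f   (+%.4f)\n",
              m$qalys$chm$year1, m$qalys$conv$year1, m$incremental$qaly_year1))
  cat(sprintf(paste0("  per %d patients: %d more event-free, %d deaths avoided,\n",
                     "    %d MIs / %d strokes / %d UA episodes prevented (incident)\n"),
              m$parameters$settings$cohort_size, e$event_free_gained,
              e$deaths_avoided, e$mi_prevented, e$stroke_prevented,
              e$ua_prevented))
  cat("  survival curve (fraction alive at end of year):\n")
  tab <- rbind(chm = m$survival$chm, conv = m$survival$conv)
  colnames(tab) <- seq_len(ncol(tab))
  print(round(tab, 4))
  invisible(x)
}

#' Plot survival curves of a fitted model
#'
#' @param x An `acs_model` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.acs_model <- function(x, ...) {
  h <- x$parameters$settings$horizon_years
  graphics::matplot(seq_len(h), cbind(x$survival$chm, x$survival$conv),
                    type = "b", pch = c(19, 1), lty = 1:2, col = c(2, 4),
                    xlab = "Year", ylab = "Fraction alive",
                    main = "Survival by treatment arm", ...)
  graphics::legend("topright", c("CHM + conventional", "conventional alone"),
                   pch = c(19, 1), lty = 1:2, col = c(2, 4), bty = "n")
  invisible(x)
}

#' Model results as a flat data frame
#'
#' @param x An `acs_model` object.
#' @param ... Unused.
#' @return Data frame with one row per arm and cycle: occupancy of each
#'   state, survival, and the discounted per-cycle QALY term.
#' @export
as.data.frame.acs_model <- function(x, ...) {
  out <- lapply(c("chm", "conv"), function(arm) {
    df <- as.data.frame(x$trace[[arm]], arm = arm)
    df$survival <- as.vector(x$survival[[arm]])
    df$qaly_term <- x$qalys[[arm]]$per_cycle
    df
  })
  do.call(rbind, out)
}
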