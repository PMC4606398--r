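# Univariate (one-way) sensitivity analysis: vary one parameter at a time
# across its range, re-run both arms, rank by induced spread.

eval_outputs <- function(params) {
  m <- run_model(params)
  c(qaly_chm = m$qalys$chm$total, qaly_conv = m$qalys$conv$total,
    incremental = m$incremental$qaly_total)
}

#' One-way sensitivity analysis (tornado table)
#'
#' Varies each ranged parameter to its low and high endpoint with all
#' other parameters held at base values, re-runs the full model for both
#' arms at each endpoint, and ranks parameters by the induced spread in
#' the selected output. Shared parameters (long-term probabilities,
#' utilities, disutilities) move in both arms simultaneously; year-1
#' decision-tree probabilities are arm-specific and move only in their own
#' arm. Sorting is by decreasing spread with ties broken by parameter
#' name.
#'
#' @param params An [`acs_parameters`][default_parameters] object.
#' @param rank_by Output used for the spread ranking: `"qaly_chm"`
#'   (CHM-arm total QALYs; default) or `"incremental"` (QALY difference).
#' @return A data frame of class `tornado`, one row per ranged parameter:
#'   `parameter`, `low`, `high`, the three outputs at each endpoint
#'   (`qaly_chm_low`, `qaly_conv_low`, `incremental_low`, and `_high`
#'   counterparts), `spread`, and `rank`. The base-case outputs are
#'   attached as attribute `base_outputs`.
#' @export
#' @examples
#' tor <- one_way_sensitivity(default_parameters())
#' head(tor, 3)
one_way_sensitivity <- function(params, rank_by = c("qaly_chm", "incremental")) {
  rank_by <- match.arg(rank_by)
  tab <- parameter_table(params)
  base_out <- eval_outputs(params)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    path <- tab$parameter[i]
    at <- function(value)
      eval_outputs(set_parameter(params, path, value))
    lo <- at(tab$low[i])
    hi <- at(tab$high[i])
    data.frame(parameter = path, low = tab$low[i], high = tab$high[i],
               qaly_chm_low = lo[["qaly_chm"]], qaly_conv_low = lo[["qaly_conv"]],
               incremental_low = lo[["incremental"]],
               qaly_chm_high = hi[["qaly_chm"]], qaly_conv_high = hi[["qaly_conv"]],
               incremental_high = hi[["incremental"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out[[paste0(rank_by, "_high")]] -
                    out[[paste0(rank_by, "_low")]])
  out <- out[order(-out$spread, out$parameter), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "base_outputs") <- base_out
  attr(out, "rank_by") <- rank_by
  class(out) <- c("tornado", "data.frame")
  out
}

#' Dominance check over one-way variations
#'
#' `TRUE` iff the incremental QALY gain of the CHM arm is strictly
#' positive at every endpoint of every one-way variation — i.e. the
#' adjunctive strategy stays dominant across the whole examined parameter
#' space.
#'
#' @param records A `tornado` data frame from [one_way_sensitivity()].
#' @return Logical scalar.
#' @export
dominance_check <- function(records) {
  all(records$incremental_low > 0) && all(records$incremental_high > 0)
}

#' @export
print.tornado <- function(x, n = 10L, ...) {
  rb <- attr(x, "rank_by")
  cat("One-way sensitivity analysis,", nrow(x), "parameters, ranked by",
      rb, "spread\n")
  cat(sprintf("  base case: qaly_chm %.4f, qaly_conv %.4f, incremental %.4f\n",
              attr(x, "base_outputs")[["qaly_chm"]],
              attr(x, "base_outputs")[["qaly_conv"]],
              attr(x, "base_outputs")[["incremental"]]))
  cat("  dominance preserved at all endpoints:", dominance_check(x), "\n")
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                         c("rank", "parameter", "low", "high", "spread")]
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tornado plot
#'
#' Horizontal-bar tornado diagram of the top parameters: for each, the
#' ranked output at the low and high endpoint relative to the base case.
#'
#' @param x A `tornado` data frame.
#' @param n Number of top-ranked parameters to draw (default 10).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.tornado <- function(x, n = 10L, ...) {
  rb <- attr(x, "rank_by")
  base <- attr(x, "base_outputs")[[rb]]
  d <- x[seq_len(min(n, nrow(x))), , drop = FALSE]
  d <- d[rev(seq_len(nrow(d))), ]
  lo <- d[[paste0(rb, "_low")]] - base
  hi <- d[[paste0(rb, "_high")]] - base
  old <- graphics::par(mar = c(4, 14, 3, 2)); on.exit(graphics::par(old))
  ylim <- c(0, nrow(d) * 1.25)
  bp <- graphics::barplot(pmin(lo, hi), horiz = TRUE, xlim = range(0, lo, hi),
                          col = "steelblue", names.arg = d$parameter,
                          las = 1, cex.names = 0.7,
                          xlab = paste(rb, "- base"), main = "Tornado diagram",
                          ...)
  graphics::barplot(pmax(lo, hi), horiz = TRUE, col = "indianred",
                    add = TRUE, axes = FALSE, names.arg = rep("", nrow(d)))
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
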