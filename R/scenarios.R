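# Scenario library and parameter-space generators: deterministic
# degenerate/closed-form parameter sets for testing, plus a seeded
# perturbation operator over the sensitivity ranges.

zero_triple <- function(x) { x[] <- 0; x }

#' Named deterministic parameter scenarios
#'
#' A small library of parameter sets exercising the model's limiting
#' behaviours:
#' \describe{
#'   \item{`paper_base`}{The packaged base case, identical to
#'     [default_parameters()].}
#'   \item{`zero_mortality`}{All death probabilities zero: survival must be
#'     100% at every cycle.}
#'   \item{`immediate_absorption`}{All death probabilities one (and event
#'     probabilities zero): the entire cohort is dead from year 1.}
#'   \item{`two_state_geometric`}{Only event-free mortality (0.027) is
#'     non-zero, so the model collapses to a two-state chain with the
#'     closed-form survival \eqn{(1 - 0.027)^{t-1}}.}
#'   \item{`reversed_dominance`}{The two arms' year-1 columns and
#'     event-free utilities are swapped, so the CHM arm is elementwise
#'     worse and cannot dominate.}
#'   \item{`equal_arms`}{Both arms share the conventional-arm year-1
#'     probabilities and the conventional event-free utility: every
#'     incremental output is exactly zero.}
#' }
#'
#' @param name Scenario name.
#' @return An `acs_parameters` object.
#' @export
#' @examples
#' scenario("two_state_geometric")$long_term$event_free$p_death
scenario <- function(name) {
  library_names <- c("paper_base", "zero_mortality", "immediate_absorption",
                     "two_state_geometric", "reversed_dominance", "equal_arms")
  if (!is.character(name) || length(name) != 1L || !name %in% library_names)
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; available: ", paste(library_names, collapse = ", "),
         call. = FALSE)
  p <- default_parameters()
  switch(name,
    paper_base = p,
    zero_mortality = {
      p$chm_arm$p_death <- zero_triple(p$chm_arm$p_death)
      p$conv_arm$p_death <- zero_triple(p$conv_arm$p_death)
      p$long_term$event_free$p_death <- zero_triple(p$long_term$event_free$p_death)
      for (st in c("post_mi", "post_ua", "post_stroke")) {
        p$long_term[[st]]$p_death_y1 <- zero_triple(p$long_term[[st]]$p_death_y1)
        p$long_term[[st]]$p_death_later <- zero_triple(p$long_term[[st]]$p_death_later)
      }
      p
    },
    immediate_absorption = {
      for (arm in c("chm_arm", "conv_arm"))
        for (f in arm_fields)
          p[[arm]][[f]] <- pv(if (f == "p_death") 1 else 0)
      p$long_term$event_free[ef_fields] <-
        lapply(ef_fields, function(f) pv(if (f == "p_death") 1 else 0))
      for (st in c("post_mi", "post_ua", "post_stroke"))
        p$long_term[[st]][post_fields] <-
          lapply(post_fields, function(f)
            pv(if (startsWith(f, "p_death")) 1 else 0))
      p
    },
    two_state_geometric = {
      for (arm in c("chm_arm", "conv_arm"))
        for (f in arm_fields) p[[arm]][[f]] <- pv(0)
      p$long_term$event_free[ef_fields] <-
        lapply(ef_fields, function(f) if (f == "p_death")
          pv(0.027, 0.014, 0.033) else pv(0))
      for (st in c("post_mi", "post_ua", "post_stroke"))
        p$long_term[[st]][post_fields] <- lapply(post_fields, function(f) pv(0))
      p
    },
    reversed_dominance = {
      tmp <- p$chm_arm; p$chm_arm <- p$conv_arm; p$conv_arm <- tmp
      tmp <- p$utilities$u_event_free_chm
      p$utilities$u_event_free_chm <- p$utilities$u_event_free_conv
      p$utilities$u_event_free_conv <- tmp
      p
    },
    equal_arms = {
      p$chm_arm <- p$conv_arm
      p$utilities$u_event_free_chm <- p$utilities$u_event_free_conv
      p
    }
  )
}

#' Seeded perturbation of a parameter set
#'
#' Moves every ranged base value a fixed fraction of the way toward a
#' randomly chosen endpoint of its sensitivity range:
#' `base + scale * (endpoint - base)` with the endpoint (low or high)
#' drawn per parameter. `scale = 0` returns the input unchanged;
#' `scale = 1` puts every value exactly at a range endpoint. Deterministic
#' given `seed`. Ranges are left untouched.
#'
#' @param params An `acs_parameters` object.
#' @param scale Fraction in `[0, 1]` of the distance to the chosen
#'   endpoint.
#' @param seed Integer seed.
#' @return A perturbed `acs_parameters` object.
#' @export
perturb <- function(params, scale, seed) {
  stopifnot(scale >= 0, scale <= 1)
  set.seed(as.integer(seed))
  out <- rapply(unclass(params)[c("chm_arm", "conv_arm", "long_term", "utilities")],
                how = "replace",
                f = function(v) {
                  if (is.numeric(v) && length(v) == 3L &&
                      identical(names(v), c("base", "low", "high"))) {
                    endpoint <- if (stats::runif(1) < 0.5) v[["low"]] else v[["high"]]
                    v[["base"]] <- if (scale == 1) endpoint
                                   else v[["base"]] + scale * (endpoint - v[["base"]])
                  }
                  v
                })
  params[names(out)] <- out
  params
}
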