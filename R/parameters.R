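# Parameter set: construction, validation, YAML I/O, random generation.
#
# Every tunable model input is a triple c(base, low, high); (low, high) is
# the univariate sensitivity range. Two long-term inputs are stored exactly
# as published even though their base value falls outside the printed range
# (post-MI and post-UA late re-infarction); validation warns rather than
# errors on those.

#' Parameter value triple
#'
#' Build a single model parameter as a named numeric vector
#' `c(base, low, high)`, where `low`/`high` delimit the univariate
#' sensitivity range.
#'
#' @param base Base-case value.
#' @param low,high Sensitivity range endpoints. Default to `base`
#'   (degenerate range).
#' @return Named numeric vector of length 3.
#' @export
#' @examples
#' pv(0.027, 0.014, 0.033)
pv <- function(base, low = base, high = base) {
  stopifnot(is.numeric(base), length(base) == 1L)
  c(base = as.numeric(base), low = as.numeric(low), high = as.numeric(high))
}

#' Default model parameters
#'
#' The packaged base-case parameter set: one-year event probabilities for
#' each treatment arm, long-term annual transition probabilities for the
#' Markov states (first-year and later-year post-event risks), EQ-5D-derived
#' utilities and event disutilities, and run settings. Each value carries
#' its univariate sensitivity range.
#'
#' Arm probabilities are annual probabilities of a first event (nonfatal MI,
#' nonfatal stroke, nonfatal unstable angina, all-cause death) during the
#' first year after PCI; they are mutually exclusive branches of the
#' one-year decision tree. Long-term probabilities are shared by both arms
#' from year 2 onward. The age-related MACE odds ratio per decade is stored
#' but not applied unless `settings$apply_age_or` is set (see
#' [build_transition_matrix()]).
#'
#' @return An object of class `acs_parameters`: a nested list with elements
#'   `chm_arm`, `conv_arm`, `long_term`, `utilities`, `settings`.
#' @seealso [validate_parameters()], [read_parameters()], [scenario()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$chm_arm$p_nonfatal_mi
#' p$utilities$u_event_free_chm
default_parameters <- function() {
  params <- list(
    chm_arm = list(
      p_nonfatal_mi     = pv(0.0050, 0.0000, 0.0119),
      p_nonfatal_stroke = pv(0.0074, 0.0000, 0.0158),
      p_nonfatal_ua     = pv(0.0149, 0.0031, 0.0267),
      p_death           = pv(0.0050, 0.0000, 0.0119)
    ),
    conv_arm = list(
      p_nonfatal_mi     = pv(0.0175, 0.0047, 0.0303),
      p_nonfatal_stroke = pv(0.0150, 0.0031, 0.0269),
      p_nonfatal_ua     = pv(0.0399, 0.0207, 0.0591),
      p_death           = pv(0.0075, 0.0000, 0.0159)
    ),
    long_term = list(
      event_free = list(
        p_mi     = pv(0.018, 0.010, 0.020),
        p_stroke = pv(0.007, 0.001, 0.009),
        p_ua     = pv(0.030, 0.020, 0.050),
        p_death  = pv(0.027, 0.014, 0.033)
      ),
      post_mi = list(
        p_death_y1     = pv(0.039, 0.008, 0.076),
        p_death_later  = pv(0.021, 0.003, 0.027),
        p_mi_y1        = pv(0.024, 0.002, 0.060),
        p_mi_later     = pv(0.018, 0.001, 0.008),  # base outside printed range
        p_stroke_y1    = pv(0.010, 0.0024, 0.024),
        p_stroke_later = pv(0.007, 0.0008, 0.022)
      ),
      post_ua = list(
        p_death_y1     = pv(0.034, 0.012, 0.050),
        p_death_later  = pv(0.020, 0.016, 0.028),
        p_mi_y1        = pv(0.036, 0.010, 0.050),
        p_mi_later     = pv(0.011, 0.010, 0.063),
        p_stroke_y1    = pv(0.018, 0.014, 0.023),
        p_stroke_later = pv(0.008, 0.006, 0.010)
      ),
      post_stroke = list(
        p_death_y1     = pv(0.115, 0.066, 0.189),
        p_death_later  = pv(0.035, 0.016, 0.061),
        p_mi_y1        = pv(0.003, 0.002, 0.006),
        p_mi_later     = pv(0.004, 0.002, 0.006),
        p_stroke_y1    = pv(0.128, 0.064, 0.189),
        p_stroke_later = pv(0.040, 0.030, 0.080)
      ),
      age_mace_or_per_10y = pv(0.50, 0.33, 0.87)
    ),
    utilities = list(
      u_event_free_chm  = pv(0.818, 0.418, 0.848),
      u_event_free_conv = pv(0.809, 0.252, 0.848),
      d_mi     = pv(0.127, 0.108, 0.147),
      d_stroke = pv(0.139, 0.118, 0.160),
      d_ua     = pv(0.117, 0.100, 0.135),
      d_death  = pv(0)
    ),
    settings = default_settings()
  )
  structure(params, class = "acs_parameters")
}

#' Default run settings
#'
#' @param horizon_years Model horizon in annual cycles (default 10).
#' @param discount_rate Annual discount rate for QALYs. Default 0.03; see
#'   the methods vignette for the calibration over `c(0, 0.03, 0.035, 0.05)`.
#' @param half_cycle Half-cycle correction convention, one of `"standard"`
#'   (half reward in the first and last cycle; default), `"entry-half"`
#'   (half first-cycle reward, trapezoidal continuation), `"none"`.
#' @param disutility_mode `"persistent"` (disutility subtracted in every
#'   year spent in an event or post-event state; default) or `"one-off"`
#'   (subtracted only in the event year, i.e. in the tunnel state).
#' @param apply_age_or Apply the age-related MACE odds ratio as a
#'   time-dependent hazard multiplier (default `FALSE`).
#' @param cohort_size Cohort size for per-cohort event counts (default 1000).
#' @return A list of settings.
#' @export
default_settings <- function(horizon_years = 10L,
                             discount_rate = 0.03,
                             half_cycle = c("standard", "entry-half", "none"),
                             disutility_mode = c("persistent", "one-off"),
                             apply_age_or = FALSE,
                             cohort_size = 1000L) {
  list(
    horizon_years = as.integer(horizon_years),
    cycle_length_years = 1,
    discount_rate = discount_rate,
    half_cycle = match.arg(half_cycle),
    disutility_mode = match.arg(disutility_mode),
    apply_age_or = isTRUE(apply_age_or),
    cohort_size = as.integer(cohort_size)
  )
}

arm_fields <- c("p_nonfatal_mi", "p_nonfatal_stroke", "p_nonfatal_ua", "p_death")
ef_fields  <- c("p_mi", "p_stroke", "p_ua", "p_death")
post_fields <- c("p_death_y1", "p_death_later", "p_mi_y1", "p_mi_later",
                 "p_stroke_y1", "p_stroke_later")
util_fields <- c("u_event_free_chm", "u_event_free_conv",
                 "d_mi", "d_stroke", "d_ua", "d_death")

check_pv <- function(x, name, unit = TRUE) {
  if (!is.numeric(x) || length(x) != 3L)
    stop("parameter '", name, "' must be a numeric triple (base, low, high)",
         call. = FALSE)
  if (anyNA(x)) stop("parameter '", name, "' contains NA", call. = FALSE)
  if (unit && (any(x < 0) || any(x > 1)))
    stop("parameter '", name, "' out of range: all of (base, low, high) ",
         "must lie in [0, 1]", call. = FALSE)
  if (x[["low"]] > x[["high"]])
    stop("parameter '", name, "' has low > high", call. = FALSE)
  if (x[["base"]] < x[["low"]] - 1e-12 || x[["base"]] > x[["high"]] + 1e-12)
    warning("parameter '", name, "' has base value ", x[["base"]],
            " outside its sensitivity range [", x[["low"]], ", ",
            x[["high"]], "] (stored as published)", call. = FALSE)
  invisible(TRUE)
}

#' Validate a parameter set
#'
#' Checks structure and invariants: every parameter is a `(base, low, high)`
#' triple of probabilities/utilities in `[0, 1]` (the age odds ratio is
#' exempt from the unit-interval bound), `low <= high`, per-state outgoing
#' base probabilities sum to less than 1 (a residual must remain), and
#' event-state utilities (`u - d`) are non-negative at base values. A base
#' value outside its own range raises a warning, not an error, so published
#' inputs can be stored verbatim.
#'
#' @param params An `acs_parameters` object (or bare list of that shape).
#' @return `params`, invisibly. Errors name the offending field.
#' @export
validate_parameters <- function(params) {
  for (top in c("chm_arm", "conv_arm", "long_term", "utilities", "settings"))
    if (is.null(params[[top]]))
      stop("parameter set is missing component '", top, "'", call. = FALSE)

  for (arm in c("chm_arm", "conv_arm")) {
    for (f in arm_fields) {
      if (is.null(params[[arm]][[f]]))
        stop("missing field '", arm, ".", f, "'", call. = FALSE)
      check_pv(params[[arm]][[f]], paste0(arm, ".", f))
    }
    s <- sum(vapply(params[[arm]][arm_fields], `[[`, numeric(1), "base"))
    if (s > 1)
      stop("year-1 event probabilities of '", arm, "' sum to ", s,
           " > 1: no event-free residual remains", call. = FALSE)
  }

  lt <- params$long_term
  for (f in ef_fields) {
    if (is.null(lt$event_free[[f]]))
      stop("missing field 'long_term.event_free.", f, "'", call. = FALSE)
    check_pv(lt$event_free[[f]], paste0("long_term.event_free.", f))
  }
  if (sum(vapply(lt$event_free[ef_fields], `[[`, numeric(1), "base")) > 1)
    stop("outgoing base probabilities of state 'event_free' sum to > 1",
         call. = FALSE)
  for (st in c("post_mi", "post_ua", "post_stroke")) {
    for (f in post_fields) {
      if (is.null(lt[[st]][[f]]))
        stop("missing field 'long_term.", st, ".", f, "'", call. = FALSE)
      check_pv(lt[[st]][[f]], paste0("long_term.", st, ".", f))
    }
    for (tenure in c("_y1", "_later")) {
      s <- sum(vapply(lt[[st]][paste0(c("p_death", "p_mi", "p_stroke"), tenure)],
                      `[[`, numeric(1), "base"))
      if (s > 1)
        stop("outgoing base probabilities of state '", st, "' (", sub("_", "", tenure),
             ") sum to ", s, " > 1", call. = FALSE)
    }
  }
  check_pv(lt$age_mace_or_per_10y, "long_term.age_mace_or_per_10y", unit = FALSE)
  if (any(lt$age_mace_or_per_10y < 0))
    stop("parameter 'long_term.age_mace_or_per_10y' must be non-negative",
         call. = FALSE)

  u <- params$utilities
  for (f in util_fields) {
    if (is.null(u[[f]])) stop("missing field 'utilities.", f, "'", call. = FALSE)
    check_pv(u[[f]], paste0("utilities.", f))
  }
  for (uf in c("u_event_free_chm", "u_event_free_conv"))
    for (df in c("d_mi", "d_stroke", "d_ua"))
      if (u[[uf]][["base"]] - u[[df]][["base"]] < 0)
        stop("negative state utility: utilities.", uf, " - utilities.", df,
             " < 0 at base values", call. = FALSE)

  s <- params$settings
  if (!is.numeric(s$horizon_years) || s$horizon_years < 1)
    stop("settings.horizon_years must be >= 1", call. = FALSE)
  if (!identical(as.numeric(s$cycle_length_years), 1))
    stop("settings.cycle_length_years is fixed at 1 year", call. = FALSE)
  if (!is.numeric(s$discount_rate) || s$discount_rate < 0)
    stop("settings.discount_rate must be >= 0", call. = FALSE)
  if (!s$half_cycle %in% c("standard", "entry-half", "none"))
    stop("settings.half_cycle must be one of 'standard', 'entry-half', 'none'",
         call. = FALSE)
  if (!s$disutility_mode %in% c("persistent", "one-off"))
    stop("settings.disutility_mode must be 'persistent' or 'one-off'",
         call. = FALSE)

  invisible(params)
}

#' @export
print.acs_parameters <- function(x, ...) {
  cat("ACS post-PCI model parameter set\n")
  fmt <- function(v) sprintf("%.4g [%.4g, %.4g]", v[["base"]], v[["low"]], v[["high"]])
  cat("  Year-1 probabilities (CHM arm):  ",
      paste(vapply(x$chm_arm, fmt, "")[1:4], collapse = ", "), "\n")
  cat("  Year-1 probabilities (conv arm): ",
      paste(vapply(x$conv_arm, fmt, "")[1:4], collapse = ", "), "\n")
  cat("  Event-free utilities: CHM", fmt(x$utilities$u_event_free_chm),
      "| conv", fmt(x$utilities$u_event_free_conv), "\n")
  cat("  Settings: horizon", x$settings$horizon_years, "y, discount",
      x$settings$discount_rate, ", half-cycle", x$settings$half_cycle, "\n")
  invisible(x)
}

## ---- YAML I/O --------------------------------------------------------------

pv_to_list <- function(x) list(base = unname(x[["base"]]),
                               low = unname(x[["low"]]),
                               high = unname(x[["high"]]))
list_to_pv <- function(x, name) {
  if (!is.list(x) || is.null(x$base))
    stop("field '", name, "' must be a map with keys base/low/high",
         call. = FALSE)
  pv(x$base, if (is.null(x$low)) x$base else x$low,
     if (is.null(x$high)) x$base else x$high)
}

walk_pv <- function(node, f, path = character()) {
  if (is.numeric(node) && length(node) == 3L &&
      identical(names(node), c("base", "low", "high")))
    return(f(node, paste(path, collapse = ".")))
  if (is.list(node))
    return(lapply(seq_along(node), function(i)
      walk_pv(node[[i]], f, c(path, names(node)[i]))))
  node
}

#' Write a parameter set to YAML
#'
#' Serialises an `acs_parameters` object to the package's YAML parameter
#' format (each parameter a `{base, low, high}` map). The format round-trips
#' losslessly through [read_parameters()].
#'
#' @param params Validated `acs_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  out <- list(
    chm_arm   = lapply(params$chm_arm, pv_to_list),
    conv_arm  = lapply(params$conv_arm, pv_to_list),
    long_term = list(
      event_free  = lapply(params$long_term$event_free, pv_to_list),
      post_mi     = lapply(params$long_term$post_mi, pv_to_list),
      post_ua     = lapply(params$long_term$post_ua, pv_to_list),
      post_stroke = lapply(params$long_term$post_stroke, pv_to_list),
      age_mace_or_per_10y = pv_to_list(params$long_term$age_mace_or_per_10y)
    ),
    utilities = lapply(params$utilities, pv_to_list),
    settings  = params$settings
  )
  # precision 20 keeps >= 17 significant digits, enough for doubles to
  # round-trip bit-exactly through the text format
  yaml::write_yaml(out, path, precision = 20L)
  invisible(path)
}

#' Read a parameter set from YAML
#'
#' Parses and validates a parameter file in the package's YAML format (see
#' the schema shipped at
#' `system.file("extdata", "parameters-schema.json", package = "acsmarkov")`
#' and the packaged base-case fixture
#' `system.file("extdata", "acs-pci-parameters.yaml", package = "acsmarkov")`).
#' Missing settings fall back to [default_settings()].
#'
#' @param path Path to a YAML parameter file.
#' @return A validated `acs_parameters` object.
#' @export
#' @examples
#' f <- system.file("extdata", "acs-pci-parameters.yaml", package = "acsmarkov")
#' p <- read_parameters(f)
#' p$long_term$event_free$p_death
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  as_group <- function(g, fields, prefix) {
    if (is.null(raw[[g]])) stop("missing section '", g, "'", call. = FALSE)
    out <- lapply(fields, function(f)
      list_to_pv(raw[[g]][[f]], paste0(prefix, ".", f)))
    names(out) <- fields
    out
  }
  lt_group <- function(g, fields) {
    out <- lapply(fields, function(f)
      list_to_pv(raw$long_term[[g]][[f]], paste0("long_term.", g, ".", f)))
    names(out) <- fields
    out
  }
  st <- raw$settings
  if (is.null(st)) st <- list()
  def <- default_settings()
  settings <- utils::modifyList(def, st[intersect(names(st), names(def))])
  settings <- default_settings(settings$horizon_years, settings$discount_rate,
                               settings$half_cycle, settings$disutility_mode,
                               settings$apply_age_or, settings$cohort_size)
  params <- structure(list(
    chm_arm  = as_group("chm_arm", arm_fields, "chm_arm"),
    conv_arm = as_group("conv_arm", arm_fields, "conv_arm"),
    long_term = list(
      event_free  = lt_group("event_free", ef_fields),
      post_mi     = lt_group("post_mi", post_fields),
      post_ua     = lt_group("post_ua", post_fields),
      post_stroke = lt_group("post_stroke", post_fields),
      age_mace_or_per_10y = list_to_pv(raw$long_term$age_mace_or_per_10y,
                                       "long_term.age_mace_or_per_10y")
    ),
    utilities = as_group("utilities", util_fields, "utilities"),
    settings = settings
  ), class = "acs_parameters")
  validate_parameters(params)
}

## ---- parameter table and path access ---------------------------------------

#' Tabulate all ranged parameters
#'
#' Flattens a parameter set to one row per `(base, low, high)` triple, with
#' a dotted path (e.g. `"long_term.event_free.p_death"`), its values, and
#' whether the parameter is arm-specific (year-1 decision-tree probability
#' of one arm) or shared between arms.
#'
#' @param params An `acs_parameters` object.
#' @return A data frame with columns `parameter`, `base`, `low`, `high`,
#'   `arm_specific`.
#' @export
parameter_table <- function(params) {
  rows <- list()
  walk_pv(unclass(params)[c("chm_arm", "conv_arm", "long_term", "utilities")],
          function(v, path) {
            rows[[length(rows) + 1L]] <<- data.frame(
              parameter = path, base = v[["base"]], low = v[["low"]],
              high = v[["high"]],
              arm_specific = grepl("^(chm|conv)_arm\\.", path),
              stringsAsFactors = FALSE)
            v
          })
  do.call(rbind, rows)
}

#' Get or set one parameter by dotted path
#'
#' @param params An `acs_parameters` object.
#' @param path Dotted path as in [parameter_table()].
#' @param value Replacement base value (range is kept).
#' @return `get_parameter()`: the `(base, low, high)` triple.
#'   `set_parameter()`: the modified parameter set (not revalidated).
#' @export
get_parameter <- function(params, path) {
  node <- params
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    node <- node[[k]]
    if (is.null(node)) stop("unknown parameter path: ", path, call. = FALSE)
  }
  node
}

#' @rdname get_parameter
#' @export
set_parameter <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys, quote(params))
  cur <- eval(expr)
  if (is.null(cur)) stop("unknown parameter path: ", path, call. = FALSE)
  cur[["base"]] <- as.numeric(value)
  eval(call("<-", expr, cur))
  params
}

## ---- random generation and rate conversion ---------------------------------

#' Random structurally valid parameter set
#'
#' Draws every ranged value uniformly within its sensitivity range (the
#' range itself is kept), producing a structurally valid parameter set for
#' property testing. Under the published ranges every per-state outgoing
#' sum stays below 1 by construction. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param settings Run settings for the generated set.
#' @return A validated `acs_parameters` object.
#' @export
random_parameter_set <- function(seed, settings = default_settings()) {
  set.seed(as.integer(seed))
  params <- default_parameters()
  params$settings <- settings
  out <- rapply(unclass(params)[c("chm_arm", "conv_arm", "long_term", "utilities")],
                how = "replace",
                f = function(v) {
                  if (is.numeric(v) && length(v) == 3L &&
                      identical(names(v), c("base", "low", "high")))
                    v[["base"]] <- stats::runif(1, v[["low"]], v[["high"]])
                  v
                })
  params[names(out)] <- out
  validate_parameters(params)
}

#' Convert an event rate to a per-period probability
#'
#' Assuming a constant hazard, the probability of at least one event over
#' `t` years at rate `rate` per year is `1 - exp(-rate * t)`.
#'
#' @param rate Event rate (events per year), non-negative.
#' @param t Period length in years, positive (default 1).
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' rate_to_probability(0.0305)        # ~0.0300
#' probability_to_rate(0.027)         # annual rate behind a 2.7% probability
rate_to_probability <- function(rate, t = 1) {
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  1 - exp(-rate * t)
}

#' @rdname rate_to_probability
#' @param p Probability in `[0, 1)`.
#' @export
probability_to_rate <- function(p, t = 1) {
  if (any(p < 0) || any(p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  -log(1 - p) / t
}
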