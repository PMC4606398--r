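# Outcome layer: rewards, QALY accumulation, event counts, incremental
# comparisons.

test_that("cycle rewards match direct utility-weighted sums", {
  p <- default_parameters()
  all_ef <- stats::setNames(c(1, rep(0, 7)), health_states())
  expect_equal(cycle_reward(all_ef, p$utilities, "chm"), 0.818)
  expect_equal(cycle_reward(all_ef, p$utilities, "conv"), 0.809)
  all_dead <- stats::setNames(c(rep(0, 7), 1), health_states())
  expect_equal(cycle_reward(all_dead, p$utilities, "chm"), 0)
  # CHM end-of-year-1 occupancy, computed by hand from the branch
  # probabilities and the utility/disutility values
  occ <- entry_distribution(run_decision_tree(p$chm_arm))
  by_hand <- 0.9677 * 0.818 + 0.005 * (0.818 - 0.127) +
    0.0074 * (0.818 - 0.139) + 0.0149 * (0.818 - 0.117)
  expect_equal(cycle_reward(occ, p$utilities, "chm"), by_hand)
  expect_equal(round(by_hand, 4), 0.8105)
  expect_error(cycle_reward(all_ef * 0.5, p$utilities, "chm"), "sum to 1")
})

test_that("one-off disutility mode spares the post-event states", {
  u <- default_parameters()$utilities
  su <- state_utilities(u, "chm", "one-off")
  expect_equal(unname(su[c("post_mi", "post_stroke", "post_ua")]),
               rep(0.818, 3))
  expect_equal(unname(su[c("new_mi", "new_stroke", "new_ua")]),
               0.818 - c(0.127, 0.139, 0.117))
  su_p <- state_utilities(u, "chm", "persistent")
  expect_equal(unname(su_p[c("post_mi", "post_stroke", "post_ua")]),
               0.818 - c(0.127, 0.139, 0.117))
})

test_that("year-1 QALYs equal the engine-independent closed form", {
  # calibration anchor for the half-cycle convention: 0.5 x utility-weighted
  # end-of-year-1 occupancy, straight from the published probabilities
  cf_chm <- year1_qaly_closed_form(0.005, 0.0074, 0.0149, 0.005,
                                   0.818, 0.127, 0.139, 0.117)
  cf_conv <- year1_qaly_closed_form(0.0175, 0.0150, 0.0399, 0.0075,
                                    0.809, 0.127, 0.139, 0.117)
  m <- run_model(default_parameters())
  expect_equal(m$qalys$chm$year1, cf_chm, tolerance = 1e-12)
  expect_equal(m$qalys$conv$year1, cf_conv, tolerance = 1e-12)
  # the closed form itself sits at ~0.4053 / ~0.3970
  expect_equal(round(cf_chm, 4), 0.4053)
  expect_equal(round(cf_conv, 4), 0.3970)
})

test_that("half-cycle conventions order as expected and discounting shrinks QALYs", {
  p <- default_parameters()
  totals <- sapply(c("standard", "entry-half", "none"), function(hc) {
    m <- run_model(p, default_settings(half_cycle = hc))
    m$qalys$chm$total
  })
  # rewards decline over time, so: none > entry-half > standard
  expect_true(totals[["none"]] > totals[["entry-half"]])
  expect_true(totals[["entry-half"]] > totals[["standard"]])
  m0 <- run_model(p, default_settings(discount_rate = 0))
  m5 <- run_model(p, default_settings(discount_rate = 0.05))
  expect_true(m0$qalys$chm$total > m5$qalys$chm$total)
  expect_equal(m0$qalys$chm$year1, m5$qalys$chm$year1)  # cycle 1 undiscounted
})

test_that("single-cycle run earns exactly the half first-cycle reward", {
  m1 <- run_model(default_parameters(), default_settings(horizon_years = 1))
  expect_equal(m1$qalys$chm$total, m1$qalys$chm$year1)
  cf <- year1_qaly_closed_form(0.005, 0.0074, 0.0149, 0.005,
                               0.818, 0.127, 0.139, 0.117)
  expect_equal(m1$qalys$chm$total, cf)
})

test_that("per-cohort event counts behave under self- and cross-comparison", {
  p <- default_parameters()
  m <- run_model(p)
  ev_self <- events_per_cohort(m$trace$chm, m$trace$chm)
  for (f in c("event_free_gained", "deaths_avoided", "mi_prevented",
              "stroke_prevented", "ua_prevented"))
    expect_identical(ev_self[[f]], 0L)
  ev <- m$events_per_1000
  expect_true(all(unlist(ev[c("event_free_gained", "deaths_avoided",
                              "mi_prevented", "stroke_prevented",
                              "ua_prevented")]) >= 0L))
  expect_error(events_per_cohort(m$trace$chm, m$trace$chm[1:5, ]),
               "different horizons")
  # equal arms: every incremental output exactly zero
  meq <- run_model(scenario("equal_arms"))
  expect_equal(meq$incremental$qaly_total, 0)
  expect_equal(meq$incremental$survival_pp, 0)
  expect_identical(meq$events_per_1000$event_free_gained, 0L)
})

test_that("QALYs move monotonically with utilities, disutilities, mortality", {
  eps <- 0.005
  bump_paths <- list(
    up = c("utilities.u_event_free_chm"),
    down = c("utilities.d_mi", "utilities.d_stroke", "utilities.d_ua",
             "long_term.event_free.p_death", "long_term.post_mi.p_death_later",
             "long_term.post_stroke.p_death_y1", "chm_arm.p_death")
  )
  for (seed in 1:100) {
    p <- random_parameter_set(seed)
    base <- run_model(p)$qalys$chm$total
    path_up <- sample(bump_paths$up, 1)
    path_dn <- sample(bump_paths$down, 1)
    v_up <- get_parameter(p, path_up)[["base"]]
    v_dn <- get_parameter(p, path_dn)[["base"]]
    q_up <- run_model(set_parameter(p, path_up, min(v_up + eps, 1)))$qalys$chm$total
    q_dn <- run_model(set_parameter(p, path_dn, min(v_dn + eps, 1)))$qalys$chm$total
    expect_gte(q_up, base)
    expect_lte(q_dn, base)
  }
})

test_that("elementwise-better year-1 risks imply non-negative gains", {
  # dominance property: if the CHM arm's year-1 probabilities are all <=
  # the conventional arm's (utilities held equal), the QALY difference is
  # >= 0; survival dominance additionally needs every post-event mortality
  # to be at least the event-free mortality (otherwise a nonfatal event
  # can be marginally protective for long-term survival, as with the
  # published post-UA later-year mortality 0.020 < event-free 0.027)
  arm_f <- c("p_nonfatal_mi", "p_nonfatal_stroke", "p_nonfatal_ua", "p_death")
  for (seed in 1:25) {
    p <- random_parameter_set(seed)
    p$utilities$u_event_free_chm <- p$utilities$u_event_free_conv
    shrink <- stats::runif(4, 0, 1)
    for (i in seq_along(arm_f))
      p$chm_arm[[arm_f[i]]][["base"]] <-
        shrink[i] * p$conv_arm[[arm_f[i]]][["base"]]
    m <- run_model(p)
    expect_gte(m$incremental$qaly_total, 0)
    # restrict to the no-protective-events regime for the survival claim
    min_post_death <- min(vapply(
      c("post_mi", "post_ua", "post_stroke"),
      function(st) min(p$long_term[[st]]$p_death_y1[["base"]],
                       p$long_term[[st]]$p_death_later[["base"]]),
      numeric(1)))
    p$long_term$event_free$p_death[["base"]] <-
      min(p$long_term$event_free$p_death[["base"]], min_post_death)
    m2 <- run_model(p)
    expect_gte(m2$incremental$survival_pp, 0)
    expect_gte(m2$incremental$qaly_total, 0)
  }
})

test_that("incremental of an arm against itself is zero", {
  m <- run_model(default_parameters())
  inc <- incremental(m$qalys$chm, m$qalys$chm, m$survival$chm, m$survival$chm)
  expect_equal(inc$qaly_total, 0)
  expect_equal(inc$qaly_year1, 0)
  expect_equal(inc$survival_pp, 0)
})
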