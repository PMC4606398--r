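# Shared helpers for the test suite.

# Independent closed-form oracle for the year-1 QALY anchor: half the
# utility-weighted end-of-year-1 occupancy, computed by direct arithmetic
# from an arm's event probabilities and the utility/disutility values,
# bypassing the Markov engine and the reward machinery.
year1_qaly_closed_form <- function(p_mi, p_stroke, p_ua, p_death,
                                   u, d_mi, d_stroke, d_ua) {
  ef <- 1 - (p_mi + p_stroke + p_ua + p_death)
  0.5 * (ef * u + p_mi * (u - d_mi) + p_stroke * (u - d_stroke) +
           p_ua * (u - d_ua) + p_death * 0)
}

# Default parameters with the known published base-outside-range row
# silenced during validation.
quiet_validate <- function(params) suppressWarnings(validate_parameters(params))

# A modified copy of the default set with one base value replaced.
with_base <- function(params, path, value) set_parameter(params, path, value)
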