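# Shared tolerances and condition classes.

# normalization tolerance for probability vectors / table rows
PROB_TOL <- 1e-9
# tie tolerance, in bits, for alpha comparisons (maxima, minimality ties);
# all worked-example values are exact dyadic-log ratios, so this only absorbs
# floating-point noise without merging genuinely distinct values
ALPHA_TOL <- 1e-8
# default cap on pre + post variable count for exhaustive enumeration
DEFAULT_GUARD <- 12L

abort_schema <- function(msg) {
  rlang::abort(msg, class = "actualcause_schema_error")
}

abort_realization <- function(msg) {
  rlang::abort(msg, class = "actualcause_realization_error")
}

abort_guard <- function(msg) {
  rlang::abort(msg, class = "actualcause_guard_error")
}
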