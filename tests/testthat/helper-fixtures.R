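# Small fixtures built in code.

# a reduced cohort spec used across tests: low rate and few trials keep
# entropy costs small while preserving the full pipeline structure
tiny_spec <- function(seed = 1, d = 0, ...) {
  cohort_spec(n_exercise = 8, n_nonexercise = 6, effect_size_d = d,
              sampling_rate_hz = 64, n_trials_per_block = 3,
              n_practice_per_block = 2, seed = seed, ...)
}

# a deterministic trial-log data frame
toy_trials <- function(rt_comp, rt_incomp, correct_comp = NULL,
                       correct_incomp = NULL) {
  correct_comp <- correct_comp %||% rep(TRUE, length(rt_comp))
  correct_incomp <- correct_incomp %||% rep(TRUE, length(rt_incomp))
  rbind(
    data.frame(iat_type = "affective", block = "compatible",
               practice = FALSE, rt_ms = rt_comp, correct = correct_comp),
    data.frame(iat_type = "affective", block = "incompatible",
               practice = FALSE, rt_ms = rt_incomp,
               correct = correct_incomp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, code) {
  set.seed(seed)
  code
}
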