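#' Specification of a synthetic cohort
#'
#' Describes a cohort of synthetic participants: group sizes, the
#' planted standardized group difference in envelope-entropy-relevant
#' amplitude-modulation regularity, where the effect lives
#' (conditions x regions), the IAT block length and EEG sampling rate.
#' Defaults mirror the study design: 33 exercisers vs 23
#' non-exercisers, 72 formal (plus 24 practice) trials per block,
#' 1000 Hz native sampling.
#'
#' The effect is planted on a per-participant latent trait: higher
#' trait means a smoother (less bursty) alpha amplitude envelope and
#' hence higher envelope entropy. Exercisers' traits are shifted by
#' `effect_size_d` standard deviations in the effect cells only, so the
#' realized standardized difference in region-averaged envelope entropy
#' tracks `effect_size_d` (see the methods vignette for the
#' calibration).
#'
#' @param n_exercise,n_nonexercise group sizes (>= 1).
#' @param effect_size_d planted standardized group difference (>= 0).
#' @param effect_conditions condition labels carrying the effect.
#' @param effect_regions region labels carrying the effect.
#' @param n_trials_per_block formal trials per block.
#' @param n_practice_per_block practice trials per block.
#' @param sampling_rate_hz native EEG sampling rate.
#' @param seed root seed; the same spec (including seed) regenerates a
#'   bit-identical cohort.
#' @param conditions which task conditions to generate EEG for (all
#'   four by default; simulation studies focused on a subset can skip
#'   the rest). Because every participant-condition has its own seed
#'   substream, a subset cohort's epochs are identical to the matching
#'   conditions of the full cohort.
#' @param signal overrides for the EEG signal model (see
#'   [signal_defaults()]).
#' @param behavior overrides for the trial-log model (see
#'   [behavior_defaults()]).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_exercise = 33, n_nonexercise = 23,
                        effect_size_d = 1.0,
                        effect_conditions = "affective_incompatible",
                        effect_regions = c("frontal", "fronto_central",
                                           "central"),
                        n_trials_per_block = 72,
                        n_practice_per_block = 24,
                        sampling_rate_hz = 1000,
                        seed = 1L,
                        conditions = iat_conditions(),
                        signal = list(), behavior = list()) {
  chk <- function(ok, field)
    if (!ok) stop("invalid cohort spec field: ", field)
  chk(is.numeric(n_exercise) && n_exercise >= 1, "n_exercise")
  chk(is.numeric(n_nonexercise) && n_nonexercise >= 1, "n_nonexercise")
  chk(is.numeric(effect_size_d) && effect_size_d >= 0, "effect_size_d")
  chk(all(effect_conditions %in% iat_conditions()), "effect_conditions")
  chk(all(effect_regions %in% names(region_map())), "effect_regions")
  chk(n_trials_per_block >= 1, "n_trials_per_block")
  chk(n_practice_per_block >= 0, "n_practice_per_block")
  chk(sampling_rate_hz > 0, "sampling_rate_hz")
  chk(is.numeric(seed) && length(seed) == 1, "seed")
  chk(all(conditions %in% iat_conditions()) && length(conditions) >= 1,
      "conditions")
  structure(list(
    n_exercise = as.integer(n_exercise),
    n_nonexercise = as.integer(n_nonexercise),
    effect_size_d = effect_size_d,
    effect_conditions = effect_conditions,
    effect_regions = effect_regions,
    n_trials_per_block = as.integer(n_trials_per_block),
    n_practice_per_block = as.integer(n_practice_per_block),
    sampling_rate_hz = sampling_rate_hz,
    seed = as.integer(seed),
    conditions = conditions,
    signal = modifyList(signal_defaults(), signal),
    behavior = modifyList(behavior_defaults(), behavior)
  ), class = "cohort_spec")
}

#' Default parameters of the synthetic EEG signal model
#'
#' Each regional source is a sum of a theta, an amplitude-modulated
#' alpha and a beta oscillation plus band-limited 1/f noise; channels
#' add independent sensor-level 1/f noise. Amplitudes are in
#' microvolts. The alpha modulation depth is the burstiness parameter
#' the group effect acts on: depth = `mod_base` - `mod_scale` x trait,
#' clamped to [0.05, 0.95]. Traits correlate `region_cor` across
#' regions within a participant.
#'
#' @return named list of model parameters.
#' @export
signal_defaults <- function() {
  list(amp_alpha = 12, amp_theta = 5, amp_beta = 4,
       f_alpha = 10, f_theta = 5, f_beta = 20, f_mod = 6,
       freq_jitter = 0.5,
       noise_sd = 3, ch_noise_sd = 2,
       mod_base = 0.5, mod_scale = 0.12, mod_epoch_sd = 0.02,
       region_cor = 0.7,
       artifact_prob = 0, artifact_uv = 150)
}

#' Default parameters of the synthetic IAT trial-log model
#'
#' Reaction times are ex-Gaussian (normal plus exponential) with an
#' incompatible-block mean shift so D-scores are positive on average;
#' error, fast-response (< 350 ms) and missing-response rates are
#' configurable. The ex-Gaussian base is floored at 360 ms so that with
#' `fast_rate = 0` no formal trial hits the < 350 ms filter.
#'
#' @return named list of model parameters.
#' @export
behavior_defaults <- function() {
  list(rt_mu = 650, rt_sigma = 80, rt_tau = 120, rt_shift = 80,
       error_rate = 0.05, fast_rate = 0.02, miss_rate = 0.01)
}

# band-limited 1/f amplitude noise, target SD sd
pink_noise <- function(n, rate, sd, band = c(3, 40)) {
  if (sd <= 0) return(numeric(n))
  hi <- min(band[2], 0.45 * rate)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f) # two-sided
  gain <- ifelse(f >= band[1] & f <= hi, 1 / sqrt(pmax(f, 1)), 0)
  x <- Re(fft(fft(rnorm(n)) * gain, inverse = TRUE) / n)
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x * sd / s
}

#' Generate one participant-condition's synthetic EEG epochs
#'
#' Builds stimulus-locked epochs spanning -500..1000 ms at the native
#' rate over the 14 electrodes of [region_map()]. Each region's source
#' is theta + amplitude-modulated alpha + beta oscillations plus 1/f
#' noise; the modulation depth per region comes from
#' `profile$mod_depth[condition, region]`. Amplitudes are referenced,
#' artifact-free microvolt signals (typically within +-50 uV) unless
#' artifact injection is enabled.
#'
#' @param profile list with `sampling_rate_hz`, `n_epochs`, `mod_depth`
#'   (condition x region matrix), and the [signal_defaults()] fields
#'   (see [generate_cohort()], which builds profiles).
#' @param condition one of [iat_conditions()].
#' @param seed integer seed for this participant-condition substream.
#' @return an [epoch_set()].
#' @export
generate_eeg_epochs <- function(profile, condition, seed) {
  if (!condition %in% iat_conditions())
    stop("unknown condition label: ", condition)
  p <- profile
  rate <- p$sampling_rate_hz
  n <- round(1.5 * rate)
  rm_ <- region_map()
  chans <- unlist(rm_, use.names = FALSE)
  t <- (seq_len(n) - 1) / rate - 0.5
  arr <- array(0, dim = c(p$n_epochs, length(chans), n))
  with_seed(seed, {
    for (e in seq_len(p$n_epochs)) {
      col <- 0
      for (r in names(rm_)) {
        m <- p$mod_depth[condition, r] +
          p$mod_epoch_sd * rnorm(1)
        m <- min(max(m, 0.02), 0.98)
        ph <- runif(4, 0, 2 * pi)
        env <- p$amp_alpha * (1 + m * cos(2 * pi * p$f_mod * t + ph[4]))
        src <- p$amp_theta * sin(2 * pi * p$f_theta * t + ph[1]) +
          env * sin(2 * pi * p$f_alpha * t + ph[2]) +
          p$amp_beta * sin(2 * pi * p$f_beta * t + ph[3]) +
          pink_noise(n, rate, p$noise_sd)
        for (ch in rm_[[r]]) {
          col <- col + 1
          arr[e, col, ] <- src + pink_noise(n, rate, p$ch_noise_sd)
        }
      }
      if (p$artifact_prob > 0 && runif(1) < p$artifact_prob) {
        j <- sample.int(n, 1)
        arr[e, sample.int(length(chans), 1), j] <-
          p$artifact_uv * sign(rnorm(1))
      }
    }
  })
  epoch_set(arr, chans, rate, condition = condition)
}

#' Generate a synthetic IAT trial log
#'
#' Per IAT type (affective, instrumental), one compatible and one
#' incompatible block, each with the configured number of practice and
#' formal trials. Reaction times are ex-Gaussian with an
#' incompatible-block shift; error, fast and missing responses are
#' drawn at the configured rates.
#'
#' @param profile list with `n_trials_per_block`,
#'   `n_practice_per_block` and the [behavior_defaults()] fields.
#' @param seed integer substream seed.
#' @return data frame with columns `iat_type`, `block`, `practice`,
#'   `rt_ms`, `correct`.
#' @export
generate_trial_log <- function(profile, seed) {
  b <- profile
  one_block <- function(iat_type, block) {
    ntot <- b$n_practice_per_block + b$n_trials_per_block
    shift <- if (block == "incompatible") b$rt_shift else 0
    rt <- pmax(rnorm(ntot, b$rt_mu + shift, b$rt_sigma), 360) +
      rexp(ntot, 1 / b$rt_tau)
    fast <- runif(ntot) < b$fast_rate
    rt[fast] <- runif(sum(fast), 150, 349)
    miss <- runif(ntot) < b$miss_rate
    rt[miss] <- NA_real_
    correct <- runif(ntot) >= b$error_rate & !miss
    data.frame(
      iat_type = iat_type, block = block,
      practice = rep(c(TRUE, FALSE),
                     c(b$n_practice_per_block, b$n_trials_per_block)),
      rt_ms = rt, correct = correct)
  }
  with_seed(seed, {
    do.call(rbind, lapply(c("affective", "instrumental"), function(it)
      rbind(one_block(it, "compatible"), one_block(it, "incompatible"))))
  })
}

#' Generate a synthetic 7-day exercise recall record
#'
#' Non-exercisers report zero moderate and vigorous activity (walking
#' is allowed); exercisers report at least one positive moderate or
#' vigorous entry, so [assign_group()] reproduces the label exactly.
#'
#' @param group_label `"exercise"` or `"non_exercise"`.
#' @param seed integer substream seed.
#' @return list of IPAQ recall fields (days/week and min/day for
#'   walking, moderate and vigorous activity).
#' @export
generate_exercise_report <- function(group_label, seed) {
  with_seed(seed, {
    wd <- sample(0:7, 1)
    wmin <- if (wd > 0) sample(seq(10, 60, 5), 1) else 0
    if (group_label == "non_exercise") {
      list(walking_days = wd, walking_min = wmin,
           moderate_days = 0, moderate_min = 0,
           vigorous_days = 0, vigorous_min = 0)
    } else {
      vd <- sample(0:3, 1)
      list(walking_days = wd, walking_min = wmin,
           moderate_days = sample(1:5, 1),
           moderate_min = sample(seq(20, 60, 10), 1),
           vigorous_days = vd,
           vigorous_min = if (vd > 0) sample(seq(20, 60, 10), 1) else 0)
    }
  })
}

block_of_condition <- function(condition) {
  # condition label -> (iat_type, block)
  parts <- strsplit(condition, "_")[[1]]
  list(iat_type = parts[1], block = parts[2])
}

#' Generate a full synthetic cohort
#'
#' Returns one record per participant: group label, per-condition EEG
#' epoch sets (one epoch per correct formal trial of the matching
#' block), the IAT trial log and the exercise recall. All randomness
#' derives from `spec$seed` via named substreams keyed by participant
#' and stage, so regenerating with the same spec is bit-identical and
#' enlarging the cohort does not perturb existing participants.
#'
#' The group effect: in `effect_conditions` x `effect_regions`,
#' exercisers' latent modulation-regularity traits are shifted by
#' `effect_size_d` SD, raising their expected envelope entropy there
#' and nowhere else.
#'
#' @param spec a [cohort_spec()].
#' @return list of participant records (class `cohort`), each with
#'   `participant_id`, `group_label`, `epoch_sets`, `trial_log`,
#'   `exercise_report`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  sgn <- spec$signal
  groups <- rep(c("exercise", "non_exercise"),
                c(spec$n_exercise, spec$n_nonexercise))
  conds <- iat_conditions()
  regions <- names(region_map())
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    pid <- sprintf("P%03d", i)
    grp <- groups[i]
    # latent modulation-regularity traits, correlated across regions
    tr <- with_seed(substream_seed(spec$seed, pid, "trait"), {
      g <- rnorm(1)
      e <- rnorm(length(regions))
      sgn$region_cor * g + sqrt(1 - sgn$region_cor^2) * e
    })
    names(tr) <- regions
    mod_depth <- matrix(0, length(conds), length(regions),
                        dimnames = list(conds, regions))
    for (cd in conds) for (r in regions) {
      v <- tr[[r]]
      if (grp == "exercise" && cd %in% spec$effect_conditions &&
          r %in% spec$effect_regions)
        v <- v + spec$effect_size_d
      mod_depth[cd, r] <- min(max(sgn$mod_base - sgn$mod_scale * v,
                                  0.05), 0.95)
    }
    trial_log <- generate_trial_log(
      c(spec$behavior, list(n_trials_per_block = spec$n_trials_per_block,
                            n_practice_per_block = spec$n_practice_per_block)),
      substream_seed(spec$seed, pid, "trials"))
    report <- generate_exercise_report(
      grp, substream_seed(spec$seed, pid, "ipaq"))
    epoch_sets <- list()
    for (cd in intersect(conds, spec$conditions)) {
      bl <- block_of_condition(cd)
      sel <- trial_log$iat_type == bl$iat_type &
        trial_log$block == bl$block & !trial_log$practice
      n_ep <- sum(trial_log$correct[sel])
      prof <- c(sgn, list(sampling_rate_hz = spec$sampling_rate_hz,
                          n_epochs = n_ep, mod_depth = mod_depth))
      epoch_sets[[cd]] <- generate_eeg_epochs(
        prof, cd, substream_seed(spec$seed, pid, "eeg", cd))
    }
    out[[i]] <- list(participant_id = pid, group_label = grp,
                     epoch_sets = epoch_sets, trial_log = trial_log,
                     exercise_report = report)
  }
  structure(out, class = "cohort", spec = spec)
}

#' @export
print.cohort <- function(x, ...) {
  g <- vapply(x, `[[`, "", "group_label")
  cat(sprintf("<cohort> %d participants (%d exercise / %d non-exercise)\n",
              length(x), sum(g == "exercise"), sum(g == "non_exercise")))
  invisible(x)
}
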