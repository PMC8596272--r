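# Synthetic EEG cohort with known, band-resolved fractal structure.
#
# Each subject is a 19-channel, 250 Hz recording containing one rest
# interval and six sound-stimulus conditions (10 s x 12 repetitions each,
# randomized order, 2 s unanalysed gaps).  Within every scheduled interval
# each channel carries stationary Gaussian noise whose power spectrum is a
# piecewise power law over 2-20 Hz:
#
#   * the *broadband* Hurst target sets the coarse tilt (how total power is
#     apportioned between the slow, alpha and beta sub-bands), which drives
#     the broadband-filtered Higuchi dimension;
#   * each sub-band's own Hurst target sets the fine in-band spectral slope,
#     which - because the Higuchi dimension is amplitude-invariant - is the
#     sole determinant of that band-filtered dimension.
#
# This gives independent, monotone control of complexity per analysis band,
# something a single-exponent fBm cannot provide (a single H moves the
# complexity of every band in the same direction).

cohort_groups <- function() c("control", "mild_dai", "severe_dai")

cohort_states <- function() {
  c("rest", "unpleasant_noise", "cough", "laughter", "crying", "barking",
    "bird_singing")
}

# Sub-band partition used for synthesis; edges chosen so each canonical
# analysis band (2-7, 8-13, 14-19 Hz) falls inside exactly one chunk.
synth_subbands <- function() {
  list(slow = c(2, 7.5), alpha = c(7.5, 13.5), beta = c(13.5, 20))
}

#' Default per-(group, state, band) Hurst targets
#'
#' Encodes the qualitative group structure the pipeline is designed to
#' recover: at rest, the severe-injury group has the flattest broadband
#' tilt (smallest H, hence the highest broadband complexity) while the
#' control group has the roughest alpha band (smallest alpha H, hence the
#' highest alpha-band complexity, with the mild group intermediate); under
#' stimulation, complexity rises relative to rest in the control and mild
#' groups (H decreases) but falls in the severe group (H increases), with
#' per-stimulus scaling strongest for "laughter".
#'
#' @return Data frame with columns `group`, `state`, `band`, `hurst`
#'   (3 x 7 x 4 rows).
#' @export
default_hurst_table <- function() {
  rest <- list(
    control    = c(broadband = 0.70, slow = 0.60, alpha = 0.45, beta = 0.60),
    mild_dai   = c(broadband = 0.70, slow = 0.60, alpha = 0.55, beta = 0.60),
    severe_dai = c(broadband = 0.55, slow = 0.50, alpha = 0.65, beta = 0.60)
  )
  response <- c(control = -0.06, mild_dai = -0.06, severe_dai = +0.08)
  stim_scale <- c(unpleasant_noise = 0.5, cough = 0.8, laughter = 1.3,
                  crying = 0.9, barking = 1.0, bird_singing = 1.1)
  band_weight <- list(
    control    = c(broadband = 1, slow = 1.00, alpha = 0.50, beta = 0),
    mild_dai   = c(broadband = 1, slow = 0.75, alpha = 0.75, beta = 0),
    severe_dai = c(broadband = 1, slow = 0.50, alpha = 1.00, beta = 0)
  )
  bands <- names(rest$control)
  rows <- list()
  for (g in cohort_groups()) {
    for (st in cohort_states()) {
      shift <- if (st == "rest") 0 else response[[g]] * stim_scale[[st]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, state = st, band = bands,
        hurst = unname(rest[[g]][bands] + shift * band_weight[[g]][bands]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Cohort simulation design
#'
#' Bundles everything needed to generate a cohort deterministically: group
#' sizes, the stimulus protocol (10 s stimuli repeated 12 times, 90 s rest,
#' randomized presentation with 2 s gaps), the per-(group, state, band)
#' Hurst targets, a left-minus-right hemisphere complexity offset applied
#' during stimulation, between-subject Hurst variability, and the master
#' seed.
#'
#' @param n_subjects Named integer vector of group sizes; default
#'   `c(control = 13, mild_dai = 13, severe_dai = 15)`, the study layout
#'   this package emulates.
#' @param effects `"default"` for the effect-encoding Hurst table
#'   ([default_hurst_table()]), `"null"` for a no-difference design (all
#'   targets 0.6, zero asymmetry) used for type-I-error calibration.
#' @param hurst_table Optional explicit `group`/`state`/`band`/`hurst`
#'   data frame overriding `effects`.
#' @param hemisphere_asymmetry Hurst offset subtracted from left-hemisphere
#'   channels during stimulus intervals (left rougher, i.e. more complex);
#'   `>= 0`.
#' @param subject_sd SD of the per-subject Hurst offset shared across all
#'   states and bands (between-subject variability).
#' @param fs Sampling rate, Hz.
#' @param stimulus_duration_s,repetitions,rest_duration_s,gap_s Protocol
#'   timing in seconds (defaults 10, 12, 90, 2).
#' @param amplitude_uv Signal scale (SD in microvolts; keeps samples within
#'   a physiologically plausible +/- 50 uV envelope).
#' @param seed Master seed; a design is a complete, reproducible description
#'   of its cohort.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = c(control = 13, mild_dai = 13,
                                         severe_dai = 15),
                          effects = c("default", "null"),
                          hurst_table = NULL,
                          hemisphere_asymmetry = 0.04,
                          subject_sd = 0.03,
                          fs = 250,
                          stimulus_duration_s = 10,
                          repetitions = 12,
                          rest_duration_s = 90,
                          gap_s = 2,
                          amplitude_uv = 15,
                          seed = 1L) {
  effects <- match.arg(effects)
  if (is.null(hurst_table)) {
    hurst_table <- if (effects == "null") {
      ht <- default_hurst_table(); ht$hurst <- 0.6; ht
    } else default_hurst_table()
    if (effects == "null") hemisphere_asymmetry <- 0
  }
  groups <- sort(unique(hurst_table$group))
  if (!setequal(names(n_subjects), groups)) {
    fe_stop("fe_param_error",
            "`n_subjects` must name exactly the groups of the hurst table")
  }
  states <- unique(hurst_table$state)
  if (length(states) != 7L || sum(states == "rest") != 1L) {
    fe_stop("fe_param_error",
            "design requires exactly 7 states, exactly one of them 'rest'")
  }
  if (any(hurst_table$hurst <= 0 | hurst_table$hurst >= 1)) {
    fe_stop("fe_param_error", "all Hurst targets must lie strictly in (0, 1)")
  }
  if (hemisphere_asymmetry < 0) {
    fe_stop("fe_param_error", "`hemisphere_asymmetry` must be >= 0")
  }
  if (any(n_subjects < 0) || any(n_subjects != round(n_subjects))) {
    fe_stop("fe_param_error", "group sizes must be nonnegative integers")
  }
  if (rest_duration_s < 1 || stimulus_duration_s <= 0 || repetitions < 1 ||
      gap_s < 0) {
    fe_stop("fe_param_error", "invalid protocol timing")
  }
  structure(list(
    n_subjects = n_subjects, hurst_table = hurst_table,
    states = c("rest", setdiff(unique(hurst_table$state), "rest")),
    hemisphere_asymmetry = hemisphere_asymmetry, subject_sd = subject_sd,
    fs = fs, stimulus_duration_s = stimulus_duration_s,
    repetitions = repetitions, rest_duration_s = rest_duration_s,
    gap_s = gap_s, amplitude_uv = amplitude_uv, seed = as.integer(seed)
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %s | %d states, fs = %g Hz, seed = %d\n",
              paste(sprintf("%s: %d", names(x$n_subjects), x$n_subjects),
                    collapse = ", "),
              length(x$states), x$fs, x$seed))
  invisible(x)
}

# subject -> (group, seed), deterministic in design$seed
cohort_manifest <- function(design) {
  n <- sum(design$n_subjects)
  if (n < 1L) fe_stop("fe_param_error", "cohort has no subjects")
  group <- rep(names(design$n_subjects), times = design$n_subjects)
  data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    group = group,
    seed = derive_seeds(design$seed, n),
    stringsAsFactors = FALSE
  )
}

# Combined amplitude-spectrum template over the synthesis sub-bands for one
# Hurst parameter set `h` (named: broadband, slow, alpha, beta).
state_template <- function(n, fs, h, amplitude) {
  subs <- synth_subbands()
  bins <- integer(0); a <- numeric(0)
  for (b in names(subs)) {
    tpl <- spectral_template(n, fs, subs[[b]][1L], subs[[b]][2L],
                             hurst_in = h[[b]],
                             power = powerlaw_band_power(subs[[b]][1L],
                                                         subs[[b]][2L],
                                                         h[["broadband"]]))
    bins <- c(bins, tpl$bins)
    a <- c(a, tpl$a)
  }
  scale <- amplitude / sqrt(sum(4 * a^2))
  list(bins = bins, a = a * scale)
}

clamp_hurst <- function(h) pmin(pmax(h, 0.05), 0.95)

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

#' Generate one subject's recording
#'
#' Builds a 19-channel recording at the design's sampling rate containing
#' one rest interval followed by the 72 stimulus intervals (12 per stimulus
#' type) in seeded random order, separated by unanalysed rest-like gaps.
#' Every scheduled interval of every channel carries spectrally shaped
#' Gaussian noise with the design's (group, state, band) Hurst targets; a
#' per-subject Hurst offset (SD `subject_sd`) is shared across states, and
#' left-hemisphere channels are shifted by `hemisphere_asymmetry` toward
#' lower Hurst (higher complexity) during stimulation.
#'
#' @param group Group label present in the design.
#' @param design A [cohort_design()].
#' @param subject_seed Integer seed; the recording is a pure function of
#'   `(group, design, subject_seed)`.
#' @return An [eeg_recording()] with the stimulus schedule attached.
#' @export
gen_subject_recording <- function(group, design, subject_seed) {
  if (!inherits(design, "cohort_design")) {
    fe_stop("fe_param_error", "`design` must be a cohort_design")
  }
  if (!group %in% names(design$n_subjects)) {
    fe_stop("fe_param_error", sprintf("unknown group '%s'", group))
  }
  fs <- design$fs
  labels <- channels_1020()
  left <- montage_pairs()$left
  left_idx <- match(left, labels)
  other_idx <- setdiff(seq_along(labels), left_idx)
  stimuli <- setdiff(design$states, "rest")
  n_rest <- as.integer(round(design$rest_duration_s * fs))
  n_stim <- as.integer(round(design$stimulus_duration_s * fs))
  n_gap <- as.integer(round(design$gap_s * fs))
  reps <- design$repetitions
  n_intervals <- length(stimuli) * reps
  n_total <- n_rest + n_intervals * (n_gap + n_stim)

  ht <- design$hurst_table
  h_of <- function(state) {
    rows <- ht[ht$group == group & ht$state == state, ]
    stats::setNames(rows$hurst, rows$band)
  }

  with_seed_opt(subject_seed, {
    u <- stats::rnorm(1L, 0, design$subject_sd)
    order_stim <- sample(rep(stimuli, each = reps))
    data <- matrix(0, n_total, length(labels),
                   dimnames = list(NULL, labels))

    interval_starts0 <- n_rest + (seq_len(n_intervals) - 1L) *
      (n_gap + n_stim) + n_gap                       # 0-based stimulus rows
    onsets <- interval_starts0 / fs

    # rest interval (both hemispheres identical in distribution)
    nf_rest <- next_pow2(n_rest)
    tpl_rest <- state_template(nf_rest, fs, clamp_hurst(h_of("rest") + u),
                               design$amplitude_uv)
    .synth_fill_cpp(data, 0L, n_rest, nf_rest, tpl_rest$bins,
                    matrix(tpl_rest$a), integer(length(labels)))

    # unanalysed rest-like gaps, one before every stimulus interval
    if (n_gap > 0L) {
      nf_gap <- next_pow2(max(n_gap, 64L))
      tpl_gap <- state_template(nf_gap, fs, clamp_hurst(h_of("rest") + u),
                                design$amplitude_uv)
      .synth_fill_cpp(data, as.integer(interval_starts0 - n_gap), n_gap,
                      nf_gap, tpl_gap$bins, matrix(tpl_gap$a),
                      integer(length(labels)))
    }

    # stimulus intervals, synthesized per stimulus type:
    # left-hemisphere channels get H - asymmetry (rougher), others H
    tpl_of_col <- integer(length(labels))
    tpl_of_col[other_idx] <- 1L
    nf_stim <- next_pow2(n_stim)
    for (st in stimuli) {
      h <- clamp_hurst(h_of(st) + u)
      h_left <- clamp_hurst(h - design$hemisphere_asymmetry)
      tpl_l <- state_template(nf_stim, fs, h_left, design$amplitude_uv)
      tpl_o <- state_template(nf_stim, fs, h, design$amplitude_uv)
      starts <- interval_starts0[order_stim == st]
      .synth_fill_cpp(data, as.integer(starts), n_stim, nf_stim, tpl_l$bins,
                      cbind(tpl_l$a, tpl_o$a), tpl_of_col)
    }

    sch <- stim_schedule(
      state = c("rest", order_stim),
      onset = c(0, onsets),
      duration = c(design$rest_duration_s,
                   rep(design$stimulus_duration_s, n_intervals))
    )
    eeg_recording(data, fs, labels, schedule = sch)
  })
}

#' Generate a full cohort
#'
#' Subject seeds are derived reproducibly from the design's master seed, so
#' the same design always yields the identical cohort.
#'
#' @param design A [cohort_design()] with at least one subject per group.
#' @param keep_signals If `FALSE`, recordings are not materialized and each
#'   entry carries only `subject`, `group` and `seed` (pass these to
#'   [gen_subject_recording()] on demand; useful for large cohorts).
#' @return List with one entry per subject:
#'   `list(subject, group, seed, recording)`.
#' @export
gen_cohort <- function(design, keep_signals = TRUE) {
  if (!inherits(design, "cohort_design")) {
    fe_stop("fe_param_error", "`design` must be a cohort_design")
  }
  if (any(design$n_subjects < 1L)) {
    fe_stop("fe_param_error", "every group needs at least one subject")
  }
  manifest <- cohort_manifest(design)
  lapply(seq_len(nrow(manifest)), function(i) {
    entry <- list(subject = manifest$subject[i], group = manifest$group[i],
                  seed = manifest$seed[i])
    if (keep_signals) {
      entry$recording <- gen_subject_recording(entry$group, design, entry$seed)
    }
    entry
  })
}

#' Write a cohort to disk (EDF + schedules + manifest)
#'
#' Generates subjects one at a time and writes each as an EDF file with a
#' tab-separated schedule sidecar, plus a cohort `manifest.tsv`
#' (subject id, group, file paths, seed).
#'
#' @param design A [cohort_design()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort_manifest(design)
  manifest$file <- file.path(dir, paste0(manifest$subject, ".edf"))
  manifest$schedule_file <- schedule_path(manifest$file)
  for (i in seq_len(nrow(manifest))) {
    rec <- gen_subject_recording(manifest$group[i], design, manifest$seed[i])
    write_recording(rec, manifest$file[i])
  }
  write_tsv_atomic(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
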