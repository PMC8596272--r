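# End-to-end orchestration: simulate -> compute -> stats from one config.
#
# A run is reproducible from its config alone: the master seed is the only
# entropy source, every output is stamped with the config hash, and outputs
# are written atomically (temp file + rename).

#' Build a run configuration
#'
#' @param n_subjects Named group sizes (see [cohort_design()]).
#' @param effects `"default"` or `"null"` effect encoding.
#' @param bands Named list of `c(low, high)` band edges in Hz.
#' @param k_max Higuchi scale cap.
#' @param epoch_seconds Epoch duration.
#' @param hemisphere_asymmetry,subject_sd,fs,stimulus_duration_s,repetitions,rest_duration_s,gap_s,amplitude_uv
#'   Design parameters, as in [cohort_design()].
#' @param response_set Response construction for the group MANOVA;
#'   `"state_means"` (the documented default: per subject, mean HFD per
#'   state across the 16 lateral channels - 7 responses).
#' @param posthoc_method One of the [posthoc()] methods.
#' @param family_residual Alpha budget for [corrected_alpha()].
#' @param seed Master seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @return Object of class `run_config` (a fully serializable list).
#' @export
run_config <- function(n_subjects = c(control = 13, mild_dai = 13,
                                      severe_dai = 15),
                       effects = "default",
                       bands = list(broadband = c(2, 20), slow = c(2, 7),
                                    alpha = c(8, 13), beta = c(14, 19)),
                       k_max = 8L, epoch_seconds = 60,
                       hemisphere_asymmetry = 0.04, subject_sd = 0.03,
                       fs = 250, stimulus_duration_s = 10, repetitions = 12L,
                       rest_duration_s = 90, gap_s = 2, amplitude_uv = 15,
                       response_set = "state_means",
                       posthoc_method = "games_howell",
                       family_residual = 0.05,
                       seed = 20200827L, out_dir = "fractaleeg_run") {
  structure(list(
    n_subjects = n_subjects, effects = effects, bands = bands,
    k_max = as.integer(k_max), epoch_seconds = epoch_seconds,
    hemisphere_asymmetry = hemisphere_asymmetry, subject_sd = subject_sd,
    fs = fs, stimulus_duration_s = stimulus_duration_s,
    repetitions = as.integer(repetitions), rest_duration_s = rest_duration_s,
    gap_s = gap_s, amplitude_uv = amplitude_uv,
    response_set = response_set, posthoc_method = posthoc_method,
    family_residual = family_residual,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Read / write a run configuration (JSON)
#'
#' @param path JSON file path.
#' @return `read_config()` returns a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) fe_stop("fe_format_error", "no such config file")
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    fe_stop("fe_format_error",
                            sprintf("unparseable config: %s", conditionMessage(e)))
                  })
  cfg <- do.call(run_config, utils::modifyList(
    as.list(formals(run_config)), raw[names(raw) %in% names(formals(run_config))],
  )[names(formals(run_config))])
  cfg$n_subjects <- unlist(raw$n_subjects)
  cfg$bands <- lapply(raw$bands, unlist)
  cfg
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$n_subjects <- as.list(out$n_subjects)   # keep group names in JSON
  atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
}

# hash of the scientific content of a config (the output location does not
# change what is computed, so it is excluded)
config_hash <- function(config) {
  core <- unclass(config)
  core$out_dir <- NULL
  core$n_subjects <- as.list(core$n_subjects)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

config_design <- function(config) {
  cohort_design(
    n_subjects = config$n_subjects, effects = config$effects,
    hemisphere_asymmetry = config$hemisphere_asymmetry,
    subject_sd = config$subject_sd, fs = config$fs,
    stimulus_duration_s = config$stimulus_duration_s,
    repetitions = config$repetitions,
    rest_duration_s = config$rest_duration_s, gap_s = config$gap_s,
    amplitude_uv = config$amplitude_uv, seed = config$seed
  )
}

config_bands <- function(config) {
  mapply(function(nm, b) band_spec(nm, b[1L], b[2L]),
         names(config$bands), config$bands, SIMPLIFY = FALSE)
}

#' Validate a run configuration
#'
#' @param config A `run_config` (or path to one).
#' @return Character vector of human-readable violations; empty when the
#'   configuration can run.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  v <- character(0)
  if (config$k_max < 2L) v <- c(v, "k_max must be >= 2")
  if (config$epoch_seconds <= 0) v <- c(v, "epoch_seconds must be positive")
  nyq <- config$fs / 2
  for (nm in names(config$bands)) {
    b <- config$bands[[nm]]
    if (b[1L] <= 0 || b[2L] <= b[1L]) {
      v <- c(v, sprintf("band '%s': edges must satisfy 0 < low < high", nm))
    } else if (b[2L] >= nyq) {
      v <- c(v, sprintf("band '%s': high edge %g Hz >= Nyquist %g Hz",
                        nm, b[2L], nyq))
    }
  }
  if (config$stimulus_duration_s * config$repetitions < config$epoch_seconds) {
    v <- c(v, sprintf("only %g s of material per stimulus for %g s epochs",
                      config$stimulus_duration_s * config$repetitions,
                      config$epoch_seconds))
  }
  if (config$rest_duration_s < config$epoch_seconds) {
    v <- c(v, "rest interval shorter than the epoch duration")
  }
  design_err <- tryCatch({ config_design(config); NULL },
                         error = function(e) conditionMessage(e))
  if (!is.null(design_err)) v <- c(v, design_err)
  if (any(config$n_subjects < 1)) v <- c(v, "every group needs >= 1 subject")
  v
}

log_event <- function(log_path, step, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), step = step),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = log_path, append = TRUE)
  message(sprintf("[fractalEEG] %s", step))
}

write_stamped_tsv <- function(df, path, hash) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(sprintf("# config_hash=%s", hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Run the full pipeline
#'
#' simulate (write the synthetic cohort as EDF + schedule sidecars), compute
#' (read the EDFs back, band-filter, epoch, tabulate HFD), and stats
#' (rest-subtracted deltas, per-band group MANOVA on the configured response
#' set, assumption checks and post-hoc comparisons).  Outputs `cohort/`,
#' `hfd.tsv`, `delta.tsv`, `stats.tsv`, `config.json` and a JSON-lines
#' `run.log` in the run directory, all stamped with the config hash;
#' re-running the same config reproduces `hfd.tsv` bit-identically.
#'
#' @param config A `run_config` (or path to a JSON config).
#' @param force Overwrite a non-empty run directory (otherwise the pipeline
#'   refuses, so partial prior runs are never silently mixed).
#' @return Invisibly, a list with the output paths and the config hash.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- read_config(config)
  violations <- validate_config(config)
  if (length(violations)) {
    fe_stop("fe_validation_error",
            paste0("invalid config:\n  - ",
                   paste(violations, collapse = "\n  - ")))
  }
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) > 0L && !force) {
    fe_stop("fe_validation_error",
            sprintf("output directory '%s' is not empty; use force = TRUE", out))
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config.json")
  write_config(config, cfg_path)
  hash <- config_hash(config)
  log_path <- file.path(out, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  log_event(log_path, "start", config_hash = hash,
            r_version = as.character(getRversion()),
            package_version = as.character(utils::packageVersion("fractalEEG")))

  design <- config_design(config)
  manifest <- write_cohort(design, file.path(out, "cohort"))
  log_event(log_path, "simulate", subjects = nrow(manifest))

  bands <- config_bands(config)
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    list(subject = manifest$subject[i], group = manifest$group[i],
         recording = read_recording(manifest$file[i]))
  })
  tab <- hfd_table(cohort, bands = bands, k_max = config$k_max,
                   target_s = config$epoch_seconds)
  write_stamped_tsv(tab, file.path(out, "hfd.tsv"), hash)
  log_event(log_path, "compute", records = nrow(tab))

  delta <- rest_difference(tab)
  write_stamped_tsv(delta, file.path(out, "delta.tsv"), hash)

  stats_tab <- pipeline_stats(tab, config, log_path)
  write_stamped_tsv(stats_tab, file.path(out, "stats.tsv"), hash)
  log_event(log_path, "stats", rows = nrow(stats_tab))

  log_event(log_path, "done")
  invisible(list(out_dir = out, config_hash = hash,
                 hfd = file.path(out, "hfd.tsv"),
                 delta = file.path(out, "delta.tsv"),
                 stats = file.path(out, "stats.tsv")))
}

#' Per-subject state-mean response matrix
#'
#' The documented default response construction for the group MANOVA: for
#' one band, each subject contributes the mean HFD per state across the 16
#' lateral channels (7 responses for the full state set).
#'
#' @param tab An `hfd_table`.
#' @param band_name Band to extract.
#' @return List with `responses` (subjects x states matrix), `group` and
#'   `subject` vectors aligned to its rows.
#' @export
state_mean_responses <- function(tab, band_name) {
  sub <- tab[tab$band == band_name, ]
  agg <- stats::aggregate(sub$hfd,
                          by = list(subject = sub$subject, group = sub$group,
                                    state = sub$state),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = c("subject", "group"),
                         timevar = "state", direction = "wide")
  resp <- as.matrix(wide[, -(1:2), drop = FALSE])
  colnames(resp) <- sub("^x\\.", "", colnames(resp))
  list(responses = resp, group = wide$group, subject = wide$subject)
}

pipeline_stats <- function(tab, config, log_path) {
  rows <- list()
  m_groups <- length(unique(tab$group))
  alpha_corr <- corrected_alpha(config$family_residual,
                                choose(m_groups, 2L))
  for (band_name in unique(tab$band)) {
    rs <- state_mean_responses(tab, band_name)
    n <- nrow(rs$responses); p <- ncol(rs$responses)
    if (n > p + m_groups) {
      mv <- wilks_manova(rs$responses, rs$group)
      rows[[length(rows) + 1L]] <- data.frame(
        band = band_name, analysis = "manova", term = "group",
        statistic = mv$wilks_lambda, df1 = mv$df_num, df2 = mv$df_den,
        p = mv$p, p_adjusted = NA_real_, effect = mv$partial_eta_sq,
        alpha = as.numeric(alpha_corr))
    } else {
      log_event(log_path, "stats_skipped", band = band_name,
                reason = sprintf("n = %d too small for %d responses", n, p))
    }
    rest_means <- rs$responses[, "rest"]
    by_group <- split(rest_means, rs$group)
    if (any(lengths(by_group) < 2L)) {
      log_event(log_path, "stats_skipped", band = band_name,
                reason = "groups too small for variance/post-hoc tests")
      next
    }
    lv <- levene_test(by_group)
    rows[[length(rows) + 1L]] <- data.frame(
      band = band_name, analysis = "levene", term = "rest",
      statistic = lv$statistic, df1 = lv$df1, df2 = lv$df2, p = lv$p,
      p_adjusted = NA_real_, effect = NA_real_,
      alpha = as.numeric(alpha_corr))
    if (length(rest_means) >= 5L) {
      resid <- unlist(lapply(by_group, function(x) x - mean(x)),
                      use.names = FALSE)
      ks <- ks_normality(resid)
      rows[[length(rows) + 1L]] <- data.frame(
        band = band_name, analysis = "ks_normality", term = "rest",
        statistic = ks$statistic, df1 = NA_real_, df2 = NA_real_, p = ks$p,
        p_adjusted = NA_real_, effect = NA_real_,
        alpha = as.numeric(alpha_corr))
    }
    ph <- posthoc(by_group, method = config$posthoc_method,
                  control = if (config$posthoc_method == "dunnett")
                    "control" else NULL,
                  seed = config$seed)
    for (i in seq_len(nrow(ph$pairs))) {
      rows[[length(rows) + 1L]] <- data.frame(
        band = band_name, analysis = paste0("posthoc_", ph$method),
        term = paste(ph$pairs$group_a[i], ph$pairs$group_b[i], sep = " vs "),
        statistic = ph$pairs$statistic[i], df1 = NA_real_, df2 = NA_real_,
        p = ph$pairs$p_adjusted[i], p_adjusted = ph$pairs$p_adjusted[i],
        effect = NA_real_, alpha = as.numeric(alpha_corr))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(band = character(0), analysis = character(0),
               term = character(0), statistic = numeric(0),
               df1 = numeric(0), df2 = numeric(0), p = numeric(0),
               p_adjusted = numeric(0), effect = numeric(0),
               alpha = numeric(0))
  rownames(out) <- NULL
  out
}
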