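#' Configuration for the synthetic EDA cohort generator
#'
#' Defaults mirror the acquisition protocol the pipeline targets: 65
#' subjects, 100 Hz sampling, one 60 s baseline per subject, and 12 low-pain
#' plus 12 high-pain stimulation trials of 10 s each, in counterbalanced
#' (seeded-random) order. The signal model is tonic level + linear drift +
#' amplitude-scaled bi-exponential skin-conductance responses (SCRs) at
#' stimulus onsets + Gaussian measurement noise, clipped positive. High-pain
#' trials draw larger SCR amplitudes than low-pain trials
#' (`scr_amp_high_mean > scr_amp_low_mean` is the class-separability knob);
#' successive trials habituate multiplicatively.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param fs Sampling rate in Hz.
#' @param baseline_dur Baseline (No Pain) duration in seconds.
#' @param n_low,n_high Number of low-/high-pain trials per subject.
#' @param trial_dur Trial duration in seconds.
#' @param rest_dur Rest period preceding each trial, seconds.
#' @param tonic_level_mean,tonic_level_sd Subject tonic skin-conductance
#'   level distribution, µS.
#' @param drift_slope_sd Standard deviation of the per-subject linear drift
#'   slope, µS/s.
#' @param scr_amp_low_mean,scr_amp_high_mean Mean SCR amplitude for low/high
#'   pain trials, µS.
#' @param scr_amp_sd Trial-to-trial amplitude standard deviation, µS
#'   (draws are truncated at ±2 sd, keeping classes strictly ordered).
#' @param tau_rise,tau_decay SCR kernel rise/decay time constants, seconds.
#' @param scr_latency Latency from stimulus onset to SCR onset, seconds.
#' @param habituation Multiplicative per-trial amplitude decay in (0, 1].
#' @param noise_sd Gaussian measurement-noise standard deviation, µS.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the config.
#' @return A validated `SynthConfig` list (class `"SynthConfig"`).
#' @examples
#' cfg <- synthConfig(n_subjects = 2, seed = 7)
#' cohort <- generateCohort(cfg)
#' @export
synthConfig <- function(n_subjects = 65L, fs = 100, baseline_dur = 60,
                        n_low = 12L, n_high = 12L, trial_dur = 10,
                        rest_dur = 20, tonic_level_mean = 2,
                        tonic_level_sd = 0.5, drift_slope_sd = 0.002,
                        scr_amp_low_mean = 0.3, scr_amp_high_mean = 0.8,
                        scr_amp_sd = 0.1, tau_rise = 0.75, tau_decay = 2,
                        scr_latency = 1, habituation = 0.97,
                        noise_sd = 0.02, seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), fs = fs,
    baseline_dur = baseline_dur, n_low = as.integer(n_low),
    n_high = as.integer(n_high), trial_dur = trial_dur,
    rest_dur = rest_dur, tonic_level_mean = tonic_level_mean,
    tonic_level_sd = tonic_level_sd, drift_slope_sd = drift_slope_sd,
    scr_amp_low_mean = scr_amp_low_mean,
    scr_amp_high_mean = scr_amp_high_mean, scr_amp_sd = scr_amp_sd,
    tau_rise = tau_rise, tau_decay = tau_decay, scr_latency = scr_latency,
    habituation = habituation, noise_sd = noise_sd, seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (cfg$fs <= 0) stopf("fs must be > 0")
  if (cfg$n_low < 0L || cfg$n_high < 0L) stopf("trial counts must be >= 0")
  if (cfg$baseline_dur <= 0 || cfg$trial_dur <= 0 || cfg$rest_dur <= 0) {
    stopf("all durations must be > 0")
  }
  if (cfg$scr_amp_high_mean <= cfg$scr_amp_low_mean) {
    stopf("scr_amp_high_mean must exceed scr_amp_low_mean (class separability)")
  }
  if (cfg$habituation <= 0 || cfg$habituation > 1) {
    stopf("habituation must be in (0, 1]")
  }
  if (cfg$tau_decay <= cfg$tau_rise || cfg$tau_rise <= 0) {
    stopf("need tau_decay > tau_rise > 0")
  }
  class(cfg) <- "SynthConfig"
  cfg
}

#' Bi-exponential (Bateman-type) SCR kernel, unit peak amplitude
#'
#' `exp(-t/tau_decay) - exp(-t/tau_rise)` scaled so the maximum is 1; zero
#' for `t <= 0` (causality). The peak occurs at
#' `t* = tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)`.
#'
#' @param t Time in seconds (vectorized).
#' @param tau_rise,tau_decay Time constants, seconds; `tau_decay > tau_rise > 0`.
#' @return Kernel values in `[0, 1]`.
#' @examples
#' scrKernel(0, 0.75, 2)   # 0
#' scrKernel(1.5, 0.75, 2) # close to the unit peak
#' @export
scrKernel <- function(t, tau_rise = 0.75, tau_decay = 2) {
  if (!is.finite(tau_rise) || !is.finite(tau_decay) ||
      tau_rise <= 0 || tau_decay <= tau_rise) {
    stopf("need tau_decay > tau_rise > 0 (got tau_rise=%g, tau_decay=%g)",
          tau_rise, tau_decay)
  }
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  v <- ifelse(t <= 0, 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak)
  pmax(v, 0)
}

#' Build a subject's stimulus schedule
#'
#' One leading baseline block labeled NoPain, then `n_low + n_high` trials
#' each preceded by a rest period. The order of Low/High labels is a seeded
#' random permutation (counterbalancing). Rest periods are unlabeled gaps.
#'
#' @param config A [synthConfig()] object.
#' @param seed Integer seed for the label permutation.
#' @return [IRanges::IRanges] of events (1-based, inclusive sample
#'   coordinates) with a `label` factor in `mcols`.
#' @export
buildSchedule <- function(config, seed = config$seed) {
  fs <- config$fs
  base_n <- round(config$baseline_dur * fs)
  trial_n <- round(config$trial_dur * fs)
  rest_n <- round(config$rest_dur * fs)
  n_tr <- config$n_low + config$n_high
  labels <- c(rep("LowPain", config$n_low), rep("HighPain", config$n_high))
  if (n_tr > 1L) labels <- withSeed(seed, sample(labels))
  starts <- 1L
  widths <- base_n
  labs <- "NoPain"
  pos <- base_n
  for (i in seq_len(n_tr)) {
    pos <- pos + rest_n
    starts <- c(starts, pos + 1L)
    widths <- c(widths, trial_n)
    labs <- c(labs, labels[i])
    pos <- pos + trial_n
  }
  ev <- IRanges::IRanges(start = starts, width = widths)
  S4Vectors::mcols(ev)$label <- painFactor(labs)
  ev
}

scheduleLength <- function(config) {
  fs <- config$fs
  n_tr <- config$n_low + config$n_high
  as.integer(round(config$baseline_dur * fs) +
    n_tr * (round(config$rest_dur * fs) + round(config$trial_dur * fs)))
}

# Truncated-normal draw at +/- 2 sd, vectorized via rejection (cheap here).
rnormTrunc2 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean[bad], sd)
    bad <- abs(x - mean) > 2 * sd
  }
  x
}

#' Generate one synthetic EDA recording
#'
#' @param config A [synthConfig()] object.
#' @param subject_id Subject identifier string.
#' @param seed Integer seed for this subject's signal draw.
#' @return An [EdaRecording].
#' @export
generateRecording <- function(config, subject_id = "S01", seed = config$seed) {
  ev <- buildSchedule(config, seed = seed)
  n <- scheduleLength(config)
  fs <- config$fs
  withSeed(deriveSeed(seed, 1L), {
    tonic <- max(rnorm(1, config$tonic_level_mean, config$tonic_level_sd), 0.3)
    slope <- rnorm(1, 0, config$drift_slope_sd)
    tt <- (seq_len(n) - 1L) / fs
    x <- tonic + slope * tt
    lab <- as.character(S4Vectors::mcols(ev)$label)
    trial_idx <- which(lab != "NoPain")
    if (length(trial_idx)) {
      amp_mean <- ifelse(lab[trial_idx] == "HighPain",
                         config$scr_amp_high_mean, config$scr_amp_low_mean)
      amp <- rnormTrunc2(length(trial_idx), amp_mean, config$scr_amp_sd)
      amp <- amp * config$habituation^(seq_along(trial_idx) - 1L)
      # kernel support: until it decays below 1e-4 of peak
      supp_n <- ceiling((config$scr_latency + 12 * config$tau_decay) * fs)
      kt <- (seq_len(supp_n) - 1L) / fs - config$scr_latency
      kern <- scrKernel(kt, config$tau_rise, config$tau_decay)
      for (k in seq_along(trial_idx)) {
        onset <- IRanges::start(ev)[trial_idx[k]]
        idx <- onset:min(onset + supp_n - 1L, n)
        x[idx] <- x[idx] + amp[k] * kern[seq_along(idx)]
      }
    }
    if (config$noise_sd > 0) x <- x + rnorm(n, 0, config$noise_sd)
    x <- pmax(x, 0.01)
    new("EdaRecording", subjectId = subject_id, fs = fs,
        conductance = x, events = ev)
  })
}

#' Generate a synthetic EDA cohort
#'
#' Each subject gets an independent sub-seed derived from `config$seed`, so
#' the cohort is a deterministic function of the config.
#'
#' @param config A [synthConfig()] object.
#' @return An [EdaCohort].
#' @examples
#' cohort <- generateCohort(synthConfig(n_subjects = 2))
#' length(cohort)
#' @export
generateCohort <- function(config) {
  recs <- lapply(seq_len(config$n_subjects), function(i) {
    generateRecording(config, subject_id = sprintf("S%02d", i),
                      seed = deriveSeed(config$seed, i))
  })
  new("EdaCohort", recordings = recs, config = unclass(config))
}

#' Write / read a cohort as plain CSV files
#'
#' Layout: one `<subject_id>.csv` per subject with columns
#' `sample_index` (0-based) and `conductance_uS` (full precision), one
#' cohort-level `annotations.csv` with columns `subject_id`, `onset_sample`
#' (0-based), `duration_samples`, `label`, and a `config.yaml` with the
#' generating configuration.
#'
#' @param cohort An [EdaCohort].
#' @param directory Output / input directory.
#' @return `writeCohort` returns `directory` invisibly; `readCohort`
#'   returns the reconstructed [EdaCohort].
#' @export
writeCohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ann <- do.call(rbind, lapply(recordings(cohort), function(r) {
    ev <- stimulusEvents(r)
    data.frame(
      subject_id = subjectId(r),
      onset_sample = IRanges::start(ev) - 1L,
      duration_samples = IRanges::width(ev),
      label = as.character(S4Vectors::mcols(ev)$label),
      stringsAsFactors = FALSE
    )
  }))
  for (r in recordings(cohort)) {
    df <- data.frame(
      sample_index = seq_along(conductance(r)) - 1L,
      conductance_uS = sprintf("%.17g", conductance(r))
    )
    utils::write.csv(df, file.path(directory, paste0(subjectId(r), ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(ann, file.path(directory, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- cohort@config
  if (length(cfg)) {
    yaml::write_yaml(cfg, file.path(directory, "config.yaml"))
  }
  invisible(directory)
}

#' @rdname writeCohort
#' @export
readCohort <- function(directory) {
  annfile <- file.path(directory, "annotations.csv")
  if (!file.exists(annfile)) {
    stopf("not a cohort directory: missing %s", annfile)
  }
  ann <- utils::read.csv(annfile, stringsAsFactors = FALSE)
  need <- c("subject_id", "onset_sample", "duration_samples", "label")
  if (!all(need %in% names(ann))) {
    stopf("%s: malformed header, need columns %s", annfile,
          paste(need, collapse = ", "))
  }
  bad <- which(!ann$label %in% PAIN_LEVELS)
  if (length(bad)) {
    stopf("%s: line %d: unknown label '%s'", annfile, bad[1] + 1L,
          ann$label[bad[1]])
  }
  cfgfile <- file.path(directory, "config.yaml")
  cfg <- if (file.exists(cfgfile)) yaml::read_yaml(cfgfile) else list()
  fs <- if (!is.null(cfg$fs)) cfg$fs else 100
  recs <- lapply(unique(ann$subject_id), function(sid) {
    f <- file.path(directory, paste0(sid, ".csv"))
    if (!file.exists(f)) stopf("missing sample file %s", f)
    df <- utils::read.csv(f)
    if (!all(c("sample_index", "conductance_uS") %in% names(df))) {
      stopf("%s: malformed header, need sample_index, conductance_uS", f)
    }
    a <- ann[ann$subject_id == sid, , drop = FALSE]
    ev <- IRanges::IRanges(start = a$onset_sample + 1L,
                           width = a$duration_samples)
    S4Vectors::mcols(ev)$label <- painFactor(a$label)
    new("EdaRecording", subjectId = sid, fs = fs,
        conductance = as.numeric(df$conductance_uS), events = ev)
  })
  new("EdaCohort", recordings = recs, config = cfg)
}
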