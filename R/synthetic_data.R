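# Seeded generator of ground-truth-labeled multiwell MEA dose-series
# recordings. Wells burst quasi-periodically (Gamma-jittered onsets;
# within-burst spike times follow a peaked Beta(2, 2) envelope so a
# well-defined pooled-rate maximum exists for IMFI estimation), with
# Poisson background firing. Drug mechanisms scale the burst statistics
# with saturating monotone concentration-response curves, emulating
# cumulative administration: 10-min epochs, vehicle first.

#' Synthetic well configuration
#'
#' @param n_electrodes Electrodes per well (fixed at 16).
#' @param duration_s Epoch duration in seconds (default 600).
#' @param burst_rate Network bursts per minute (default 20). Mature
#'   cultures burst every few seconds; with the 4 x IMFI windowing rule
#'   this baseline yields roughly 50 raster windows per 600-s epoch, the
#'   scale implied by published per-well window counts.
#' @param burst_duration_s Burst envelope duration in seconds (default 0.5).
#' @param spikes_per_burst Spikes per network burst, spread over the
#'   participating electrodes (default 120).
#' @param participating_electrodes Electrodes taking part in bursts
#'   (default 12; electrodes `0..participating_electrodes - 1`).
#' @param background_rate Background Poisson rate per electrode in Hz
#'   (default 0.3).
#' @param timing_jitter_s Standard deviation of the Gamma-distributed
#'   inter-burst interval (default 0.45 s, i.e. ~15% of the default 3-s
#'   burst period -- quasi-periodic rhythms, matching the premise that
#'   IMFI windowing captures a regular network-burst cycle).
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @return An object of class `synth_well_config`.
#' @export
synth_well_config <- function(n_electrodes = 16, duration_s = 600,
                              burst_rate = 20, burst_duration_s = 0.5,
                              spikes_per_burst = 120,
                              participating_electrodes = 12,
                              background_rate = 0.3, timing_jitter_s = 0.45,
                              seed = NULL) {
  .assert(n_electrodes == 16, "the data model is 16 electrodes per well")
  .assert(duration_s > 0 && burst_rate > 0 && burst_duration_s > 0 &&
            spikes_per_burst >= 1 && timing_jitter_s >= 0 &&
            background_rate >= 0, "rates and durations must be positive")
  .assert(participating_electrodes >= 1 && participating_electrodes <= 16,
          "participating_electrodes must be in 1..16")
  structure(list(n_electrodes = 16L, duration_s = duration_s,
                 burst_rate = burst_rate,
                 burst_duration_s = burst_duration_s,
                 spikes_per_burst = as.integer(round(spikes_per_burst)),
                 participating_electrodes = as.integer(participating_electrodes),
                 background_rate = background_rate,
                 timing_jitter_s = timing_jitter_s, seed = seed),
            class = "synth_well_config")
}

.check_feasible <- function(cfg) {
  period <- 60 / cfg$burst_rate
  .assert(cfg$burst_duration_s < period,
          "infeasible config: burst duration %.3g s >= burst period %.3g s",
          cfg$burst_duration_s, period)
  invisible(period)
}

.generate_recording_impl <- function(cfg, condition, well_id) {
  period <- .check_feasible(cfg)
  dur <- cfg$duration_s
  # quasi-periodic onsets: Gamma inter-burst intervals, mean = period,
  # sd = timing_jitter_s
  jit <- max(cfg$timing_jitter_s, 1e-6)
  shape <- (period / jit)^2
  onsets <- numeric(0)
  t <- stats::runif(1, 0, period)
  while (t + cfg$burst_duration_s <= dur) {
    onsets <- c(onsets, t)
    t <- t + stats::rgamma(1, shape = shape, rate = shape / period)
  }
  part <- seq_len(cfg$participating_electrodes) - 1L
  el <- integer(0); tm <- numeric(0)
  for (on in onsets) {
    n <- cfg$spikes_per_burst
    tm <- c(tm, on + cfg$burst_duration_s * stats::rbeta(n, 2, 2))
    el <- c(el, sample(part, n, replace = TRUE))
  }
  for (e in 0:15) {
    nb <- stats::rpois(1, cfg$background_rate * dur)
    if (nb > 0) {
      tm <- c(tm, stats::runif(nb, 0, dur))
      el <- c(el, rep(e, nb))
    }
  }
  tm <- round(tm, 5)  # spike-table text resolution; keeps round trips exact
  trains <- lapply(0:15, function(e) {
    tt <- sort(tm[el == e])
    tt <- unique(tt)
    spike_train(e, tt, duration_s = dur)
  })
  rec <- well_recording(well_id, trains, condition, duration_s = dur)
  attr(rec, "truth") <- list(n_bursts = length(onsets), onsets = onsets,
                             peak_times = onsets + cfg$burst_duration_s / 2,
                             period_s = period,
                             burst_duration_s = cfg$burst_duration_s,
                             ibi_s = period - cfg$burst_duration_s,
                             spikes_per_burst = cfg$spikes_per_burst)
  rec
}

#' Generate one synthetic well epoch
#'
#' @param cfg A [synth_well_config()]; when `cfg$seed` is set the draw is
#'   seeded (and the global RNG stream is left untouched).
#' @param condition The epoch's [condition_label()] (default: a vehicle
#'   epoch of a compound named `"synthetic"`).
#' @param well_id Well identifier.
#' @return A [well_recording()] with a `"truth"` attribute carrying the
#'   generator ground truth (burst onsets, pooled-rate peak times, period,
#'   per-burst spike count).
#' @export
generate_vehicle_recording <- function(cfg,
                                       condition = vehicle_condition("synthetic"),
                                       well_id = "synth") {
  .assert(inherits(cfg, "synth_well_config"), "synth_well_config required")
  if (!is.null(cfg$seed))
    withr::with_seed(cfg$seed,
                     .generate_recording_impl(cfg, condition, well_id))
  else .generate_recording_impl(cfg, condition, well_id)
}

#' Concentration-dependent drug-effect model
#'
#' Each affected burst parameter follows a saturating monotone multiplier
#' curve `m(c) = 1 + (max_mult - 1) * c^h / (c^h + ec50^h)`: identity at
#' concentration 0, approaching `max_mult` (above or below 1) at saturating
#' concentration.
#'
#' @param mechanism Mechanism identifier (doubles as the synthetic compound
#'   name).
#' @param risk_class `"seizure-causing"` or `"seizure-free"`.
#' @param effects Named list over a subset of `burst_rate`,
#'   `burst_duration_s`, `spikes_per_burst`, `background_rate`; each entry
#'   a list with `max_mult`, `ec50`, `hill`.
#' @return An object of class `drug_effect_model`.
#' @export
drug_effect_model <- function(mechanism, risk_class, effects = list()) {
  ok <- c("burst_rate", "burst_duration_s", "spikes_per_burst",
          "background_rate")
  .assert(all(names(effects) %in% ok), "effects must be among: %s",
          paste(ok, collapse = ", "))
  for (e in effects)
    .assert(all(c("max_mult", "ec50", "hill") %in% names(e)) &&
              e$max_mult > 0 && e$ec50 > 0 && e$hill > 0,
            "each effect needs positive max_mult, ec50, hill")
  .assert(risk_class %in% c("seizure-causing", "seizure-free"),
          "risk_class must be seizure-causing or seizure-free")
  structure(list(mechanism = mechanism, risk_class = risk_class,
                 effects = effects),
            class = "drug_effect_model")
}

#' Multiplier curve of a drug-effect model at a concentration
#'
#' @param model A [drug_effect_model()].
#' @param concentration Concentration (same unit as the `ec50`s).
#' @return Named multiplier vector over the four modifiable parameters
#'   (1 for unaffected parameters).
#' @export
effect_multipliers <- function(model, concentration) {
  .assert(concentration >= 0, "concentration must be >= 0")
  out <- c(burst_rate = 1, burst_duration_s = 1, spikes_per_burst = 1,
           background_rate = 1)
  for (p in names(model$effects)) {
    e <- model$effects[[p]]
    frac <- concentration^e$hill / (concentration^e$hill + e$ec50^e$hill)
    out[p] <- 1 + (e$max_mult - 1) * frac
  }
  out
}

#' Apply a drug effect to a well configuration
#'
#' @param cfg A [synth_well_config()].
#' @param model A [drug_effect_model()].
#' @param concentration Concentration at which to evaluate the multipliers.
#' @return The scaled `synth_well_config`; errors when the scaled
#'   configuration is infeasible (burst duration reaching the burst period).
#' @export
apply_drug_effect <- function(cfg, model, concentration) {
  .assert(inherits(cfg, "synth_well_config"), "synth_well_config required")
  .assert(inherits(model, "drug_effect_model"), "drug_effect_model required")
  m <- effect_multipliers(model, concentration)
  out <- cfg
  out$burst_rate <- cfg$burst_rate * m[["burst_rate"]]
  out$burst_duration_s <- cfg$burst_duration_s * m[["burst_duration_s"]]
  out$spikes_per_burst <- max(1L, as.integer(round(
    cfg$spikes_per_burst * m[["spikes_per_burst"]])))
  out$background_rate <- cfg$background_rate * m[["background_rate"]]
  .check_feasible(out)
  out
}

#' Generate a cumulative-administration dose series for one well
#'
#' The vehicle epoch comes first, then one epoch per ascending
#' concentration. Per-well baseline variability (burst rate and burst size)
#' is drawn once per well, so wells of the same compound differ in their
#' baseline rhythm, as real wells do.
#'
#' @param cfg Baseline [synth_well_config()] (vehicle conditions).
#' @param model A [drug_effect_model()].
#' @param concentrations Strictly ascending concentration vector.
#' @param seed Well seed; every epoch derives its own child seed.
#' @param well_id Well identifier.
#' @return A [dose_series_recording()]; each epoch keeps its `"truth"`
#'   attribute.
#' @export
generate_dose_series <- function(cfg, model, concentrations, seed = 1,
                                 well_id = "synth") {
  .assert(length(concentrations) >= 1, "empty concentration list")
  .assert(!is.unsorted(concentrations, strictly = TRUE) &&
            all(concentrations > 0),
          "concentrations must be positive and strictly ascending")
  base <- cfg
  mult <- withr::with_seed(.child_seed(seed, 0),
                           stats::rlnorm(2, 0, c(0.15, 0.10)))
  base$burst_rate <- base$burst_rate * mult[1]
  base$spikes_per_burst <- max(1L, as.integer(round(base$spikes_per_burst *
                                                      mult[2])))
  base$seed <- .child_seed(seed, 1)
  epochs <- list(generate_vehicle_recording(
    base, vehicle_condition(model$mechanism, model$risk_class), well_id))
  for (i in seq_along(concentrations)) {
    ci <- apply_drug_effect(base, model, concentrations[i])
    ci$seed <- .child_seed(seed, i + 1)
    cond <- condition_label(model$mechanism, concentrations[i], "uM",
                            is_vehicle = FALSE,
                            risk_class = model$risk_class)
    epochs[[i + 1]] <- generate_vehicle_recording(ci, cond, well_id)
  }
  dose_series_recording(well_id, epochs)
}

.effect_mult_of <- function(size) {
  switch(size, small = 1.2, medium = 2, large = 3,
         stop("effect size must be small, medium or large"))
}

#' Library of reference synthetic mechanisms
#'
#' Five mechanisms emulating characteristic concentration-dependent burst
#' changes: `nob_up` (burst-rate increase, 4-AP-like), `nob_down_sib_up`
#' (fewer, larger bursts, theophylline-like), `ts_down` (overall firing
#' decrease, kainate-like), `dob_down` (burst shortening,
#' picrotoxin-like), and `null` (seizure-free; identical to vehicle apart
#' from the seed).
#'
#' @param effect_size `"small"`, `"medium"` or `"large"` -- maximal
#'   multipliers 1.2, 2 and 3 (reciprocal for decreasing parameters).
#' @param ec50 Half-max concentration of every curve (default 3).
#' @param hill Hill slope (default 2).
#' @return Named list of [drug_effect_model()]s.
#' @export
mechanism_library <- function(effect_size = c("large", "medium", "small"),
                              ec50 = 3, hill = 2) {
  M <- .effect_mult_of(match.arg(effect_size))
  up <- list(max_mult = M, ec50 = ec50, hill = hill)
  dn <- list(max_mult = 1 / M, ec50 = ec50, hill = hill)
  list(
    nob_up = drug_effect_model("nob_up", "seizure-causing",
                               list(burst_rate = up)),
    nob_down_sib_up = drug_effect_model("nob_down_sib_up", "seizure-causing",
                                        list(burst_rate = dn,
                                             spikes_per_burst = up)),
    ts_down = drug_effect_model("ts_down", "seizure-causing",
                                list(spikes_per_burst = dn,
                                     background_rate = dn)),
    dob_down = drug_effect_model("dob_down", "seizure-causing",
                                 list(burst_duration_s = dn)),
    null = drug_effect_model("null", "seizure-free", list()))
}

#' Risk-screening panel: four positive mechanisms and two negatives
#'
#' The four positive mechanisms of [mechanism_library()] plus two
#' independent seizure-free compounds (`negative_a`, `negative_b`) whose
#' epochs are distribution-identical to vehicle except for the seed.
#'
#' @inheritParams mechanism_library
#' @return Named list of [drug_effect_model()]s.
#' @export
risk_panel <- function(effect_size = c("large", "medium", "small"),
                       ec50 = 3, hill = 2) {
  lib <- mechanism_library(effect_size, ec50, hill)
  list(nob_up = lib$nob_up, nob_down_sib_up = lib$nob_down_sib_up,
       ts_down = lib$ts_down, dob_down = lib$dob_down,
       negative_a = drug_effect_model("negative_a", "seizure-free", list()),
       negative_b = drug_effect_model("negative_b", "seizure-free", list()))
}

#' Drug-identification panel: 13 distinct mechanisms plus one negative
#'
#' Thirteen seizure-causing mechanisms with distinct effect signatures
#' (combinations of burst-rate, burst-duration, burst-size and background
#' changes) and one seizure-free `negative` compound, mirroring a
#' 13-compound + pooled-negative 14-class identification task.
#'
#' @inheritParams mechanism_library
#' @return Named list of 14 [drug_effect_model()]s.
#' @export
drug_id_panel <- function(effect_size = c("large", "medium", "small"),
                          ec50 = 3, hill = 2) {
  M <- .effect_mult_of(match.arg(effect_size))
  up <- list(max_mult = M, ec50 = ec50, hill = hill)
  dn <- list(max_mult = 1 / M, ec50 = ec50, hill = hill)
  sig <- list(
    rate_up = list(burst_rate = up),
    rate_down = list(burst_rate = dn),
    sib_up = list(spikes_per_burst = up),
    sib_down = list(spikes_per_burst = dn),
    dur_up = list(burst_duration_s = up),
    dur_down = list(burst_duration_s = dn),
    bg_up = list(background_rate = up),
    rate_down_sib_up = list(burst_rate = dn, spikes_per_burst = up),
    rate_up_dur_down = list(burst_rate = up, burst_duration_s = dn),
    rate_up_sib_down = list(burst_rate = up, spikes_per_burst = dn),
    rate_down_dur_up = list(burst_rate = dn, burst_duration_s = up),
    rate_up_bg_up = list(burst_rate = up, background_rate = up),
    dur_down_sib_up = list(burst_duration_s = dn, spikes_per_burst = up))
  panel <- lapply(names(sig), function(nm)
    drug_effect_model(nm, "seizure-causing", sig[[nm]]))
  names(panel) <- names(sig)
  panel$negative <- drug_effect_model("negative", "seizure-free", list())
  panel
}

#' Generate a labeled multiwell dataset from a mechanism panel
#'
#' @param panel Named list of [drug_effect_model()]s (e.g. [risk_panel()] or
#'   [drug_id_panel()]).
#' @param wells_per_compound Wells per compound (default 3).
#' @param concentrations Concentration series shared by all compounds
#'   (default `c(1, 3, 10, 30)` micromolar).
#' @param base_cfg Baseline [synth_well_config()].
#' @param seed Panel seed; every well derives its own child seed.
#' @param dir Optional output directory; when given, the spike table
#'   (`spikes.tsv`), metadata sidecar (`metadata.yaml`) and per-epoch truth
#'   table (`truth.tsv`) are written there.
#' @return List with `series` (named list of [dose_series_recording()]s)
#'   and `truth` (data frame with one row per epoch: well, compound,
#'   concentration, vehicle flag, risk class, and generator ground truth
#'   `n_bursts_true`, `period_s_true`, `ibi_s_true`, `dob_s_true`,
#'   `sib_true`).
#' @export
generate_labeled_dataset <- function(panel, wells_per_compound = 3,
                                     concentrations = c(1, 3, 10, 30),
                                     base_cfg = synth_well_config(),
                                     seed = 1, dir = NULL) {
  .assert(length(panel) >= 1 &&
            all(vapply(panel, inherits, logical(1), "drug_effect_model")),
          "panel must be a list of drug_effect_model")
  series <- list()
  truth <- list()
  for (ci in seq_along(panel)) {
    model <- panel[[ci]]
    for (wj in seq_len(wells_per_compound)) {
      wid <- sprintf("%s_w%02d", model$mechanism, wj)
      s <- generate_dose_series(base_cfg, model, concentrations,
                                seed = .child_seed(seed, ci * 101, wj),
                                well_id = wid)
      series[[wid]] <- s
      truth[[wid]] <- do.call(rbind, lapply(s$epochs, function(e) {
        tr <- attr(e, "truth")
        data.frame(well = wid, compound = model$mechanism,
                   concentration = e$condition$concentration,
                   unit = e$condition$unit,
                   is_vehicle = e$condition$is_vehicle,
                   risk_class = model$risk_class,
                   n_bursts_true = tr$n_bursts, period_s_true = tr$period_s,
                   ibi_s_true = tr$ibi_s, dob_s_true = tr$burst_duration_s,
                   sib_true = tr$spikes_per_burst)
      }))
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_spike_table(series, file.path(dir, "spikes.tsv"),
                      file.path(dir, "metadata.yaml"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  list(series = series, truth = truth)
}
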