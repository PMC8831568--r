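# Data model for multiwell MEA recordings and the plain-text spike-table
# format. A recording is one well of a 24-well MEA plate: 16 extracellular
# electrodes, 600 s of spike times per concentration epoch. Compounds are
# administered cumulatively, so a well yields an ordered dose series:
# vehicle (0.1% DMSO) first, then strictly ascending concentrations.

#' Spike train of a single electrode
#'
#' @param electrode_index Integer electrode index, 0-15.
#' @param times Numeric spike times in seconds, strictly ascending,
#'   0-based from the start of the epoch.
#' @param duration_s Epoch duration in seconds; all times must lie in
#'   `[0, duration_s]`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(electrode_index, times = numeric(), duration_s = 600) {
  electrode_index <- as.integer(electrode_index)
  .assert(length(electrode_index) == 1 && electrode_index >= 0 &&
            electrode_index <= 15,
          "electrode_index must be a single integer in 0..15, got %s",
          paste(electrode_index, collapse = ","))
  times <- as.numeric(times)
  .assert(all(is.finite(times)), "spike times must be finite")
  .assert(!is.unsorted(times, strictly = TRUE),
          "spike times of electrode %d must be strictly ascending",
          electrode_index)
  .assert(length(times) == 0 || (times[1] >= 0 && times[length(times)] <= duration_s),
          "spike times of electrode %d outside [0, %g]",
          electrode_index, duration_s)
  structure(list(electrode_index = electrode_index, times = times),
            class = "spike_train")
}

#' Condition label of one concentration epoch
#'
#' @param compound Compound name.
#' @param concentration Concentration magnitude (in `unit`).
#' @param unit Concentration unit, `"uM"` or `"%v/v"` (the DMSO vehicle is
#'   dosed as 0.1% v/v).
#' @param is_vehicle `TRUE` for the pre-drug vehicle-control epoch.
#' @param risk_class One of `"seizure-causing"`, `"seizure-free"`,
#'   `"unknown"`.
#' @return An object of class `condition_label`.
#' @export
condition_label <- function(compound, concentration, unit = "uM",
                            is_vehicle = FALSE, risk_class = "unknown") {
  .assert(is.character(compound) && nzchar(compound), "compound name required")
  .assert(unit %in% c("uM", "%v/v"), "unit must be 'uM' or '%%v/v'")
  .assert(risk_class %in% c("seizure-causing", "seizure-free", "unknown"),
          "invalid risk_class '%s'", risk_class)
  concentration <- as.numeric(concentration)
  .assert(is.finite(concentration) && concentration >= 0,
          "concentration must be a non-negative number")
  structure(list(compound = compound, concentration = concentration,
                 unit = unit, is_vehicle = isTRUE(is_vehicle),
                 risk_class = risk_class),
            class = "condition_label")
}

#' Vehicle-control condition (0.1% DMSO) for a compound's well
#' @param compound Compound administered later in the same well.
#' @param risk_class Risk class of that compound.
#' @return A `condition_label` with `is_vehicle = TRUE`.
#' @export
vehicle_condition <- function(compound, risk_class = "unknown") {
  condition_label(compound, 0.1, "%v/v", is_vehicle = TRUE,
                  risk_class = risk_class)
}

#' One well for one concentration epoch
#'
#' @param well_id Well identifier string.
#' @param spike_trains List of exactly 16 [spike_train()] objects, one per
#'   electrode 0-15 (in order).
#' @param condition A [condition_label()].
#' @param duration_s Epoch duration in seconds (default 600, i.e. the
#'   10-minute recording per concentration).
#' @return An object of class `well_recording`.
#' @export
well_recording <- function(well_id, spike_trains, condition, duration_s = 600) {
  .assert(length(spike_trains) == 16, "well %s: expected 16 spike trains, got %d",
          well_id, length(spike_trains))
  idx <- vapply(spike_trains, function(s) s$electrode_index, integer(1))
  .assert(identical(idx, 0:15),
          "well %s: spike trains must cover electrodes 0..15 in order", well_id)
  .assert(inherits(condition, "condition_label"), "condition_label required")
  ok <- vapply(spike_trains, function(s)
    length(s$times) == 0 || max(s$times) <= duration_s, logical(1))
  .assert(all(ok), "well %s: spike times exceed duration %g s", well_id, duration_s)
  structure(list(well_id = well_id, duration_s = as.numeric(duration_s),
                 spike_trains = spike_trains, condition = condition),
            class = "well_recording")
}

#' Cumulative-administration dose series of one well
#'
#' Ordered epochs of a single well: the vehicle epoch first, then one epoch
#' per strictly ascending concentration of one compound.
#'
#' @param well_id Well identifier.
#' @param epochs List of [well_recording()]s in administration order.
#' @return An object of class `dose_series_recording`.
#' @export
dose_series_recording <- function(well_id, epochs) {
  .assert(length(epochs) >= 1, "well %s: at least one epoch required", well_id)
  .assert(all(vapply(epochs, inherits, logical(1), "well_recording")),
          "epochs must be well_recording objects")
  .assert(epochs[[1]]$condition$is_vehicle,
          "well %s: first epoch must be the vehicle epoch", well_id)
  .assert(!any(vapply(epochs[-1], function(e) e$condition$is_vehicle, logical(1))),
          "well %s: only the first epoch may be the vehicle epoch", well_id)
  comp <- unique(vapply(epochs, function(e) e$condition$compound, character(1)))
  .assert(length(comp) == 1, "well %s: epochs mix compounds: %s", well_id,
          paste(comp, collapse = ", "))
  if (length(epochs) > 2) {
    conc <- vapply(epochs[-1], function(e) e$condition$concentration, numeric(1))
    .assert(!is.unsorted(conc, strictly = TRUE),
            "well %s: non-monotone epoch boundaries (concentrations must be strictly ascending)",
            well_id)
  }
  structure(list(well_id = well_id, epochs = epochs),
            class = "dose_series_recording")
}

#' Raw voltage trace of one electrode
#'
#' @param electrode_index Electrode index 0-15.
#' @param samples Numeric voltage samples.
#' @param sampling_rate Sampling rate in Hz (default 20000).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(electrode_index, samples, sampling_rate = 20000) {
  .assert(sampling_rate > 0, "sampling_rate must be positive")
  structure(list(electrode_index = as.integer(electrode_index),
                 samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "raw_trace")
}

.total_spikes <- function(rec) {
  sum(vapply(rec$spike_trains, function(s) length(s$times), integer(1)))
}

# pooled (electrode, time) table of one recording, sorted by time
.pool_spikes <- function(rec) {
  el <- rep(0:15, vapply(rec$spike_trains, function(s) length(s$times), integer(1)))
  tm <- unlist(lapply(rec$spike_trains, function(s) s$times), use.names = FALSE)
  if (length(tm) == 0)
    return(data.frame(electrode = integer(), time = numeric()))
  o <- order(tm, el)
  data.frame(electrode = el[o], time = tm[o])
}

# ---------------------------------------------------------------------------
# Spike-table format: one delimited text file for all wells with columns
# (well, epoch, electrode, time_s); epoch is the 1-based position in that
# well's administration order. Conditions and durations live in a YAML
# metadata sidecar. Times are printed at 1e-5 s resolution so a
# write -> read -> write cycle is byte-identical.

.fmt_time <- function(t) sprintf("%.5f", t)

#' Write dose-series recordings to a spike table plus metadata sidecar
#'
#' @param series A `dose_series_recording` or a list of them.
#' @param path Path of the delimited spike table (TSV with header
#'   `well  epoch  electrode  time_s`).
#' @param metadata_path Path of the YAML metadata sidecar.
#' @return Invisibly, `c(path, metadata_path)`.
#' @export
write_spike_table <- function(series, path, metadata_path) {
  if (inherits(series, "dose_series_recording")) series <- list(series)
  .assert(length(series) >= 1 &&
            all(vapply(series, inherits, logical(1), "dose_series_recording")),
          "series must be dose_series_recording objects")
  names(series) <- vapply(series, function(s) s$well_id, character(1))

  lines <- character(0)
  meta <- list(wells = list())
  for (s in series) {
    first <- s$epochs[[1]]$condition
    eps <- lapply(seq_along(s$epochs), function(i) {
      e <- s$epochs[[i]]
      list(concentration = e$condition$concentration,
           unit = e$condition$unit,
           vehicle = e$condition$is_vehicle,
           duration_s = e$duration_s)
    })
    meta$wells[[s$well_id]] <- list(compound = first$compound,
                                    risk_class = first$risk_class,
                                    epochs = eps)
    for (i in seq_along(s$epochs)) {
      p <- .pool_spikes(s$epochs[[i]])
      if (nrow(p))
        lines <- c(lines, sprintf("%s\t%d\t%d\t%s", s$well_id, i,
                                  p$electrode, .fmt_time(p$time)))
    }
  }
  writeLines(c("well\tepoch\telectrode\ttime_s", lines), path)
  yaml::write_yaml(meta, metadata_path, precision = 12)
  invisible(c(path, metadata_path))
}

#' Read a spike table plus metadata sidecar
#'
#' @param path Spike-table path (see [write_spike_table()] for the format).
#' @param metadata_path YAML metadata sidecar path.
#' @return Named list of `dose_series_recording`, one per well.
#' @export
read_spike_table <- function(path, metadata_path) {
  meta <- yaml::read_yaml(metadata_path)
  .assert(is.list(meta$wells) && length(meta$wells) >= 1,
          "metadata declares no wells")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
  .assert(identical(names(tab), c("well", "epoch", "electrode", "time_s")),
          "spike table must have columns well, epoch, electrode, time_s")
  unknown <- setdiff(unique(tab$well), names(meta$wells))
  .assert(length(unknown) == 0, "spike table references unknown well(s): %s",
          paste(unknown, collapse = ", "))
  .assert(all(tab$electrode >= 0 & tab$electrode <= 15),
          "electrode indices outside 0..15")

  out <- list()
  for (w in names(meta$wells)) {
    m <- meta$wells[[w]]
    .assert(length(m$epochs) >= 1, "well %s: metadata declares no epochs", w)
    veh <- vapply(m$epochs, function(e) isTRUE(e$vehicle), logical(1))
    .assert(veh[1] && !any(veh[-1]),
            "well %s: metadata must declare the vehicle epoch first (and only first)", w)
    rows <- tab[tab$well == w, , drop = FALSE]
    .assert(all(rows$epoch >= 1 & rows$epoch <= length(m$epochs)),
            "well %s: spike rows reference undeclared epochs", w)
    epochs <- lapply(seq_along(m$epochs), function(i) {
      e <- m$epochs[[i]]
      cond <- condition_label(m$compound, e$concentration, e$unit,
                              is_vehicle = isTRUE(e$vehicle),
                              risk_class = m$risk_class %||% "unknown")
      er <- rows[rows$epoch == i, , drop = FALSE]
      trains <- lapply(0:15, function(el) {
        tt <- sort(er$time_s[er$electrode == el])
        spike_train(el, tt, duration_s = e$duration_s)
      })
      well_recording(w, trains, cond, duration_s = e$duration_s)
    })
    out[[w]] <- dose_series_recording(w, epochs)
  }
  out
}
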