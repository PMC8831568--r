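# Network-burst detection and the five burst parameters: TS (total spikes),
# NoB (number of network bursts), IBI (inter-network-burst interval), DoB
# (duration of a network burst), SiB (spikes in a network burst); plus the
# percent-of-control dose-response analysis with one-way ANOVA followed by
# Dunnett's test against the vehicle control.

#' Network-burst detector configuration
#'
#' The detector is a four-step pooled-ISI method: (1) pool the spikes of all
#' 16 electrodes into one sorted train; (2) candidate bursts are maximal
#' runs of pooled inter-spike intervals `<= isi_th_s`; (3) candidates
#' separated by a gap `< merge_gap_s` are merged; (4) candidates with fewer
#' than `min_spikes` spikes or fewer than `min_electrodes` participating
#' electrodes are discarded.
#'
#' @param isi_th_s Pooled inter-spike-interval threshold in seconds
#'   (default 0.1). With `adaptive_isi = TRUE` the threshold is instead
#'   placed at the trough of the pooled log-ISI histogram when that
#'   histogram is bimodal.
#' @param merge_gap_s Merge gap in seconds (default 0.1).
#' @param min_spikes Minimum spikes per burst (default 50).
#' @param min_electrodes Minimum participating electrodes (default 4).
#' @param rate_bin_s Bin width (s) of the pooled firing-rate histogram used
#'   to locate a burst's peak-rate time (default 0.01).
#' @param adaptive_isi Use the log-ISI-histogram trough as the ISI threshold.
#' @param ibi_mode IBI convention: `"end_to_onset"` (default; gap from a
#'   burst's end to the next burst's onset) or `"onset_to_onset"`.
#' @return An object of class `burst_config`.
#' @export
burst_config <- function(isi_th_s = 0.1, merge_gap_s = 0.1, min_spikes = 50,
                         min_electrodes = 4, rate_bin_s = 0.01,
                         adaptive_isi = FALSE,
                         ibi_mode = c("end_to_onset", "onset_to_onset")) {
  .assert(isi_th_s > 0 && merge_gap_s >= 0 && rate_bin_s > 0,
          "thresholds must be positive")
  .assert(min_spikes >= 1 && min_electrodes >= 1 && min_electrodes <= 16,
          "min_spikes >= 1 and 1 <= min_electrodes <= 16 required")
  structure(list(isi_th_s = isi_th_s, merge_gap_s = merge_gap_s,
                 min_spikes = as.integer(min_spikes),
                 min_electrodes = as.integer(min_electrodes),
                 rate_bin_s = rate_bin_s, adaptive_isi = isTRUE(adaptive_isi),
                 ibi_mode = match.arg(ibi_mode)),
            class = "burst_config")
}

# trough of the log10-ISI histogram between its two largest modes; falls
# back to the fixed default when the histogram is not clearly bimodal
.adaptive_isi_threshold <- function(isi, default) {
  isi <- isi[isi > 0]
  if (length(isi) < 100) return(default)
  d <- stats::density(log10(isi), n = 256)
  y <- d$y
  loc_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(loc_max) < 2) return(default)
  top2 <- sort(loc_max[order(y[loc_max], decreasing = TRUE)][1:2])
  seg <- top2[1]:top2[2]
  10^d$x[seg[which.min(y[seg])]]
}

#' Detect network bursts in one well recording
#'
#' @param rec A [well_recording()].
#' @param cfg A [burst_config()].
#' @return A data frame of class `network_burst_list` with one row per burst
#'   and columns `t_start`, `t_end`, `spike_count`, `n_electrodes`,
#'   `peak_rate_time` (time of maximum pooled firing rate within the burst,
#'   ties broken toward the earliest bin). Bursts are non-overlapping and
#'   time-ordered; the list may be empty.
#' @export
detect_network_bursts <- function(rec, cfg = burst_config()) {
  .assert(inherits(rec, "well_recording"), "well_recording required")
  .assert(inherits(cfg, "burst_config"), "burst_config required")
  empty <- data.frame(t_start = numeric(), t_end = numeric(),
                      spike_count = integer(), n_electrodes = integer(),
                      peak_rate_time = numeric())
  class(empty) <- c("network_burst_list", "data.frame")
  pool <- .pool_spikes(rec)
  n <- nrow(pool)
  if (n == 0) return(empty)

  isi_th <- cfg$isi_th_s
  if (cfg$adaptive_isi && n >= 2)
    isi_th <- .adaptive_isi_threshold(diff(pool$time), cfg$isi_th_s)

  # step 2: candidate = maximal run of pooled ISIs <= threshold
  starts <- which(c(TRUE, diff(pool$time) > isi_th))
  ends <- c(starts[-1] - 1L, n)

  # step 3: merge candidates separated by less than merge_gap_s
  if (length(starts) > 1) {
    gap <- pool$time[starts[-1]] - pool$time[ends[-length(ends)]]
    keep_new <- c(TRUE, gap >= cfg$merge_gap_s)
    starts <- starts[keep_new]
    ends <- ends[c(keep_new[-1], TRUE)]
  }

  # step 4: size and participation filters
  bursts <- lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    cnt <- length(idx)
    nel <- length(unique(pool$electrode[idx]))
    if (cnt < cfg$min_spikes || nel < cfg$min_electrodes) return(NULL)
    t0 <- pool$time[starts[i]]
    t1 <- pool$time[ends[i]]
    tt <- pool$time[idx]
    nb <- max(1L, ceiling((t1 - t0) / cfg$rate_bin_s))
    bin <- pmin(nb, floor((tt - t0) / cfg$rate_bin_s) + 1L)
    counts <- tabulate(bin, nb)
    pb <- which.max(counts)  # which.max = earliest maximal bin
    peak <- min(max(t0 + (pb - 0.5) * cfg$rate_bin_s, t0), t1)
    data.frame(t_start = t0, t_end = t1, spike_count = cnt,
               n_electrodes = nel, peak_rate_time = peak)
  })
  bursts <- bursts[!vapply(bursts, is.null, logical(1))]
  if (length(bursts) == 0) return(empty)
  out <- do.call(rbind, bursts)
  rownames(out) <- NULL
  class(out) <- c("network_burst_list", "data.frame")
  out
}

#' Compute the five burst parameters of one epoch
#'
#' @param rec The [well_recording()] the bursts were detected in.
#' @param bursts Output of [detect_network_bursts()] on `rec`.
#' @param ibi_mode IBI convention (see [burst_config()]).
#' @return An object of class `burst_parameter_set`: a list with `TS`,
#'   `NoB`, `IBI`, `DoB`, `SiB`. Parameters undefined at low burst counts
#'   (IBI needs 2 bursts; DoB and SiB need 1) are `NA`.
#' @export
compute_burst_parameters <- function(rec, bursts,
                                     ibi_mode = c("end_to_onset",
                                                  "onset_to_onset")) {
  .assert(inherits(rec, "well_recording"), "well_recording required")
  ibi_mode <- match.arg(ibi_mode)
  nb <- nrow(bursts)
  ibi <- NA_real_
  if (nb >= 2) {
    ibi <- if (ibi_mode == "end_to_onset")
      mean(bursts$t_start[-1] - bursts$t_end[-nb])
    else mean(diff(bursts$t_start))
  }
  structure(list(TS = .total_spikes(rec),
                 NoB = nb,
                 IBI = ibi,
                 DoB = if (nb >= 1) mean(bursts$t_end - bursts$t_start) else NA_real_,
                 SiB = if (nb >= 1) mean(bursts$spike_count) else NA_real_,
                 well_id = rec$well_id),
            class = "burst_parameter_set")
}

#' Percent-of-control burst parameters
#'
#' Expresses a drug epoch's burst parameters as a percentage of the same
#' well's vehicle-control epoch (vehicle = 100%).
#'
#' @param drug,vehicle [compute_burst_parameters()] results from the same
#'   well.
#' @return Named numeric vector (`TS`, `NoB`, `IBI`, `DoB`, `SiB`) of
#'   percentages; `NA` (with a warning) where the vehicle parameter is 0 or
#'   missing.
#' @export
percent_of_control <- function(drug, vehicle) {
  .assert(inherits(drug, "burst_parameter_set") &&
            inherits(vehicle, "burst_parameter_set"),
          "burst_parameter_set inputs required")
  .assert(identical(drug$well_id, vehicle$well_id),
          "drug and vehicle parameter sets come from different wells (%s vs %s)",
          drug$well_id, vehicle$well_id)
  par_names <- c("TS", "NoB", "IBI", "DoB", "SiB")
  num <- unlist(drug[par_names])
  den <- unlist(vehicle[par_names])
  bad <- is.na(den) | den == 0
  if (any(bad & !is.na(num)))
    warning(sprintf("well %s: vehicle %s is 0 or undefined; %% of control is NA",
                    drug$well_id,
                    paste(par_names[bad & !is.na(num)], collapse = ", ")))
  out <- 100 * num / den
  out[bad] <- NA_real_
  out
}

#' Dose-response table of percent-of-control values
#'
#' @param pct Long data frame with columns `compound`, `concentration`,
#'   `parameter`, `well`, `value` (percent of control per well).
#' @return Data frame with per compound x concentration x parameter the mean
#'   percent of control, `sem` (sd / sqrt(n); 0 when `n = 1`), and `n`
#'   wells. Missing per-well values are excluded (their count is reported in
#'   `n_missing`).
#' @export
dose_response_table <- function(pct) {
  .assert(all(c("compound", "concentration", "parameter", "well", "value")
              %in% names(pct)), "missing columns in pct")
  key <- interaction(pct$compound, pct$concentration, pct$parameter,
                     drop = TRUE)
  rows <- lapply(split(pct, key), function(g) {
    v <- g$value
    miss <- sum(is.na(v))
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(compound = g$compound[1], concentration = g$concentration[1],
               parameter = g$parameter[1],
               mean = if (n) mean(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else if (n == 1) 0 else NA_real_,
               n = n, n_missing = miss)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound, out$parameter, out$concentration), ]
  rownames(out) <- NULL
  out
}

#' Dunnett comparisons of each concentration against vehicle
#'
#' One-way ANOVA followed by Dunnett's test: each concentration group of one
#' compound x parameter family is compared against the vehicle group with
#' family-wise adjusted two-sided p values (multivariate-t machinery of
#' \pkg{multcomp}). Dunnett flags are gatekept on the omnibus ANOVA:
#' significance is only declared when the ANOVA p value is below `alpha`.
#'
#' @param values Numeric observations (e.g. percent-of-control per well).
#' @param groups Grouping vector the same length as `values`; coerced to a
#'   factor whose levels order the output.
#' @param vehicle_level The level of `groups` that is the vehicle control.
#' @param alpha Gatekeeping/flagging level for `sig_05` (default 0.05); the
#'   stricter flag `sig_01` uses 0.01.
#' @return Data frame with one row per non-vehicle group: `group`,
#'   `p_adjusted`, `p_omnibus`, `sig_05`, `sig_01` (with
#'   `sig_01 => sig_05`). Degenerate input with zero variance everywhere
#'   yields `p_adjusted = 1` with a warning.
#' @export
dunnett_vs_vehicle <- function(values, groups, vehicle_level, alpha = 0.05) {
  groups <- as.factor(groups)
  .assert(vehicle_level %in% levels(groups),
          "vehicle level '%s' not found in groups", vehicle_level)
  groups <- stats::relevel(groups, ref = vehicle_level)
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  cnt <- table(groups)
  .assert(all(cnt >= 2), "each group needs >= 2 observations (got: %s)",
          paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))
  treat <- levels(groups)[-1]
  wvar <- tapply(values, groups, stats::var)
  if (all(wvar == 0, na.rm = TRUE)) {
    warning("zero within-group variance everywhere: returning p = 1")
    return(data.frame(group = treat, p_adjusted = 1,
                      p_omnibus = 1, sig_05 = FALSE, sig_01 = FALSE))
  }
  d <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = d)
  p_omni <- summary(fit)[[1]][["Pr(>F)"]][1]
  # the multivariate-t tail probabilities are computed by randomized
  # quadrature; pin the stream so repeated calls agree
  gl <- withr::with_seed(1L, summary(multcomp::glht(
    fit, linfct = multcomp::mcp(g = "Dunnett"))))
  p_adj <- as.numeric(gl$test$pvalues)
  gate <- is.finite(p_omni) && p_omni < alpha
  data.frame(group = treat, p_adjusted = p_adj, p_omnibus = p_omni,
             sig_05 = gate & p_adj < alpha,
             sig_01 = gate & p_adj < 0.01)
}
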