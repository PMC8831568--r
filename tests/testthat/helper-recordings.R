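# shared fixtures and independent oracles

# well recording from a data frame of (electrode, time)
rec_from_df <- function(df, well_id = "A1", duration_s = 600,
                        condition = vehicle_condition("testdrug")) {
  trains <- lapply(0:15, function(e)
    spike_train(e, sort(df$time[df$electrode == e]), duration_s = duration_s))
  well_recording(well_id, trains, condition, duration_s = duration_s)
}

empty_rec <- function(well_id = "A1", duration_s = 600,
                      condition = vehicle_condition("testdrug")) {
  rec_from_df(data.frame(electrode = integer(), time = numeric()),
              well_id, duration_s, condition)
}

# independent brute-force pooled-ISI burst oracle: scans the pooled train
# spike by spike instead of using vectorized run arithmetic
oracle_bursts <- function(df, isi_th = 0.1, merge_gap = 0.1, min_spikes = 50,
                          min_electrodes = 4) {
  o <- order(df$time, df$electrode)
  tt <- df$time[o]; el <- df$electrode[o]
  n <- length(tt)
  if (n == 0) return(data.frame(t_start = numeric(), t_end = numeric(),
                                spike_count = integer(),
                                n_electrodes = integer()))
  # step 2: group spikes whenever the gap exceeds the ISI threshold
  grp <- integer(n); g <- 1L; grp[1] <- 1L
  for (i in 2:n) {
    if (tt[i] - tt[i - 1] > isi_th) g <- g + 1L
    grp[i] <- g
  }
  cand <- lapply(unique(grp), function(gg) which(grp == gg))
  # step 3: merge neighbours closer than the merge gap
  merged <- list(cand[[1]])
  if (length(cand) > 1) {
    for (i in 2:length(cand)) {
      prev <- merged[[length(merged)]]
      if (tt[cand[[i]][1]] - tt[prev[length(prev)]] < merge_gap)
        merged[[length(merged)]] <- c(prev, cand[[i]])
      else merged[[length(merged) + 1]] <- cand[[i]]
    }
  }
  # step 4: filters
  rows <- lapply(merged, function(idx) {
    if (length(idx) < min_spikes) return(NULL)
    if (length(unique(el[idx])) < min_electrodes) return(NULL)
    data.frame(t_start = tt[idx[1]], t_end = tt[idx[length(idx)]],
               spike_count = length(idx),
               n_electrodes = length(unique(el[idx])))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(data.frame(t_start = numeric(),
                                           t_end = numeric(),
                                           spike_count = integer(),
                                           n_electrodes = integer()))
  do.call(rbind, rows)
}

# pairwise-rank AUC oracle: concordant pairs plus half ties over P x N
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# dense-burst recording used by rasterization/feature tests: regular bursts
# so the vehicle epoch always yields > 2 detected network bursts
regular_burst_df <- function(n_bursts = 60, period = 10, dur_b = 0.4,
                             spikes = 80, electrodes = 0:11, t0 = 1) {
  do.call(rbind, lapply(seq_len(n_bursts) - 1, function(i) {
    tt <- t0 + i * period + seq(0, dur_b, length.out = spikes)
    data.frame(electrode = rep_len(electrodes, spikes), time = tt)
  }))
}
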