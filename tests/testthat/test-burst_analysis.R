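test_that("network-burst detection matches its construction on clustered input", {
  expect_equal(nrow(detect_network_bursts(empty_rec())), 0)

  # 3 clusters of 120 spikes over 12 electrodes within 0.5 s at 10/20/30 s
  mk_cluster <- function(t0) data.frame(
    electrode = rep_len(0:11, 120),
    time = t0 + seq(0, 0.5, length.out = 120))
  df <- rbind(mk_cluster(10), mk_cluster(20), mk_cluster(30))
  rec <- rec_from_df(df)
  b <- detect_network_bursts(rec)
  expect_equal(nrow(b), 3)
  expect_true(all(abs(b$t_start - c(10, 20, 30)) <= 0.01))
  expect_equal(b$spike_count, rep(120L, 3))
  expect_equal(b$n_electrodes, rep(12L, 3))
  expect_true(all(b$peak_rate_time >= b$t_start & b$peak_rate_time <= b$t_end))

  # two clusters separated by less than the merge gap fuse into one burst
  df2 <- rbind(mk_cluster(10), mk_cluster(10.55))  # gap 0.05 < 0.1
  b2 <- detect_network_bursts(rec_from_df(df2))
  expect_equal(nrow(b2), 1)
  expect_equal(b2$spike_count, 240L)

  # sub-threshold candidates (too few spikes / electrodes) are discarded
  few <- data.frame(electrode = rep_len(0:11, 20),
                    time = 5 + seq(0, 0.3, length.out = 20))
  expect_equal(nrow(detect_network_bursts(rec_from_df(few))), 0)
  narrow <- data.frame(electrode = rep_len(0:2, 120),
                       time = 5 + seq(0, 0.3, length.out = 120))
  expect_equal(nrow(detect_network_bursts(rec_from_df(narrow))), 0)
})

test_that("detector agrees exactly with the brute-force pooled-ISI oracle", {
  cfgs <- list(burst_config(),
               burst_config(isi_th_s = 0.05, merge_gap_s = 0.2,
                            min_spikes = 20, min_electrodes = 2))
  for (trial in 1:40) {
    df <- withr::with_seed(trial, {
      n <- sample(0:500, 1)
      data.frame(electrode = sample(0:15, n, TRUE),
                 time = round(sort(runif(n, 0, 60)), 5))
    })
    df <- df[!duplicated(df$time), , drop = FALSE]
    for (cfg in cfgs) {
      got <- detect_network_bursts(rec_from_df(df, duration_s = 60), cfg)
      want <- oracle_bursts(df, cfg$isi_th_s, cfg$merge_gap_s,
                            cfg$min_spikes, cfg$min_electrodes)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_equal(got$t_start, want$t_start)
        expect_equal(got$t_end, want$t_end)
        expect_equal(got$spike_count, want$spike_count)
        expect_equal(got$n_electrodes, want$n_electrodes)
      }
    }
  }
})

test_that("burst list is invariant under electrode relabeling", {
  df <- withr::with_seed(5, data.frame(
    electrode = sample(0:15, 400, TRUE),
    time = round(sort(c(runif(200, 10, 10.4), runif(200, 30, 30.4))), 5)))
  df <- df[!duplicated(df$time), ]
  perm <- withr::with_seed(6, sample(0:15))
  df2 <- transform(df, electrode = perm[electrode + 1])
  b1 <- detect_network_bursts(rec_from_df(df))
  b2 <- detect_network_bursts(rec_from_df(df2))
  expect_equal(b1[c("t_start", "t_end", "spike_count", "n_electrodes")],
               b2[c("t_start", "t_end", "spike_count", "n_electrodes")])
})

test_that("the five burst parameters follow their definitions", {
  p0 <- compute_burst_parameters(empty_rec(),
                                 detect_network_bursts(empty_rec()))
  expect_equal(p0$TS, 0)
  expect_equal(p0$NoB, 0)
  expect_true(is.na(p0$IBI) && is.na(p0$DoB) && is.na(p0$SiB))

  # 3 bursts (0,1), (10,11), (20,21) of 50 spikes + 10 out-of-burst spikes
  bursts <- data.frame(t_start = c(0, 10, 20), t_end = c(1, 11, 21),
                       spike_count = c(50L, 50L, 50L),
                       n_electrodes = 12L, peak_rate_time = c(0.5, 10.5, 20.5))
  df <- data.frame(electrode = rep_len(0:15, 160),
                   time = c(seq(0, 1, length.out = 50),
                            seq(10, 11, length.out = 50),
                            seq(20, 21, length.out = 50),
                            seq(40, 49, length.out = 10)))
  rec <- rec_from_df(df)
  p <- compute_burst_parameters(rec, bursts)
  expect_equal(p$TS, 160)
  expect_equal(p$NoB, 3)
  expect_equal(p$DoB, 1.0)
  expect_equal(p$SiB, 50)
  expect_equal(p$IBI, 9.0)  # end-to-next-onset convention
  expect_equal(compute_burst_parameters(rec, bursts,
                                        ibi_mode = "onset_to_onset")$IBI, 10)

  p1 <- compute_burst_parameters(rec, bursts[1, ])
  expect_equal(p1$NoB, 1)
  expect_true(is.na(p1$IBI))
  expect_false(is.na(p1$DoB))
})

test_that("percent of control handles identity, scaling and guards", {
  bursts <- function(n, rec) {
    b <- detect_network_bursts(rec)
    b
  }
  mk_pars <- function(NoB, well = "A1") {
    structure(list(TS = 1000, NoB = NoB, IBI = 5, DoB = 1, SiB = 100,
                   well_id = well), class = "burst_parameter_set")
  }
  expect_equal(unname(percent_of_control(mk_pars(10), mk_pars(10))),
               rep(100, 5))
  expect_equal(percent_of_control(mk_pars(32), mk_pars(10))[["NoB"]], 320)
  expect_warning(pc <- percent_of_control(mk_pars(5), mk_pars(0)), "NoB")
  expect_true(is.na(pc[["NoB"]]))
  expect_error(percent_of_control(mk_pars(1, "A1"), mk_pars(1, "B2")),
               "different wells")
})

test_that("dose-response table reports mean, SEM and well counts", {
  pct <- data.frame(compound = "d", concentration = 1, parameter = "NoB",
                    well = c("w1", "w2", "w3"), value = c(90, 100, 110))
  drt <- dose_response_table(pct)
  expect_equal(drt$mean, 100)
  expect_equal(drt$sem, 10 / sqrt(3), tolerance = 1e-12)
  expect_equal(drt$n, 3)

  same <- transform(pct, value = 100)
  expect_equal(dose_response_table(same)$sem, 0)

  single <- pct[1, ]
  drt1 <- dose_response_table(single)
  expect_equal(drt1$sem, 0)
  expect_equal(drt1$n, 1)
})

test_that("Dunnett comparisons gatekeep on the ANOVA and match the k=2 t-test", {
  # identical samples in every group: nothing significant
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("veh", "c1", "c2"), each = 3)
  res <- dunnett_vs_vehicle(v, g, "veh")
  expect_true(all(!res$sig_05))

  # k = 2 balanced: adjusted p reduces to the pooled two-sided t-test p
  set.seed(42)
  x <- rnorm(8); y <- rnorm(8) + 1.2
  res2 <- dunnett_vs_vehicle(c(x, y), rep(c("veh", "c1"), each = 8), "veh")
  p_t <- t.test(y, x, var.equal = TRUE)$p.value
  expect_lt(abs(res2$p_adjusted - p_t), 0.005)

  # strong separation (control N(0,1) vs N(5,1), n = 4) flags at 0.01
  set.seed(7)
  v3 <- c(rnorm(4), rnorm(4, 5))
  res3 <- dunnett_vs_vehicle(v3, rep(c("veh", "hi"), each = 4), "veh")
  expect_true(res3$sig_01)
  expect_true(res3$sig_05)  # flag(0.01) => flag(0.05)

  # degenerate zero-variance input
  expect_warning(res4 <- dunnett_vs_vehicle(rep(5, 6),
                                            rep(c("veh", "c1"), each = 3),
                                            "veh"), "zero")
  expect_equal(res4$p_adjusted, 1)

  expect_error(dunnett_vs_vehicle(1:4, c("veh", "veh", "c1", "c2"), "veh"),
               ">= 2 observations")
})

test_that("the adaptive ISI threshold lands in the log-ISI trough", {
  # bimodal ISI structure: 0.02-s within-burst intervals, 5-s gaps
  df <- regular_burst_df(n_bursts = 20, period = 5, dur_b = 0.4,
                         spikes = 120, t0 = 1)
  rec <- rec_from_df(df, duration_s = 120)
  b_adaptive <- detect_network_bursts(rec, burst_config(adaptive_isi = TRUE))
  b_fixed <- detect_network_bursts(rec, burst_config())
  expect_equal(nrow(b_adaptive), 20)
  expect_equal(b_adaptive$t_start, b_fixed$t_start)

  # too few intervals for a histogram: falls back to the configured default
  few <- rec_from_df(data.frame(electrode = 0:3, time = 1:4), duration_s = 10)
  expect_equal(nrow(detect_network_bursts(few,
                                          burst_config(adaptive_isi = TRUE))),
               0)
})
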