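test_that("the generator is seeded-deterministic and hits exact counts", {
  cfg <- synth_well_config(seed = 5)
  r1 <- generate_vehicle_recording(cfg)
  r2 <- generate_vehicle_recording(cfg)
  expect_identical(lapply(r1$spike_trains, `[[`, "times"),
                   lapply(r2$spike_trains, `[[`, "times"))

  # background 0, fixed spikes per burst -> TS is exactly bursts x spikes
  cfg0 <- synth_well_config(burst_rate = 6, spikes_per_burst = 100,
                            background_rate = 0, duration_s = 110, seed = 8)
  r0 <- generate_vehicle_recording(cfg0)
  truth <- attr(r0, "truth")
  expect_equal(sum(sapply(r0$spike_trains, function(s) length(s$times))),
               100 * truth$n_bursts)

  expect_error(generate_vehicle_recording(
    synth_well_config(burst_rate = 60, burst_duration_s = 2)), "infeasible")
})

test_that("burst detection recovers the configured rhythm from vehicle wells", {
  cfg <- synth_well_config(burst_rate = 6, seed = 42)
  rec <- generate_vehicle_recording(cfg)
  b <- detect_network_bursts(rec)
  expect_true(abs(nrow(b) - 60) <= 6)  # 60 bursts/10 min within 10%

  # parameter recovery at default noise across seeds
  for (sd_i in 1:3) {
    cfg_i <- synth_well_config(seed = 200 + sd_i)
    rec_i <- generate_vehicle_recording(cfg_i)
    tr <- attr(rec_i, "truth")
    b_i <- detect_network_bursts(rec_i)
    p <- compute_burst_parameters(rec_i, b_i)
    expect_lt(abs(p$NoB - tr$n_bursts) / tr$n_bursts, 0.10)
    expect_lt(abs(p$IBI - tr$ibi_s) / tr$ibi_s, 0.15)
    expect_lt(abs(p$DoB - tr$burst_duration_s) / tr$burst_duration_s, 0.15)
    expect_lt(abs(p$SiB - tr$spikes_per_burst) / tr$spikes_per_burst, 0.10)
  }
})

test_that("drug-effect multipliers are monotone, saturating and identity at 0", {
  lib <- mechanism_library("large")
  m <- lib$nob_up
  expect_equal(unname(effect_multipliers(m, 0)), rep(1, 4))
  cc <- c(0.3, 1, 3, 10, 30, 100)
  mult <- sapply(cc, function(c) effect_multipliers(m, c)[["burst_rate"]])
  expect_true(all(diff(mult) > 0))
  expect_equal(effect_multipliers(m, 1e9)[["burst_rate"]], 3, tolerance = 1e-6)
  expect_equal(effect_multipliers(m, 3)[["burst_rate"]], 2)  # half-max at ec50

  dn <- lib$dob_down
  md <- sapply(cc, function(c) effect_multipliers(dn, c)[["burst_duration_s"]])
  expect_true(all(diff(md) < 0))  # decreasing parameter, reciprocal multiplier

  cfg <- synth_well_config()
  cfg3 <- apply_drug_effect(cfg, m, 1e9)
  expect_equal(cfg3$burst_rate, cfg$burst_rate * 3, tolerance = 1e-5)
  expect_equal(apply_drug_effect(cfg, m, 0)$burst_rate, cfg$burst_rate)
  # infeasible after scaling: burst period shrinks below burst duration
  long <- synth_well_config(burst_rate = 25, burst_duration_s = 1.1)
  expect_error(apply_drug_effect(long, m, 1e9), "infeasible")
})

test_that("dose series carry vehicle first, labels and well variability", {
  cfg <- synth_well_config(duration_s = 120)
  m <- mechanism_library("large")$nob_up
  s <- generate_dose_series(cfg, m, c(1, 3, 10, 30, 100), seed = 3,
                            well_id = "W9")
  expect_length(s$epochs, 6)  # vehicle + 5 concentrations
  expect_true(s$epochs[[1]]$condition$is_vehicle)
  expect_equal(sapply(s$epochs[-1], function(e) e$condition$concentration),
               c(1, 3, 10, 30, 100))
  expect_true(all(sapply(s$epochs, function(e)
    e$condition$risk_class == "seizure-causing")))

  # different well seeds draw different baseline burst periods
  s2 <- generate_dose_series(cfg, m, c(1, 3), seed = 4, well_id = "Wx")
  s3 <- generate_dose_series(cfg, m, c(1, 3), seed = 5, well_id = "Wy")
  expect_false(isTRUE(all.equal(attr(s2$epochs[[1]], "truth")$period_s,
                                attr(s3$epochs[[1]], "truth")$period_s)))

  expect_error(generate_dose_series(cfg, m, numeric(), seed = 1), "empty")
  expect_error(generate_dose_series(cfg, m, c(3, 1), seed = 1), "ascending")
})

test_that("labeled datasets enumerate the panel and land on disk readably", {
  panel <- risk_panel("large")
  cfg <- synth_well_config(duration_s = 60, burst_rate = 12)
  dir <- withr::local_tempdir()
  dat <- generate_labeled_dataset(panel, wells_per_compound = 3,
                                  concentrations = c(3, 30),
                                  base_cfg = cfg, seed = 2, dir = dir)
  expect_length(dat$series, 6 * 3)  # 4 positive + 2 negative, 3 wells each
  expect_equal(nrow(dat$truth), 18 * 3)  # vehicle + 2 concentrations per well
  expect_setequal(unique(dat$truth$risk_class),
                  c("seizure-causing", "seizure-free"))

  back <- read_spike_table(file.path(dir, "spikes.tsv"),
                           file.path(dir, "metadata.yaml"))
  expect_length(back, 18)
  w <- names(dat$series)[1]
  expect_equal(lapply(back[[w]]$epochs[[1]]$spike_trains, `[[`, "times"),
               lapply(dat$series[[w]]$epochs[[1]]$spike_trains, `[[`, "times"))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})

test_that("the drug-id panel has 14 distinctly labeled mechanisms", {
  panel <- drug_id_panel("large")
  expect_length(panel, 14)
  expect_equal(sum(sapply(panel, function(m) m$risk_class == "seizure-free")),
               1)
  sigs <- sapply(panel, function(m)
    paste(sort(sprintf("%s%s", names(m$effects),
                       ifelse(sapply(m$effects, `[[`, "max_mult") > 1,
                              "+", "-"))), collapse = ","))
  expect_equal(anyDuplicated(sigs[sapply(panel, function(m)
    length(m$effects) > 0)]), 0)  # no two positives share a signed signature
})
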