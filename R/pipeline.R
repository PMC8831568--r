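# Orchestration of the full workflow: simulate (or load) -> burst analysis
# -> IMFI rasterization -> feature extraction -> classifier training ->
# risk / drug-ID prediction -> ROC evaluation -> report files. A single
# declarative config governs all stages; stage outputs are cached
# content-addressed, and every artifact is stamped with the config hash and
# seed.

#' Pipeline configuration
#'
#' @param simulate List describing the synthetic input: `panel` (`"risk"`,
#'   `"drug_id"`, or a list of [drug_effect_model()]s), `effect_size`,
#'   `wells_per_compound`, `concentrations`, and optionally `base_cfg` (a
#'   [synth_well_config()]). Ignored when `input` is given.
#' @param input Optional list with `spike_table` and `metadata` paths of a
#'   recorded dataset (see [read_spike_table()]).
#' @param seed Master seed for simulation, splits and training.
#' @param burst A [burst_config()].
#' @param render A [render_config()].
#' @param extractor An [extractor_spec()]; the default uses the rectified
#'   fixture backend, mirroring the rectified activations of the reference
#'   fc7 layer.
#' @param normalize_method Vehicle-normalization variant (`"zscore"` by
#'   default in the pipeline: per-well standardization makes wells with
#'   different baseline variability comparable).
#' @param risk_spec [pattern_net_spec()] of the risk network.
#' @param risk_replicates Replicate risk networks trained with distinct
#'   seeds whose window probabilities are averaged (default 5, mirroring
#'   the replicate-model design of the drug-identification task).
#' @param drugid Run the drug-identification task too? (`FALSE`,
#'   `"holdout"` or `"loo"`.)
#' @param drugid_replicates Replicate models per held-out well for the
#'   `"loo"` scheme (default 5).
#' @param test_wells Wells to hold out; `"auto"` holds out the last well of
#'   each compound.
#' @param training_concentration_min Lowest concentration of
#'   seizure-causing compounds labeled positive / with its own drug class
#'   during training; lower concentrations are predicted but not trained on
#'   (default 3, the half-max concentration of the synthetic mechanism
#'   curves: designated training concentrations are those at and above the
#'   half-max response, and lower concentrations are judged as unlearned
#'   data).
#' @param aggregation Risk aggregation mode (see [aggregate_risk()]).
#' @param costs Named misclassification costs `fp`, `tn`, `fn`, `tp` for
#'   the operating point.
#' @param f_variant F-measure variant (see [classification_metrics()]).
#' @param out_dir Report directory (`NULL`: no files written).
#' @param cache_dir Stage-cache directory (`NULL`: no caching).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(panel = "risk",
                                            effect_size = "large",
                                            wells_per_compound = 3,
                                            concentrations = c(1, 3, 10, 30)),
                            input = NULL, seed = 1,
                            burst = burst_config(),
                            render = render_config(),
                            extractor = extractor_spec(rectify = TRUE),
                            normalize_method = "zscore",
                            risk_spec = risk_net_spec(),
                            risk_replicates = 5,
                            drugid = FALSE, drugid_replicates = 5,
                            test_wells = "auto",
                            training_concentration_min = 3,
                            aggregation = "proportion",
                            costs = c(fp = 1, tn = 0, fn = 1, tp = 0),
                            f_variant = "standard_f1",
                            out_dir = NULL, cache_dir = NULL) {
  structure(list(simulate = simulate, input = input, seed = seed,
                 burst = burst, render = render, extractor = extractor,
                 normalize_method = normalize_method,
                 risk_spec = risk_spec, risk_replicates = risk_replicates,
                 drugid = drugid,
                 drugid_replicates = drugid_replicates,
                 test_wells = test_wells,
                 training_concentration_min = training_concentration_min,
                 aggregation = aggregation, costs = costs,
                 f_variant = f_variant, out_dir = out_dir,
                 cache_dir = cache_dir),
            class = "pipeline_config")
}

.cache_fetch <- function(cache_dir, key, compute) {
  if (is.null(cache_dir)) {
    out <- compute()
    attr(out, "cache_hit") <- FALSE
    return(out)
  }
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) {
    out <- readRDS(f)
    attr(out, "cache_hit") <- TRUE
    return(out)
  }
  out <- compute()
  saveRDS(out, f)
  attr(out, "cache_hit") <- FALSE
  out
}

.auto_test_wells <- function(series) {
  comp <- vapply(series, function(s) s$epochs[[1]]$condition$compound,
                 character(1))
  unlist(lapply(split(names(series), comp), function(w) w[length(w)]),
         use.names = FALSE)
}

.resolve_panel <- function(sim) {
  if (is.character(sim$panel)) {
    switch(sim$panel,
           risk = risk_panel(sim$effect_size %||% "large"),
           drug_id = drug_id_panel(sim$effect_size %||% "large"),
           stop("unknown panel '", sim$panel, "'"))
  } else sim$panel
}

# window-level risk truth: TRUE = positive, FALSE = negative, NA = a
# seizure-causing compound's epoch below the training concentration
.risk_truth <- function(meta, conc_min) {
  pos <- meta$risk_class == "seizure-causing" & !meta$is_vehicle
  lab <- rep(NA, nrow(meta))
  lab[meta$is_vehicle | meta$risk_class == "seizure-free"] <- FALSE
  lab[pos & meta$concentration >= conc_min] <- TRUE
  lab
}

#' Run the full raster-plot machine-learning pipeline
#'
#' Stages: data (simulate or load, with validation before any training),
#' burst analysis (five parameters, percent-of-control dose-response table,
#' Dunnett tests), rasterization + feature extraction + vehicle
#' normalization, risk-network holdout training with well/concentration
#' aggregation, ROC evaluation at the cost-slope operating point, and
#' optionally drug identification. Deterministic given the config; report
#' files are stamped with the config hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_report` with elements `config_hash`,
#'   `dose_response`, `dunnett`, `dataset` (the [build_window_dataset()]),
#'   `risk` (model, predictions, ROC, operating point, metrics), and
#'   `drug_id` (when enabled).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  .assert(inherits(config, "pipeline_config"), "pipeline_config required")
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_hash <- .object_digest(config[setdiff(names(config),
                                            c("out_dir", "cache_dir"))])
  say("pipeline config %s (seed %d)", cfg_hash, config$seed)
  say("burst config: isi_th=%g merge_gap=%g min_spikes=%d min_electrodes=%d",
      config$burst$isi_th_s, config$burst$merge_gap_s,
      config$burst$min_spikes, config$burst$min_electrodes)

  # --- stage: data -----------------------------------------------------
  data_key <- paste0("data_", .object_digest(list(config$simulate,
                                                  config$input, config$seed)))
  dat <- .cache_fetch(config$cache_dir, data_key, function() {
    if (!is.null(config$input)) {
      series <- read_spike_table(config$input$spike_table,
                                 config$input$metadata)
      list(series = series, truth = NULL)
    } else {
      panel <- .resolve_panel(config$simulate)
      generate_labeled_dataset(
        panel,
        wells_per_compound = config$simulate$wells_per_compound %||% 3,
        concentrations = config$simulate$concentrations %||% c(1, 3, 10, 30),
        base_cfg = config$simulate$base_cfg %||% synth_well_config(),
        seed = config$seed)
    }
  })
  series <- dat$series
  say("data: %d wells (%s)", length(series),
      if (attr(dat, "cache_hit")) "cached" else "computed")

  # --- stage: burst analysis -------------------------------------------
  burst_key <- paste0("burst_", .object_digest(list(data_key, config$burst)))
  ba <- .cache_fetch(config$cache_dir, burst_key, function() {
    pct <- list(); params <- list()
    for (s in series) {
      sets <- lapply(s$epochs, function(e)
        compute_burst_parameters(e, detect_network_bursts(e, config$burst),
                                 ibi_mode = config$burst$ibi_mode))
      veh <- sets[[1]]
      for (i in seq_along(sets)) {
        e <- s$epochs[[i]]
        params[[length(params) + 1L]] <- data.frame(
          well = s$well_id, compound = e$condition$compound,
          concentration = e$condition$concentration,
          is_vehicle = e$condition$is_vehicle,
          TS = sets[[i]]$TS, NoB = sets[[i]]$NoB, IBI = sets[[i]]$IBI,
          DoB = sets[[i]]$DoB, SiB = sets[[i]]$SiB)
        if (i > 1) {
          pc <- suppressWarnings(percent_of_control(sets[[i]], veh))
          pct[[length(pct) + 1L]] <- data.frame(
            compound = e$condition$compound,
            concentration = e$condition$concentration,
            parameter = names(pc), well = s$well_id, value = unname(pc))
        }
      }
    }
    pct <- do.call(rbind, pct)
    params <- do.call(rbind, params)
    drt <- dose_response_table(pct)
    # Dunnett family: all concentrations of one compound x parameter,
    # vehicle (= 100% by construction) as the reference group
    tests <- list()
    for (cp in unique(pct$compound)) {
      for (pa in unique(pct$parameter)) {
        g <- pct[pct$compound == cp & pct$parameter == pa, ]
        g <- g[!is.na(g$value), ]
        veh100 <- data.frame(value = rep(100, length(unique(g$well))),
                             concentration = 0)
        cnt <- table(g$concentration)
        if (nrow(veh100) < 2 || length(cnt) < 1 || any(cnt < 2)) next
        res <- tryCatch(suppressWarnings(dunnett_vs_vehicle(
          c(veh100$value, g$value),
          c(rep("vehicle", nrow(veh100)), as.character(g$concentration)),
          "vehicle")), error = function(e) NULL)
        if (!is.null(res)) {
          res$compound <- cp; res$parameter <- pa
          tests[[length(tests) + 1L]] <- res
        }
      }
    }
    list(params = params, pct = pct, dose_response = drt,
         dunnett = if (length(tests)) do.call(rbind, tests) else NULL)
  })
  say("burst analysis: %d epochs (%s)", nrow(ba$params),
      if (attr(ba, "cache_hit")) "cached" else "computed")

  # --- stage: features -------------------------------------------------
  feat_key <- paste0("feat_", .object_digest(list(data_key, config$burst,
                                                  config$render,
                                                  config$extractor,
                                                  config$normalize_method)))
  ds <- .cache_fetch(config$cache_dir, feat_key, function()
    build_window_dataset(series, config$burst, config$render,
                         config$extractor,
                         normalize_method = config$normalize_method))
  say("features: %d windows x %d dims (%s)", nrow(ds$features),
      ncol(ds$features), if (attr(ds, "cache_hit")) "cached" else "computed")

  test_wells <- if (identical(config$test_wells, "auto"))
    .auto_test_wells(series) else config$test_wells
  meta <- ds$meta

  # --- stage: risk -----------------------------------------------------
  risk_key <- paste0("risk_", .object_digest(list(feat_key, config$risk_spec,
                                                  config$risk_replicates,
                                                  test_wells,
                                                  config$training_concentration_min,
                                                  config$aggregation,
                                                  config$costs, config$seed)))
  risk <- .cache_fetch(config$cache_dir, risk_key, function() {
    truth <- .risk_truth(meta, config$training_concentration_min)
    lab <- factor(ifelse(truth, "seizure-causing", "seizure-free"),
                  levels = c("seizure-causing", "seizure-free"))
    sub <- which(!is.na(lab) & !(meta$well %in% test_wells))
    .assert(length(unique(lab[sub])) == 2,
            "risk training needs both classes among the training wells")
    test_rows <- which(meta$well %in% test_wells)
    .assert(length(test_rows) > 0, "no windows in the held-out wells")
    models <- list()
    p_acc <- 0
    for (r in seq_len(config$risk_replicates)) {
      split <- make_dataset_split(meta$well[sub], character(), 0.75,
                                  seed = .child_seed(config$seed, 11, r))
      spec <- config$risk_spec
      spec$seed <- .child_seed(config$seed, 12, r)
      model <- train_pattern_net(ds$features[sub, , drop = FALSE], lab[sub],
                                 split, spec)
      models[[r]] <- model
      p_acc <- p_acc +
        predict_windows(model, ds$features[test_rows, , drop = FALSE])
    }
    model <- models[[1]]
    probs <- p_acc / config$risk_replicates
    p_pos <- probs[, "seizure-causing"]
    agg <- aggregate_risk(p_pos, meta[test_rows, ], mode = config$aggregation)
    # ROC over test windows whose truth is defined
    t_truth <- truth[test_rows]
    ok <- !is.na(t_truth)
    roc <- roc_curve(p_pos[ok], t_truth[ok])
    op <- optimal_operating_point(roc,
                                  cost_fp = config$costs[["fp"]],
                                  cost_tn = config$costs[["tn"]],
                                  cost_fn = config$costs[["fn"]],
                                  cost_tp = config$costs[["tp"]])
    cm <- confusion_at(op$threshold, p_pos[ok], t_truth[ok],
                       groups = meta$compound[test_rows][ok])
    list(model = model, n_models = length(models), window_probs = p_pos,
         test_rows = test_rows, aggregated = agg, roc = roc,
         operating_point = op, confusion = cm,
         metrics = classification_metrics(cm, config$f_variant))
  })
  say("risk: test AUC %.4f, operating point %.3f (%s)",
      risk$roc$auc, risk$operating_point$threshold,
      if (attr(risk, "cache_hit")) "cached" else "computed")

  # --- stage: drug identification (optional) ---------------------------
  drug_id <- NULL
  if (!isFALSE(config$drugid)) {
    did_key <- paste0("drugid_", .object_digest(list(feat_key, config$drugid,
                                                     config$drugid_replicates,
                                                     test_wells, config$seed,
                                                     config$training_concentration_min)))
    drug_id <- .cache_fetch(config$cache_dir, did_key, function() {
      # class composition: each seizure-causing compound at its designated
      # concentrations is its own class; the pooled negative class is the
      # seizure-free compounds' windows (including their vehicle epochs).
      # Drug wells' vehicle epochs are predicted but not trained on.
      lab <- rep(NA_character_, nrow(meta))
      pos <- meta$risk_class == "seizure-causing" & !meta$is_vehicle &
        meta$concentration >= config$training_concentration_min
      lab[pos] <- meta$compound[pos]
      lab[meta$risk_class == "seizure-free"] <- "negative"
      keep <- !is.na(lab)
      lab <- factor(lab, levels = c(sort(unique(lab[keep & lab != "negative"])),
                                    "negative"))
      spec <- drugid_net_spec(n_classes = nlevels(lab),
                              seed = .child_seed(config$seed, 21))
      spec$max_iterations <- 800L
      if (identical(config$drugid, "loo")) {
        loo <- run_leave_one_well_out(ds$features[keep, , drop = FALSE],
                                      lab[keep], meta$well[keep], spec,
                                      replicates = config$drugid_replicates,
                                      seed = .child_seed(config$seed, 22))
        agg <- aggregate_drug_id(loo$probs, meta[keep, ])
        list(scheme = "loo", aggregated = agg, n_models = loo$n_models)
      } else {
        sub <- which(keep & !(meta$well %in% test_wells))
        split <- make_dataset_split(meta$well[sub], character(), 0.75,
                                    seed = .child_seed(config$seed, 23))
        model <- train_pattern_net(ds$features[sub, , drop = FALSE],
                                   droplevels(lab[sub]), split, spec)
        test_rows <- which(meta$well %in% test_wells & (keep | meta$is_vehicle))
        probs <- predict_windows(model, ds$features[test_rows, , drop = FALSE])
        agg <- aggregate_drug_id(probs, meta[test_rows, ])
        list(scheme = "holdout", model = model, aggregated = agg,
             n_models = 1L)
      }
    })
    say("drug identification: %d models (%s)", drug_id$n_models,
        if (attr(drug_id, "cache_hit")) "cached" else "computed")
  }

  report <- structure(list(config = config, config_hash = cfg_hash,
                           seed = config$seed, test_wells = test_wells,
                           burst_params = ba$params,
                           dose_response = ba$dose_response,
                           dunnett = ba$dunnett, dataset = ds, risk = risk,
                           drug_id = drug_id),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

.write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .write_tsv(report$burst_params, file.path(dir, "burst_parameters.tsv"))
  .write_tsv(report$dose_response, file.path(dir, "dose_response.tsv"))
  if (!is.null(report$dunnett))
    .write_tsv(report$dunnett, file.path(dir, "dunnett.tsv"))
  .write_tsv(report$dataset$imfi, file.path(dir, "imfi.tsv"))
  .write_tsv(report$risk$aggregated$wells, file.path(dir, "risk_wells.tsv"))
  .write_tsv(report$risk$aggregated$concentrations,
             file.path(dir, "risk_concentrations.tsv"))
  if (!is.null(report$drug_id))
    .write_tsv(report$drug_id$aggregated, file.path(dir, "drug_id.tsv"))
  m <- report$risk$metrics
  yaml::write_yaml(list(
    config_hash = report$config_hash, seed = report$seed,
    test_wells = report$test_wells,
    auc = report$risk$roc$auc,
    operating_point = list(S = report$risk$operating_point$S,
                           threshold = report$risk$operating_point$threshold,
                           fpr = report$risk$operating_point$fpr,
                           tpr = report$risk$operating_point$tpr),
    metrics = list(Acc = m$Acc, PPV = m$PPV, Sen = m$Sen, Spec = m$Spec,
                   F = m$F, f_variant = m$f_variant)),
    file.path(dir, "summary.yaml"))
  invisible(dir)
}

#' Dose-response plot of percent-of-control curves
#'
#' One panel per parameter, percent-of-control (vehicle = 100%) against
#' concentration with SEM error bars, with significance stars when Dunnett
#' results are supplied.
#'
#' @param drt A [dose_response_table()] result for one compound.
#' @param dunnett Optional [dunnett_vs_vehicle()] results (`parameter`,
#'   `group`, `sig_05`, `sig_01` columns).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(drt, dunnett = NULL) {
  .assert(requireNamespace("ggplot2", quietly = TRUE),
          "ggplot2 is required for plotting")
  drt$parameter <- factor(drt$parameter,
                          levels = c("TS", "NoB", "IBI", "DoB", "SiB"))
  p <- ggplot2::ggplot(drt, ggplot2::aes(x = concentration, y = mean)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
                           width = 0.05) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "concentration", y = "% of vehicle control")
  if (!is.null(dunnett)) {
    stars <- dunnett[dunnett$sig_05, ]
    if (nrow(stars)) {
      stars$label <- ifelse(stars$sig_01, "**", "*")
      stars$concentration <- as.numeric(as.character(stars$group))
      key <- paste(drt$parameter, drt$concentration)
      skey <- paste(stars$parameter, stars$concentration)
      stars$y <- (drt$mean + drt$sem)[match(skey, key)] * 1.05
      stars$parameter <- factor(stars$parameter, levels = levels(drt$parameter))
      p <- p + ggplot2::geom_text(data = stars,
                                  ggplot2::aes(x = concentration, y = y,
                                               label = label))
    }
  }
  p
}
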