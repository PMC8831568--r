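# 4096-dimensional image features through a pluggable extractor contract,
# and per-well vehicle normalization. The reference backbone is an
# AlexNet-style object-recognition network whose fc7 fully connected layer
# emits a 4096-d descriptor per image; its pretrained weights are not
# bundled, so the package ships a deterministic "fixture" backend (a seeded
# random projection of the 32 x 32 downsampled image to 4096 dimensions)
# with the same contract, which is what the tests and the synthetic
# pipeline use.

.mearaster_cache <- new.env(parent = emptyenv())

#' Feature-extractor specification
#'
#' @param backend `"fixture"` (seeded random projection; always available)
#'   or `"alexnet-fc7"` (the reference pretrained backbone; requires
#'   externally supplied weights and errors with remediation advice when
#'   they are absent).
#' @param output_dim Feature dimension; the fc7-style contract is 4096.
#' @param input_size Image edge length expected by the backend (default 227).
#' @param proj_size Downsampling edge length of the fixture backend
#'   (default 32; the projection input is `proj_size^2` pixels).
#' @param seed Seed of the fixture backend's projection matrix (default 20).
#' @param rectify Apply a ReLU rectification to the projected features
#'   (default `FALSE`). The reference fc7 layer emits rectified activations,
#'   and rectification makes deviation-magnitude information linearly
#'   accessible to downstream shallow classifiers; the plain (unrectified)
#'   projection is the fixture's canonical definition.
#' @return An object of class `extractor_spec`.
#' @export
extractor_spec <- function(backend = c("fixture", "alexnet-fc7"),
                           output_dim = 4096, input_size = 227,
                           proj_size = 32, seed = 20, rectify = FALSE) {
  backend <- match.arg(backend)
  .assert(output_dim == 4096,
          "the fc7-style feature contract is 4096-dimensional")
  structure(list(backend = backend, output_dim = as.integer(output_dim),
                 input_size = as.integer(input_size),
                 proj_size = as.integer(proj_size), seed = as.integer(seed),
                 rectify = isTRUE(rectify)),
            class = "extractor_spec")
}

# block-mean downsample of a pixel matrix to s x s (index-mapped blocks, so
# any input size works)
.downsample <- function(px, s) {
  H <- nrow(px); W <- ncol(px)
  gr <- floor((seq_len(H) - 1) * s / H)
  gc <- floor((seq_len(W) - 1) * s / W)
  m <- rowsum(px, gr)
  m <- t(rowsum(t(m), gc))
  cnt <- outer(tabulate(gr + 1L, s), tabulate(gc + 1L, s))
  m / cnt
}

# fixture projection matrix (proj_size^2 x 4096), cached per (seed, dims)
.fixture_projection <- function(spec) {
  key <- sprintf("proj_%d_%d_%d", spec$seed, spec$proj_size, spec$output_dim)
  if (is.null(.mearaster_cache[[key]])) {
    d_in <- spec$proj_size^2
    .mearaster_cache[[key]] <- withr::with_seed(
      spec$seed,
      matrix(stats::rnorm(d_in * spec$output_dim), d_in,
             spec$output_dim) / sqrt(d_in))
  }
  .mearaster_cache[[key]]
}

.flatten_for_fixture <- function(img, spec) {
  as.vector(.downsample(img$pixels, spec$proj_size))  # column-major flatten
}

#' Extract a 4096-d feature vector from a raster image
#'
#' Deterministic given `(img, spec)`; the backbone (when configured) is used
#' in evaluation mode only -- no weights are ever updated.
#'
#' @param img A [render_raster()] result.
#' @param spec An [extractor_spec()].
#' @return Numeric vector of length 4096 with provenance attributes
#'   `well_id`, `condition`, `window_index`.
#' @export
extract_features <- function(img, spec = extractor_spec()) {
  .assert(inherits(img, "raster_image"), "raster_image required")
  .assert(inherits(spec, "extractor_spec"), "extractor_spec required")
  v <- switch(spec$backend,
    fixture = {
      vv <- drop(.flatten_for_fixture(img, spec) %*%
                   .fixture_projection(spec))
      if (spec$rectify) pmax(vv, 0) else vv
    },
    `alexnet-fc7` = stop(paste0(
      "backend 'alexnet-fc7' needs externally supplied pretrained weights, ",
      "which are not bundled with this package; use ",
      "extractor_spec(backend = 'fixture') for a self-contained extractor ",
      "with the same 4096-d contract"), call. = FALSE))
  .assert(length(v) == spec$output_dim && all(is.finite(v)),
          "extractor must return %d finite values", spec$output_dim)
  attr(v, "well_id") <- img$well_id
  attr(v, "condition") <- img$condition
  attr(v, "window_index") <- img$window_index
  v
}

#' Extract features for a list of images as a matrix
#'
#' Batch form of [extract_features()] (one BLAS call for the fixture
#' backend).
#'
#' @param images List of `raster_image` objects.
#' @param spec An [extractor_spec()].
#' @return Numeric matrix, one row per image, 4096 columns.
#' @export
extract_feature_matrix <- function(images, spec = extractor_spec()) {
  .assert(length(images) > 0, "no images")
  if (spec$backend == "fixture") {
    x <- t(vapply(images, .flatten_for_fixture, numeric(spec$proj_size^2),
                  spec = spec))
    fx <- x %*% .fixture_projection(spec)
    return(if (spec$rectify) pmax(fx, 0) else fx)
  }
  t(vapply(images, function(im) as.numeric(extract_features(im, spec)),
           numeric(spec$output_dim)))
}

#' Per-well vehicle normalization of feature vectors
#'
#' Corrects for differing initial states between wells by centering every
#' window's features around the per-dimension mean of that same well's
#' vehicle-epoch features. A z-score variant additionally divides by the
#' vehicle per-dimension standard deviation.
#'
#' @param features Numeric matrix, one row per window, 4096 columns.
#' @param meta Data frame with one row per window; must contain `well` and
#'   `is_vehicle`.
#' @param method `"center"` (default) or `"zscore"`.
#' @param eps Standard-deviation floor of the z-score variant, on the scale
#'   of the features (default 0.01): dimensions whose vehicle spread is
#'   below the floor are divided by `sd + eps` rather than their raw (near
#'   zero) spread, which would explode the scores.
#' @return The normalized feature matrix, with attribute
#'   `normalized = method`.
#' @export
vehicle_normalize <- function(features, meta, method = c("center", "zscore"),
                              eps = 0.01) {
  method <- match.arg(method)
  .assert(is.matrix(features) && nrow(features) == nrow(meta),
          "features and meta must have one row per window")
  .assert(all(c("well", "is_vehicle") %in% names(meta)),
          "meta must contain 'well' and 'is_vehicle'")
  out <- features
  for (w in unique(meta$well)) {
    rows <- which(meta$well == w)
    veh <- rows[meta$is_vehicle[rows]]
    .assert(length(veh) >= 1,
            "well %s has no vehicle windows to normalize against", w)
    mu <- colMeans(features[veh, , drop = FALSE])
    out[rows, ] <- sweep(features[rows, , drop = FALSE], 2, mu)
    if (method == "zscore") {
      sdv <- apply(features[veh, , drop = FALSE], 2, stats::sd)
      sdv[!is.finite(sdv)] <- 0
      out[rows, ] <- sweep(out[rows, , drop = FALSE], 2, sdv + eps, "/")
    }
  }
  attr(out, "normalized") <- method
  out
}

#' Build the windowed feature dataset of a dose-series panel
#'
#' Full front half of the pipeline for a set of wells: detect network bursts
#' in each well's vehicle epoch, estimate the IMFI, segment every epoch of
#' the well into 4 x IMFI windows, render each window, extract features, and
#' vehicle-normalize per well.
#'
#' @param series List of [dose_series_recording()]s (e.g. from
#'   [read_spike_table()] or [generate_labeled_dataset()]).
#' @param burst_cfg [burst_config()] used for vehicle burst detection.
#' @param render_cfg [render_config()].
#' @param spec [extractor_spec()].
#' @param normalize Apply [vehicle_normalize()] (default `TRUE`).
#' @param normalize_method Normalization variant passed to
#'   [vehicle_normalize()] (default `"center"`).
#' @return List of class `window_dataset`: `features` (n x 4096 matrix),
#'   `meta` (data frame: `well`, `compound`, `concentration`, `unit`,
#'   `is_vehicle`, `risk_class`, `window_index`), and `imfi` (per-well IMFI
#'   table).
#' @export
build_window_dataset <- function(series, burst_cfg = burst_config(),
                                 render_cfg = render_config(),
                                 spec = extractor_spec(), normalize = TRUE,
                                 normalize_method = "center") {
  if (inherits(series, "dose_series_recording")) series <- list(series)
  feats <- list(); metas <- list(); imfis <- list()
  for (s in series) {
    veh <- s$epochs[[1]]
    vb <- detect_network_bursts(veh, burst_cfg)
    imfi <- estimate_imfi(veh, vb)  # errors, naming the well, when < 2 bursts
    imfis[[s$well_id]] <- data.frame(well = s$well_id, imfi_s = imfi$imfi_s,
                                     n_intervals = imfi$n_intervals)
    for (e in s$epochs) {
      wins <- segment_windows(e, imfi)
      if (length(wins) == 0) next
      imgs <- lapply(wins, render_raster, cfg = render_cfg)
      feats[[length(feats) + 1L]] <- extract_feature_matrix(imgs, spec)
      metas[[length(metas) + 1L]] <- data.frame(
        well = s$well_id,
        compound = e$condition$compound,
        concentration = e$condition$concentration,
        unit = e$condition$unit,
        is_vehicle = e$condition$is_vehicle,
        risk_class = e$condition$risk_class,
        window_index = vapply(wins, function(w) w$window_index, integer(1)))
    }
  }
  features <- do.call(rbind, feats)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  if (normalize)
    features <- vehicle_normalize(features, meta, method = normalize_method)
  structure(list(features = features, meta = meta,
                 imfi = do.call(rbind, imfis)),
            class = "window_dataset")
}
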