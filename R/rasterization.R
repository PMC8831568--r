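# IMFI estimation and raster-plot rendering. Each well's raster window
# width is four times its baseline IMFI -- the inter-maximum-frequency
# interval, i.e. the typical spacing between successive network bursts'
# peak-firing-rate times in the vehicle epoch. Windowing by the well's own
# burst rhythm makes image content comparable across wells whose baseline
# burst frequency differs.

#' Estimate the IMFI of a well from its vehicle epoch
#'
#' The IMFI is taken as the median of the successive differences of the
#' network bursts' `peak_rate_time` (pooled-rate maxima); the median guards
#' against occasional missed or split bursts.
#'
#' @param vehicle_rec The vehicle-epoch [well_recording()].
#' @param bursts [detect_network_bursts()] output for that epoch; at least
#'   two bursts are required, otherwise the window width is undefined and an
#'   error naming the well is raised.
#' @return An object of class `imfi_estimate`: list with `well_id`,
#'   `imfi_s`, `n_intervals`, `source = "vehicle"`.
#' @export
estimate_imfi <- function(vehicle_rec, bursts) {
  .assert(inherits(vehicle_rec, "well_recording"), "well_recording required")
  .assert(isTRUE(vehicle_rec$condition$is_vehicle),
          "well %s: IMFI must be estimated on the vehicle epoch",
          vehicle_rec$well_id)
  nb <- nrow(bursts)
  if (nb < 2)
    stop(sprintf(paste0("well %s: %d network burst(s) in the vehicle epoch; ",
                        "at least 2 are needed to define the IMFI window width"),
                 vehicle_rec$well_id, nb), call. = FALSE)
  d <- diff(bursts$peak_rate_time)
  structure(list(well_id = vehicle_rec$well_id,
                 imfi_s = stats::median(d),
                 n_intervals = length(d), source = "vehicle"),
            class = "imfi_estimate")
}

#' Segment an epoch into non-overlapping 4 x IMFI windows
#'
#' Windows are anchored at the epoch start at `t0 = 0, 4*IMFI, 8*IMFI, ...`;
#' the trailing partial window is discarded.
#'
#' @param rec A [well_recording()] (any epoch of the well).
#' @param imfi The well's [estimate_imfi()] result (from its vehicle epoch).
#' @return List of `raster_window` objects: each has `well_id`, `condition`,
#'   `t0`, `width` (= 4 x IMFI), `window_index`, and `spikes`, a data frame
#'   of (electrode, t_offset) pairs with offsets in `[0, width)`. Empty list
#'   with a warning when `4 * IMFI` exceeds the epoch duration.
#' @export
segment_windows <- function(rec, imfi) {
  .assert(inherits(rec, "well_recording"), "well_recording required")
  .assert(inherits(imfi, "imfi_estimate"), "imfi_estimate required")
  .assert(identical(rec$well_id, imfi$well_id),
          "IMFI of well %s applied to recording of well %s",
          imfi$well_id, rec$well_id)
  width <- 4 * imfi$imfi_s
  nw <- floor(rec$duration_s / width)
  if (nw < 1) {
    warning(sprintf("well %s: window width %.3g s exceeds epoch duration %g s; no windows",
                    rec$well_id, width, rec$duration_s))
    return(list())
  }
  pool <- .pool_spikes(rec)
  win_of <- floor(pool$time / width) + 1  # 1-based; tail windows dropped below
  lapply(seq_len(nw), function(i) {
    sel <- win_of == i
    structure(list(well_id = rec$well_id, condition = rec$condition,
                   t0 = (i - 1) * width, width = width, window_index = i,
                   spikes = data.frame(electrode = pool$electrode[sel],
                                       t_offset = pool$time[sel] - (i - 1) * width)),
              class = "raster_window")
  })
}

#' Raster-image rendering configuration
#'
#' @param width_px,height_px Image size in pixels (default 227 x 227, the
#'   input size of the feature-extraction backbone).
#' @param dot_px Spike dot size in pixels (default 1). With 16 electrode
#'   bands of ~14 px, larger dots saturate the area a burst occupies, so
#'   within-burst spike-count changes stop altering the image; 1-px dots
#'   keep pixel darkness roughly proportional to local spike count.
#' @param background,foreground Pixel intensities in `[0, 1]`; default black
#'   dots (0) on a white background (1).
#' @return An object of class `render_config`.
#' @export
render_config <- function(width_px = 227, height_px = 227, dot_px = 1,
                          background = 1, foreground = 0) {
  .assert(width_px >= 16 && height_px >= 16 && dot_px >= 1,
          "image must be at least 16 px and dot_px >= 1")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 dot_px = as.integer(dot_px),
                 background = background, foreground = foreground),
            class = "render_config")
}

#' Render one raster window to an image
#'
#' Electrode `e` maps to the `e`-th of 16 equal horizontal bands (electrode
#' 0 at the top); time maps linearly to columns over `[0, width)`. Each
#' spike is drawn as a `dot_px` x `dot_px` foreground square anchored at the
#' top-left of its (band, column) position; the rendering is a deterministic
#' function of the window and the configuration.
#'
#' @param window A `raster_window` from [segment_windows()].
#' @param cfg A [render_config()].
#' @return An object of class `raster_image`: list with `pixels` (numeric
#'   `height_px x width_px` matrix), and provenance fields `well_id`,
#'   `condition`, `window_index`.
#' @export
render_raster <- function(window, cfg = render_config()) {
  .assert(inherits(window, "raster_window"), "raster_window required")
  .assert(inherits(cfg, "render_config"), "render_config required")
  H <- cfg$height_px; W <- cfg$width_px
  px <- matrix(cfg$background, nrow = H, ncol = W)
  sp <- window$spikes
  if (nrow(sp)) {
    row0 <- floor(sp$electrode * H / 16) + 1L
    col0 <- pmin(W, floor(sp$t_offset / window$width * W) + 1L)
    for (dr in 0:(cfg$dot_px - 1L)) {
      r <- row0 + dr
      okr <- r <= H
      for (dc in 0:(cfg$dot_px - 1L)) {
        cc <- col0 + dc
        ok <- okr & cc <= W
        px[cbind(r[ok], cc[ok])] <- cfg$foreground
      }
    }
  }
  structure(list(pixels = px, well_id = window$well_id,
                 condition = window$condition,
                 window_index = window$window_index),
            class = "raster_image")
}

#' Export a raster image as PNG
#'
#' The filename encodes provenance as
#' `well__compound__conc__windowNNN.png`.
#'
#' @param img A [render_raster()] result.
#' @param dir Output directory.
#' @return The written path, invisibly.
#' @export
write_raster_png <- function(img, dir) {
  .assert(inherits(img, "raster_image"), "raster_image required")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cond <- img$condition
  fn <- sprintf("%s__%s__%s%s__window%03d.png", img$well_id, cond$compound,
                format(cond$concentration),
                if (cond$unit == "uM") "uM" else "pct",
                img$window_index)
  path <- file.path(dir, fn)
  png::writePNG(img$pixels, path)
  invisible(path)
}
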