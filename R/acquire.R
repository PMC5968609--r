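# Virtual imaging layer: render per-cycle transmitted-light / fluorescence
# image pairs from a simulated chip, detect cells on the transmitted channel,
# and measure per-cell mean fluorescence intensity (MFI).
#
# This module is an explicit surrogate for the instrument's proprietary
# recognition and repositioning software: detection is Otsu thresholding on
# the transmitted channel followed by connected-component labelling and an
# area filter (the stand-in for rejecting debris and foreign particles),
# all via EBImage.

#' Render one field of view for one cycle
#'
#' Cells are drawn as Gaussian-blurred disks on both channels. On the
#' fluorescence channel a cell's disk amplitude equals its stained MFI for
#' that cycle, so the mean pixel intensity over the cell footprint recovers
#' the simulated MFI (up to blur at the rim). On the transmitted channel all
#' cells share a fixed contrast amplitude. The fluorescence background is the
#' FOV's additive illumination offset B plus Gaussian shot-like noise.
#'
#' @param experiment A `chip_experiment` with simulated cycles.
#' @param fov_id FOV index (row-major from 1).
#' @param cycle Cycle index (1-based, one marker per cycle).
#' @param pixel_size_um Microns per pixel (default 0.5).
#' @param psf_sigma_um Gaussian point-spread sigma in microns (default 0.5).
#' @param noise_sd Raster background noise sd in AU (default 0: noise enters
#'   through the simulated MFIs; raster noise is extra).
#' @return A `field_image_pair`: `transmitted` and `fluorescence` matrices
#'   (equal shape), `fov_id`, `cycle`, `marker`, `pixel_size_um`, and the
#'   FOV origin in chip coordinates.
#' @export
render_fov <- function(experiment, fov_id, cycle, pixel_size_um = 0.5,
                       psf_sigma_um = 0.5, noise_sd = 0) {
  cy <- experiment$cycles
  if (is.null(cy)) param_error("experiment has no simulated cycles")
  geom <- experiment$geometry
  if (fov_id < 1 || fov_id > geom$n_fov) {
    stop(errorCondition(paste0("unknown fov_id: ", fov_id),
                        class = c("chipcsf_lookup_error", "error")))
  }
  if (cycle < 1 || cycle > length(experiment$panel)) {
    stop(errorCondition(paste0("cycle out of range: ", cycle),
                        class = c("chipcsf_lookup_error", "error")))
  }
  npx <- ceiling(geom$fov_size_um / pixel_size_um)
  if (npx > 512) param_error("raster larger than 512x512; increase pixel size")
  row0 <- (fov_id - 1L) %/% geom$fov_cols
  col0 <- (fov_id - 1L) %% geom$fov_cols
  x0 <- col0 * geom$fov_size_um
  y0 <- row0 * geom$fov_size_um

  bg_B <- cy$illum_B[fov_id]
  fl <- matrix(bg_B, npx, npx)          # [x, y] like EBImage
  tr <- matrix(0.1, npx, npx)

  sel <- which(cy$present[, cycle] &
                 fov_of(cy$pos_x[, cycle], cy$pos_y[, cycle], geom) == fov_id)
  px <- (seq_len(npx) - 0.5) * pixel_size_um
  for (i in sel) {
    cx <- cy$pos_x[i, cycle] - x0
    cyy <- cy$pos_y[i, cycle] - y0
    r <- sqrt(experiment$cells$size_um2[i] / pi)
    win <- ceiling((r + 4 * psf_sigma_um) / pixel_size_um)
    ix <- max(1, floor(cx / pixel_size_um) - win):min(npx, ceiling(cx / pixel_size_um) + win)
    iy <- max(1, floor(cyy / pixel_size_um) - win):min(npx, ceiling(cyy / pixel_size_um) + win)
    if (!length(ix) || !length(iy)) next
    dx <- px[ix] - cx
    dy <- px[iy] - cyy
    d <- sqrt(outer(dx^2, dy^2, "+"))
    # disk convolved with an isotropic Gaussian, radial erf profile
    prof <- 0.5 * (1 + erf_((r - d) / (sqrt(2) * psf_sigma_um)))
    fl[ix, iy] <- fl[ix, iy] + cy$mfi_stained[i, cycle] * prof
    tr[ix, iy] <- tr[ix, iy] + 0.8 * prof
  }
  if (noise_sd > 0) {
    fl <- fl + matrix(stats::rnorm(npx * npx, 0, noise_sd), npx, npx)
    tr <- tr + matrix(stats::rnorm(npx * npx, 0, 0.02), npx, npx)
  }
  structure(list(
    fov_id = fov_id, cycle = cycle, marker = experiment$panel[cycle],
    transmitted = tr, fluorescence = fl, pixel_size_um = pixel_size_um,
    origin_um = c(x = x0, y = y0)
  ), class = "field_image_pair")
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Detect cells on a transmitted-light raster
#'
#' Otsu global thresholding on the (range-normalised) transmitted image,
#' connected-component labelling, and an area filter standing in for the
#' manual rejection of debris and foreign particles. A blank raster yields
#' zero detections, not an error.
#'
#' @param pair A `field_image_pair` (or a list with `transmitted`,
#'   `pixel_size_um`, `origin_um`, `fov_id`, `cycle`).
#' @param min_area_um2,max_area_um2 Accepted component area range (um^2);
#'   defaults bracket lymphocytes (~60 um^2) through monocytes (~150 um^2).
#' @return data.frame of detections: `label` (component id), `x`, `y`
#'   (centroid, chip coordinates, um), `area_um2`, `fov`, `cycle`, plus the
#'   label mask as attribute `"mask"` for MFI measurement.
#' @export
detect_cells <- function(pair, min_area_um2 = 15, max_area_um2 = 400) {
  tr <- pair$transmitted
  if (!length(tr)) param_error("empty raster")
  rng <- range(tr)
  empty <- data.frame(label = integer(), x = numeric(), y = numeric(),
                      area_um2 = numeric(), fov = integer(), cycle = integer(),
                      stringsAsFactors = FALSE)
  if (diff(rng) < 1e-9) {
    attr(empty, "mask") <- matrix(0L, nrow(tr), ncol(tr))
    return(empty)
  }
  norm <- (tr - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- EBImage::bwlabel(norm > th)
  m <- EBImage::imageData(mask)
  n_comp <- max(m)
  if (n_comp == 0) {
    attr(empty, "mask") <- m
    return(empty)
  }
  px_area <- pair$pixel_size_um^2
  area <- tabulate(m[m > 0], nbins = n_comp) * px_area
  cx <- vapply(seq_len(n_comp), function(l) mean(row(m)[m == l]), numeric(1))
  cyy <- vapply(seq_len(n_comp), function(l) mean(col(m)[m == l]), numeric(1))
  keep <- area >= min_area_um2 & area <= max_area_um2
  # drop rejected components from the mask so measurement can't use them
  m[m %in% which(!keep)] <- 0L
  if (!any(keep)) {
    attr(empty, "mask") <- m
    return(empty)
  }
  det <- data.frame(
    label = which(keep),
    x = pair$origin_um[["x"]] + (cx[keep] - 0.5) * pair$pixel_size_um,
    y = pair$origin_um[["y"]] + (cyy[keep] - 0.5) * pair$pixel_size_um,
    area_um2 = area[keep],
    fov = pair$fov_id,
    cycle = pair$cycle,
    stringsAsFactors = FALSE
  )
  attr(det, "mask") <- m
  det
}

#' Measure per-cell MFI on the fluorescence raster
#'
#' MFI is the mean fluorescence pixel intensity over each detection's
#' connected-component mask (the mask produced by [detect_cells()] on the
#' matched transmitted frame).
#'
#' @param pair The matching `field_image_pair`.
#' @param detections Output of [detect_cells()] on `pair`.
#' @return `detections` with an `mfi` column appended.
#' @export
measure_mfi <- function(pair, detections) {
  mask <- attr(detections, "mask")
  if (is.null(mask)) param_error("detections carry no component mask")
  if (!identical(dim(mask), dim(pair$fluorescence))) {
    param_error("mask and fluorescence raster shapes differ")
  }
  mfi <- vapply(detections$label, function(l) {
    sel <- mask == l
    if (!any(sel)) {
      stop(errorCondition("empty detection mask",
                          class = c("chipcsf_measure_error", "error")))
    }
    mean(pair$fluorescence[sel])
  }, numeric(1))
  detections$mfi <- pmax(mfi, 0)
  detections
}

#' Run image-mode acquisition over a whole experiment
#'
#' Renders every FOV for every cycle, detects cells on the transmitted
#' channel and measures fluorescence MFIs — the image-mode alternative to
#' reading MFIs straight from the simulator (table mode).
#'
#' @param experiment A `chip_experiment` with simulated cycles.
#' @param pixel_size_um,psf_sigma_um,noise_sd Passed to [render_fov()].
#' @param fovs Optional subset of FOV indices (default: all).
#' @return data.frame of measured detections across FOVs and cycles
#'   (columns of [measure_mfi()] plus `marker`).
#' @export
acquire_experiment <- function(experiment, pixel_size_um = 0.5,
                               psf_sigma_um = 0.5, noise_sd = 0, fovs = NULL) {
  if (is.null(fovs)) fovs <- seq_len(experiment$geometry$n_fov)
  out <- list()
  for (k in seq_along(experiment$panel)) {
    for (f in fovs) {
      pair <- render_fov(experiment, f, k, pixel_size_um, psf_sigma_um, noise_sd)
      det <- detect_cells(pair)
      if (nrow(det)) {
        det <- measure_mfi(pair, det)
        det$marker <- pair$marker
        out[[length(out) + 1L]] <- det
      }
    }
  }
  if (!length(out)) {
    return(data.frame(label = integer(), x = numeric(), y = numeric(),
                      area_um2 = numeric(), fov = integer(), cycle = integer(),
                      mfi = numeric(), marker = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(out, function(d) { attr(d, "mask") <- NULL; d }))
}

#' Write an experiment's rendered images as a multi-page TIFF
#'
#' One page per (cycle, channel), fluorescence rescaled to `[0, 1]` by the
#' stack maximum. Requires the optional tiff package.
#'
#' @param experiment A `chip_experiment` with simulated cycles.
#' @param path Output file path.
#' @param fov_id FOV to export.
#' @param pixel_size_um Passed to [render_fov()].
#' @return `path`, invisibly.
#' @export
write_experiment_tiff <- function(experiment, path, fov_id = 1,
                                  pixel_size_um = 0.5) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    param_error("the 'tiff' package is required for TIFF export")
  }
  pages <- list()
  for (k in seq_along(experiment$panel)) {
    pair <- render_fov(experiment, fov_id, k, pixel_size_um)
    pages[[length(pages) + 1L]] <- t(pair$transmitted / max(pair$transmitted, 1))
    pages[[length(pages) + 1L]] <- t(pair$fluorescence / max(pair$fluorescence, 1))
  }
  tiff::writeTIFF(pages, path)
  invisible(path)
}
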