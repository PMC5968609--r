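# Synthetic CSF samples and virtual chip experiments.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: CSF cellularity as a two-component mixture (normocellular < 5/ul,
# pleocytosis >= 5/ul), per-cell Bernoulli loss during centrifugation,
# uniform chip loading over a FOV grid, per-population lognormal marker
# expression, and iterative stain-image-bleach cycles with per-cell
# autofluorescence, per-FOV illumination inhomogeneity, measurement noise,
# and cell detachment/reattachment during fluid exchange.

#' Chip geometry: the field-of-view grid
#'
#' Coordinates are 0-based microns, x rightward, y downward, origin at the
#' chip's top-left corner. The instrument's real chip dimensions are not
#' published; the grid is a free configuration parameter.
#'
#' @param fov_rows,fov_cols Grid of microscope positions (>= 1 each).
#' @param fov_size_um Side length of one square FOV in microns.
#' @return A `chip_geometry` list.
#' @export
chip_geometry <- function(fov_rows = 10, fov_cols = 10, fov_size_um = 128) {
  if (fov_rows < 1 || fov_cols < 1) param_error("fov grid must be >= 1 x 1")
  if (fov_size_um <= 0) param_error("fov_size_um must be > 0")
  structure(list(fov_rows = as.integer(fov_rows), fov_cols = as.integer(fov_cols),
                 fov_size_um = fov_size_um,
                 n_fov = as.integer(fov_rows) * as.integer(fov_cols)),
            class = "chip_geometry")
}

#' Preanalytic parameters: centrifugation loss
#'
#' The default per-cell loss probability of 0.593 matches the mean 59.3%
#' cell loss observed when absolute CSF cell numbers were counted before and
#' after centrifugation.
#'
#' @param loss_probability Per-cell Bernoulli loss probability in `[0, 1]`.
#' @param resuspension_volume_ul Pellet resuspension volume (microlitres).
#' @return A `preanalytics_params` list.
#' @export
preanalytics_params <- function(loss_probability = 0.593,
                                resuspension_volume_ul = 50) {
  stopifnot_scalar_prob(loss_probability, "loss_probability")
  if (resuspension_volume_ul <= 0) param_error("resuspension volume must be > 0")
  structure(list(loss_probability = loss_probability,
                 resuspension_volume_ul = resuspension_volume_ul),
            class = "preanalytics_params")
}

#' Per-cycle measurement kinetics
#'
#' For cell i on FOV p in the cycle staining marker m:
#' \deqn{MFI_{stained} = L_p (g E_{i,m} + A_i) + B_p + \epsilon}
#' \deqn{MFI_{postbleach} = L_p (\rho g E_{i,m} + A_i) + B_p + \epsilon'}
#' where E is true expression, g the stain gain, rho the residual-dye
#' fraction after bleaching, A_i per-cell autofluorescence (lognormal,
#' fully retained by bleaching), L_p / B_p per-FOV multiplicative and
#' additive illumination terms, and epsilon Gaussian measurement noise.
#' Before every cycle each attached cell detaches with `detach_prob`
#' (fluid-exchange shear); a detached cell reattaches at a new uniform
#' position with `reattach_prob`, visible from the next cycle on.
#'
#' @param gain Stain gain g (scalar, applied to every marker).
#' @param residual_dye Residual-dye fraction rho in `[0, 1]` (default 0:
#'   bleaching is complete).
#' @param af_meanlog,af_sdlog Lognormal autofluorescence parameters (AU).
#' @param illum_sdlog Log-sd of the per-FOV multiplicative field L (mean 1).
#' @param offset_max Per-FOV additive offset B drawn uniform on `[0, offset_max]`.
#' @param detach_prob Per-cell per-cycle detachment probability.
#' @param reattach_prob Probability a detached cell reattaches elsewhere.
#' @param noise_sd Gaussian measurement noise sd (AU), per image.
#' @param adhesion_weights Optional named vector of relative adhesion weights
#'   per population (e.g. monocytes adhering more strongly than lymphocytes);
#'   scales each population's detachment probability inversely. Default NULL
#'   (uniform adhesion).
#' @return A `cycle_kinetics` list.
#' @export
cycle_kinetics <- function(gain = 1, residual_dye = 0,
                           af_meanlog = log(50), af_sdlog = 0.4,
                           illum_sdlog = 0.1, offset_max = 20,
                           detach_prob = 0.02, reattach_prob = 0.3,
                           noise_sd = 8, adhesion_weights = NULL) {
  stopifnot_scalar_prob(residual_dye, "residual_dye")
  stopifnot_scalar_prob(detach_prob, "detach_prob")
  stopifnot_scalar_prob(reattach_prob, "reattach_prob")
  if (gain <= 0) param_error("gain must be > 0")
  if (noise_sd < 0) param_error("noise_sd must be >= 0")
  structure(list(gain = gain, residual_dye = residual_dye,
                 af_meanlog = af_meanlog, af_sdlog = af_sdlog,
                 illum_sdlog = illum_sdlog, offset_max = offset_max,
                 detach_prob = detach_prob, reattach_prob = reattach_prob,
                 noise_sd = noise_sd, adhesion_weights = adhesion_weights),
            class = "cycle_kinetics")
}

#' Generate a cohort of virtual CSF samples
#'
#' Concentrations come from a two-component mixture: normocellular samples
#' (< 5 leukocytes/ul) from a lognormal with median ~1.5/ul, pleocytic
#' samples from 5 + lognormal(2.14, 1.75)/ul, calibrated so that ~62/27/14%
#' of pleocytic samples exceed 10/30/50 per ul. Volumes are lognormal with
#' median 4 ml clamped to `[1, 15]` ml (routine punctures up to 5 ml, large
#' withdrawals up to 15 ml).
#'
#' @param n_samples Number of samples (>= 1).
#' @param pleocytic_fraction Proportion of samples with pleocytosis
#'   (>= 5/ul); the observed cohort rate is 0.245.
#' @param composition_presets Named presets assigned to samples:
#'   normocellular samples get `"control"`, pleocytic samples `"MS-like"`
#'   by default; pass a single preset name to use it throughout.
#' @param seed Master seed (the cohort substream is derived from it).
#' @param force_concentration Optional numeric vector (recycled) forcing the
#'   drawn concentration, e.g. a known clinical cell count.
#' @return List of `csf_sample` objects with fields `sample_id`,
#'   `concentration` (cells/ul), `volume_ml`, `pleocytic`, `composition`,
#'   and `absolute_count` = concentration x volume x 1000.
#' @export
generate_cohort <- function(n_samples, pleocytic_fraction = 0.245,
                            composition_presets = NULL, seed = 1,
                            force_concentration = NULL) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    param_error("n_samples must be >= 1")
  }
  stopifnot_scalar_prob(pleocytic_fraction, "pleocytic_fraction")
  n_samples <- as.integer(n_samples)
  set.seed(sub_seed(seed, "cohort"))
  pleo <- stats::runif(n_samples) < pleocytic_fraction
  conc <- numeric(n_samples)
  # truncated normocellular component: resample the few draws landing >= 5
  n_norm <- sum(!pleo)
  if (n_norm) {
    x <- stats::rlnorm(n_norm, log(1.5), 0.6)
    while (any(x >= 5)) x[x >= 5] <- stats::rlnorm(sum(x >= 5), log(1.5), 0.6)
    conc[!pleo] <- x
  }
  if (any(pleo)) conc[pleo] <- 5 + stats::rlnorm(sum(pleo), 2.14, 1.75)
  vol <- pmin(15, pmax(1, stats::rlnorm(n_samples, log(4), 0.4)))
  if (!is.null(force_concentration)) {
    conc <- rep_len(force_concentration, n_samples)
    pleo <- conc >= 5
  }
  lapply(seq_len(n_samples), function(i) {
    preset <- if (is.null(composition_presets)) {
      if (pleo[i]) "MS-like" else "control"
    } else {
      rep_len(composition_presets, n_samples)[i]
    }
    structure(list(
      sample_id = sprintf("S%04d", i),
      concentration = conc[i],
      volume_ml = vol[i],
      pleocytic = unname(pleo[i]),
      composition = composition_preset(preset),
      absolute_count = round(conc[i] * vol[i] * 1000)
    ), class = "csf_sample")
  })
}

#' Apply preanalytic cell loss to a sample
#'
#' Each of the sample's cells survives centrifugation independently with
#' probability `1 - loss_probability`, so the recovered count is
#' Binomial(absolute count, 1 - loss).
#'
#' @param sample A `csf_sample`.
#' @param params [preanalytics_params()].
#' @param seed Master seed (preanalytics substream).
#' @return Integer recovered cell count.
#' @export
apply_preanalytics <- function(sample, params = preanalytics_params(), seed = 1) {
  stopifnot(inherits(sample, "csf_sample"), sample$absolute_count >= 0)
  set.seed(sub_seed(seed, "preanalytics"))
  stats::rbinom(1, sample$absolute_count, 1 - params$loss_probability)
}

#' Load recovered cells onto a virtual chip
#'
#' Each cell gets a phenotype drawn by composition fractions, a true
#' expression value per marker from its population's lognormal component,
#' a uniform position on the chip (re-drawn, up to 20 times, if it lands
#' within 4 um of an already placed cell), and a cell area from size modes
#' (lymphocytes ~60 um^2, monocytes ~150 um^2, 15% CV).
#'
#' @param recovered_count Number of cells to place (>= 0).
#' @param composition List of [population_profile()] (fractions sum to 1).
#' @param geometry [chip_geometry()].
#' @param seed Master seed (loading substream).
#' @param sample_id Sample label carried into exports.
#' @return A `chip_experiment` with `cells` (data.frame: cell_id, phenotype,
#'   x, y, fov, size_um2), an `expression` matrix (cells x markers, true E),
#'   the panel, geometry, and an empty cycle stack.
#' @export
load_chip <- function(recovered_count, composition, geometry = chip_geometry(),
                      seed = 1, sample_id = "S0001") {
  if (recovered_count < 0) param_error("recovered_count must be >= 0")
  validate_composition(composition)
  set.seed(sub_seed(seed, "loading"))
  n <- as.integer(recovered_count)
  panel <- composition[[1]]$expression$marker
  fracs <- vapply(composition, function(p) p$fraction, numeric(1))
  pops <- vapply(composition, function(p) p$name, character(1))
  width <- geometry$fov_cols * geometry$fov_size_um
  height <- geometry$fov_rows * geometry$fov_size_um

  if (n == 0) {
    cells <- data.frame(cell_id = integer(), phenotype = character(),
                        x = numeric(), y = numeric(), fov = integer(),
                        size_um2 = numeric(), stringsAsFactors = FALSE)
    expr <- matrix(numeric(), 0, length(panel), dimnames = list(NULL, panel))
  } else {
    idx <- sample.int(length(pops), n, replace = TRUE, prob = fracs)
    xy <- draw_positions(n, width, height, min_sep = 4, max_retries = 20)
    is_mono <- grepl("monocyte", pops[idx], ignore.case = TRUE)
    size_mode <- ifelse(is_mono, 150, 60)
    size <- stats::rnorm(n, size_mode, 0.15 * size_mode)
    size <- pmax(size, 0.4 * size_mode)
    cells <- data.frame(
      cell_id = seq_len(n),
      phenotype = pops[idx],
      x = xy[, 1], y = xy[, 2],
      fov = fov_of(xy[, 1], xy[, 2], geometry),
      size_um2 = size,
      stringsAsFactors = FALSE
    )
    expr <- matrix(0, n, length(panel), dimnames = list(NULL, panel))
    for (j in seq_along(composition)) {
      sel <- idx == j
      if (!any(sel)) next
      e <- composition[[j]]$expression
      for (k in seq_along(panel)) {
        if (is.finite(e$meanlog[k])) {
          expr[sel, k] <- stats::rlnorm(sum(sel), e$meanlog[k], e$sdlog[k])
        } # negative state: E stays exactly 0
      }
    }
  }
  structure(list(
    sample_id = sample_id, geometry = geometry, panel = panel,
    composition = composition, cells = cells, expression = expr,
    cycles = NULL, seed = seed
  ), class = "chip_experiment")
}

# uniform positions with a minimum-separation re-draw (bounded retries);
# collisions that persist after max_retries are kept (dense chips overlap)
draw_positions <- function(n, width, height, min_sep = 4, max_retries = 20) {
  x <- stats::runif(n, 0, width)
  y <- stats::runif(n, 0, height)
  if (n > 1) {
    for (r in seq_len(max_retries)) {
      p <- close_pairs(x, y, x, y, min_sep)
      p <- p[p[, "i"] != p[, "j"], , drop = FALSE]
      if (!nrow(p)) break
      # re-draw the later member of each clashing pair
      redo <- unique(pmax(p[, "i"], p[, "j"]))
      x[redo] <- stats::runif(length(redo), 0, width)
      y[redo] <- stats::runif(length(redo), 0, height)
    }
  }
  cbind(x, y)
}

#' Map chip coordinates to FOV index
#'
#' FOVs are numbered row-major starting at 1 from the chip's top-left.
#'
#' @param x,y Coordinates in microns.
#' @param geometry [chip_geometry()].
#' @return Integer FOV indices.
#' @export
fov_of <- function(x, y, geometry) {
  col <- pmin(geometry$fov_cols - 1L, pmax(0L, floor(x / geometry$fov_size_um)))
  row <- pmin(geometry$fov_rows - 1L, pmax(0L, floor(y / geometry$fov_size_um)))
  as.integer(row * geometry$fov_cols + col + 1L)
}

#' Simulate iterative stain-image-bleach cycles
#'
#' One marker per cycle, in panel order. Before each cycle every attached
#' cell detaches with the (population-weighted) detachment probability; a
#' detached cell reattaches at a new uniform position with
#' `reattach_prob`, measurable from the following cycle on. Stained and
#' post-bleach MFIs follow the [cycle_kinetics()] model; negatively sampled
#' MFIs are clamped to 0 and counted.
#'
#' @param experiment A `chip_experiment` from [load_chip()].
#' @param kinetics [cycle_kinetics()].
#' @param seed Master seed (cycles substream).
#' @return The experiment with `cycles` filled: `present` (cells x cycles
#'   logical), `pos_x`/`pos_y` (cells x cycles), `mfi_stained` /
#'   `mfi_postbleach` (cells x cycles, NA where absent), per-cell
#'   autofluorescence `af`, per-FOV fields `illum_L` / `illum_B`,
#'   `true_reattached` / `true_detached` flags, and `n_clamped`.
#' @export
simulate_cycles <- function(experiment, kinetics = cycle_kinetics(), seed = 1) {
  stopifnot(inherits(experiment, "chip_experiment"))
  set.seed(sub_seed(seed, "cycles"))
  geom <- experiment$geometry
  panel <- experiment$panel
  n_cyc <- length(panel)
  n <- nrow(experiment$cells)
  width <- geom$fov_cols * geom$fov_size_um
  height <- geom$fov_rows * geom$fov_size_um

  af <- stats::rlnorm(n, kinetics$af_meanlog, kinetics$af_sdlog)
  L <- stats::rlnorm(geom$n_fov, 0, kinetics$illum_sdlog)
  B <- stats::runif(geom$n_fov, 0, kinetics$offset_max)

  p_det <- rep(kinetics$detach_prob, n)
  if (!is.null(kinetics$adhesion_weights) && n > 0) {
    w <- kinetics$adhesion_weights
    m <- match(experiment$cells$phenotype, names(w))
    scale <- ifelse(is.na(m), 1, 1 / w[m])
    p_det <- pmin(1, kinetics$detach_prob * scale)
  }

  present <- matrix(FALSE, n, n_cyc)
  pos_x <- matrix(NA_real_, n, n_cyc)
  pos_y <- matrix(NA_real_, n, n_cyc)
  mfi_s <- matrix(NA_real_, n, n_cyc)
  mfi_b <- matrix(NA_real_, n, n_cyc)
  attached <- rep(TRUE, n)
  gone <- rep(FALSE, n)          # detached for good
  pending <- rep(FALSE, n)       # reattached, visible from next cycle
  cur_x <- experiment$cells$x
  cur_y <- experiment$cells$y
  ever_detached <- rep(FALSE, n)
  reattached <- rep(FALSE, n)
  n_clamped <- 0L

  for (k in seq_len(n_cyc)) {
    if (n > 0) {
      # pending reattachments become visible this cycle
      attached[pending] <- TRUE
      pending <- rep(FALSE, n)
      # fluid exchange before imaging: shear detachment
      det <- attached & (stats::runif(n) < p_det)
      if (any(det)) {
        ever_detached[det] <- TRUE
        attached[det] <- FALSE
        re <- det & (stats::runif(n) < kinetics$reattach_prob) & !reattached
        gone[det & !re] <- TRUE
        if (any(re)) {
          reattached[re] <- TRUE
          pending[re] <- TRUE
          xy <- cbind(stats::runif(sum(re), 0, width),
                      stats::runif(sum(re), 0, height))
          cur_x[re] <- xy[, 1]
          cur_y[re] <- xy[, 2]
        }
      }
      idx <- which(attached)
      if (length(idx)) {
        present[idx, k] <- TRUE
        pos_x[idx, k] <- cur_x[idx]
        pos_y[idx, k] <- cur_y[idx]
        p <- fov_of(cur_x[idx], cur_y[idx], geom)
        e <- experiment$expression[idx, k]
        sig <- kinetics$gain * e
        s <- L[p] * (sig + af[idx]) + B[p] +
          stats::rnorm(length(idx), 0, kinetics$noise_sd)
        b <- L[p] * (kinetics$residual_dye * sig + af[idx]) + B[p] +
          stats::rnorm(length(idx), 0, kinetics$noise_sd)
        n_clamped <- n_clamped + sum(s < 0) + sum(b < 0)
        mfi_s[idx, k] <- pmax(s, 0)
        mfi_b[idx, k] <- pmax(b, 0)
      }
    }
  }
  experiment$cycles <- list(
    present = present, pos_x = pos_x, pos_y = pos_y,
    mfi_stained = mfi_s, mfi_postbleach = mfi_b,
    af = af, illum_L = L, illum_B = B,
    true_detached = ever_detached & !reattached,
    true_reattached = reattached,
    n_clamped = n_clamped, kinetics = kinetics
  )
  experiment
}

#' Export a chip experiment as a long per-cell-per-cycle table
#'
#' One row per (cell, cycle) where the cell is present: sample_id, cell_id,
#' cycle, marker, fov, x, y, size, mfi_stained, mfi_postbleach, present,
#' true_phenotype. Writable to CSV with [utils::write.csv()].
#'
#' @param experiment A `chip_experiment` with cycles simulated.
#' @return data.frame in the documented schema.
#' @export
experiment_table <- function(experiment) {
  cy <- experiment$cycles
  if (is.null(cy)) param_error("experiment has no simulated cycles")
  n <- nrow(experiment$cells)
  n_cyc <- length(experiment$panel)
  if (n == 0) {
    return(data.frame(sample_id = character(), cell_id = integer(),
                      cycle = integer(), marker = character(), fov = integer(),
                      x = numeric(), y = numeric(), size_um2 = numeric(),
                      mfi_stained = numeric(), mfi_postbleach = numeric(),
                      present = logical(), true_phenotype = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- which(cy$present, arr.ind = TRUE)
  rows <- rows[order(rows[, "row"], rows[, "col"]), , drop = FALSE]
  i <- rows[, "row"]; k <- rows[, "col"]
  data.frame(
    sample_id = experiment$sample_id,
    cell_id = experiment$cells$cell_id[i],
    cycle = as.integer(k),
    marker = experiment$panel[k],
    fov = fov_of(cy$pos_x[rows], cy$pos_y[rows], experiment$geometry),
    x = cy$pos_x[rows], y = cy$pos_y[rows],
    size_um2 = experiment$cells$size_um2[i],
    mfi_stained = cy$mfi_stained[rows],
    mfi_postbleach = cy$mfi_postbleach[rows],
    present = TRUE,
    true_phenotype = experiment$cells$phenotype[i],
    stringsAsFactors = FALSE
  )
}
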