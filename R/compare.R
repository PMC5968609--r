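# Bland-Altman method agreement between pipeline estimates and a reference
# method, and the end-to-end simulated recovery experiment.

#' Bland-Altman agreement analysis
#'
#' Differences are taken as reference minus chip, so a negative bias means
#' the chip method reads higher than the reference. Limits of agreement are
#' bias +/- 1.96 x the sample standard deviation (n - 1) of the differences;
#' no small-sample t-correction is applied.
#'
#' @param reference,chip Paired numeric vectors (n >= 2, finite).
#' @param label Optional quantity label carried into the result.
#' @return An `agreement_result`: `bias`, `loa_low`, `loa_high`, `sd_diff`,
#'   `n`, `differences`, `averages`, `label`.
#' @export
bland_altman <- function(reference, chip, label = "") {
  if (length(reference) != length(chip)) {
    stop(errorCondition("reference and chip vectors differ in length",
                        class = c("chipcsf_pairing_error", "error")))
  }
  ok <- is.finite(reference) & is.finite(chip)
  reference <- reference[ok]; chip <- chip[ok]
  if (length(reference) < 2) {
    stop(errorCondition("need >= 2 finite pairs for limits of agreement",
                        class = c("chipcsf_samplesize_error", "error")))
  }
  d <- reference - chip
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    n = length(d), differences = d, averages = (reference + chip) / 2,
    label = label
  ), class = "agreement_result")
}

#' Plot data for a Bland-Altman plot
#'
#' @param result An `agreement_result`.
#' @return data.frame with `average` and `difference` columns plus bias/LoA
#'   attributes, ready for a difference-vs-average plot.
#' @export
bland_altman_plot_data <- function(result) {
  stopifnot(inherits(result, "agreement_result"))
  out <- data.frame(average = result$averages, difference = result$differences)
  attr(out, "bias") <- result$bias
  attr(out, "loa") <- c(result$loa_low, result$loa_high)
  out
}

#' Simulated cross-validation recovery experiment
#'
#' For each virtual patient the configured composition is the reference
#' measurement (the simulated flow-cytometry ground truth, optionally with
#' measurement noise) and the full chip pipeline — preanalytic loss, chip
#' loading, cycle simulation, track QC, gating — yields the chip
#' measurement. Chips failing the sufficiency policy are excluded and
#' counted, mirroring the partially analyzable cross-validation subset.
#' Agreement is computed per population (T, B, monocytes) and for the
#' CD4:CD8 ratio.
#'
#' @param n_patients Number of virtual patients.
#' @param pleocytic_fraction Cohort mix passed to [generate_cohort()].
#' @param composition_presets Optional preset name(s) forwarded to
#'   [generate_cohort()] (e.g. a single preset so that cohorts differing in
#'   cellularity share one composition).
#' @param geometry,kinetics,policy Pipeline configuration.
#' @param flow_noise_sd Gaussian noise sd added to the reference
#'   percentages (percentage points), emulating flow-cytometry measurement
#'   error; default 1.
#' @param max_cells Cap on cells loaded per chip (keeps dense pleocytic
#'   chips tractable; default 8000).
#' @param seed Master seed.
#' @return List: `agreement` (named list of `agreement_result` for T, B,
#'   monocyte, cd4_cd8), `paired` (long data.frame of all pairs),
#'   `n_analyzable`, `n_excluded`.
#' @export
recovery_experiment <- function(n_patients, pleocytic_fraction = 0.245,
                                composition_presets = NULL,
                                geometry = chip_geometry(),
                                kinetics = cycle_kinetics(),
                                policy = sufficiency_policy(),
                                flow_noise_sd = 1, max_cells = 8000,
                                seed = 1) {
  cohort <- generate_cohort(n_patients, pleocytic_fraction,
                            composition_presets = composition_presets,
                            seed = seed)
  set.seed(sub_seed(seed, "compare"))
  pair_rows <- list()
  n_excl <- 0L
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    rec <- apply_preanalytics(s, seed = seed + i)
    exp <- load_chip(min(rec, max_cells), s$composition, geometry,
                     seed = seed + i, sample_id = s$sample_id)
    if (!assess_sufficiency(exp, policy)$sufficient) {
      n_excl <- n_excl + 1L
      next
    }
    exp <- simulate_cycles(exp, kinetics, seed = seed + i)
    tab <- assemble_cell_table(correct_experiment(exp))
    if (nrow(tab) < 2) { n_excl <- n_excl + 1L; next }
    gs <- population_stats(apply_gates(tab))
    chip_pct <- function(nm) sum(gs$percentages[intersect(nm, names(gs$percentages))])
    truth <- vapply(s$composition, function(p) p$fraction, numeric(1))
    names(truth) <- vapply(s$composition, function(p) p$name, character(1))
    tpops <- function(pat) 100 * sum(truth[grepl(pat, names(truth))])
    ref_T <- tpops("^CD4|^CD8|^T")
    ref_B <- tpops("^B|plasmablast")
    ref_M <- tpops("monocyte")
    cd4_t <- 100 * sum(truth[grepl("^CD4", names(truth))])
    cd8_t <- 100 * sum(truth[grepl("^CD8", names(truth))])
    ref_ratio <- if (cd8_t > 0) cd4_t / cd8_t else NA_real_
    noise <- stats::rnorm(3, 0, flow_noise_sd)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      sample_id = s$sample_id,
      pleocytic = s$pleocytic,
      quantity = c("T", "B", "monocyte", "cd4_cd8"),
      reference = c(ref_T + noise[1], ref_B + noise[2], ref_M + noise[3],
                    ref_ratio),
      chip = c(chip_pct(c("T_CD4", "T_CD4_Tcm", "T_CD8", "T_other")),
               chip_pct(c("B", "B_memory_switched", "plasmablast")),
               chip_pct("monocyte"),
               gs$cd4_cd8_ratio),
      stringsAsFactors = FALSE
    )
  }
  paired <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(sample_id = character(), pleocytic = logical(),
               quantity = character(), reference = numeric(), chip = numeric())
  agreement <- list()
  for (q in unique(paired$quantity)) {
    sel <- paired[paired$quantity == q, ]
    if (nrow(sel) >= 2) {
      agreement[[q]] <- bland_altman(sel$reference, sel$chip, label = q)
    }
  }
  list(agreement = agreement, paired = paired,
       n_analyzable = length(pair_rows), n_excluded = n_excl)
}
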