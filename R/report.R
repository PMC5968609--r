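# Chip cell-density sufficiency, cohort-stratified sufficiency tables, and
# protocol time budgets.

#' Sufficiency policy
#'
#' A chip is analyzable only when enough cells land in each microscope
#' position; below the cut-off the chip is discarded. The default cut-off
#' is 20 cells per field of view, aggregated as the mean over FOVs (a
#' per-FOV minimum rule is available by configuration).
#'
#' @param min_cells_per_fov Cut-off (> 0), default 20.
#' @param aggregation `"mean"` (default) or `"min"` over FOVs.
#' @return A `sufficiency_policy` list.
#' @export
sufficiency_policy <- function(min_cells_per_fov = 20,
                               aggregation = c("mean", "min")) {
  if (min_cells_per_fov <= 0) param_error("min_cells_per_fov must be > 0")
  structure(list(min_cells_per_fov = min_cells_per_fov,
                 aggregation = match.arg(aggregation)),
            class = "sufficiency_policy")
}

#' Assess whether a loaded chip has sufficient cell density
#'
#' @param experiment A `chip_experiment` (cycles not required).
#' @param policy [sufficiency_policy()].
#' @return List: `sufficient` (>= cut-off, inclusive), `cells_per_fov`
#'   (the aggregated density), `n_cells`, `n_fov`.
#' @export
assess_sufficiency <- function(experiment, policy = sufficiency_policy()) {
  stopifnot(inherits(experiment, "chip_experiment"))
  n <- nrow(experiment$cells)
  n_fov <- experiment$geometry$n_fov
  dens <- if (policy$aggregation == "mean") {
    n / n_fov
  } else {
    min(tabulate(experiment$cells$fov, nbins = n_fov))
  }
  list(sufficient = dens >= policy$min_cells_per_fov,
       cells_per_fov = dens, n_cells = n, n_fov = n_fov)
}

.CONC_STRATA <- data.frame(
  stratum = c("<5", ">=5", ">=10", ">=30", ">=50"),
  lower = c(-Inf, 5, 10, 30, 50),
  upper = c(5, Inf, Inf, Inf, Inf)
)
.ABS_STRATA <- data.frame(
  stratum = c("<10000", ">=10000", ">=50000", ">=100000"),
  lower = c(-Inf, 1e4, 5e4, 1e5),
  upper = c(1e4, Inf, Inf, Inf)
)

#' Cohort-stratified sufficiency report
#'
#' Counts and one-decimal percentages of chips with sufficient cell density,
#' stratified by CSF cell concentration (<5, >=5, >=10, >=30, >=50 per ul)
#' and by absolute cell count (<10000, >=10000, >=50000, >=100000), plus an
#' all-samples row. The ">=" strata are cumulative (overlapping), so
#' sufficient counts are non-increasing along >=5, >=10, >=30, >=50.
#'
#' @param cohort data.frame with columns `concentration` (cells/ul),
#'   `absolute_count`, and logical `sufficient`.
#' @return data.frame: `group` ("concentration", "absolute", "all"),
#'   `stratum`, `n`, `sufficient_n`, `pct` (one decimal).
#' @export
stratified_report <- function(cohort) {
  if (!nrow(cohort)) {
    return(data.frame(group = character(), stratum = character(),
                      n = integer(), sufficient_n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("concentration", "absolute_count", "sufficient") %in%
                  names(cohort)))
  one <- function(group, strata, value) {
    do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
      sel <- value >= strata$lower[i] & value < strata$upper[i]
      data.frame(group = group, stratum = strata$stratum[i],
                 n = sum(sel), sufficient_n = sum(cohort$sufficient[sel]),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(
    one("concentration", .CONC_STRATA, cohort$concentration),
    one("absolute", .ABS_STRATA, cohort$absolute_count),
    data.frame(group = "all", stratum = "all", n = nrow(cohort),
               sufficient_n = sum(cohort$sufficient), stringsAsFactors = FALSE)
  )
  out$pct <- proportion_pct(out$sufficient_n, out$n)
  out
}

#' Sufficiency report from published count pairs
#'
#' Computes the report's percentages directly from (n, sufficient_n) count
#' pairs, as when re-deriving a printed table rather than simulating chips.
#'
#' @param counts data.frame with columns `stratum`, `n`, `sufficient_n`
#'   (and optionally `group`).
#' @return The same data.frame with a `pct` column (one decimal, half-up).
#' @export
stratified_report_from_counts <- function(counts) {
  stopifnot(all(c("n", "sufficient_n") %in% names(counts)))
  if (any(counts$sufficient_n > counts$n)) {
    param_error("sufficient_n exceeds n in some stratum")
  }
  counts$pct <- proportion_pct(counts$sufficient_n, counts$n)
  counts
}

#' Cohort bookkeeping summary
#'
#' Percentages (one decimal) of normocellular (< 5/ul) and pleocytic
#' (>= 5/ul) samples and of samples with >= `abs_cutoff` absolute cells.
#'
#' @param cohort data.frame with `concentration` and `absolute_count`
#'   columns, or a list of `csf_sample` objects.
#' @param abs_cutoff Absolute-count threshold (default 10000).
#' @return List with `n`, `normocellular_n`/`pct`, `pleocytic_n`/`pct`,
#'   `abs_over_n`/`pct`.
#' @export
cohort_summary <- function(cohort, abs_cutoff = 10000) {
  if (!is.data.frame(cohort)) {
    cohort <- data.frame(
      concentration = vapply(cohort, `[[`, numeric(1), "concentration"),
      absolute_count = vapply(cohort, `[[`, numeric(1), "absolute_count")
    )
  }
  n <- nrow(cohort)
  nn <- sum(cohort$concentration < 5)
  pn <- n - nn
  an <- sum(cohort$absolute_count >= abs_cutoff)
  list(n = n,
       normocellular_n = nn, normocellular_pct = proportion_pct(nn, n),
       pleocytic_n = pn, pleocytic_pct = proportion_pct(pn, n),
       abs_over_n = an, abs_over_pct = proportion_pct(an, n))
}

#' Protocol time budget for the bleaching step
#'
#' Bleaching is the rate-limiting step of each stain-image-bleach cycle:
#' 30 s per microscope position in the current instrument setting, so 50
#' positions cost 25 minutes of bleaching per cycle.
#'
#' @param positions Number of scanned positions (> 0).
#' @param cycles Number of staining cycles (> 0).
#' @param bleach_seconds_per_position Default 30.
#' @return List: `minutes_per_cycle`, `total_minutes`.
#' @export
time_budget <- function(positions, cycles = 1, bleach_seconds_per_position = 30) {
  if (positions <= 0 || cycles <= 0 || bleach_seconds_per_position <= 0) {
    param_error("positions, cycles and bleach seconds must all be > 0")
  }
  per_cycle <- positions * bleach_seconds_per_position / 60
  list(minutes_per_cycle = per_cycle, total_minutes = per_cycle * cycles)
}
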