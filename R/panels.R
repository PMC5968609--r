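# Marker panels, population expression profiles, and gating band thresholds.
#
# Expression is modelled per population and marker as an ordinal state
# (negative / low / positive / high) realised as a lognormal component in
# arbitrary fluorescence units (AU). The instrument reports no absolute
# units, only ordinal gates, so the component means are decade-spaced modes:
#   negative -> true expression E = 0 (any measured signal is pure
#               autofluorescence + background),
#   low      -> mode ~150 AU (the CD19^low plasmablast niche),
#   positive -> mode ~1100 AU,
#   high     -> mode ~8200 AU,
# with log-sd 0.25 (natural log). Band thresholds sit at the geometric
# midpoints between adjacent modes.

.STATE_MEANLOG <- c(negative = -Inf, low = log(150), positive = log(1100),
                    high = log(8200))
.STATE_SDLOG <- 0.25

#' Standard 11-marker Chipcytometry panel
#'
#' The surface-marker panel used for routine CSF immunophenotyping:
#' CD3, CD4, CD8, CD14, CD19, CD24, CD27, CD38, CD45RA, CD56, HLA-DR.
#' One marker is stained, imaged and bleached per cycle.
#'
#' @param extended If `TRUE`, append the B-cell immunoglobulin / light-chain
#'   extension (IgA, IgD, IgM, IgG, Kappa, Lambda) used when a clonal B-cell
#'   process is suspected.
#' @return Character vector of marker names in staining order.
#' @export
standard_panel <- function(extended = FALSE) {
  base <- c("CD3", "CD4", "CD8", "CD14", "CD19", "CD24", "CD27", "CD38",
            "CD45RA", "CD56", "HLA-DR")
  if (extended) c(base, c("IgA", "IgD", "IgM", "IgG", "Kappa", "Lambda")) else base
}

#' Build a population expression profile
#'
#' @param name Population label.
#' @param fraction Proportion of leukocytes in `[0, 1]`.
#' @param states Named character vector marker -> state in
#'   `c("negative", "low", "positive", "high")`. Markers of the panel absent
#'   from `states` default to `"negative"`.
#' @param panel Marker panel the profile must cover.
#' @param sdlog Log-sd of the lognormal expression component (must be > 0).
#' @return A `population_profile` list with `name`, `fraction` and an
#'   `expression` data.frame (marker, state, meanlog, sdlog).
#' @export
population_profile <- function(name, fraction, states, panel = standard_panel(),
                               sdlog = .STATE_SDLOG) {
  if (fraction < 0 || fraction > 1) param_error("fraction must be in [0, 1]")
  if (sdlog <= 0) param_error("sdlog must be > 0")
  bad <- setdiff(names(states), panel)
  if (length(bad)) param_error("states for markers not in panel: ",
                               paste(bad, collapse = ", "))
  st <- setNames(rep("negative", length(panel)), panel)
  st[names(states)] <- states
  if (!all(st %in% names(.STATE_MEANLOG))) param_error("unknown expression state")
  structure(list(
    name = name,
    fraction = fraction,
    expression = data.frame(
      marker = panel,
      state = unname(st),
      meanlog = unname(.STATE_MEANLOG[st]),
      sdlog = sdlog,
      stringsAsFactors = FALSE
    )
  ), class = "population_profile")
}

#' Validate a composition (a list of population profiles)
#'
#' Checks that fractions sum to 1 within 1e-9 and that every profile covers
#' the same panel.
#'
#' @param composition List of [population_profile()] objects.
#' @return The composition, invisibly, or an error.
#' @export
validate_composition <- function(composition) {
  stopifnot(length(composition) >= 1)
  tot <- sum(vapply(composition, function(p) p$fraction, numeric(1)))
  if (abs(tot - 1) > 1e-9) {
    param_error("population fractions sum to ", format(tot), ", expected 1")
  }
  panels <- lapply(composition, function(p) p$expression$marker)
  if (!all(vapply(panels, identical, logical(1), panels[[1]]))) {
    param_error("profiles cover different panels")
  }
  invisible(composition)
}

# internal: build a composition from a compact list(name = list(fraction, states))
.build_composition <- function(entries, panel) {
  profs <- lapply(names(entries), function(nm) {
    population_profile(nm, entries[[nm]]$fraction, entries[[nm]]$states, panel = panel)
  })
  validate_composition(profs)
  profs
}

#' Preset CSF population compositions
#'
#' Named presets of population mixes with marker expression per population:
#' * `"MS-like"`: CD4-dominated T cells mostly of central-memory phenotype
#'   (CD27+ CD45RA-), an expanded B compartment with class-switched memory
#'   cells and plasmablasts (CD19 low, CD27+, CD38 high), few monocytes —
#'   the picture of an inflammatory CNS disorder.
#' * `"control"`: normocellular non-inflammatory mix; T-cell dominated,
#'   scarce B cells, relatively more monocytes.
#' * `"lymphoma-like"`: a dominant clonal IgM+ lambda-restricted B-cell
#'   population over a small polyclonal background (extended panel).
#'
#' @param name Preset name.
#' @return List of [population_profile()] objects (fractions sum to 1).
#' @export
composition_preset <- function(name = c("MS-like", "control", "lymphoma-like")) {
  name <- match.arg(name)
  pos <- "positive"
  t_base <- c(CD3 = pos)
  if (name == "MS-like") {
    panel <- standard_panel()
    entries <- list(
      CD4_Tcm = list(fraction = 0.40, states = c(t_base, CD4 = pos, CD27 = pos)),
      CD4_naive = list(fraction = 0.17, states = c(t_base, CD4 = pos, CD27 = pos,
                                                   CD45RA = pos)),
      CD8_T = list(fraction = 0.21, states = c(t_base, CD8 = pos, CD27 = pos,
                                               CD45RA = pos)),
      B_memory_switched = list(fraction = 0.075, states = c(
        CD19 = pos, CD24 = pos, CD27 = pos, "HLA-DR" = pos)),
      B_naive = list(fraction = 0.030, states = c(
        CD19 = pos, CD24 = pos, "HLA-DR" = pos)),
      plasmablast = list(fraction = 0.018, states = c(
        CD19 = "low", CD27 = pos, CD38 = "high", "HLA-DR" = pos)),
      monocyte = list(fraction = 0.015, states = c(
        CD14 = pos, CD4 = "low", "HLA-DR" = pos)),
      NK = list(fraction = 0.042, states = c(CD56 = pos, CD38 = pos)),
      DC = list(fraction = 0.040, states = c("HLA-DR" = "high", CD4 = "low"))
    )
  } else if (name == "control") {
    panel <- standard_panel()
    entries <- list(
      CD4_Tcm = list(fraction = 0.36, states = c(t_base, CD4 = pos, CD27 = pos)),
      CD4_naive = list(fraction = 0.20, states = c(t_base, CD4 = pos, CD27 = pos,
                                                   CD45RA = pos)),
      CD8_T = list(fraction = 0.24, states = c(t_base, CD8 = pos, CD27 = pos,
                                               CD45RA = pos)),
      B_naive = list(fraction = 0.015, states = c(
        CD19 = pos, CD24 = pos, "HLA-DR" = pos)),
      monocyte = list(fraction = 0.10, states = c(
        CD14 = pos, CD4 = "low", "HLA-DR" = pos)),
      NK = list(fraction = 0.055, states = c(CD56 = pos, CD38 = pos)),
      DC = list(fraction = 0.030, states = c("HLA-DR" = "high", CD4 = "low"))
    )
  } else {
    panel <- standard_panel(extended = TRUE)
    bcl <- c(CD19 = pos, CD24 = pos, "HLA-DR" = pos)
    entries <- list(
      B_clonal_lambda = list(fraction = 0.80, states = c(
        bcl, CD27 = pos, IgM = pos, Lambda = pos)),
      B_poly_kappa = list(fraction = 0.024, states = c(bcl, IgD = pos, IgM = pos,
                                                       Kappa = pos)),
      B_poly_lambda = list(fraction = 0.016, states = c(bcl, IgD = pos, IgM = pos,
                                                        Lambda = pos)),
      CD4_T = list(fraction = 0.09, states = c(t_base, CD4 = pos, CD27 = pos)),
      CD8_T = list(fraction = 0.04, states = c(t_base, CD8 = pos, CD27 = pos,
                                               CD45RA = pos)),
      monocyte = list(fraction = 0.02, states = c(
        CD14 = pos, CD4 = "low", "HLA-DR" = pos)),
      NK = list(fraction = 0.01, states = c(CD56 = pos, CD38 = pos))
    )
  }
  .build_composition(entries, panel)
}

#' Default per-marker gating band thresholds
#'
#' Bands on log10(corrected MFI + 1): negative below `th_low`, low in
#' `[th_low, th_pos)`, positive in `[th_pos, th_high)`, high at or above
#' `th_high`. Defaults sit at the geometric midpoints between the simulator's
#' expression modes (negative/low boundary anchored just above the corrected
#' noise floor): 45, 410, 3000 AU.
#'
#' @param markers Character vector of marker names.
#' @return data.frame with columns marker, th_low, th_pos, th_high (log10 AU).
#' @export
default_thresholds <- function(markers = standard_panel(extended = TRUE)) {
  data.frame(
    marker = markers,
    th_low = log10(45 + 1),
    th_pos = log10(410 + 1),
    th_high = log10(3000 + 1),
    stringsAsFactors = FALSE
  )
}
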