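# Bleach-subtraction background correction, cross-cycle track matching, and
# exclusion of artificial phenotypes.
#
# The artificial-phenotype hazard: a cell detected in early cycles that
# detaches mid-experiment shows zero expression for every later marker; a
# cell that reattaches elsewhere shows zero expression for every earlier
# marker. Both would masquerade as exotic marker-negative phenotypes, so
# cells are retained only when present, at a spatially consistent position,
# in every cycle of the panel. The original workflow excluded such cells by
# manual review; here the rules are deterministic.

#' Bleach subtraction
#'
#' The post-bleach MFI — autofluorescence plus local illumination background,
#' with the dye bleached away — is subtracted from the stained MFI, removing
#' the per-cell autofluorescence term and the additive per-FOV offset.
#' Negative differences (noise around a true zero) are floored at 0 and
#' flagged; the signed difference is kept alongside because diagnostics on
#' true-negative populations need the unfloored mean.
#'
#' @param raw_mfi Stained MFI vector (>= 0).
#' @param postbleach_mfi Post-bleach MFI vector, same length/pairing.
#' @return data.frame with `corrected` (floored at 0), `corrected_signed`,
#'   and `negative` (flag: difference was < 0).
#' @export
bleach_subtract <- function(raw_mfi, postbleach_mfi) {
  if (length(raw_mfi) != length(postbleach_mfi)) {
    stop(errorCondition("raw and post-bleach vectors differ in length",
                        class = c("chipcsf_pairing_error", "error")))
  }
  if (any(raw_mfi < 0, na.rm = TRUE) || any(postbleach_mfi < 0, na.rm = TRUE)) {
    param_error("MFIs must be >= 0")
  }
  d <- raw_mfi - postbleach_mfi
  data.frame(corrected = pmax(d, 0), corrected_signed = d,
             negative = !is.na(d) & d < 0)
}

#' Link detections across cycles into tracks
#'
#' Greedy nearest-neighbour linking from cycle k to k+1 within a matching
#' radius. Candidate links are sorted by distance (ties by smaller source
#' cell id); each detection joins at most one track. Later-cycle detections
#' left unmatched start new tracks — the candidate reattached cells.
#'
#' @param detections data.frame with columns `cycle`, `x`, `y` and a
#'   per-cycle detection id column `det_id` (unique within a cycle); extra
#'   columns are carried along.
#' @param radius Matching radius in um (> 0). Default 5, about half a
#'   lymphocyte diameter.
#' @param n_cycles Total number of cycles (default: max observed).
#' @return `detections` with a `track_id` column; tracks are numbered by
#'   first appearance.
#' @export
match_tracks <- function(detections, radius = 5, n_cycles = NULL) {
  if (!is.numeric(radius) || radius <= 0) param_error("radius must be > 0")
  stopifnot(all(c("cycle", "x", "y", "det_id") %in% names(detections)))
  if (!nrow(detections)) {
    detections$track_id <- integer()
    return(detections)
  }
  if (is.null(n_cycles)) n_cycles <- max(detections$cycle)
  detections <- detections[order(detections$cycle, detections$det_id), ]
  detections$track_id <- NA_integer_
  next_track <- 1L
  first <- detections$cycle == min(detections$cycle)
  detections$track_id[first] <- seq_len(sum(first))
  next_track <- sum(first) + 1L
  cycles <- sort(unique(detections$cycle))
  for (ci in seq_along(cycles)[-1]) {
    prev <- which(detections$cycle == cycles[ci - 1])
    cur <- which(detections$cycle == cycles[ci])
    if (length(prev) && length(cur)) {
      cand <- close_pairs(detections$x[prev], detections$y[prev],
                          detections$x[cur], detections$y[cur], radius)
      if (nrow(cand)) {
        ord <- order(cand[, "d"], detections$det_id[prev[cand[, 1]]])
        cand <- cand[ord, , drop = FALSE]
        used_p <- rep(FALSE, length(prev))
        used_c <- rep(FALSE, length(cur))
        for (r in seq_len(nrow(cand))) {
          ip <- cand[r, 1]; ic <- cand[r, 2]
          if (!used_p[ip] && !used_c[ic]) {
            detections$track_id[cur[ic]] <- detections$track_id[prev[ip]]
            used_p[ip] <- TRUE
            used_c[ic] <- TRUE
          }
        }
      }
    }
    new <- cur[is.na(detections$track_id[cur])]
    if (length(new)) {
      detections$track_id[new] <- seq.int(next_track, length.out = length(new))
      next_track <- next_track + length(new)
    }
  }
  attr(detections, "n_cycles") <- n_cycles
  detections
}

# all (i, j) pairs with distance <= radius between point sets 1 and 2,
# via spatial binning at the radius scale (avoids the dense n1 x n2 matrix)
close_pairs <- function(x1, y1, x2, y2, radius) {
  bkey <- function(bx, by) (bx + 4096) * 1e5 + (by + 4096)
  b2 <- bkey(floor(x2 / radius), floor(y2 / radius))
  groups <- split(seq_along(x2), b2)
  ukeys <- as.numeric(names(groups))
  bx1 <- floor(x1 / radius); by1 <- floor(y1 / radius)
  out_i <- list(); out_j <- list()
  for (dx in -1:1) for (dy in -1:1) {
    pos <- match(bkey(bx1 + dx, by1 + dy), ukeys)
    hit <- which(!is.na(pos))
    if (!length(hit)) next
    g <- groups[pos[hit]]
    ni <- lengths(g)
    out_i[[length(out_i) + 1L]] <- rep.int(hit, ni)
    out_j[[length(out_j) + 1L]] <- unlist(g, use.names = FALSE)
  }
  i <- unlist(out_i); j <- unlist(out_j)
  if (!length(i)) return(matrix(numeric(), 0, 3, dimnames = list(NULL, c("i", "j", "d"))))
  d <- sqrt((x1[i] - x2[j])^2 + (y1[i] - y2[j])^2)
  ok <- d <= radius
  cbind(i = i[ok], j = j[ok], d = d[ok])
}

#' Flag artificial phenotypes by track completeness
#'
#' A track is retained only if it spans every cycle from the first to the
#' last: tracks that start after cycle 1 are candidate reattached cells
#' (`excluded_reattached`), tracks that end before the final cycle are lost
#' cells (`excluded_partial_track`) whose later markers would read as
#' spuriously negative.
#'
#' @param tracks Output of [match_tracks()].
#' @param n_cycles Number of cycles in the panel (>= 1); defaults to the
#'   value recorded by [match_tracks()].
#' @return data.frame, one row per track: `track_id`, `first_cycle`,
#'   `last_cycle`, `n_obs`, `qc_status` in
#'   `c("retained", "excluded_partial_track", "excluded_reattached")`.
#' @export
flag_artificial <- function(tracks, n_cycles = attr(tracks, "n_cycles")) {
  if (is.null(n_cycles) || n_cycles < 1) param_error("n_cycles must be >= 1")
  if (!nrow(tracks)) {
    return(data.frame(track_id = integer(), first_cycle = integer(),
                      last_cycle = integer(), n_obs = integer(),
                      qc_status = character(), stringsAsFactors = FALSE))
  }
  sp <- split(tracks$cycle, tracks$track_id)
  first <- vapply(sp, min, numeric(1))
  last <- vapply(sp, max, numeric(1))
  nobs <- lengths(sp)
  status <- ifelse(first > 1, "excluded_reattached",
                   ifelse(nobs < n_cycles, "excluded_partial_track", "retained"))
  data.frame(track_id = as.integer(names(sp)), first_cycle = as.integer(first),
             last_cycle = as.integer(last), n_obs = as.integer(nobs),
             qc_status = status, row.names = NULL, stringsAsFactors = FALSE)
}

#' Run table-mode correction and QC on a simulated experiment
#'
#' The table-mode pipeline: per-cycle detections are taken from the
#' simulator's presence flags and positions, linked into tracks, QC'd for
#' artificial phenotypes, and bleach-subtracted into a per-cell corrected
#' MFI matrix.
#'
#' @param experiment A `chip_experiment` with simulated cycles.
#' @param radius Matching radius for [match_tracks()] (um).
#' @return A `cell_records` list: `records` (per-track data.frame with
#'   qc_status and, for retained tracks, one corrected-MFI column per
#'   marker), `tracks`, `qc` (a summary with counts per status and the
#'   negativity rate), and `panel`.
#' @export
correct_experiment <- function(experiment, radius = 5) {
  cy <- experiment$cycles
  if (is.null(cy)) param_error("experiment has no simulated cycles")
  n_cyc <- length(experiment$panel)
  pres <- which(cy$present, arr.ind = TRUE)
  det <- data.frame(
    cycle = as.integer(pres[, "col"]),
    det_id = as.integer(pres[, "row"]),
    x = cy$pos_x[pres], y = cy$pos_y[pres],
    sim_cell = as.integer(pres[, "row"]),
    mfi_stained = cy$mfi_stained[pres],
    mfi_postbleach = cy$mfi_postbleach[pres],
    stringsAsFactors = FALSE
  )
  tracks <- match_tracks(det, radius = radius, n_cycles = n_cyc)
  flags <- flag_artificial(tracks, n_cycles = n_cyc)

  corr <- bleach_subtract(tracks$mfi_stained, tracks$mfi_postbleach)
  tracks$corrected <- corr$corrected
  tracks$corrected_signed <- corr$corrected_signed

  rec <- flags
  mfi_mat <- matrix(NA_real_, nrow(flags), n_cyc,
                    dimnames = list(NULL, experiment$panel))
  row_of <- match(tracks$track_id, flags$track_id)
  mfi_mat[cbind(row_of, tracks$cycle)] <- tracks$corrected
  # tracks are ordered by cycle: the first occurrence is each track's start
  firsts <- tracks[!duplicated(tracks$track_id), ]
  fo <- match(flags$track_id, firsts$track_id)
  rec$size_um2 <- experiment$cells$size_um2[firsts$sim_cell[fo]]
  rec$x <- firsts$x[fo]
  rec$y <- firsts$y[fo]
  rec$true_phenotype <- experiment$cells$phenotype[firsts$sim_cell[fo]]
  rec$sim_cell <- firsts$sim_cell[fo]
  rec <- cbind(rec, as.data.frame(mfi_mat, check.names = FALSE))

  structure(list(
    records = rec, tracks = tracks, panel = experiment$panel,
    qc = list(
      n_tracks = nrow(flags),
      n_retained = sum(flags$qc_status == "retained"),
      n_excluded_partial = sum(flags$qc_status == "excluded_partial_track"),
      n_excluded_reattached = sum(flags$qc_status == "excluded_reattached"),
      negativity_rate = mean(corr$negative),
      n_clamped_sim = cy$n_clamped
    )
  ), class = "cell_records")
}

#' Assemble the retained-cell corrected-MFI table
#'
#' One row per retained cell, one column per marker, plus cell id, size and
#' first-cycle coordinates. After QC no retained cell can have a missing
#' marker value.
#'
#' @param records A `cell_records` object from [correct_experiment()].
#' @return data.frame with columns `cell_id`, `x`, `y`, `size_um2`,
#'   `true_phenotype`, then one column per marker.
#' @export
assemble_cell_table <- function(records) {
  stopifnot(inherits(records, "cell_records"))
  rec <- records$records
  if (anyDuplicated(rec$track_id)) {
    stop(errorCondition("duplicate cell ids in records",
                        class = c("chipcsf_integrity_error", "error")))
  }
  keep <- rec[rec$qc_status == "retained", , drop = FALSE]
  out <- data.frame(cell_id = keep$track_id, x = keep$x, y = keep$y,
                    size_um2 = keep$size_um2,
                    true_phenotype = keep$true_phenotype,
                    stringsAsFactors = FALSE)
  cbind(out, keep[, records$panel, drop = FALSE])
}
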