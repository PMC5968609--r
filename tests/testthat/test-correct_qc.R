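# Bleach subtraction, track matching, artificial-phenotype QC.

test_that("bleach subtraction is exact arithmetic with a floored negative flag", {
  expect_equal(bleach_subtract(500, 120)$corrected, 380)
  r <- bleach_subtract(c(100, 50), c(100, 80))
  expect_equal(r$corrected, c(0, 0))
  expect_equal(r$corrected_signed, c(0, -30))
  expect_identical(r$negative, c(FALSE, TRUE))
  expect_error(bleach_subtract(1:3, 1:2), class = "chipcsf_pairing_error")
  expect_error(bleach_subtract(-1, 0), class = "chipcsf_param_error")
})

test_that("corrected MFI removes autofluorescence and additive background", {
  # true-negative population: E = 0 for every marker, yet heavy per-cell
  # autofluorescence and per-FOV offsets
  comp <- list(population_profile("neg", 1, c(M1 = "negative"),
                                  panel = c("M1", "M2")))
  e <- load_chip(10000, comp, chip_geometry(10, 10), seed = 31)

  # noise-free: exact invariance to A_i and B_p
  k0 <- cycle_kinetics(noise_sd = 0, detach_prob = 0, af_meanlog = log(500),
                       offset_max = 100)
  s0 <- simulate_cycles(e, k0, seed = 31)
  d0 <- s0$cycles$mfi_stained - s0$cycles$mfi_postbleach
  expect_true(all(abs(d0) < 1e-9))

  # with default noise: signed mean ~ 0 within 3 standard errors
  k1 <- cycle_kinetics(detach_prob = 0, af_meanlog = log(500), offset_max = 100)
  s1 <- simulate_cycles(e, k1, seed = 32)
  corr <- bleach_subtract(as.vector(s1$cycles$mfi_stained),
                          as.vector(s1$cycles$mfi_postbleach))
  se <- stats::sd(corr$corrected_signed) / sqrt(length(corr$corrected_signed))
  expect_lt(abs(mean(corr$corrected_signed)), 3 * se)
})

test_that("track matching equals brute-force assignment on a toy reattachment", {
  expect_error(match_tracks(data.frame(cycle = 1, det_id = 1, x = 0, y = 0),
                            radius = 0), class = "chipcsf_param_error")

  # single cycle: every detection a length-1 track
  one <- match_tracks(data.frame(cycle = 1, det_id = 1:4,
                                 x = c(0, 10, 20, 30), y = 0), radius = 5)
  expect_equal(sort(one$track_id), 1:4)

  # static positions, no detachment: all tracks full-length
  comp <- toy_composition(0.5)
  sim <- simulate_cycles(load_chip(300, comp, seed = 33),
                         noiseless_kinetics(), seed = 33)
  cr <- correct_experiment(sim)
  expect_equal(cr$qc$n_retained, 300)
  expect_equal(cr$qc$n_tracks, 300)

  # 5 cells x 3 cycles, one cell detaches after cycle 2 and reattaches far
  # away in cycle 3: greedy linking must equal the exhaustive
  # minimal-total-distance assignment
  det <- data.frame(
    cycle = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 3),
    det_id = c(1:5, 1:5, 1:5),
    x = c(0, 30, 60, 90, 120, 0.4, 30.2, 59.8, 90.1, 120.3,
          0.1, 29.9, 60.2, 89.8, 200),
    y = c(rep(0, 10), 0.2, -0.1, 0.1, 0, 50)
  )
  got <- match_tracks(det, radius = 5, n_cycles = 3)
  oracle <- brute_force_tracks(det, radius = 5, n_cycles = 3)
  # same partition of detections into tracks
  expect_equal(rand_index(got$track_id, oracle), 1)
  flags <- flag_artificial(got, n_cycles = 3)
  expect_equal(sum(flags$qc_status == "retained"), 4)
  expect_equal(sum(flags$qc_status == "excluded_partial_track"), 1)
  expect_equal(sum(flags$qc_status == "excluded_reattached"), 1)
})

test_that("artificial-phenotype flags follow track completeness", {
  tr <- data.frame(cycle = c(1:10, 1:3, 4:10),
                   det_id = 1, x = 0, y = 0,
                   track_id = c(rep(1L, 10), rep(2L, 3), rep(3L, 7)))
  flags <- flag_artificial(tr, n_cycles = 10)
  expect_equal(flags$qc_status[flags$track_id == 1], "retained")
  expect_equal(flags$qc_status[flags$track_id == 2], "excluded_partial_track")
  expect_equal(flags$qc_status[flags$track_id == 3], "excluded_reattached")
  expect_error(flag_artificial(tr, n_cycles = 0), class = "chipcsf_param_error")
})

test_that("QC recall for simulated reattached cells is high at default radius", {
  sim <- tiny_experiment(n = 3000, seed = 35,
                         kinetics = cycle_kinetics(detach_prob = 0.05,
                                                   reattach_prob = 0.5))
  cr <- correct_experiment(sim)
  cy <- sim$cycles
  # ground truth: reattached cells visible in at least one post-gap cycle
  visible_reattached <- which(cy$true_reattached & vapply(
    seq_len(nrow(cy$present)), function(i) {
      p <- cy$present[i, ]
      gap <- match(FALSE, p)
      !is.na(gap) && any(p[seq_along(p) > gap])
    }, logical(1)))
  rec <- cr$records
  caught <- vapply(visible_reattached, function(cell) {
    any(rec$qc_status[rec$sim_cell == cell] == "excluded_reattached")
  }, logical(1))
  expect_gte(length(visible_reattached), 50)
  expect_gte(mean(caught), 0.95)
})

test_that("QC exclusion rate grows with detachment probability", {
  rates <- vapply(c(0, 0.02, 0.08, 0.2), function(p) {
    sim <- tiny_experiment(n = 600, seed = 36,
                           kinetics = cycle_kinetics(detach_prob = p))
    qc <- correct_experiment(sim)$qc
    1 - qc$n_retained / qc$n_tracks
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_equal(rates[1], 0)
})

test_that("the assembled cell table holds retained cells with full panels", {
  sim <- tiny_experiment(n = 400, seed = 37)
  cr <- correct_experiment(sim)
  tab <- assemble_cell_table(cr)
  expect_equal(nrow(tab), cr$qc$n_retained)
  # no retained cell has a missing marker value
  expect_false(anyNA(tab[, cr$panel]))
  # excluded tracks are not in the table
  expect_true(all(tab$cell_id %in%
                    cr$records$track_id[cr$records$qc_status == "retained"]))

  # zero retained cells: empty table with full header
  none <- simulate_cycles(load_chip(0, composition_preset("MS-like")), seed = 1)
  tab0 <- assemble_cell_table(correct_experiment(none))
  expect_equal(nrow(tab0), 0)
  expect_true(all(standard_panel() %in% names(tab0)))

  # duplicate ids are an integrity error
  bad <- cr
  bad$records <- rbind(cr$records, cr$records[1, ])
  expect_error(assemble_cell_table(bad), class = "chipcsf_integrity_error")
})
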