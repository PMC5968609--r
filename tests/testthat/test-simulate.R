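# Synthetic cohort, preanalytic loss, chip loading, and cycle simulation.

test_that("cohort generation respects the cellularity mix and forced counts", {
  expect_error(generate_cohort(0), class = "chipcsf_param_error")
  expect_error(generate_cohort(10, pleocytic_fraction = 1.5),
               class = "chipcsf_param_error")

  co <- generate_cohort(10000, pleocytic_fraction = 1.0, seed = 7)
  conc <- vapply(co, `[[`, numeric(1), "concentration")
  expect_true(all(conc >= 5))

  co0 <- generate_cohort(10000, pleocytic_fraction = 0, seed = 7)
  expect_true(all(vapply(co0, `[[`, numeric(1), "concentration") < 5))

  vols <- vapply(co, `[[`, numeric(1), "volume_ml")
  expect_true(all(vols >= 1 & vols <= 15))

  # a known clinical cell count can be forced; absolute count follows
  ms <- generate_cohort(1, composition_presets = "MS-like", seed = 2,
                        force_concentration = 24)[[1]]
  expect_equal(ms$concentration, 24)
  expect_equal(ms$absolute_count, round(24 * ms$volume_ml * 1000))

  # determinism: identical seeds give identical cohorts
  expect_identical(generate_cohort(50, seed = 5), generate_cohort(50, seed = 5))
})

test_that("preanalytic loss matches a per-cell Bernoulli oracle", {
  s <- generate_cohort(1, seed = 1, force_concentration = 10)[[1]]
  s$absolute_count <- 10000

  none <- preanalytics_params(loss_probability = 0)
  expect_equal(apply_preanalytics(s, none, seed = 1), 10000)

  s0 <- s; s0$absolute_count <- 0
  expect_equal(apply_preanalytics(s0, seed = 1), 0)

  # Monte-Carlo: mean recovered ~ n(1-p); oracle = per-cell Bernoulli draws
  p <- 0.593
  rec <- vapply(1:1000, function(i) apply_preanalytics(s, seed = i), numeric(1))
  set.seed(42)
  oracle <- vapply(1:1000, function(i) sum(stats::runif(10000) > p), numeric(1))
  se <- sqrt(p * (1 - p) * 10000) / sqrt(1000)
  expect_lt(abs(mean(rec) - 10000 * (1 - p)), 3 * se)
  expect_lt(abs(mean(rec) - mean(oracle)), 3 * sqrt(2) * se)
})

test_that("chip loading reproduces composition, density and geometry", {
  comp <- toy_composition(0.7)
  expect_error(load_chip(-1, comp), class = "chipcsf_param_error")

  e0 <- load_chip(0, comp)
  expect_equal(nrow(e0$cells), 0)
  expect_equal(assess_sufficiency(e0)$cells_per_fov, 0)

  e <- load_chip(2000, comp, chip_geometry(10, 10), seed = 3)
  expect_equal(nrow(e$cells) / e$geometry$n_fov, 20)
  expect_true(all(e$cells$x >= 0 & e$cells$x <= 10 * 128))
  expect_equal(e$cells$fov, fov_of(e$cells$x, e$cells$y, e$geometry))

  # composition recovery at n = 50000 within 3 binomial standard errors
  big <- load_chip(50000, comp, chip_geometry(20, 20), seed = 4)
  phat <- mean(big$cells$phenotype == "A")
  se <- sqrt(0.7 * 0.3 / 50000)
  expect_lt(abs(phat - 0.7), 3 * se)
  # expression: population A positive on M1, zero on M2
  a <- big$cells$phenotype == "A"
  expect_true(all(big$expression[a, "M2"] == 0))
  expect_true(all(big$expression[a, "M1"] > 0))
})

test_that("cycle simulation follows the measurement model and detachment law", {
  comp <- toy_composition(0.5)
  e <- load_chip(500, comp, seed = 5)

  # no detachment: every cell present in every cycle
  sim0 <- simulate_cycles(e, noiseless_kinetics(), seed = 5)
  expect_true(all(sim0$cycles$present))

  # rho = 0, noise 0, L = 1, B = 0: stained - postbleach = g * E exactly
  d <- sim0$cycles$mfi_stained - sim0$cycles$mfi_postbleach
  expect_equal(unname(d), unname(e$expression[, , drop = FALSE]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # conservation: once absent (and not reattached), never present again
  simd <- simulate_cycles(load_chip(2000, comp, seed = 6),
                          cycle_kinetics(detach_prob = 0.1, reattach_prob = 0),
                          seed = 6)
  pr <- simd$cycles$present
  for (k in 2:ncol(pr)) expect_true(all(pr[, k] <= pr[, k - 1]))

  # full-track fraction ~ (1-p)^n_cycles against a direct per-cell oracle
  panel10 <- paste0("M", 1:10)
  comp10 <- list(population_profile("A", 1, c(M1 = "positive"), panel = panel10))
  e10 <- load_chip(10000, comp10, chip_geometry(20, 20), seed = 7)
  sim <- simulate_cycles(e10, cycle_kinetics(detach_prob = 0.05), seed = 7)
  frac_full <- mean(rowSums(sim$cycles$present) == 10)
  p_expect <- 0.95^10
  se <- sqrt(p_expect * (1 - p_expect) / 10000)
  expect_lt(abs(frac_full - p_expect), 3 * se)
  set.seed(99)
  oracle <- mean(vapply(1:10000, function(i) all(stats::runif(10) > 0.05),
                        logical(1)))
  expect_lt(abs(frac_full - oracle), 3 * sqrt(2) * se)

  # a cell absent in cycle k has no MFI in cycle k; MFIs are non-negative
  expect_true(all(is.na(sim$cycles$mfi_stained[!sim$cycles$present])))
  expect_true(all(sim$cycles$mfi_stained[sim$cycles$present] >= 0))

  # determinism: identical seed and config give identical tables
  t1 <- experiment_table(simulate_cycles(e10, cycle_kinetics(), seed = 8))
  t2 <- experiment_table(simulate_cycles(e10, cycle_kinetics(), seed = 8))
  expect_identical(t1, t2)
})

test_that("experiment table export matches the documented long schema", {
  sim <- tiny_experiment(n = 50, seed = 9)
  tab <- experiment_table(sim)
  expect_setequal(names(tab), c("sample_id", "cell_id", "cycle", "marker",
                                "fov", "x", "y", "size_um2", "mfi_stained",
                                "mfi_postbleach", "present", "true_phenotype"))
  expect_equal(nrow(tab), sum(sim$cycles$present))
  # round-trip through CSV is value-identical
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$mfi_stained, tab$mfi_stained, tolerance = 1e-12)
  expect_identical(back$marker, tab$marker)
})
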