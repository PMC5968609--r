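# Gating, population statistics, clonality, clustering.

test_that("band classification and gate definitions behave as documented", {
  th <- default_thresholds("CD19")
  b <- intensity_band(c(0, 100, 1000, 10000), th)
  expect_equal(as.character(b), c("negative", "low", "positive", "high"))

  # a cell negative for everything is unclassified
  tab <- as.data.frame(setNames(as.list(rep(0, 11)), standard_panel()),
                       check.names = FALSE)
  expect_equal(apply_gates(tab), "unclassified")

  # the plasmablast definition: CD19 low, CD27 positive, CD38 high
  pb <- tab
  pb$CD19 <- 100; pb$CD27 <- 1000; pb$CD38 <- 10000
  expect_equal(apply_gates(pb), "plasmablast")

  # missing marker column is a schema error
  expect_error(apply_gates(tab[, -1], tree = default_gate_tree()),
               class = "chipcsf_schema_error")

  # first-match-wins is order-stable under row permutation
  sim <- tiny_experiment(n = 300, seed = 41)
  t1 <- assemble_cell_table(correct_experiment(sim))
  lab <- apply_gates(t1)
  perm <- sample(nrow(t1))
  expect_identical(apply_gates(t1[perm, ])[order(perm)], lab)
})

test_that("gating recovers simulated phenotypes", {
  # noise-free, well-separated bands: 100% accuracy
  sim0 <- simulate_cycles(
    load_chip(2000, composition_preset("MS-like"), seed = 42),
    noiseless_kinetics(), seed = 42)
  tab0 <- assemble_cell_table(correct_experiment(sim0))
  lab0 <- apply_gates(tab0)
  expect_equal(mean(lab0 == expected_label(tab0$true_phenotype)), 1)

  # default noise and distortions: >= 95% accuracy
  sim1 <- tiny_experiment(n = 2000, seed = 43)
  tab1 <- assemble_cell_table(correct_experiment(sim1))
  lab1 <- apply_gates(tab1)
  expect_gte(mean(lab1 == expected_label(tab1$true_phenotype)), 0.95)

  # subset counts never exceed their parent at any tree level
  st <- population_stats(lab1)
  t_total <- sum(st$counts[c("T_CD4_Tcm", "T_CD4", "T_CD8", "T_other")],
                 na.rm = TRUE)
  expect_lte(st$counts[["T_CD4_Tcm"]], t_total)
  expect_lte(sum(st$counts), st$n)
})

test_that("population statistics compute percentages and guarded ratios", {
  expect_error(population_stats(character(0)), class = "chipcsf_empty_error")

  lab <- c(rep("T_CD4", 79), rep("B", 12), rep("monocyte", 9))
  st <- population_stats(lab)
  expect_equal(unname(st$percentages[c("T_CD4", "B", "monocyte")]),
               c(79.0, 12.0, 9.0))

  # zero denominator: ratio flagged undefined, never infinite
  expect_true(is.na(st$cd4_cd8_ratio))
  expect_true("cd4_cd8" %in% st$undefined)

  # reported-percentage mode reproduces the printed clinical ratios
  rep_case <- population_stats(percentages = c(T = 79, B = 12, monocyte = 1.5))
  expect_equal(rep_case$b_monocyte_ratio, 8.0)
})

test_that("light-chain clonality calls follow the ratio bounds", {
  mk <- function(kappa, lambda) {
    n <- length(kappa)
    data.frame(Kappa = kappa, Lambda = lambda)
  }
  # forced lambda restriction
  strong <- mk(rep(0, 50), rep(1000, 50))
  expect_equal(light_chain_clonality(strong)$call, "lambda")

  # ratio 30:25 = 1.2 inside the default clinical bounds: polyclonal
  poly <- mk(c(rep(1000, 30), rep(0, 25)), c(rep(0, 30), rep(1000, 25)))
  r <- light_chain_clonality(poly)
  expect_equal(r$kappa_n, 30)
  expect_equal(r$lambda_n, 25)
  expect_equal(r$call, "polyclonal")

  # too few B cells: indeterminate
  expect_equal(light_chain_clonality(mk(0, 1000))$call, "indeterminate")
  expect_error(light_chain_clonality(data.frame(Kappa = 1)),
               class = "chipcsf_schema_error")

  # simulated monoclonal-lambda expansion is called lambda at n >= 50 B cells
  calls <- vapply(1:10, function(i) {
    sim <- simulate_cycles(
      load_chip(400, composition_preset("lymphoma-like"), seed = 50 + i),
      cycle_kinetics(), seed = 50 + i)
    tab <- assemble_cell_table(correct_experiment(sim))
    b <- tab[apply_gates(tab, thresholds = default_thresholds()) %in%
               c("B", "B_memory_switched", "plasmablast"), ]
    light_chain_clonality(b)$call
  }, character(1))
  expect_true(all(calls == "lambda"))
})

test_that("cluster ordering separates simulated populations", {
  sim <- simulate_cycles(
    load_chip(120, toy_composition(0.5, panel = c("M1", "M2")), seed = 44),
    noiseless_kinetics(), seed = 44)
  tab <- assemble_cell_table(correct_experiment(sim))
  res <- cluster_heatmap(tab, markers = c("M1", "M2"), k = 2)
  expect_gte(rand_index(res$cluster, tab$true_phenotype), 0.95)

  # contiguous blocks per population in the dendrogram ordering
  ord_pop <- tab$true_phenotype[res$order]
  expect_lte(sum(ord_pop[-1] != ord_pop[-length(ord_pop)]), 1)

  # identical cells collapse to one cluster at any positive height
  same <- tab[rep(1, 10), ]
  expect_warning(res1 <- cluster_heatmap(same, markers = c("M1", "M2")),
                 "constant")
  expect_equal(length(unique(stats::cutree(res1$hclust, h = 1e-9))), 1)

  # heatmap export writes a file
  f <- withr::local_tempfile(fileext = ".png")
  cluster_heatmap(tab, markers = c("M1", "M2"), heatmap_file = f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
})
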