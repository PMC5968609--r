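#!/usr/bin/env Rscript
# One chip end to end in both modes: simulate an MS-like sample, run
# table-mode correction/QC/gating, and exercise the image mode
# (render -> detect -> measure) on one field of view. Writes
# results/demo_cell_table.csv, results/demo_gates.csv and
# results/demo_heatmap.png.

suppressMessages(library(chipcsf))
dir.create("results", showWarnings = FALSE)
seed <- 424242

sample <- generate_cohort(1, composition_presets = "MS-like", seed = seed,
                          force_concentration = 24)[[1]]
cat(sprintf("virtual patient: %.0f cells/ul x %.1f ml = %d cells\n",
            sample$concentration, sample$volume_ml, sample$absolute_count))
rec <- apply_preanalytics(sample, seed = seed)
exp <- load_chip(min(rec, 4000), sample$composition, seed = seed)
cat(sprintf("recovered %d cells (%.1f%% loss), %.1f cells/FOV\n", rec,
            100 * (1 - rec / sample$absolute_count),
            assess_sufficiency(exp)$cells_per_fov))
exp <- simulate_cycles(exp, cycle_kinetics(), seed = seed)

cr <- correct_experiment(exp)
cat(sprintf("QC: %d tracks, %d retained, %d partial, %d reattached; negativity rate %.3f\n",
            cr$qc$n_tracks, cr$qc$n_retained, cr$qc$n_excluded_partial,
            cr$qc$n_excluded_reattached, cr$qc$negativity_rate))
tab <- assemble_cell_table(cr)
write.csv(tab, "results/demo_cell_table.csv", row.names = FALSE)

labels <- apply_gates(tab)
st <- population_stats(labels)
gates <- data.frame(population = names(st$percentages),
                    count = as.integer(st$counts), pct = as.numeric(st$percentages))
write.csv(gates, "results/demo_gates.csv", row.names = FALSE)
print(gates, row.names = FALSE)
cat(sprintf("CD4:CD8 ratio %.1f, B:monocyte ratio %.1f, plasmablasts %.1f%% of B\n",
            st$cd4_cd8_ratio, st$b_monocyte_ratio, st$plasmablast_pct_of_b))

res <- cluster_heatmap(tab, heatmap_file = "results/demo_heatmap.png", k = 4)
cat("heatmap written; cluster sizes:", table(res$cluster), "\n")

# image mode on FOV 1: detection + MFI measurement against simulator truth
pair <- render_fov(exp, fov_id = 1, cycle = 1)
det <- measure_mfi(pair, detect_cells(pair))
truth_n <- sum(exp$cycles$present[, 1] &
                 fov_of(exp$cycles$pos_x[, 1], exp$cycles$pos_y[, 1],
                        exp$geometry) == 1)
cat(sprintf("image mode FOV 1, cycle 1 (%s): %d cells present, %d detected\n",
            pair$marker, truth_n, nrow(det)))
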