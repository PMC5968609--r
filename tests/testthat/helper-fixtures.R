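# Shared fixtures and independent oracles for the test suite.

# two-population toy composition on a minimal panel
toy_composition <- function(frac_a = 0.7, panel = c("M1", "M2")) {
  list(
    population_profile("A", frac_a, c(M1 = "positive"), panel = panel),
    population_profile("B", 1 - frac_a, c(M2 = "positive"), panel = panel)
  )
}

# a small fully-simulated experiment on the standard panel
tiny_experiment <- function(n = 200, preset = "MS-like", seed = 11,
                            kinetics = cycle_kinetics(), geometry = chip_geometry()) {
  exp <- load_chip(n, composition_preset(preset), geometry, seed = seed)
  simulate_cycles(exp, kinetics, seed = seed)
}

# noise-free, distortion-free kinetics: corrected MFI equals true expression
noiseless_kinetics <- function(...) {
  cycle_kinetics(illum_sdlog = 0, offset_max = 0, noise_sd = 0,
                 detach_prob = 0, ...)
}

# expected gate label for each simulated true phenotype (standard panel)
expected_label <- function(phenotype) {
  map <- c(CD4_Tcm = "T_CD4_Tcm", CD4_naive = "T_CD4", CD8_T = "T_CD8",
           B_memory_switched = "B", B_naive = "B", plasmablast = "plasmablast",
           monocyte = "monocyte", NK = "NK", DC = "DC", CD4_T = "T_CD4",
           B_clonal_lambda = "B", B_poly_kappa = "B", B_poly_lambda = "B")
  unname(map[phenotype])
}

# Rand index between two labelings (pair-counting, computed from scratch)
rand_index <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

# brute-force minimal-total-distance linking across cycles: enumerates every
# injective assignment between consecutive cycles (links only within radius)
# and returns the track id per detection row of `det` (ordered like
# match_tracks orders them). Exponential; for toy inputs only.
brute_force_tracks <- function(det, radius, n_cycles) {
  det <- det[order(det$cycle, det$det_id), ]
  cycles <- sort(unique(det$cycle))
  track <- rep(NA_integer_, nrow(det))
  first <- det$cycle == cycles[1]
  track[first] <- seq_len(sum(first))
  next_id <- sum(first) + 1L
  for (ci in seq_along(cycles)[-1]) {
    prev <- which(det$cycle == cycles[ci - 1])
    cur <- which(det$cycle == cycles[ci])
    dmat <- sqrt(outer(det$x[prev], det$x[cur], "-")^2 +
                   outer(det$y[prev], det$y[cur], "-")^2)
    # enumerate assignments: each cur index maps to a prev index or 0 (new)
    best <- NULL; best_cost <- Inf; best_links <- 0L
    choices <- c(0L, seq_along(prev))
    grid <- expand.grid(rep(list(choices), length(cur)))
    for (g in seq_len(nrow(grid))) {
      asg <- as.integer(grid[g, ])
      nz <- asg[asg > 0]
      if (anyDuplicated(nz)) next
      ok <- all(vapply(seq_along(asg), function(j) {
        asg[j] == 0 || dmat[asg[j], j] <= radius
      }, logical(1)))
      if (!ok) next
      cost <- sum(vapply(seq_along(asg), function(j) {
        if (asg[j] == 0) 0 else dmat[asg[j], j]
      }, numeric(1)))
      links <- length(nz)
      # maximise links, then minimise total distance
      if (links > best_links || (links == best_links && cost < best_cost)) {
        best <- asg; best_cost <- cost; best_links <- links
      }
    }
    for (j in seq_along(cur)) {
      if (best[j] > 0) {
        track[cur[j]] <- track[prev[best[j]]]
      } else {
        track[cur[j]] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  track
}
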