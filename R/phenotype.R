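# Hierarchical gating of corrected MFIs into CSF immune populations,
# summary statistics, light-chain clonality, and cluster heatmaps.
#
# Gating operates on ordinal intensity bands per marker — negative / low /
# positive / high — defined by three log10 thresholds. Band semantics of the
# gate predicates:
#   "neg"        band == negative
#   "low"        band == low           (e.g. CD19^low on plasmablasts)
#   "pos"        band  > low           (positive or high)
#   "high"       band == high          (e.g. CD38^high, strong HLA-DR)
#   "pos_or_low" band  > negative      (any expression, e.g. the B gate)
# Rules are evaluated in order, first match wins; unmatched cells are
# "unclassified".

#' Classify corrected MFIs into intensity bands
#'
#' @param mfi Corrected MFI vector (linear AU, >= 0).
#' @param th One row of a thresholds table (th_low/th_pos/th_high on
#'   log10(MFI + 1)).
#' @return factor with levels negative, low, positive, high.
#' @export
intensity_band <- function(mfi, th) {
  x <- log10(mfi + 1)
  cut(x, breaks = c(-Inf, th$th_low, th$th_pos, th$th_high, Inf),
      labels = c("negative", "low", "positive", "high"), right = FALSE)
}

#' The default CSF gate tree
#'
#' Ordered first-match-wins rules reconstructing the populations of routine
#' CSF immunophenotyping: T cells (CD3+) with CD4/CD8 subsets and the
#' central-memory subset (CD27+ CD45RA-), B cells (CD19 low-or-positive,
#' CD3-) with plasmablasts (CD19 low, CD27+, CD38 high) and class-switched
#' memory cells (CD27+ IgG+, extended panel only), monocytes (CD14+),
#' NK cells (CD56+ CD3-), and dendritic cells (lineage-negative with strong
#' HLA-DR). The instrument's predefined gating strategies are not published;
#' this tree is a reconstruction of the populations they name.
#'
#' @param panel Marker panel the tree may reference.
#' @return A `gate_tree`: list of rules (name, parent, predicates).
#' @export
default_gate_tree <- function(panel = standard_panel()) {
  rule <- function(name, parent, ...) list(name = name, parent = parent,
                                           predicates = c(...))
  rules <- list(
    rule("T_CD4_Tcm", "T", CD3 = "pos", CD4 = "pos", CD27 = "pos",
         CD45RA = "neg"),
    rule("T_CD4", "T", CD3 = "pos", CD4 = "pos"),
    rule("T_CD8", "T", CD3 = "pos", CD8 = "pos"),
    rule("T_other", "T", CD3 = "pos"),
    rule("plasmablast", "B", CD3 = "neg", CD19 = "low", CD27 = "pos",
         CD38 = "high"),
    if ("IgG" %in% panel) {
      rule("B_memory_switched", "B", CD3 = "neg", CD19 = "pos_or_low",
           CD27 = "pos", IgG = "pos")
    },
    rule("B", "B", CD3 = "neg", CD19 = "pos_or_low"),
    rule("monocyte", "monocyte", CD14 = "pos"),
    rule("NK", "NK", CD56 = "pos", CD3 = "neg"),
    rule("DC", "DC", CD3 = "neg", CD14 = "neg", CD19 = "neg", CD56 = "neg",
         `HLA-DR` = "high")
  )
  rules <- Filter(Negate(is.null), rules)
  used <- unique(unlist(lapply(rules, function(r) names(r$predicates))))
  missing <- setdiff(used, panel)
  if (length(missing)) param_error("gate tree references markers not in panel: ",
                                   paste(missing, collapse = ", "))
  structure(rules, class = "gate_tree")
}

.pred_match <- function(band, pred) {
  switch(pred,
         neg = band == "negative",
         low = band == "low",
         pos = band %in% c("positive", "high"),
         high = band == "high",
         pos_or_low = band != "negative",
         param_error("unknown predicate: ", pred))
}

#' Apply a gate tree to a corrected-MFI cell table
#'
#' @param cell_table Output of [assemble_cell_table()] (or any data.frame
#'   with one column per marker of corrected linear MFIs).
#' @param tree A `gate_tree` (default [default_gate_tree()]).
#' @param thresholds Per-marker band thresholds ([default_thresholds()]).
#' @return Character vector of population labels, one per row ("unclassified"
#'   where no rule matches).
#' @export
apply_gates <- function(cell_table, tree = NULL,
                        thresholds = default_thresholds()) {
  markers <- intersect(thresholds$marker, names(cell_table))
  if (is.null(tree)) tree <- default_gate_tree(markers)
  used <- unique(unlist(lapply(tree, function(r) names(r$predicates))))
  absent <- setdiff(used, names(cell_table))
  if (length(absent)) {
    stop(errorCondition(
      paste0("cell table lacks marker column(s): ", paste(absent, collapse = ", ")),
      class = c("chipcsf_schema_error", "error")))
  }
  n <- nrow(cell_table)
  bands <- lapply(setNames(used, used), function(m) {
    th <- thresholds[thresholds$marker == m, , drop = FALSE]
    if (!nrow(th)) param_error("no thresholds for marker ", m)
    intensity_band(cell_table[[m]], th)
  })
  labels <- rep("unclassified", n)
  open <- rep(TRUE, n)
  for (r in tree) {
    hit <- open
    for (m in names(r$predicates)) {
      hit <- hit & .pred_match(bands[[m]], r$predicates[[m]])
    }
    labels[hit] <- r$name
    open <- open & !hit
  }
  labels
}

#' Population summary statistics and clinical ratios
#'
#' Percentages are reported to one decimal. Ratios are computed from the
#' percentages: the CD4:CD8 ratio from the CD4 and CD8 T-cell percentages,
#' the B:monocyte ratio from total B (including plasmablasts and memory
#' subsets) and monocyte percentages, and plasmablasts as a percentage of
#' all B cells. A zero denominator flags the ratio undefined (NA), never
#' infinite.
#'
#' @param labels Character vector of per-cell labels from [apply_gates()];
#'   alternatively NULL if `percentages` is given.
#' @param percentages Optional named numeric vector of population
#'   percentages (e.g. `c(T = 79, B = 12, monocyte = 1.5)`) to compute the
#'   ratios from directly, as when re-analysing reported numbers.
#' @return A `gate_result` list: `counts`, `percentages` (one decimal),
#'   `n`, `cd4_cd8_ratio`, `b_monocyte_ratio`, `plasmablast_pct_of_b`,
#'   and `undefined` (names of undefined ratios).
#' @export
population_stats <- function(labels = NULL, percentages = NULL) {
  if (is.null(labels) && is.null(percentages)) {
    stop(errorCondition("no cells and no percentages supplied",
                        class = c("chipcsf_empty_error", "error")))
  }
  if (!is.null(labels)) {
    if (!length(labels)) {
      stop(errorCondition("no retained cells",
                          class = c("chipcsf_empty_error", "error")))
    }
    counts <- table(labels)
    n <- length(labels)
    pct <- setNames(proportion_pct(as.numeric(counts), n), names(counts))
  } else {
    counts <- NULL
    n <- NA_integer_
    pct <- percentages
  }
  g <- function(nm) sum(pct[intersect(nm, names(pct))], na.rm = TRUE)
  cd4 <- g(c("T_CD4", "T_CD4_Tcm", "CD4"))
  cd8 <- g(c("T_CD8", "CD8"))
  b_all <- g(c("B", "B_memory_switched", "plasmablast"))
  mono <- g(c("monocyte"))
  pb <- g("plasmablast")
  undefined <- character()
  ratio <- function(num, den, nm) {
    if (is.na(den) || den == 0) {
      undefined <<- c(undefined, nm)
      NA_real_
    } else round_half_up(num / den, 1)
  }
  structure(list(
    counts = counts, percentages = pct, n = n,
    cd4_cd8_ratio = ratio(cd4, cd8, "cd4_cd8"),
    b_monocyte_ratio = ratio(b_all, mono, "b_monocyte"),
    plasmablast_pct_of_b = if (b_all > 0) round_half_up(100 * pb / b_all, 1) else NA_real_,
    undefined = undefined
  ), class = "gate_result")
}

#' Kappa/lambda light-chain clonality of the B-cell compartment
#'
#' Counts kappa-positive and lambda-positive B cells and calls restriction
#' from the kappa:lambda ratio. The default bounds (0.26, 1.65) are the
#' conventional clinical reference interval for the kappa:lambda ratio; they
#' are a documented convention, not a measured property of this assay.
#'
#' @param b_cells Cell table restricted to B-lineage cells, with `Kappa`
#'   and `Lambda` marker columns (corrected MFIs).
#' @param thresholds Band thresholds (positivity at `th_pos`).
#' @param ratio_bounds Lower/upper kappa:lambda bounds for the polyclonal
#'   range.
#' @param min_b Minimum B-cell count for a determinate call (default 10).
#' @return A `clonality_result`: `kappa_n`, `lambda_n`, `ratio`, `call` in
#'   `c("kappa", "lambda", "polyclonal", "indeterminate")`.
#' @export
light_chain_clonality <- function(b_cells, thresholds = default_thresholds(),
                                  ratio_bounds = c(0.26, 1.65), min_b = 10) {
  if (!all(c("Kappa", "Lambda") %in% names(b_cells))) {
    stop(errorCondition("Kappa/Lambda columns required",
                        class = c("chipcsf_schema_error", "error")))
  }
  kb <- intensity_band(b_cells$Kappa,
                       thresholds[thresholds$marker == "Kappa", , drop = FALSE])
  lb <- intensity_band(b_cells$Lambda,
                       thresholds[thresholds$marker == "Lambda", , drop = FALSE])
  kn <- sum(kb %in% c("positive", "high"))
  ln <- sum(lb %in% c("positive", "high"))
  ratio <- if (ln > 0) kn / ln else if (kn > 0) Inf else NA_real_
  call <- if (nrow(b_cells) < min_b || (kn + ln) == 0) {
    "indeterminate"
  } else if (is.na(ratio)) {
    "indeterminate"
  } else if (ratio < ratio_bounds[1]) {
    "lambda"
  } else if (ratio > ratio_bounds[2]) {
    "kappa"
  } else {
    "polyclonal"
  }
  structure(list(kappa_n = kn, lambda_n = ln, ratio = ratio, call = call,
                 ratio_bounds = ratio_bounds),
            class = "clonality_result")
}

#' Agglomerative cluster ordering of cells for heatmap display
#'
#' Cells are clustered on z-scored log10(MFI + 1) with [stats::hclust()];
#' constant-valued markers are dropped from the z-scoring with a warning.
#' The ordering is deterministic for fixed linkage and distance.
#'
#' @param cell_table Cell table with marker columns.
#' @param markers Markers to use (default: all panel markers present).
#' @param linkage Linkage method for [stats::hclust()] (default "ward.D2").
#' @param distance Distance for [stats::dist()] (default "euclidean").
#' @param k Number of clusters to cut at (default 2).
#' @param heatmap_file Optional PNG path; written with pheatmap when
#'   available, otherwise [stats::heatmap()] via grDevices.
#' @return List: `order` (row order), `cluster` (integer labels from
#'   [stats::cutree()]), `hclust`, `markers_used`.
#' @export
cluster_heatmap <- function(cell_table, markers = NULL, linkage = "ward.D2",
                            distance = "euclidean", k = 2,
                            heatmap_file = NULL) {
  if (is.null(markers)) {
    markers <- intersect(standard_panel(extended = TRUE), names(cell_table))
  }
  if (nrow(cell_table) < 2) param_error("need >= 2 cells to cluster")
  x <- log10(as.matrix(cell_table[, markers, drop = FALSE]) + 1)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant marker(s) from z-scoring: ",
            paste(markers[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    markers <- markers[sds > 0]
  }
  z <- if (ncol(x)) scale(x) else matrix(0, nrow(cell_table), 1)
  hc <- stats::hclust(stats::dist(z, method = distance), method = linkage)
  cl <- stats::cutree(hc, k = min(k, nrow(z)))
  if (!is.null(heatmap_file)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(heatmap_file, width = 900, height = 700)
      pheatmap::pheatmap(z[hc$order, , drop = FALSE], cluster_rows = FALSE,
                         cluster_cols = FALSE, show_rownames = FALSE)
      grDevices::dev.off()
    } else {
      grDevices::png(heatmap_file, width = 900, height = 700)
      stats::heatmap(z, Rowv = stats::as.dendrogram(hc), Colv = NA,
                     labRow = FALSE)
      grDevices::dev.off()
    }
  }
  list(order = hc$order, cluster = cl, hclust = hc, markers_used = markers)
}
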