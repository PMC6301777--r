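#' Panel performance metrics
#'
#' `mae` is the mean absolute error between calibrated estimates and their
#' cell-sorted references. `mmce` is the mean mixed-cell error, the mean
#' absolute cell-sorted estimate — the error of the trivial estimator that
#' calls every cell-type difference zero, and so the baseline a useful
#' estimator must beat. `r_squared` is the squared Pearson correlation
#' between (uncalibrated) regression estimates and references, i.e. the
#' simple-regression coefficient of determination, insensitive to affine
#' shifts that calibration would remove.
#'
#' @param calibrated,reference,lr_estimates numeric vectors (equal length).
#' @return A single number.
#' @export
mae <- function(calibrated, reference) {
  if (!length(calibrated) || length(calibrated) != length(reference)) {
    stop("mae needs two equal-length, nonempty vectors", call. = FALSE)
  }
  mean(abs(calibrated - reference))
}

#' @rdname mae
#' @export
mmce <- function(reference) {
  if (!length(reference)) stop("mmce of an empty panel is undefined",
                               call. = FALSE)
  mean(abs(reference))
}

#' @rdname mae
#' @export
r_squared <- function(lr_estimates, reference) {
  if (length(lr_estimates) != length(reference) || length(reference) < 3) {
    stop("r_squared needs two equal-length vectors of length >= 3",
         call. = FALSE)
  }
  if (stats::var(lr_estimates) <= 0 || stats::var(reference) <= 0) {
    stop("r_squared undefined: an argument has zero variance", call. = FALSE)
  }
  stats::cor(lr_estimates, reference)^2
}

#' Summarize a robust panel's estimation performance
#'
#' One report row per target, shaped like the published performance table:
#' retained panel size, MAE of calibrated estimates, MMCE baseline, R^2
#' between regression and cell-sorted estimates, the number and percentage
#' of retained CpGs with absolute error below `ae_threshold`, and the mean
#' target proportion across samples in percent.
#'
#' @param robust a [build_robust_panel()] result.
#' @param props a [proportion_table()] (for the mean target fraction).
#' @param scheme a [cell_type_scheme()].
#' @param ae_threshold absolute-error accuracy cutoff; default 0.05.
#' @param target target name (default: taken from the panel).
#' @return One-row data.frame; metric fields are `NA` for an empty panel.
#' @export
summarize_panel <- function(robust, props, scheme, ae_threshold = 0.05,
                            target = NULL) {
  stopifnot(is.data.frame(robust))
  if (is.null(target)) {
    target <- if (nrow(robust)) robust$target[1L] else NA_character_
  }
  kept <- robust[which(robust$retained), , drop = FALSE]
  mean_prop <- if (!is.na(target)) {
    100 * mean(agglomerate_proportions(props, target, scheme))
  } else {
    NA_real_
  }
  if (!nrow(kept)) {
    return(data.frame(target = target, candidate_size = nrow(robust),
                      panel_size = 0L, mae = NA_real_, mmce = NA_real_,
                      r_squared = NA_real_, n_accurate = NA_integer_,
                      pct_accurate = NA_real_, mean_proportion_pct = mean_prop,
                      ae_threshold = ae_threshold, stringsAsFactors = FALSE))
  }
  r2 <- if (nrow(kept) >= 3 && stats::var(kept$lr_estimate) > 0 &&
              stats::var(kept$cell_sorted_estimate) > 0) {
    r_squared(kept$lr_estimate, kept$cell_sorted_estimate)
  } else if (max(abs(kept$calibrated_estimate -
                       kept$cell_sorted_estimate)) < 1e-8) {
    1  # degenerate exact panel: perfect agreement
  } else {
    NA_real_
  }
  n_acc <- sum(kept$absolute_error < ae_threshold)
  data.frame(target = target, candidate_size = nrow(robust),
             panel_size = nrow(kept),
             mae = mae(kept$calibrated_estimate, kept$cell_sorted_estimate),
             mmce = mmce(kept$cell_sorted_estimate), r_squared = r2,
             n_accurate = n_acc, pct_accurate = 100 * n_acc / nrow(kept),
             mean_proportion_pct = mean_prop, ae_threshold = ae_threshold,
             stringsAsFactors = FALSE)
}

#' Overlap between two CpG panels
#'
#' Count and percentage (relative to the first panel) of shared CpGs; used
#' to check that panels derived from independent datasets agree.
#'
#' @param panel_a,panel_b character vectors of CpG ids (or panel data.frames
#'   with a `cpg_id` column).
#' @return List with `count` and `percent` (`NA` when `panel_a` is empty).
#' @export
panel_overlap <- function(panel_a, panel_b) {
  ids <- function(x) unique(if (is.data.frame(x)) x$cpg_id else
    as.character(x))
  a <- ids(panel_a); b <- ids(panel_b)
  n <- length(intersect(a, b))
  list(count = n,
       percent = if (length(a)) 100 * n / length(a) else NA_real_)
}

panel_cpgs <- function(panels, top_n = NULL) {
  if (is.data.frame(panels)) panels <- list(panels)
  if (!is.list(panels)) panels <- list(data.frame(cpg_id =
                                                    as.character(panels)))
  out <- character(0)
  for (p in panels) {
    if (!is.data.frame(p)) p <- data.frame(cpg_id = as.character(p))
    ids <- p$cpg_id
    if (!is.null(top_n)) {
      if (top_n < length(ids) && "p_value" %in% names(p)) {
        ids <- ids[order(p$p_value)][seq_len(top_n)]
      } else if (top_n < length(ids)) {
        ids <- ids[seq_len(top_n)]
      } else {
        message("top_n exceeds panel size (", length(ids),
                "); using the full panel")
      }
    }
    out <- union(out, ids)
  }
  out
}

#' Hierarchically cluster cell-sorted samples on panel CpGs
#'
#' Agglomerative clustering of the sorted samples restricted to the union
#' of the given panels' CpGs (optionally the top `top_n` per panel, ranked
#' by the panel's t-test p-value). Returns the dendrogram as an `hclust`,
#' an `ape::phylo` and a Newick string, plus a purity score: the fraction
#' of samples whose cophenetically nearest neighbour carries the same
#' cell label — 1 when samples of a type always cluster together first.
#'
#' @param sorted a [beta_matrix()] of sorted samples.
#' @param panels a panel data.frame, list of panel data.frames, or character
#'   vector of CpG ids.
#' @param top_n optional per-panel cap, ranked by `p_value`.
#' @param distance distance measure for [stats::dist()]; default Euclidean.
#' @param linkage agglomeration method for [stats::hclust()]; default
#'   average.
#' @return List with `hclust`, `phylo`, `newick`, `purity`.
#' @export
cluster_sorted_samples <- function(sorted, panels, top_n = NULL,
                                   distance = "euclidean",
                                   linkage = "average") {
  stopifnot(inherits(sorted, "beta_matrix"))
  if (nrow(sorted$values) < 2) {
    stop("need at least 2 samples to cluster", call. = FALSE)
  }
  cpgs <- panel_cpgs(panels, top_n)
  cpgs <- intersect(cpgs, colnames(sorted$values))
  if (!length(cpgs)) stop("no panel CpGs present in the sorted matrix",
                          call. = FALSE)
  V <- sorted$values[, cpgs, drop = FALSE]
  d <- stats::dist(V, method = distance)
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  coph <- as.matrix(stats::cophenetic(hc))
  diag(coph) <- Inf
  lab <- sorted$samples$cell_label
  hits <- vapply(seq_len(nrow(coph)), function(i) {
    nn <- which(coph[i, ] == min(coph[i, ]))
    any(lab[nn] == lab[i])
  }, logical(1))
  list(hclust = hc, phylo = phy,
       newick = ape::write.tree(phy), purity = mean(hits))
}
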