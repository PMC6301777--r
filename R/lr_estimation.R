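#' Per-CpG simple linear regression of mixed beta on target proportion
#'
#' Under the linear mixing model the mixed-cell beta value at a CpG is
#' `y_i = b0 + b1 p_i + e_i` where `p_i` is the target type's (or
#' grouping's) fraction in sample `i`, the intercept is the pooled
#' non-target methylation and the slope is the target-minus-rest methylation
#' difference. `fit_cpg` fits one site by ordinary least squares.
#'
#' @param y numeric vector of mixed-cell beta values (length >= 3).
#' @param p numeric vector of target proportions, same length, with
#'   positive variance.
#' @return List with `intercept`, `slope`, `slope_se`, `residual_sd`, `n`.
#'   An exactly collinear fit yields `slope_se = 0`.
#' @export
fit_cpg <- function(y, p) {
  n <- length(y)
  if (n != length(p)) stop("y and p lengths differ", call. = FALSE)
  if (n < 3) stop("need at least 3 samples (df = n - 2 >= 1)", call. = FALSE)
  sxx <- sum((p - mean(p))^2)
  if (sxx <= 0) {
    stop("degenerate design: target proportion has zero variance",
         call. = FALSE)
  }
  slope <- sum((p - mean(p)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(p)
  rss <- max(sum((y - intercept - slope * p)^2), 0)
  residual_sd <- sqrt(rss / (n - 2))
  list(intercept = intercept, slope = slope,
       slope_se = residual_sd / sqrt(sxx), residual_sd = residual_sd, n = n)
}

# vectorized OLS of each column of Y on the single covariate p
fit_lr_columns <- function(Y, p) {
  n <- nrow(Y)
  pc <- p - mean(p)
  sxx <- sum(pc^2)
  ybar <- colMeans(Y)
  slope <- as.vector(crossprod(pc, Y)) / sxx
  intercept <- ybar - slope * mean(p)
  # explicit residuals: the shortcut RSS = S_yy - slope^2 S_xx cancels
  # catastrophically on (near-)exact fits and would inflate zero SEs
  R <- Y - rep(intercept, each = n) - outer(p, slope)
  residual_sd <- sqrt(colSums(R^2) / (n - 2))
  data.frame(cpg_id = colnames(Y), intercept = intercept, slope = slope,
             slope_se = residual_sd / sqrt(sxx), residual_sd = residual_sd,
             n = n, stringsAsFactors = FALSE, row.names = NULL)
}

#' Regression (LR) estimates over a CpG panel
#'
#' Fits the per-CpG regression of mixed-cell beta on the agglomerated target
#' proportion for every CpG in the panel. Slopes are regression coefficients
#' and are deliberately not constrained to \[-1,1\]; set
#' `truncate_slopes = TRUE` to clamp them post hoc (off by default, and not
#' part of the evaluated method).
#'
#' @param mixed a [beta_matrix()] of mixed samples.
#' @param props a [proportion_table()]; rows matched to `mixed` by
#'   `sample_id`.
#' @param target base type or grouping name.
#' @param scheme a [cell_type_scheme()].
#' @param panel a `candidate_panel`, a character vector of CpG ids, or
#'   `NULL` for all CpGs in `mixed`.
#' @param truncate_slopes clamp slopes into \[-1,1\] after fitting.
#' @return An object of class `lr_estimate_set`: data.frame with columns
#'   `target`, `cpg_id`, `intercept`, `slope`, `slope_se`, `residual_sd`,
#'   `n`.
#' @export
estimate_panel <- function(mixed, props, target, scheme, panel = NULL,
                           truncate_slopes = FALSE) {
  stopifnot(inherits(mixed, "beta_matrix"))
  ids <- intersect(mixed$samples$sample_id, props$sample_id)
  if (!length(ids)) {
    stop("no overlapping sample_ids between mixed data and proportions",
         call. = FALSE)
  }
  if (length(ids) < 3) {
    stop("need at least 3 aligned mixed samples", call. = FALSE)
  }
  p_all <- agglomerate_proportions(props, target, scheme)
  p <- unname(p_all[ids])
  cpgs <- if (is.null(panel)) {
    colnames(mixed$values)
  } else if (is.data.frame(panel)) {
    panel$cpg_id
  } else {
    as.character(panel)
  }
  out <- data.frame(target = character(0), cpg_id = character(0),
                    intercept = numeric(0), slope = numeric(0),
                    slope_se = numeric(0), residual_sd = numeric(0),
                    n = integer(0), stringsAsFactors = FALSE)
  if (length(cpgs)) {
    absent <- setdiff(cpgs, colnames(mixed$values))
    if (length(absent)) {
      stop(length(absent), " panel CpG(s) absent from mixed data, e.g. ",
           absent[1L], call. = FALSE)
    }
    Y <- mixed$values[match(ids, mixed$samples$sample_id), cpgs,
                      drop = FALSE]
    miss <- colSums(is.na(Y)) > 0
    if (any(miss)) {
      message(sum(miss), " CpG(s) with missing mixed values dropped")
      Y <- Y[, !miss, drop = FALSE]
    }
    if (stats::var(p) <= 0) {
      stop(sprintf("degenerate design for target '%s': proportion variance is zero",
                   target), call. = FALSE)
    }
    if (ncol(Y)) {
      out <- fit_lr_columns(Y, p)
      if (truncate_slopes) out$slope <- pmin(1, pmax(-1, out$slope))
      out <- cbind(target = target, out, stringsAsFactors = FALSE)
    }
  }
  class(out) <- c("lr_estimate_set", "data.frame")
  out
}
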