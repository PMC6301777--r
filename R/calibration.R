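#' Calibration of regression estimates against cell-sorted references
#'
#' Regression slopes estimated from mixed-cell data may be shifted and
#' inflated relative to the cell-sorted truth (correlated cell-type
#' profiles do that without making the estimates useless). The calibration
#' step fits `lr = alpha + beta * cell_sorted` by OLS across the candidate
#' panel; each estimate is then mapped back via
#' `(estimate - alpha) / beta`, which by construction regresses on the
#' reference with slope 1 and intercept 0.
#'
#' @param lr an `lr_estimate_set` (or data.frame with `cpg_id`, `slope`).
#' @param ref a `cell_sorted_reference` (or data.frame with `cpg_id`,
#'   `cell_sorted_estimate`).
#' @param beta_floor smallest usable `|beta|`; below it the calibrated
#'   values would amplify noise by more than `1/beta_floor` and the fit is
#'   flagged uncalibratable.
#' @return An object of class `calibration_fit`: list with `alpha`, `beta`,
#'   `n`, `uncalibratable`.
#' @export
fit_calibration <- function(lr, ref, beta_floor = 0.05) {
  m <- merge(as.data.frame(lr)[, c("cpg_id", "slope")],
             as.data.frame(ref)[, c("cpg_id", "cell_sorted_estimate")],
             by = "cpg_id")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  bad <- function(msg) {
    warning("uncalibratable panel: ", msg, call. = FALSE)
    structure(list(alpha = NA_real_, beta = NA_real_, n = nrow(m),
                   uncalibratable = TRUE), class = "calibration_fit")
  }
  if (nrow(m) < 3) return(bad("fewer than 3 CpGs with both estimates"))
  x <- m$cell_sorted_estimate
  y <- m$slope
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) return(bad("cell-sorted estimates have zero variance"))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(x)
  if (abs(beta) < beta_floor) {
    return(bad(sprintf("|beta| = %.3g below floor %.3g", abs(beta),
                       beta_floor)))
  }
  structure(list(alpha = alpha, beta = beta, n = nrow(m),
                 uncalibratable = FALSE), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  if (x$uncalibratable) {
    cat("<calibration_fit> UNCALIBRATABLE (n =", x$n, ")\n")
  } else {
    cat(sprintf("<calibration_fit> alpha = %.4g, beta = %.4g (n = %d)\n",
                x$alpha, x$beta, x$n))
  }
  invisible(x)
}

#' Apply a calibration fit to regression estimates
#'
#' `calibrated = (estimate - alpha) / beta`;
#' `calibrated_se = se / |beta|`.
#'
#' @param estimate,se numeric vectors of regression slopes and their
#'   standard errors.
#' @param fit a [fit_calibration()] result.
#' @return List with `calibrated_estimate` and `calibrated_se`.
#' @export
calibrate <- function(estimate, se, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$uncalibratable) {
    stop("cannot calibrate with an uncalibratable fit", call. = FALSE)
  }
  list(calibrated_estimate = (estimate - fit$alpha) / fit$beta,
       calibrated_se = se / abs(fit$beta))
}

#' Standardized discrepancy (D) between calibrated and cell-sorted estimates
#'
#' `D = (calibrated - cell_sorted) / calibrated_se`. Standard errors at
#' rounding level (< `se_floor`, default 1e-10) arise from exactly collinear
#' fits, where D would be a ratio of rounding errors; such sites get `D = 0`
#' when the discrepancy is also at rounding level (< 1e-8), otherwise an
#' infinite D (always rejected downstream).
#'
#' @param calibrated,cell_sorted,calibrated_se numeric vectors.
#' @param se_floor threshold below which a standard error is treated as an
#'   exact fit.
#' @return Numeric vector of D statistics (may contain `Inf`).
#' @export
d_statistic <- function(calibrated, cell_sorted, calibrated_se,
                        se_floor = 1e-10) {
  disc <- calibrated - cell_sorted
  exact <- calibrated_se < se_floor
  D <- disc / calibrated_se
  D[exact] <- ifelse(abs(disc[exact]) < 1e-8, 0, sign(disc[exact]) * Inf)
  D
}

#' Accuracy screen on the D statistic
#'
#' Under no true discrepancy, D follows a Student t distribution with
#' `n_samples - 2` degrees of freedom (it is a regression slope up to sign),
#' so a CpG is rejected as inaccurately estimated when
#' `2 P(T >= |D|) < alpha`.
#'
#' @param D numeric vector of D statistics.
#' @param n_samples number of mixed samples behind the regression (>= 3).
#' @param alpha per-CpG screening level in (0,1); default 0.05.
#' @return List with `p_value` and logical `retained` (`p >= alpha`).
#' @export
d_test <- function(D, n_samples, alpha = 0.05) {
  if (n_samples < 3) stop("n_samples must be >= 3", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  p <- ifelse(is.finite(D),
              2 * stats::pt(abs(D), df = n_samples - 2, lower.tail = FALSE),
              0)
  list(p_value = p, retained = p >= alpha)
}

#' Build the robust panel: calibrate, screen with D, keep accurate CpGs
#'
#' Fits the calibration over the full candidate panel, computes each CpG's
#' calibrated estimate, standardized discrepancy D against the cell-sorted
#' reference, and its t(N-2) p-value, and flags retained CpGs
#' (`p >= d_alpha`). If the panel is uncalibratable every CpG is unretained
#' and a warning is raised.
#'
#' @param panel a `candidate_panel`.
#' @param lr the matching `lr_estimate_set`.
#' @param ref the matching `cell_sorted_reference`.
#' @param n_samples mixed-sample count for the t reference distribution
#'   (default: taken from `lr$n`).
#' @param d_alpha screening level; default 0.05.
#' @param d_fdr apply Benjamini-Hochberg to the D p-values before screening
#'   (off by default; the evaluated method screens per CpG at fixed alpha).
#' @param beta_floor passed to [fit_calibration()].
#' @return An object of class `robust_panel`: data.frame with the candidate
#'   columns plus `lr_estimate`, `lr_se`, `calibrated_estimate`,
#'   `calibrated_se`, `d_stat`, `d_pvalue`, `retained`, `absolute_error`;
#'   attributes `d_alpha` and `calibration`.
#' @export
build_robust_panel <- function(panel, lr, ref, n_samples = NULL,
                               d_alpha = 0.05, d_fdr = FALSE,
                               beta_floor = 0.05) {
  stopifnot(is.data.frame(panel), is.data.frame(lr), is.data.frame(ref))
  out <- merge(as.data.frame(panel),
               as.data.frame(lr)[, c("cpg_id", "slope", "slope_se")],
               by = "cpg_id")
  names(out)[names(out) == "slope"] <- "lr_estimate"
  names(out)[names(out) == "slope_se"] <- "lr_se"
  if (is.null(n_samples)) {
    n_samples <- if (nrow(lr)) max(lr$n) else 0L
  }
  fit <- if (nrow(out)) {
    fit_calibration(lr[lr$cpg_id %in% out$cpg_id, , drop = FALSE], ref,
                    beta_floor = beta_floor)
  } else {
    structure(list(alpha = NA_real_, beta = NA_real_, n = 0L,
                   uncalibratable = TRUE), class = "calibration_fit")
  }
  if (nrow(out) && !fit$uncalibratable) {
    cal <- calibrate(out$lr_estimate, out$lr_se, fit)
    out$calibrated_estimate <- cal$calibrated_estimate
    out$calibrated_se <- cal$calibrated_se
    out$d_stat <- d_statistic(out$calibrated_estimate,
                              out$cell_sorted_estimate, out$calibrated_se)
    pv <- d_test(out$d_stat, n_samples, d_alpha)$p_value
    if (d_fdr) pv <- bh_adjust(pv)
    out$d_pvalue <- pv
    out$retained <- pv >= d_alpha
    out$absolute_error <- abs(out$calibrated_estimate -
                                out$cell_sorted_estimate)
  } else {
    if (nrow(out)) {
      warning("uncalibratable candidate panel: all CpGs unretained",
              call. = FALSE)
    }
    out$calibrated_estimate <- rep(NA_real_, nrow(out))
    out$calibrated_se <- rep(NA_real_, nrow(out))
    out$d_stat <- rep(NA_real_, nrow(out))
    out$d_pvalue <- rep(NA_real_, nrow(out))
    out$retained <- rep(FALSE, nrow(out))
    out$absolute_error <- rep(NA_real_, nrow(out))
  }
  out <- out[order(out$p_value, out$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "d_alpha") <- d_alpha
  attr(out, "calibration") <- fit
  class(out) <- c("robust_panel", "data.frame")
  out
}
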