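fake_lr <- function(slope, se = 0.04, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("cg%03d", seq_along(slope))
  k <- length(ids)
  data.frame(target = rep("T", k), cpg_id = ids, intercept = rep(0, k),
             slope = slope, slope_se = rep_len(se, k),
             residual_sd = rep_len(se, k), n = rep(6L, k),
             stringsAsFactors = FALSE)
}
fake_ref <- function(est, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("cg%03d", seq_along(est))
  data.frame(target = rep("T", length(ids)), cpg_id = ids,
             cell_sorted_estimate = est, stringsAsFactors = FALSE)
}

test_that("calibration fit recovers affine relationships", {
  x <- seq(-0.4, 0.4, length.out = 20)
  fit_id <- fit_calibration(fake_lr(x), fake_ref(x))
  expect_equal(fit_id$alpha, 0)
  expect_equal(fit_id$beta, 1)

  fit_af <- fit_calibration(fake_lr(0.1 + 2 * x), fake_ref(x))
  expect_equal(fit_af$alpha, 0.1)
  expect_equal(fit_af$beta, 2)

  withr::local_seed(41)
  y <- 0.05 + 1.5 * x + rnorm(20, sd = 0.1)
  fit <- fit_calibration(fake_lr(y), fake_ref(x))
  o <- ols_oracle(y, x)
  expect_equal(fit$alpha, o$intercept, tolerance = 1e-10)
  expect_equal(fit$beta, o$slope, tolerance = 1e-10)
})

test_that("degenerate calibrations are flagged uncalibratable", {
  expect_warning(f1 <- fit_calibration(fake_lr(c(1, 2)), fake_ref(c(1, 2))),
                 "fewer than 3")
  expect_true(f1$uncalibratable)
  expect_warning(f2 <- fit_calibration(fake_lr(runif(5)),
                                       fake_ref(rep(0.2, 5))),
                 "zero variance")
  expect_true(f2$uncalibratable)
  x <- seq(-0.4, 0.4, length.out = 10)
  expect_warning(f3 <- fit_calibration(fake_lr(0.01 * x), fake_ref(x)),
                 "floor")
  expect_true(f3$uncalibratable)
  expect_error(calibrate(0.5, 0.1, f3), "uncalibratable")
})

test_that("calibrate applies the affine correction and scales the SE", {
  fit <- structure(list(alpha = 0.1, beta = 2, n = 10,
                        uncalibratable = FALSE), class = "calibration_fit")
  r <- calibrate(0.5, 0.04, fit)
  expect_equal(r$calibrated_estimate, 0.2)
  expect_equal(r$calibrated_se, 0.02)

  neg <- structure(list(alpha = 0, beta = -1, n = 10,
                        uncalibratable = FALSE), class = "calibration_fit")
  rn <- calibrate(0.3, 0.04, neg)
  expect_equal(rn$calibrated_estimate, -0.3)
  expect_equal(rn$calibrated_se, 0.04)       # |beta| in the SE
})

test_that("calibration identity: calibrated estimates regress at (0, 1)", {
  withr::local_seed(42)
  x <- runif(50, -0.5, 0.5)
  y <- -0.07 + 1.8 * x + rnorm(50, sd = 0.08)
  fit <- fit_calibration(fake_lr(y), fake_ref(x))
  cal <- calibrate(y, 0.04, fit)$calibrated_estimate
  o <- ols_oracle(cal, x)
  expect_equal(o$slope, 1, tolerance = 1e-8)
  expect_equal(o$intercept, 0, tolerance = 1e-8)
})

test_that("D statistic follows the standardized-discrepancy formula", {
  # calibrated 0.30 vs reference 0.20 with lr se 0.04 under beta-hat 2
  fit <- structure(list(alpha = 0, beta = 2, n = 10,
                        uncalibratable = FALSE), class = "calibration_fit")
  cal_se <- calibrate(0.6, 0.04, fit)$calibrated_se
  expect_equal(d_statistic(0.30, 0.20, cal_se), 5.0)
  expect_equal(d_statistic(0.25, 0.25, 0.04), 0)
  expect_equal(d_statistic(0.20, 0.30, cal_se),
               -d_statistic(0.30, 0.20, cal_se))
  # zero-SE conventions
  expect_equal(d_statistic(0.4, 0.4, 0), 0)
  expect_equal(d_statistic(0.5, 0.4, 0), Inf)
})

test_that("D screen uses the t(N-2) reference distribution", {
  r0 <- d_test(0, 6)
  expect_equal(r0$p_value, 1)
  expect_true(r0$retained)

  r5 <- d_test(5, 6, alpha = 0.05)
  # independent tail evaluation by numerical integration of the t(4) density
  tail <- stats::integrate(function(t) stats::dt(t, 4), 5, Inf)$value
  expect_equal(r5$p_value, 2 * tail, tolerance = 1e-6)
  expect_equal(r5$p_value, 0.0075, tolerance = 1e-2)
  expect_false(r5$retained)

  rinf <- d_test(Inf, 6)
  expect_equal(rinf$p_value, 0)
  expect_false(rinf$retained)

  # alpha -> 0 retains everything with a finite D
  tiny <- d_test(c(0, 2, 8), 6, alpha = 1e-12)
  expect_true(all(tiny$retained))
  expect_error(d_test(1, 2), "n_samples")
  expect_error(d_test(1, 6, alpha = 1.2), "alpha")
})

test_that("retention is monotone in alpha", {
  withr::local_seed(55)
  D <- rt(300, df = 4)
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  kept <- vapply(alphas, function(a) sum(d_test(D, 6, a)$retained),
                 numeric(1))
  expect_false(is.unsorted(kept))   # lowering alpha never shrinks the panel
})

test_that("robust panel keeps accurate CpGs and rejects a planted bias", {
  withr::local_seed(66)
  n <- 200
  x <- runif(n, -0.5, 0.5)
  se <- 0.04
  slope <- x + rnorm(n, sd = se)
  slope[1] <- x[1] + 10 * se                  # grossly biased CpG
  ids <- sprintf("cg%03d", 1:n)
  panel <- data.frame(cpg_id = ids, target = "T", t_stat = 10,
                      p_value = 1e-9, q_value = 1e-8,
                      cell_sorted_estimate = x, stringsAsFactors = FALSE)
  rb <- build_robust_panel(panel, fake_lr(slope, se, ids), fake_ref(x, ids),
                           n_samples = 6, d_alpha = 0.05)
  expect_s3_class(rb, "robust_panel")
  expect_false(rb$retained[rb$cpg_id == "cg001"])
  expect_gt(mean(rb$retained), 0.8)
  expect_equal(rb$absolute_error,
               abs(rb$calibrated_estimate - rb$cell_sorted_estimate))
  expect_true(all(rb$retained == (rb$d_pvalue >= 0.05)))

  # empty candidate panel passes through as an empty robust panel
  rb0 <- build_robust_panel(panel[0, ], fake_lr(numeric(0), ids = character(0)),
                            fake_ref(numeric(0), ids = character(0)),
                            n_samples = 6)
  expect_equal(nrow(rb0), 0)
})

test_that("an uncalibratable panel is reported all-unretained", {
  ids <- sprintf("cg%03d", 1:5)
  panel <- data.frame(cpg_id = ids, target = "T", t_stat = 5, p_value = 1e-6,
                      q_value = 1e-5, cell_sorted_estimate = rep(0.3, 5),
                      stringsAsFactors = FALSE)
  expect_warning(  # both the fit and the panel builder flag the degeneracy
    expect_warning(
      rb <- build_robust_panel(panel, fake_lr(runif(5), ids = ids),
                               fake_ref(rep(0.3, 5), ids = ids),
                               n_samples = 6),
      "zero variance"),
    "all CpGs unretained")
  expect_true(all(!rb$retained))
  expect_true(all(is.na(rb$calibrated_estimate)))
})
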