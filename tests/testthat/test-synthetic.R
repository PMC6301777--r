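test_that("profile generator validates its arguments", {
  expect_error(generate_cell_profiles(0), "n_cpgs")
  expect_error(generate_cell_profiles(100, effect_size = 0), "effect_size")
  expect_error(generate_cell_profiles(100, effect_size = 1.5), "effect_size")
  expect_error(generate_cell_profiles(100, diff_fraction = 2),
               "diff_fraction")
  expect_error(generate_cell_profiles(10, diff_fraction = 0.9),
               "too large")
})

test_that("no differential signal means identical profiles per CpG", {
  tr <- generate_cell_profiles(100, diff_fraction = 0, seed = 4)
  expect_true(all(tr$cell_profiles == tr$cell_profiles[, 1]))
  expect_true(all(lengths(tr$differential_sets) == 0))
})

test_that("planted set sizes and disjointness match the design", {
  tr <- generate_cell_profiles(1000, diff_fraction = 0.05,
                               effect_size = 0.4, seed = 1)
  expect_true(all(lengths(tr$differential_sets) == 50))
  all_ids <- unlist(tr$differential_sets, use.names = FALSE)
  expect_equal(anyDuplicated(all_ids), 0L)
  # planted difference from the other types' mean is the effect size,
  # except where clipping intervened (recorded)
  for (k in colnames(tr$cell_profiles)) {
    ids <- setdiff(tr$differential_sets[[k]],
                   tr$clipping$cpg_id[tr$clipping$cell_type == k])
    others <- setdiff(colnames(tr$cell_profiles), k)
    gap <- abs(tr$cell_profiles[ids, k] -
                 rowMeans(tr$cell_profiles[ids, others, drop = FALSE]))
    expect_equal(unname(gap), rep(0.4, length(ids)))
  }
})

test_that("clipping to [0,1] is recorded, never silent", {
  tr <- generate_cell_profiles(400, diff_fraction = 0.1, effect_size = 0.4,
                               baseline_levels = 0.9, baseline_weights = 1,
                               seed = 2)
  expect_gt(nrow(tr$clipping), 0)
  expect_true(all(tr$clipping$clipped == 1))    # 0.9 + 0.4 -> 1
  expect_true(all(tr$clipping$raw > 1))
  expect_true(all(tr$cell_profiles >= 0 & tr$cell_profiles <= 1))
})

test_that("proportion draws respect mode, mean and simplex", {
  tr <- generate_cell_profiles(10, proportion_mode = "dirichlet", seed = 1)
  expect_error(draw_proportions(1, tr), "n_subjects")
  expect_error(draw_proportions(6, tr, concentration = 0), "concentration")
  tr0 <- tr; tr0$mean_proportions["NK"] <- 0
  tr0$mean_proportions <- tr0$mean_proportions / sum(tr0$mean_proportions)
  expect_error(draw_proportions(6, tr0), "degenerate")

  # concentration limit: rows collapse onto the mean
  p_big <- draw_proportions(5, tr, concentration = 1e7, seed = 3)
  m <- as.matrix(as.data.frame(p_big)[, names(tr$mean_proportions)])
  expect_true(all(abs(t(m) - tr$mean_proportions) < 1e-3))

  # Monte-Carlo: empirical means converge to the configured means
  p_mc <- draw_proportions(10000, tr, concentration = 50, seed = 7)
  mc <- colMeans(as.data.frame(p_mc)[, names(tr$mean_proportions)])
  expect_true(all(abs(mc - tr$mean_proportions) < 0.01))
  expect_true(all(abs(rowSums(as.data.frame(p_mc)[, -1]) - 1) < 1e-9))
})

test_that("fixed-remainder draws vary the target and split the rest evenly", {
  tr <- generate_cell_profiles(10, seed = 1)  # fixed_remainder mode
  p <- draw_proportions(8, tr, seed = 5, target = "CD4T")
  df <- as.data.frame(p)
  expect_gt(stats::var(df$CD4T), 0)
  others <- setdiff(blood_scheme()$base_types, "CD4T")
  spread <- apply(df[, others], 1, function(r) diff(range(r)))
  expect_true(all(spread < 1e-12))            # equal weights
  expect_true(all(abs(rowSums(df[, -1]) - 1) < 1e-9))
})

test_that("mixing is the proportion-weighted average plus Normal noise", {
  sc <- cell_type_scheme(c("A", "B"))
  tr <- generate_cell_profiles(1, sc, diff_fraction = 0, seed = 1,
                               noise_sd = 0,
                               mean_proportions = c(A = 0.5, B = 0.5))
  tr$cell_profiles[1, ] <- c(0.5, 0.25)
  props <- proportion_table(data.frame(sample_id = "s1", A = 0.6, B = 0.4),
                            sc)
  y <- mix_samples(tr, props)
  expect_equal(unname(y$values[1, 1]), 0.6 * 0.5 + 0.4 * 0.25)  # 0.40

  # identity mixture reproduces the first type's profile exactly
  tr2 <- generate_cell_profiles(50, sc, diff_fraction = 0.2, seed = 2,
                                noise_sd = 0,
                                mean_proportions = c(A = 0.5, B = 0.5))
  pid <- proportion_table(data.frame(sample_id = "s1", A = 1, B = 0), sc)
  y2 <- mix_samples(tr2, pid)
  expect_equal(unname(y2$values[1, ]), unname(tr2$cell_profiles[, "A"]))

  # schema error on mismatched columns
  other <- proportion_table(data.frame(sample_id = "s1", X = 0.3, Y = 0.7),
                            cell_type_scheme(c("X", "Y")))
  expect_error(mix_samples(tr2, other), "do not match")
})

test_that("mixing noise behaves like centred Normal noise (CLT check)", {
  tr <- generate_cell_profiles(10000, diff_fraction = 0, seed = 3,
                               noise_sd = 0.01,
                               baseline_levels = 0.5, baseline_weights = 1)
  props <- draw_proportions(2, tr, seed = 1, target = "CD4T")
  tr0 <- tr; tr0$noise_sd <- 0
  y  <- suppressMessages(mix_samples(tr, props, seed = 9))
  y0 <- mix_samples(tr0, props, seed = 9)
  resid <- y$values[1, ] - y0$values[1, ]
  expect_lt(abs(mean(resid)), 3 * 0.01 / sqrt(10000))
  expect_equal(stats::sd(resid), 0.01, tolerance = 0.05)
})

test_that("conservation: zero-noise mixtures equal the weighted average", {
  tr <- generate_cell_profiles(500, seed = 6, noise_sd = 0,
                               proportion_mode = "dirichlet")
  props <- draw_proportions(6, tr, seed = 2)
  y <- mix_samples(tr, props)
  P <- as.matrix(as.data.frame(props)[, colnames(tr$cell_profiles)])
  expect_equal(unname(y$values), unname(P %*% t(tr$cell_profiles)),
               tolerance = 1e-12)
  expect_identical(attr(y, "n_clipped"), 0L)
})

test_that("sorted samples reproduce profiles at sd 0 and count 6 x 7", {
  tr <- generate_cell_profiles(200, seed = 8)
  s0 <- generate_cell_sorted_samples(tr, 6, within_subject_sd = 0)
  expect_equal(nrow(s0$values), 42L)
  for (k in colnames(tr$cell_profiles)) {
    rows <- s0$samples$cell_label == k
    expect_true(all(t(s0$values[rows, ]) == tr$cell_profiles[, k]))
  }
  expect_error(generate_cell_sorted_samples(tr, 6, within_subject_sd = -1),
               ">= 0")
})

test_that("sorted-sample means concentrate around the profiles", {
  tr <- generate_cell_profiles(2000, seed = 9, diff_fraction = 0,
                               baseline_levels = 0.5, baseline_weights = 1)
  s <- suppressMessages(
    generate_cell_sorted_samples(tr, 6, within_subject_sd = 0.02, seed = 4))
  rows <- s$samples$cell_label == "CD4T"
  dev <- abs(colMeans(s$values[rows, ]) - tr$cell_profiles[, "CD4T"])
  expect_gte(mean(dev <= 4 * 0.02 / sqrt(6)), 0.99)
})

test_that("dataset generation is seed-deterministic and shape-correct", {
  cfg <- simulation_config(n_cpgs = 300, n_subjects = 6, seed = 42)
  b1 <- generate_dataset(cfg)
  b2 <- generate_dataset(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  expect_equal(dim(b1$mixed_data), c(6L, 300L))
  expect_equal(dim(b1$sorted_data), c(42L, 300L))
  expect_setequal(b1$proportions$sample_id, b1$mixed_data$samples$sample_id)
  expect_error(simulation_config(n_subjects = 1), "n_subjects")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
})

test_that("bundle files round-trip through the writers", {
  b <- make_bundle(n_cpgs = 50, seed = 5)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_setequal(list.files(dir),
                  c("betas_sorted.tsv", "betas_mixed.tsv",
                    "proportions.tsv", "truth.json"))
  sc <- blood_scheme()
  mixed <- read_beta_matrix(file.path(dir, "betas_mixed.tsv"))
  expect_equal(mixed$values, b$mixed_data$values, tolerance = 1e-12)
  props <- read_proportions(file.path(dir, "proportions.tsv"), sc)
  expect_equal(as.data.frame(props)$CD4T,
               as.data.frame(b$proportions)$CD4T, tolerance = 1e-10)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$effect_size, b$truth$effect_size)
})

test_that("config files load from YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cpgs: 120", "n_subjects: 4",
               "proportion_mode: dirichlet", "seed: 9"), fy)
  cfg <- read_simulation_config(fy)
  expect_equal(cfg$n_cpgs, 120)
  expect_equal(cfg$proportion_mode, "dirichlet")
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_cpgs = 60, seed = 2, effect_size = 0.3), fj,
                       auto_unbox = TRUE)
  expect_equal(read_simulation_config(fj)$effect_size, 0.3)
})
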