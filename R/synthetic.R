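#' Synthetic ground truth: cell-type methylation profiles
#'
#' Draws a per-CpG baseline beta value from a mixture of low, intermediate
#' and high methylation levels (mimicking the bimodal distribution of array
#' beta values) and plants, for each cell type, a disjoint set of
#' differentially methylated CpGs whose profile differs from the shared
#' baseline by `effect_size` in a random direction. Values are clipped to
#' \[0,1\] and every clipping event is recorded.
#'
#' @param n_cpgs number of CpG sites (>= 1).
#' @param scheme a [cell_type_scheme()]; defaults to [blood_scheme()].
#' @param diff_fraction fraction of CpGs planted as differential per cell
#'   type (disjoint across types, so `K * round(diff_fraction * n_cpgs)`
#'   must not exceed `n_cpgs`).
#' @param effect_size absolute beta difference at planted CpGs, in (0, 1].
#' @param seed integer seed; the draw is fully reproducible.
#' @param baseline_levels,baseline_weights mixture defining the per-CpG
#'   shared baseline beta value.
#' @param noise_sd measurement noise sd on the beta scale used later by
#'   [mix_samples()]; scalar or length-`n_cpgs` vector.
#' @param proportion_mode `"fixed_remainder"` or `"dirichlet"`, consumed by
#'   [draw_proportions()].
#' @param mean_proportions named mean fraction per base type (sum 1). Default:
#'   published whole-blood means for [blood_scheme()], uniform otherwise.
#' @param include_groupings also plant, for each grouping in the scheme, a
#'   disjoint set of CpGs where every member type shifts jointly by
#'   `effect_size` — lineage-level signal that makes grouping targets
#'   selectable. Off by default (the base contract plants per-type signal
#'   only).
#' @return An object of class `synthetic_truth` with elements
#'   `cell_profiles` (n_cpgs x K matrix), `differential_sets` (list per
#'   type), `effect_size`, `noise_sd`, `proportion_mode`, `mean_proportions`,
#'   `seed`, `clipping` (data.frame of clipped entries) and `scheme`.
#' @export
generate_cell_profiles <- function(n_cpgs, scheme = blood_scheme(),
                                   diff_fraction = 0.05, effect_size = 0.4,
                                   seed = 1L,
                                   baseline_levels = c(0.1, 0.5, 0.9),
                                   baseline_weights = c(0.4, 0.2, 0.4),
                                   noise_sd = 0.02,
                                   proportion_mode = c("fixed_remainder",
                                                       "dirichlet"),
                                   mean_proportions = NULL,
                                   include_groupings = FALSE) {
  if (length(n_cpgs) != 1L || is.na(n_cpgs) || n_cpgs < 1) {
    stop("n_cpgs must be a positive count", call. = FALSE)
  }
  n_cpgs <- as.integer(n_cpgs)
  if (diff_fraction < 0 || diff_fraction > 1) {
    stop("diff_fraction must be in [0,1]", call. = FALSE)
  }
  if (effect_size <= 0 || effect_size > 1) {
    stop("effect_size must be in (0,1]", call. = FALSE)
  }
  proportion_mode <- match.arg(proportion_mode)
  K <- length(scheme$base_types)
  if (is.null(mean_proportions)) {
    mean_proportions <- if (setequal(scheme$base_types,
                                     names(blood_mean_proportions()))) {
      blood_mean_proportions()[scheme$base_types]
    } else {
      stats::setNames(rep(1 / K, K), scheme$base_types)
    }
  }
  mean_proportions <- mean_proportions[scheme$base_types]
  if (any(is.na(mean_proportions)) || any(mean_proportions < 0) ||
      abs(sum(mean_proportions) - 1) > 1e-9) {
    stop("mean_proportions must be nonnegative over all base types and sum to 1",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || any(noise_sd < 0) ||
      !(length(noise_sd) %in% c(1L, n_cpgs))) {
    stop("noise_sd must be a nonnegative scalar or length-n_cpgs vector",
         call. = FALSE)
  }
  targets <- scheme$base_types
  if (include_groupings) targets <- c(targets, names(scheme$groupings))
  n_diff <- round(diff_fraction * n_cpgs)
  if (length(targets) * n_diff > n_cpgs) {
    stop("diff_fraction too large: planted sets (disjoint across targets) ",
         "would exceed the CpG universe", call. = FALSE)
  }
  cpg_ids <- sprintf("cg%08d", seq_len(n_cpgs))

  withr::with_seed(seed, {
    baseline <- sample(baseline_levels, n_cpgs, replace = TRUE,
                       prob = baseline_weights)
    profiles <- matrix(baseline, nrow = n_cpgs, ncol = K,
                       dimnames = list(cpg_ids, scheme$base_types))
    diff_sets <- stats::setNames(
      rep(list(character(0)), length(targets)), targets)
    clip <- list()
    if (n_diff > 0) {
      pool <- sample.int(n_cpgs)  # disjoint planted sets across targets
      for (k in seq_along(targets)) {
        members <- resolve_target(targets[k], scheme)
        idx <- pool[seq.int((k - 1L) * n_diff + 1L, k * n_diff)]
        dir <- sample(c(-1, 1), n_diff, replace = TRUE)
        raw <- baseline[idx] + dir * effect_size
        clipped <- pmin(pmax(raw, 0), 1)
        hit <- which(clipped != raw)
        if (length(hit)) {
          clip[[length(clip) + 1L]] <- data.frame(
            cpg_id = cpg_ids[idx[hit]],
            cell_type = targets[k],
            raw = raw[hit], clipped = clipped[hit],
            stringsAsFactors = FALSE)
        }
        profiles[idx, members] <- clipped  # joint shift for groupings
        diff_sets[[k]] <- cpg_ids[idx]
      }
    }
  })
  clipping <- if (length(clip)) do.call(rbind, clip) else
    data.frame(cpg_id = character(0), cell_type = character(0),
               raw = numeric(0), clipped = numeric(0))
  structure(list(cell_profiles = profiles, differential_sets = diff_sets,
                 effect_size = effect_size, noise_sd = noise_sd,
                 proportion_mode = proportion_mode,
                 mean_proportions = mean_proportions, seed = seed,
                 clipping = clipping, scheme = scheme),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d CpGs x %d cell types; effect %.2f; %d planted/type; %d clipped\n",
              nrow(x$cell_profiles), ncol(x$cell_profiles), x$effect_size,
              length(x$differential_sets[[1L]]), nrow(x$clipping)))
  invisible(x)
}

#' Draw per-sample cell-type proportions
#'
#' Two designs. `fixed_remainder` (the analytically clean design): the
#' target's fraction varies uniformly across subjects around its mean while
#' the remainder is split among the other types with fixed relative weights
#' (`"equal"` by default, so the regression slope's estimand equals the
#' unweighted cell-sorted difference of means exactly). `dirichlet` (the
#' realistic design): rows drawn from a Dirichlet with the configured mean
#' and `concentration`, exposing the weighted-vs-unweighted remainder
#' mismatch that real mixtures carry.
#'
#' @param n_subjects number of mixed samples (>= 2; regression needs spread).
#' @param truth a [generate_cell_profiles()] result (supplies mode, means,
#'   scheme).
#' @param concentration Dirichlet concentration (sum of shape parameters);
#'   larger means rows closer to the mean.
#' @param seed integer seed.
#' @param target for `fixed_remainder`: base type or grouping whose fraction
#'   is varied (default: first base type).
#' @param remainder_weights `"equal"` or `"mean"` relative weights for the
#'   non-target types in `fixed_remainder` mode.
#' @return A [proportion_table()] with subjects `S1..Sn`.
#' @export
draw_proportions <- function(n_subjects, truth, concentration = 100,
                             seed = 1L, target = NULL,
                             remainder_weights = c("equal", "mean")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 2) {
    stop("n_subjects must be >= 2 (the regression needs variation)",
         call. = FALSE)
  }
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  remainder_weights <- match.arg(remainder_weights)
  n_subjects <- as.integer(n_subjects)
  scheme <- truth$scheme
  m <- truth$mean_proportions
  if (any(m <= 0)) {
    stop("degenerate mean_proportions: zero component", call. = FALSE)
  }
  K <- length(scheme$base_types)
  P <- withr::with_seed(seed, {
    if (truth$proportion_mode == "fixed_remainder") {
      if (is.null(target)) target <- scheme$base_types[1L]
      members <- resolve_target(target, scheme)
      others <- setdiff(scheme$base_types, members)
      mc <- sum(m[members])
      p <- stats::runif(n_subjects, 0.5 * mc, min(0.95, 1.5 * mc))
      w_in <- if (remainder_weights == "equal") {
        rep(1 / length(members), length(members))
      } else m[members] / sum(m[members])
      w_out <- if (remainder_weights == "equal") {
        rep(1 / length(others), length(others))
      } else m[others] / sum(m[others])
      P <- matrix(0, n_subjects, K,
                  dimnames = list(NULL, scheme$base_types))
      P[, members] <- outer(p, w_in)
      P[, others] <- outer(1 - p, w_out)
      P
    } else {
      shapes <- concentration * m
      g <- matrix(stats::rgamma(n_subjects * K, shape = rep(shapes,
                                                            each = n_subjects)),
                  n_subjects, K, dimnames = list(NULL, scheme$base_types))
      g / rowSums(g)
    }
  })
  df <- data.frame(sample_id = paste0("S", seq_len(n_subjects)),
                   stringsAsFactors = FALSE)
  df[scheme$base_types] <- P[, scheme$base_types]
  proportion_table(df, scheme)
}

#' Mix cell-type profiles into whole-tissue beta values
#'
#' Each mixed sample's beta value is the proportion-weighted average of the
#' cell-type profiles plus Normal noise on the beta scale,
#' `y_ij = sum_k p_ik x_jk + e_ij`, `e_ij ~ N(0, sigma_j)`, clipped to
#' \[0,1\]. The number of clipped entries is reported via the `n_clipped`
#' attribute and a message (heavy clipping signals a violated noise model).
#'
#' @param truth a `synthetic_truth`.
#' @param proportions a [proportion_table()] over the truth's base types.
#' @param seed integer seed.
#' @return A [beta_matrix()] of mixed samples (`cell_label = "mixed"`), with
#'   attribute `n_clipped`.
#' @export
mix_samples <- function(truth, proportions, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  types <- colnames(truth$cell_profiles)
  if (!all(types %in% names(proportions))) {
    stop("proportion columns do not match the truth's cell types",
         call. = FALSE)
  }
  P <- as.matrix(as.data.frame(proportions)[, types])
  X <- truth$cell_profiles                      # J x K
  Y <- P %*% t(X)                               # samples x CpGs
  n_clipped <- 0L
  if (any(truth$noise_sd > 0)) {
    sds <- rep(truth$noise_sd, length.out = ncol(Y))
    E <- withr::with_seed(seed, {
      matrix(stats::rnorm(length(Y), sd = rep(sds, each = nrow(Y))),
             nrow = nrow(Y))
    })
    Y <- Y + E
    clipped <- Y < 0 | Y > 1
    n_clipped <- sum(clipped)
    if (n_clipped > 0) {
      Y <- pmin(pmax(Y, 0), 1)
      message(n_clipped, " mixed beta value(s) clipped to [0,1]")
    }
  }
  ann <- data.frame(sample_id = proportions$sample_id,
                    subject_id = proportions$sample_id,
                    cell_label = "mixed", stringsAsFactors = FALSE)
  bm <- beta_matrix(Y, ann, cpg_ids = rownames(X))
  attr(bm, "n_clipped") <- n_clipped
  bm
}

#' Generate per-subject cell-sorted samples
#'
#' One purified sample per (subject, cell type): the type's true profile plus
#' Normal within-subject noise, clipped to \[0,1\] with the clip count
#' reported. `within_subject_sd = 0` reproduces the profiles exactly.
#'
#' @param truth a `synthetic_truth`.
#' @param n_subjects number of subjects.
#' @param within_subject_sd nonnegative noise sd on the beta scale.
#' @param seed integer seed.
#' @return A [beta_matrix()] with `n_subjects * K` rows and attribute
#'   `n_clipped`.
#' @export
generate_cell_sorted_samples <- function(truth, n_subjects = 6,
                                         within_subject_sd = 0.02,
                                         seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (within_subject_sd < 0) {
    stop("within_subject_sd must be >= 0", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  types <- colnames(truth$cell_profiles)
  grid <- expand.grid(subject = paste0("S", seq_len(n_subjects)),
                      cell_type = types, stringsAsFactors = FALSE)
  X <- t(truth$cell_profiles)                   # K x J
  Y <- X[grid$cell_type, , drop = FALSE]        # samples x CpGs
  n_clipped <- 0L
  if (within_subject_sd > 0) {
    Y <- Y + withr::with_seed(seed, {
      matrix(stats::rnorm(length(Y), sd = within_subject_sd), nrow = nrow(Y))
    })
    clipped <- Y < 0 | Y > 1
    n_clipped <- sum(clipped)
    if (n_clipped > 0) {
      Y <- pmin(pmax(Y, 0), 1)
      message(n_clipped, " sorted beta value(s) clipped to [0,1]")
    }
  }
  ann <- data.frame(sample_id = paste0(grid$subject, "_", grid$cell_type),
                    subject_id = grid$subject,
                    cell_label = grid$cell_type, stringsAsFactors = FALSE)
  bm <- beta_matrix(Y, ann, cpg_ids = rownames(truth$cell_profiles))
  attr(bm, "n_clipped") <- n_clipped
  bm
}

#' Simulation configuration
#'
#' Validated parameter set for [generate_dataset()]. Defaults state the
#' emulated design: 6 subjects, the 7-type whole-blood scheme with published
#' mean proportions, 5% planted differential CpGs per type with a 0.4 beta
#' effect, and 0.02 beta-scale noise for both mixed and sorted samples.
#'
#' @param n_cpgs,n_subjects design size.
#' @param scheme a [cell_type_scheme()].
#' @param mean_proportions named mean fractions (default per scheme).
#' @param proportion_mode `"fixed_remainder"` or `"dirichlet"`.
#' @param target varied target for `fixed_remainder` mode.
#' @param remainder_weights `"equal"` or `"mean"` (fixed_remainder mode).
#' @param concentration Dirichlet concentration.
#' @param diff_fraction,effect_size planted differential signal.
#' @param include_groupings also plant lineage-level differential CpGs (see
#'   [generate_cell_profiles()]).
#' @param noise_sd,within_subject_sd beta-scale noise sds (mixed / sorted).
#' @param seed master seed; stage seeds are derived from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cpgs = 5000, n_subjects = 6,
                              scheme = blood_scheme(),
                              mean_proportions = NULL,
                              proportion_mode = c("fixed_remainder",
                                                  "dirichlet"),
                              target = NULL,
                              remainder_weights = c("equal", "mean"),
                              concentration = 100,
                              diff_fraction = 0.05, effect_size = 0.4,
                              include_groupings = FALSE,
                              noise_sd = 0.02, within_subject_sd = 0.02,
                              seed = 1L) {
  proportion_mode <- match.arg(proportion_mode)
  remainder_weights <- match.arg(remainder_weights)
  cfg <- list(n_cpgs = n_cpgs, n_subjects = n_subjects, scheme = scheme,
              mean_proportions = mean_proportions,
              proportion_mode = proportion_mode, target = target,
              remainder_weights = remainder_weights,
              concentration = concentration, diff_fraction = diff_fraction,
              effect_size = effect_size,
              include_groupings = isTRUE(include_groupings),
              noise_sd = noise_sd,
              within_subject_sd = within_subject_sd, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid config field '%s': %s", field, msg),
                  call. = FALSE)
  }
  chk(is.numeric(cfg$n_cpgs) && cfg$n_cpgs >= 1, "n_cpgs", "positive count")
  chk(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 2, "n_subjects",
      ">= 2 required")
  chk(inherits(cfg$scheme, "cell_type_scheme"), "scheme",
      "not a cell_type_scheme")
  chk(cfg$proportion_mode %in% c("fixed_remainder", "dirichlet"),
      "proportion_mode", "unknown mode")
  chk(is.numeric(cfg$concentration) && cfg$concentration > 0,
      "concentration", "> 0 required")
  chk(is.numeric(cfg$diff_fraction) && cfg$diff_fraction >= 0 &&
        cfg$diff_fraction <= 1, "diff_fraction", "in [0,1]")
  chk(is.numeric(cfg$effect_size) && cfg$effect_size > 0 &&
        cfg$effect_size <= 1, "effect_size", "in (0,1]")
  chk(is.numeric(cfg$noise_sd) && all(cfg$noise_sd >= 0), "noise_sd",
      ">= 0 required")
  chk(is.numeric(cfg$within_subject_sd) && cfg$within_subject_sd >= 0,
      "within_subject_sd", ">= 0 required")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && !is.na(cfg$seed),
      "seed", "single integer required")
  if (!is.null(cfg$target)) resolve_target(cfg$target, cfg$scheme)
  invisible(cfg)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Recognized fields: n_cpgs, n_subjects, cell_types, groupings,
#' mean_proportions, proportion_mode, target, remainder_weights,
#' concentration, diff_fraction, effect_size, noise_sd, within_subject_sd,
#' seed. Omitted fields take [simulation_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  scheme <- if (!is.null(raw$cell_types)) {
    cell_type_scheme(raw$cell_types,
                     if (is.null(raw$groupings)) list() else
                       lapply(raw$groupings, unlist))
  } else {
    blood_scheme()
  }
  mp <- raw$mean_proportions
  if (!is.null(mp)) mp <- unlist(mp)
  args <- raw[intersect(names(raw),
                        c("n_cpgs", "n_subjects", "proportion_mode", "target",
                          "remainder_weights", "concentration",
                          "diff_fraction", "effect_size", "include_groupings",
                          "noise_sd", "within_subject_sd", "seed"))]
  do.call(simulation_config,
          c(args, list(scheme = scheme, mean_proportions = mp)))
}

#' Generate a full paired sorted/mixed dataset
#'
#' Runs the generator end to end: cell profiles, per-sample proportions,
#' mixed whole-tissue samples and per-subject sorted samples, all seeded
#' deterministically from the config's master seed.
#'
#' @param config a [simulation_config()].
#' @return An object of class `synthetic_bundle`: list with `sorted_data`,
#'   `mixed_data`, `proportions`, `truth`, `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  validate_simulation_config(config)
  truth <- generate_cell_profiles(
    n_cpgs = config$n_cpgs, scheme = config$scheme,
    diff_fraction = config$diff_fraction, effect_size = config$effect_size,
    include_groupings = config$include_groupings,
    seed = config$seed, noise_sd = config$noise_sd,
    proportion_mode = config$proportion_mode,
    mean_proportions = config$mean_proportions)
  props <- draw_proportions(config$n_subjects, truth,
                            concentration = config$concentration,
                            seed = config$seed + 1L, target = config$target,
                            remainder_weights = config$remainder_weights)
  mixed <- mix_samples(truth, props, seed = config$seed + 2L)
  sorted <- generate_cell_sorted_samples(truth, config$n_subjects,
                                         within_subject_sd =
                                           config$within_subject_sd,
                                         seed = config$seed + 3L)
  structure(list(sorted_data = sorted, mixed_data = mixed,
                 proportions = props, truth = truth, config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d CpGs; %d sorted + %d mixed samples\n",
              ncol(x$mixed_data$values), nrow(x$sorted_data$values),
              nrow(x$mixed_data$values)))
  invisible(x)
}

#' Write a synthetic bundle to a directory
#'
#' Emits `betas_sorted.tsv`, `betas_mixed.tsv`, `proportions.tsv` and
#' `truth.json` (profiles, planted sets, clipping log, generator settings).
#'
#' @param bundle a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(bundle$sorted_data, file.path(dir, "betas_sorted.tsv"))
  write_beta_matrix(bundle$mixed_data, file.path(dir, "betas_mixed.tsv"))
  write_proportions(bundle$proportions, file.path(dir, "proportions.tsv"))
  tr <- bundle$truth
  truth_json <- list(
    cell_types = colnames(tr$cell_profiles),
    cpg_ids = rownames(tr$cell_profiles),
    cell_profiles = unname(as.data.frame(tr$cell_profiles)),
    differential_sets = tr$differential_sets,
    effect_size = tr$effect_size, noise_sd = tr$noise_sd,
    proportion_mode = tr$proportion_mode,
    mean_proportions = as.list(tr$mean_proportions),
    seed = tr$seed, clipping = tr$clipping)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
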