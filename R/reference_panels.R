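#' Cell-sorted reference estimate of a type's methylation difference
#'
#' The ground-truth quantity the regression slope is judged against: per CpG,
#' the mean beta over the sorted samples purified to the target (or to any
#' member of a grouping) minus the pooled mean over all other sorted samples,
#' each sample weighted equally. Mixed samples are always excluded.
#'
#' @param sorted a [beta_matrix()] of sorted samples (labels must be base
#'   types; any `"mixed"` rows are dropped).
#' @param target base type or grouping name.
#' @param scheme a [cell_type_scheme()].
#' @return An object of class `cell_sorted_reference`: data.frame with
#'   columns `target`, `cpg_id`, `cell_sorted_estimate`, with attributes
#'   `n_target`/`n_other` (sample counts).
#' @export
cell_sorted_estimate <- function(sorted, target, scheme) {
  stopifnot(inherits(sorted, "beta_matrix"))
  members <- resolve_target(target, scheme)
  if (length(members) >= length(scheme$base_types)) {
    stop("target covers all base types: no complement to compare against",
         call. = FALSE)
  }
  keep <- sorted$samples$cell_label %in% scheme$base_types
  lab <- sorted$samples$cell_label[keep]
  V <- sorted$values[keep, , drop = FALSE]
  in_t <- lab %in% members
  if (!any(in_t) || !all(scheme$base_types %in% lab)) {
    stop("sorted data must contain at least one sample per base type",
         call. = FALSE)
  }
  est <- colMeans(V[in_t, , drop = FALSE]) - colMeans(V[!in_t, , drop = FALSE])
  out <- data.frame(target = target, cpg_id = colnames(V),
                    cell_sorted_estimate = unname(est),
                    stringsAsFactors = FALSE)
  attr(out, "n_target") <- sum(in_t)
  attr(out, "n_other") <- sum(!in_t)
  class(out) <- c("cell_sorted_reference", "data.frame")
  out
}

#' Two-sided two-sample pooled t-test
#'
#' Classic equal-variance t statistic with `df = n_a + n_b - 2` and a
#' two-sided p-value. Degenerate inputs follow fixed conventions: zero pooled
#' variance with equal means gives `t = 0, p = 1`; zero pooled variance with
#' unequal means gives an infinite statistic, `p = 0`, and `degenerate =
#' TRUE`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return List with `statistic`, `p_value`, `df`, `degenerate`.
#' @export
pooled_t_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  df <- na + nb - 2
  sp2 <- (sum((group_a - mean(group_a))^2) +
            sum((group_b - mean(group_b))^2)) / df
  delta <- mean(group_a) - mean(group_b)
  if (sp2 <= 0) {
    if (delta == 0) {
      return(list(statistic = 0, p_value = 1, df = df, degenerate = FALSE))
    }
    return(list(statistic = sign(delta) * Inf, p_value = 0, df = df,
                degenerate = TRUE))
  }
  t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       df = df, degenerate = FALSE)
}

# vectorized pooled t over the columns of two sample-by-CpG matrices
row_pooled_t <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  df <- na + nb - 2
  ma <- colMeans(A); mb <- colMeans(B)
  ssa <- colSums(A^2) - na * ma^2
  ssb <- colSums(B^2) - nb * mb^2
  sp2 <- pmax(ssa + ssb, 0) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  delta <- ma - mb
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- ifelse(is.finite(t), 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              0)
  p[t == 0 & se == 0] <- 1
  list(statistic = t, p_value = p, df = df)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up FDR adjustment: sort p ascending, multiply by `n / rank`,
#' enforce monotonicity from the largest down, cap at 1. Ties are handled by
#' stable ordering.
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return Vector of q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  n <- length(p_values)
  o <- order(p_values)
  q <- pmin(1, rev(cummin(rev(p_values[o] * n / seq_len(n)))))
  q[order(o)]
}

#' Select a candidate cell-associated CpG panel
#'
#' Splits the sorted samples into target (purified to the target type, or to
#' any member of the target grouping) versus the rest, runs a two-sided
#' pooled t-test per CpG, adjusts with Benjamini-Hochberg, and keeps CpGs
#' with `q <= fdr`. Selected CpGs carry their cell-sorted reference
#' estimates; rows are ordered by ascending p-value, ties by CpG id.
#'
#' @param sorted a [beta_matrix()] of sorted samples.
#' @param target base type or grouping name.
#' @param scheme a [cell_type_scheme()].
#' @param fdr nominal FDR threshold in (0, 1\]; default `1e-4`.
#' @return An object of class `candidate_panel`: data.frame with columns
#'   `cpg_id`, `target`, `t_stat`, `p_value`, `q_value`,
#'   `cell_sorted_estimate`; attribute `fdr_threshold`.
#' @export
select_candidate_panel <- function(sorted, target, scheme, fdr = 1e-4) {
  stopifnot(inherits(sorted, "beta_matrix"))
  if (!is.numeric(fdr) || fdr <= 0 || fdr > 1) {
    stop("fdr must be in (0,1]", call. = FALSE)
  }
  members <- resolve_target(target, scheme)
  keep <- sorted$samples$cell_label %in% scheme$base_types
  lab <- sorted$samples$cell_label[keep]
  V <- sorted$values[keep, , drop = FALSE]
  miss <- colSums(is.na(V)) > 0
  if (any(miss)) {
    message(sum(miss), " CpG(s) with missing sorted values dropped")
    V <- V[, !miss, drop = FALSE]
  }
  in_t <- lab %in% members
  tt <- row_pooled_t(V[in_t, , drop = FALSE], V[!in_t, , drop = FALSE])
  q <- bh_adjust(tt$p_value)
  ref <- cell_sorted_estimate(subset_beta(sorted, samples = keep,
                                          cpgs = colnames(V)),
                              target, scheme)
  sel <- which(q <= fdr)
  out <- data.frame(cpg_id = colnames(V)[sel],
                    target = rep(target, length(sel)),
                    t_stat = tt$statistic[sel], p_value = tt$p_value[sel],
                    q_value = q[sel],
                    cell_sorted_estimate = ref$cell_sorted_estimate[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) {
    warning(sprintf("no CpGs pass FDR %g for target '%s'", fdr, target),
            call. = FALSE)
  }
  attr(out, "fdr_threshold") <- fdr
  class(out) <- c("candidate_panel", "data.frame")
  out
}

#' Write/read a candidate or robust panel TSV
#' @param panel panel data.frame.
#' @param path file path.
#' @return `path` (write) or the panel data.frame (read).
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
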