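#' Beta-value matrix with sample annotations
#'
#' Container for methylation beta values (fractions in \[0,1\]) with samples
#' in rows and CpGs in columns, plus per-sample annotations: `sample_id`,
#' `subject_id` and `cell_label` (a base cell-type name for sorted samples,
#' `"mixed"` for whole-tissue samples).
#'
#' @param values numeric matrix, samples x CpGs; dimnames optional (taken
#'   from `samples$sample_id` and `cpg_ids`).
#' @param samples data.frame with columns `sample_id`, `subject_id`,
#'   `cell_label`, one row per row of `values`.
#' @param cpg_ids character vector of unique CpG identifiers (defaults to
#'   `colnames(values)`).
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, samples, cpg_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cpg_ids)) {
    stop("cpg_ids required when values has no column names", call. = FALSE)
  }
  cpg_ids <- as.character(cpg_ids)
  stopifnot(is.data.frame(samples))
  need <- c("sample_id", "subject_id", "cell_label")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns sample_id, subject_id, cell_label",
         call. = FALSE)
  }
  samples <- as.data.frame(samples)[, need]
  samples$sample_id <- as.character(samples$sample_id)
  samples$subject_id <- as.character(samples$subject_id)
  samples$cell_label <- as.character(samples$cell_label)
  if (nrow(samples) != nrow(values)) {
    stop("samples has ", nrow(samples), " rows but values has ",
         nrow(values), call. = FALSE)
  }
  if (length(cpg_ids) != ncol(values)) {
    stop("cpg_ids length does not match number of columns", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in beta matrix", call. = FALSE)
  }
  if (anyDuplicated(cpg_ids)) {
    stop("duplicate cpg_id in beta matrix", call. = FALSE)
  }
  check_beta_range(values, cpg_ids, samples$sample_id)
  dimnames(values) <- list(samples$sample_id, cpg_ids)
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples),
            class = "beta_matrix")
}

# beta values must be in [0,1] up to tolerance; NA allowed (flagged missing)
check_beta_range <- function(values, cpg_ids, sample_ids, tol = 1e-9) {
  bad <- which(!is.na(values) & (values < -tol | values > 1 + tol),
               arr.ind = TRUE)
  if (nrow(bad)) {
    show <- utils::head(bad, 5L)
    cells <- apply(show, 1L, function(ij) {
      sprintf("[%s, %s]=%g", sample_ids[ij[1L]], cpg_ids[ij[2L]],
              values[ij[1L], ij[2L]])
    })
    stop(sprintf("%d beta value(s) outside [0,1]: %s%s", nrow(bad),
                 paste(cells, collapse = ", "),
                 if (nrow(bad) > 5L) ", ..." else ""), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d samples x %d CpGs\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$cell_label)
  cat("  labels:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Subset a beta matrix by samples and/or CpGs
#' @param x a [beta_matrix()].
#' @param samples logical/integer/character index into samples.
#' @param cpgs logical/integer/character index into CpGs.
#' @return A [beta_matrix()].
#' @export
subset_beta <- function(x, samples = NULL, cpgs = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  v <- x$values
  s <- x$samples
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, s$sample_id) else samples
    v <- v[idx, , drop = FALSE]
    s <- s[idx, , drop = FALSE]
  }
  if (!is.null(cpgs)) v <- v[, cpgs, drop = FALSE]
  beta_matrix(v, s)
}

sniff_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
}

#' Read a beta-value matrix from TSV/CSV
#'
#' With `samples_in_rows` (the format this package writes) the file has
#' columns `sample_id`, `subject_id`, `cell_label` followed by one column per
#' CpG. With `cpgs_in_rows` the first column is `cpg_id` and the remaining
#' columns are samples; annotations then default to `subject_id = sample_id`
#' and `cell_label = "mixed"`.
#'
#' @param path file path; delimiter (tab or comma) is sniffed from the header.
#' @param orientation `"samples_in_rows"` or `"cpgs_in_rows"`.
#' @return A [beta_matrix()]; values outside \[0,1\] raise an error naming
#'   the offending cells.
#' @export
read_beta_matrix <- function(path,
                             orientation = c("samples_in_rows",
                                             "cpgs_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (orientation == "samples_in_rows") {
    need <- c("sample_id", "subject_id", "cell_label")
    if (!all(need %in% names(df))) {
      stop("expected columns sample_id, subject_id, cell_label", call. = FALSE)
    }
    ann <- df[, need]
    vals <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
    storage.mode(vals) <- "double"
    beta_matrix(vals, ann, cpg_ids = colnames(vals))
  } else {
    cpg <- as.character(df[[1L]])
    vals <- t(as.matrix(df[, -1L, drop = FALSE]))
    storage.mode(vals) <- "double"
    ann <- data.frame(sample_id = rownames(vals),
                      subject_id = rownames(vals),
                      cell_label = "mixed", stringsAsFactors = FALSE)
    beta_matrix(vals, ann, cpg_ids = cpg)
  }
}

#' Write a beta matrix as TSV (samples in rows)
#' @param x a [beta_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "beta_matrix"))
  df <- cbind(x$samples, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample cell-type proportion table
#'
#' Validates and normalizes a table of per-sample cell-type fractions: one
#' row per mixed sample (`sample_id`) and one column per base type in the
#' scheme. Fractions must be nonnegative; row sums within 1e-6 of 1 are
#' accepted as-is, deviations up to 0.02 are renormalized with a warning,
#' larger deviations are an error. Percent input (row sums near 100) is
#' auto-detected and divided by 100.
#'
#' @param df data.frame with `sample_id` plus one column per base type.
#' @param scheme a [cell_type_scheme()].
#' @return A data.frame of class `proportion_table`.
#' @export
proportion_table <- function(df, scheme) {
  stopifnot(is.data.frame(df), inherits(scheme, "cell_type_scheme"))
  if (!"sample_id" %in% names(df)) {
    stop("proportion table needs a sample_id column", call. = FALSE)
  }
  missing <- setdiff(scheme$base_types, names(df))
  if (length(missing)) {
    stop("proportion table lacks cell-type column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, c("sample_id", scheme$base_types)]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in proportion table", call. = FALSE)
  }
  m <- as.matrix(df[, scheme$base_types])
  if (any(is.na(m))) stop("missing proportion values", call. = FALSE)
  if (any(m < 0)) stop("negative cell-type fraction", call. = FALSE)
  rs <- rowSums(m)
  if (stats::median(rs) > 50) {  # percent input
    message("proportions look like percentages (row sums ~100); dividing by 100")
    m <- m / 100
    rs <- rs / 100
  }
  dev <- abs(rs - 1)
  if (any(dev > 0.02)) {
    i <- which.max(dev)
    stop(sprintf("row sum %.4f for sample '%s' deviates from 1 by more than 0.02",
                 rs[i], df$sample_id[i]), call. = FALSE)
  }
  if (any(dev > 1e-6)) {
    warning(sprintf("%d proportion row(s) renormalized to sum 1 (max deviation %.4g)",
                    sum(dev > 1e-6), max(dev)), call. = FALSE)
  }
  m <- m / rs
  df[, scheme$base_types] <- m
  class(df) <- c("proportion_table", "data.frame")
  df
}

#' Read a cell-type proportion table
#' @param path TSV/CSV with `sample_id` plus one column per base type;
#'   percent or fraction units are auto-detected.
#' @param scheme a [cell_type_scheme()].
#' @return A [proportion_table()].
#' @export
read_proportions <- function(path, scheme) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  proportion_table(df, scheme)
}

#' Write a proportion table as TSV
#' @param props a [proportion_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(props, path) {
  utils::write.table(as.data.frame(props), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
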