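#' Cell-type scheme: base leukocyte types and named lineage groupings
#'
#' A scheme defines the K base cell types appearing in sorted data and
#' proportion tables, plus named groupings (nonempty proper subsets of the
#' base types) that can be used as estimation targets, e.g. a lymphocyte
#' lineage treated as a single target by summing member proportions.
#'
#' @param base_types character vector of unique cell-type names (K >= 2).
#' @param groupings named list; each element a character vector of member
#'   base types forming a nonempty, proper subset of `base_types`.
#' @return An object of class `cell_type_scheme` with elements `base_types`
#'   and `groupings`.
#' @examples
#' cell_type_scheme(c("A", "B", "C"), list(AB = c("A", "B")))
#' @export
cell_type_scheme <- function(base_types, groupings = list()) {
  base_types <- as.character(base_types)
  if (length(base_types) < 2L) {
    stop("a cell-type scheme needs at least two base types", call. = FALSE)
  }
  if (anyDuplicated(base_types)) {
    stop("base cell-type names must be unique", call. = FALSE)
  }
  if ("mixed" %in% base_types) {
    stop("'mixed' is reserved for whole-tissue samples", call. = FALSE)
  }
  if (length(groupings)) {
    if (is.null(names(groupings)) || any(!nzchar(names(groupings)))) {
      stop("groupings must be a named list", call. = FALSE)
    }
    for (nm in names(groupings)) {
      g <- unique(as.character(groupings[[nm]]))
      if (!length(g) || !all(g %in% base_types)) {
        stop(sprintf("grouping '%s' must be a nonempty subset of base types", nm),
             call. = FALSE)
      }
      if (length(g) >= length(base_types)) {
        stop(sprintf("grouping '%s' must be a proper subset of base types", nm),
             call. = FALSE)
      }
      groupings[[nm]] <- g
    }
  }
  structure(list(base_types = base_types, groupings = groupings),
            class = "cell_type_scheme")
}

#' @export
print.cell_type_scheme <- function(x, ...) {
  cat("<cell_type_scheme> ", length(x$base_types), " base types: ",
      paste(x$base_types, collapse = ", "), "\n", sep = "")
  for (nm in names(x$groupings)) {
    cat("  ", nm, ": ", paste(x$groupings[[nm]], collapse = " + "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Default whole-blood leukocyte scheme
#'
#' Seven flow-sortable leukocyte subtypes and the five standard lineage
#' groupings used as estimation targets: Lymphocyte-I (all lymphocytes),
#' Lymphocyte-II (lymphocytes without CD19+ B), Myeloid-I (all myeloids),
#' Myeloid-II (granulocytes) and Pan-T.
#'
#' @return A [cell_type_scheme()].
#' @export
blood_scheme <- function() {
  cell_type_scheme(
    base_types = c("Neutrophil", "Eosinophil", "CD4T", "CD8T",
                   "CD19B", "NK", "Monocyte"),
    groupings = list(
      "Lymphocyte-I"  = c("CD4T", "CD8T", "CD19B", "NK"),
      "Lymphocyte-II" = c("CD4T", "CD8T", "NK"),
      "Myeloid-I"     = c("Neutrophil", "Eosinophil", "Monocyte"),
      "Myeloid-II"    = c("Neutrophil", "Eosinophil"),
      "Pan-T"         = c("CD4T", "CD8T")
    )
  )
}

#' Mean leukocyte fractions of whole blood (FACS)
#'
#' Published mean cell-subtype percentages of whole blood in healthy adults
#' (Neutrophil 65.0, CD4+T 13.4, CD8+T 6.1, NK 2.4, CD19+B 3.0, Monocyte 5.4,
#' Eosinophil 3.8). The printed percentages sum to 99.1 because of rounding;
#' with `normalize = TRUE` (the generator default) they are rescaled to sum
#' exactly to 1.
#'
#' @param normalize logical; rescale to sum 1 (fractions) instead of keeping
#'   the printed values.
#' @param percent logical; return percentages instead of fractions.
#' @return Named numeric vector over [blood_scheme()] base types.
#' @export
blood_mean_proportions <- function(normalize = TRUE, percent = FALSE) {
  pct <- c(Neutrophil = 65.0, Eosinophil = 3.8, CD4T = 13.4, CD8T = 6.1,
           CD19B = 3.0, NK = 2.4, Monocyte = 5.4)
  out <- if (normalize) pct / sum(pct) else pct / 100
  if (percent) out * 100 else out
}

#' Resolve an estimation target to its member base types
#' @keywords internal
resolve_target <- function(target, scheme) {
  stopifnot(inherits(scheme, "cell_type_scheme"))
  if (length(target) != 1L || !is.character(target)) {
    stop("target must be a single cell-type or grouping name", call. = FALSE)
  }
  if (target %in% scheme$base_types) return(target)
  if (target %in% names(scheme$groupings)) return(scheme$groupings[[target]])
  stop(sprintf("unknown target '%s': not a base type or grouping", target),
       call. = FALSE)
}

#' Agglomerate per-sample proportions for a target type or grouping
#'
#' For a base type, its column; for a lineage grouping, the sum of the member
#' columns — the regression covariate for that target. Also accepts a named
#' numeric vector (e.g. published mean percentages) in place of a table.
#'
#' @param props a `proportion_table` (or plain data.frame with a `sample_id`
#'   column plus one column per base type), or a named numeric vector.
#' @param target a base type name or grouping name in `scheme`.
#' @param scheme a [cell_type_scheme()].
#' @return Numeric vector of target fractions, named by sample id when
#'   `props` is a table.
#' @examples
#' agglomerate_proportions(blood_mean_proportions(FALSE, percent = TRUE),
#'                         "Myeloid-I", blood_scheme())  # 74.2
#' @export
agglomerate_proportions <- function(props, target, scheme) {
  members <- resolve_target(target, scheme)
  if (is.numeric(props) && !is.null(names(props))) {
    missing <- setdiff(members, names(props))
    if (length(missing)) {
      stop("proportion vector lacks: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    return(sum(props[members]))
  }
  stopifnot(is.data.frame(props))
  missing <- setdiff(members, names(props))
  if (length(missing)) {
    stop("proportion table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- rowSums(props[, members, drop = FALSE])
  names(out) <- props$sample_id
  out
}
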