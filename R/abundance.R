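#' Construct an abundance table
#'
#' The common currency of the pipeline: a samples x features matrix of
#' non-negative relative abundances (or count-like values) with optional
#' per-feature lineage/class metadata.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   dimnames set to sample and feature ids.
#' @param feature_meta optional data.frame of per-feature metadata (one row per
#'   feature, rownames matching feature ids), e.g. parsed taxonomic ranks or a
#'   metabolite class column.
#' @param scale_tag one of `"percent"`, `"proportion"`, `"count"`. Percent rows
#'   must sum to at most 100, proportion rows to at most 1. Never guessed from
#'   the data.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, feature_meta = NULL,
                            scale_tag = c("percent", "proportion", "count")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature id: ", colnames(values)[duplicated(colnames(values))][1L])
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at (%s, %s); missing cells are not imputed",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value %g at (%s, %s)", values[idx[1L], idx[2L]],
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  rs <- rowSums(values)
  if (scale_tag == "percent" && any(rs > 100 + 1e-6))
    stop("row sums exceed 100 for scale_tag = 'percent': ",
         rownames(values)[which.max(rs)])
  if (scale_tag == "proportion" && any(rs > 1 + 1e-9))
    stop("row sums exceed 1 for scale_tag = 'proportion': ",
         rownames(values)[which.max(rs)])
  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta)
    if (nrow(feature_meta) != ncol(values))
      stop("feature_meta must have one row per feature")
    rownames(feature_meta) <- colnames(values)
  }
  structure(list(values = values, feature_meta = feature_meta,
                 scale_tag = scale_tag),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  if (!is.null(x$feature_meta))
    cat("feature metadata columns:", paste(colnames(x$feature_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' @rdname abundance_table
#' @param x an `abundance_table`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname abundance_table
#' @export
feature_ids <- function(x) colnames(x$values)

#' Subset an abundance table
#'
#' @param x an `abundance_table`.
#' @param i sample selector, `j` feature selector (as for a matrix).
#' @param j see `i`.
#' @param ... ignored.
#' @export
`[.abundance_table` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  fm <- if (is.null(x$feature_meta)) NULL else x$feature_meta[colnames(v), , drop = FALSE]
  abundance_table(v, fm, x$scale_tag)
}

#' Construct a cohort design
#'
#' Per-sample group label (disease/control) plus clinical covariates; the input
#' to matching and balance diagnostics.
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character/factor with levels `disease` and `control`.
#' @param covariates data.frame of clinical covariates (numeric or categorical),
#'   one row per sample, or NULL.
#' @return a data.frame of class `cohort_design` with columns `sample_id`,
#'   `group`, then the covariates.
#' @export
cohort_design <- function(sample_id, group, covariates = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicated sample id: ", sample_id[duplicated(sample_id)][1L])
  group <- as.character(group)
  bad <- setdiff(unique(group), c("disease", "control"))
  if (length(bad))
    stop("group labels must be 'disease'/'control'; got: ",
         paste(bad, collapse = ", "))
  df <- data.frame(sample_id = sample_id,
                   group = factor(group, levels = c("control", "disease")),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(sample_id))
      stop("covariates must have one row per sample")
    df <- cbind(df, covariates)
  }
  rownames(df) <- sample_id
  class(df) <- c("cohort_design", "data.frame")
  df
}

#' @export
print.cohort_design <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("cohort_design: %d samples (%d disease / %d control), covariates: %s\n",
              nrow(x), tab[["disease"]], tab[["control"]],
              paste(design_covariate_names(x), collapse = ", ")))
  invisible(x)
}

design_covariate_names <- function(design) {
  setdiff(colnames(design), c("sample_id", "group"))
}

#' Check that a design covers the samples of a table
#'
#' @param design a `cohort_design`.
#' @param table an `abundance_table`.
#' @keywords internal
check_design_covers <- function(design, table) {
  missing <- setdiff(sample_ids(table), design$sample_id)
  if (length(missing))
    stop("samples absent from design: ", paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}
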