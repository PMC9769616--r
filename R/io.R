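#' Read an abundance table from disk
#'
#' Two dialects are supported. `"lineage"` is the merged-profiler layout:
#' feature rows labelled with a pipe-separated taxonomy (first column
#' `clade_name`, e.g. `k__Bacteria|p__Firmicutes|...|s__x`), one column per
#' sample. `"plain"` is a rectangular TSV/CSV with a header; orientation is
#' given by `orientation`. In memory the canonical orientation is always
#' samples x features.
#'
#' The scale is taken from `scale_tag`, never guessed from the data: silent
#' percent/proportion rescaling is a classic source of error in microbiome
#' work.
#'
#' @param path file path.
#' @param dialect `"lineage"` or `"plain"`.
#' @param scale_tag `"percent"`, `"proportion"` or `"count"`.
#' @param orientation for the plain dialect: `"features_x_samples"` (default,
#'   the common on-disk layout) or `"samples_x_features"`.
#' @param sep field separator; default tab.
#' @return an [abundance_table].
#' @export
read_abundance_table <- function(path,
                                 dialect = c("lineage", "plain"),
                                 scale_tag = c("percent", "proportion", "count"),
                                 orientation = c("features_x_samples",
                                                 "samples_x_features"),
                                 sep = "\t") {
  dialect <- match.arg(dialect)
  scale_tag <- match.arg(scale_tag)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("table must have an id column plus data columns: ", path)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature/sample id in first column: ",
         ids[duplicated(ids)][1L])
  num <- raw[, -1L, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    col <- colnames(num)[bad][1L]
    v <- suppressWarnings(as.numeric(num[[col]]))
    row <- which(is.na(v) & !is.na(num[[col]]))[1L]
    stop(sprintf("non-numeric cell at (row '%s', column '%s')",
                 if (is.na(row)) "?" else ids[row], col))
  }
  m <- as.matrix(num)
  rownames(m) <- ids

  feature_meta <- NULL
  if (dialect == "lineage") {
    # lineage rows: features x samples always
    feature_meta <- parse_lineages(ids)
    m <- t(m)
  } else if (orientation == "features_x_samples") {
    m <- t(m)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample id: ", rownames(m)[duplicated(rownames(m))][1L])
  abundance_table(m, feature_meta = feature_meta, scale_tag = scale_tag)
}

# Parse "k__A|p__B|...|s__x" lineage strings into rank columns.
parse_lineages <- function(lineages) {
  ranks <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus", s = "species")
  out <- data.frame(lineage = lineages, stringsAsFactors = FALSE)
  for (r in ranks) out[[r]] <- NA_character_
  parts <- strsplit(lineages, "|", fixed = TRUE)
  for (i in seq_along(parts)) {
    for (p in parts[[i]]) {
      pref <- sub("__.*$", "", p)
      if (pref %in% names(ranks))
        out[i, ranks[[pref]]] <- sub("^.__", "", p)
    }
  }
  out
}

#' Write an abundance table to TSV
#'
#' @param x an [abundance_table].
#' @param path output path.
#' @param orientation on-disk orientation (default features x samples, the
#'   common interchange layout).
#' @export
write_abundance_table <- function(x, path,
                                  orientation = c("features_x_samples",
                                                  "samples_x_features")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "features_x_samples") t(x$values) else x$values
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- if (orientation == "features_x_samples") "feature_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort design table
#'
#' @param path CSV/TSV path with a sample-id column, a group column and
#'   covariate columns.
#' @param sample_col,group_col column names.
#' @param synonyms named character vector mapping raw group labels to
#'   `disease`/`control`, e.g. `c(SCAD = "disease", HC = "control")`. Labels
#'   already equal to `disease`/`control` need no entry.
#' @param sep field separator; `NULL` to infer from the file extension.
#' @return a [cohort_design].
#' @export
read_design <- function(path, sample_col = "sample_id", group_col = "group",
                        synonyms = c(disease = "disease", control = "control"),
                        sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (!sample_col %in% colnames(df)) stop("missing sample id column: ", sample_col)
  if (!group_col %in% colnames(df)) stop("missing group column: ", group_col)
  ids <- as.character(df[[sample_col]])
  if (anyDuplicated(ids)) stop("duplicated sample id: ", ids[duplicated(ids)][1L])
  raw_group <- as.character(df[[group_col]])
  map <- c(synonyms, disease = "disease", control = "control")
  unknown <- setdiff(unique(raw_group), names(map))
  if (length(unknown))
    stop("unknown group label(s) ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(names(map), collapse = ", "))
  group <- unname(map[raw_group])
  cov <- df[, setdiff(colnames(df), c(sample_col, group_col)), drop = FALSE]
  if (ncol(cov) == 0) cov <- NULL
  cohort_design(ids, group, cov)
}

#' Read a rooted phylogeny from Newick
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree, validated: unique leaf names, non-negative
#'   branch lengths, rooted.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("Newick parse error in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  validate_phylogeny(tree)
  tree
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogeny")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf name: ", tree$tip.label[duplicated(tree$tip.label)][1L])
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length: ", min(tree$edge.length))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(TRUE)
}

#' Write a phylogeny to Newick
#'
#' Round-trips through [read_newick] preserve topology and branch lengths to
#' 1e-9.
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Write a rectangular result table as TSV
#'
#' Header carried, stable column order, no quoting or row names.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_results <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
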