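#' Prevalence filter
#'
#' Keeps features detected (nonzero) in strictly more than `min_fraction` of
#' samples — so at the default 0.10, a feature present in exactly 10% of
#' samples is removed.
#'
#' @param table an [abundance_table].
#' @param min_fraction in `[0, 1)`.
#' @param renormalize re-close rows to their original scale after filtering
#'   (default FALSE: abundances are left as-is).
#' @return the filtered [abundance_table].
#' @export
prevalence_filter <- function(table, min_fraction = 0.10, renormalize = FALSE) {
  if (min_fraction < 0 || min_fraction >= 1) stop("min_fraction must be in [0, 1)")
  prev <- colMeans(table$values > 0)
  keep <- prev > min_fraction
  if (!any(keep)) stop("prevalence filter removed all features")
  out <- table[, keep]
  if (renormalize) {
    target <- switch(table$scale_tag, percent = 100, proportion = 1, NA_real_)
    if (!is.na(target)) {
      rs <- rowSums(out$values)
      rs[rs == 0] <- 1
      out$values <- out$values / rs * target
    }
  }
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences are disease minus control per pair. Zero differences are
#' discarded (classic Wilcoxon, default) or kept with Pratt's zero-rank method.
#' Exact p by enumeration of sign assignments when the effective n is at most
#' `exact_max` and no |d| are tied; otherwise normal approximation with tie
#' correction and continuity correction.
#'
#' @param values named numeric vector over samples.
#' @param pairs a `pair_set` (or data.frame with `disease_sample`,
#'   `control_sample`).
#' @param zero_policy `"discard"` or `"pratt"`.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @param exact_max cutoff for the exact computation (default 12).
#' @return list: `statistic` (W+, sum of positive ranks), `p_value`,
#'   `n_effective`, `degenerate` (TRUE when no nonzero differences; p is then
#'   reported as 1).
#' @export
paired_signed_rank <- function(values, pairs, zero_policy = c("discard", "pratt"),
                               alternative = "two.sided", exact_max = 12) {
  zero_policy <- match.arg(zero_policy)
  miss <- setdiff(c(pairs$disease_sample, pairs$control_sample), names(values))
  if (length(miss)) stop("values missing for sample(s): ", paste(miss, collapse = ", "))
  d <- values[pairs$disease_sample] - values[pairs$control_sample]
  nz <- d != 0
  n_eff <- sum(nz)
  if (n_eff == 0)
    return(list(statistic = 0, p_value = 1, n_effective = 0L, degenerate = TRUE))
  if (zero_policy == "discard") {
    dd <- d[nz]
    ties <- anyDuplicated(abs(dd)) > 0
    exact <- n_eff <= exact_max && !ties
    wt <- suppressWarnings(stats::wilcox.test(dd, alternative = alternative,
                                              exact = exact, correct = TRUE))
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                n_effective = as.integer(n_eff), degenerate = FALSE))
  }
  # Pratt: rank |d| including zeros, drop zero ranks, normal approximation
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  n <- length(d)
  mu <- (n * (n + 1) / 2 - sum(r[d == 0])) / 2
  # variance with zero and tie adjustments (Pratt)
  tie_tab <- table(r[d != 0])
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(r[d == 0]^2) / 4 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w_plus - mu)
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(statistic = w_plus, p_value = min(p, 1), n_effective = as.integer(n_eff),
       degenerate = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; a thin, name-preserving wrapper over
#' `p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and names.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired differential-abundance table
#'
#' One row per feature: paired signed-rank statistic and p, BH q across the
#' table (one family per table), direction, and a zero-robust median paired
#' log2 ratio (pseudo-count = half the smallest nonzero value in the table).
#'
#' Pairs produced by matching with replacement reuse controls; they are treated
#' as independent paired observations, as is conventional for quasi-paired
#' designs, and the result carries a `reused_controls` attribute surfacing the
#' caveat.
#'
#' @param table an [abundance_table] (typically prevalence-filtered).
#' @param pairs a `pair_set`.
#' @param alpha significance level on q (default 0.05).
#' @param zero_policy passed to [paired_signed_rank].
#' @return data.frame of class `diff_table`: `feature_id`, `n_effective_pairs`,
#'   `statistic`, `p_value`, `q_value`, `direction`, `median_log2_ratio`,
#'   `significant`; ordered by q then feature id.
#' @export
differential_table <- function(table, pairs, alpha = 0.05,
                               zero_policy = "discard") {
  m <- table$values
  miss <- setdiff(c(pairs$disease_sample, pairs$control_sample), rownames(m))
  if (length(miss)) stop("table missing sample(s): ", paste(miss, collapse = ", "))
  nzv <- m[m > 0]
  eps <- if (length(nzv)) min(nzv) / 2 else 0.5
  di <- match(pairs$disease_sample, rownames(m))
  ci <- match(pairs$control_sample, rownames(m))
  res <- lapply(colnames(m), function(f) {
    v <- m[, f]
    names(v) <- rownames(m)
    t <- paired_signed_rank(v, pairs, zero_policy = zero_policy)
    lr <- log2((v[di] + eps) / (v[ci] + eps))
    med <- stats::median(lr)
    data.frame(feature_id = f, n_effective_pairs = t$n_effective,
               statistic = t$statistic, p_value = t$p_value,
               direction = if (med > 0) "disease-up" else if (med < 0)
                 "disease-down" else "none",
               median_log2_ratio = med, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < alpha
  out <- out[order(out$q_value, out$feature_id),
             c("feature_id", "n_effective_pairs", "statistic", "p_value",
               "q_value", "direction", "median_log2_ratio", "significant")]
  rownames(out) <- NULL
  attr(out, "reused_controls") <- anyDuplicated(pairs$control_sample) > 0
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Hypergeometric annotation-set enrichment
#'
#' Upper-tail test per term: with `N` background features, `K` annotated to the
#' term, `n` selected and `k` selected-and-annotated, `p = P[X >= k]` for
#' `X ~ Hypergeom(N, K, n)`; BH across terms. Terms with no background
#' annotation are skipped.
#'
#' @param selected character vector of selected features (subset of
#'   `background`).
#' @param background character vector of background features.
#' @param annotation data.frame/matrix with two columns, feature and term (one
#'   row per assignment), or a named list term -> features.
#' @return data.frame class `enrichment_table`: `term_id`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, ordered by p.
#' @export
hypergeom_enrichment <- function(selected, background, annotation) {
  background <- unique(background)
  selected <- unique(selected)
  if (length(setdiff(selected, background)))
    stop("selected features must be a subset of the background")
  terms <- if (is.list(annotation) && !is.data.frame(annotation)) {
    annotation
  } else {
    ann <- as.data.frame(annotation, stringsAsFactors = FALSE)
    split(as.character(ann[[1L]]), as.character(ann[[2L]]))
  }
  N <- length(background)
  n <- length(selected)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), background)
    K <- length(members)
    if (K == 0) return(NULL)  # no background annotation: skipped
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(term_id = character(0), k = integer(0),
                                K = integer(0), n = integer(0), N = integer(0),
                                p_value = numeric(0), q_value = numeric(0)),
                     class = c("enrichment_table", "data.frame")))
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Exact conditional p from the hypergeometric distribution of the (1,1) cell.
#' A zero margin makes the table uninformative: p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return the p-value.
#' @export
fisher_one_sided <- function(tab, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab, alternative = alternative)$p.value
}
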