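#' Per-pair change-trend signs
#'
#' For each disease-control pair, the sign of the feature's change from the
#' matched control to the disease sample: +1, -1, or 0 when the absolute
#' difference is at most `tie_epsilon`.
#'
#' @param values named numeric vector over samples.
#' @param pairs a `pair_set`.
#' @param tie_epsilon differences with absolute value <= this map to 0
#'   (default 0: only exact ties).
#' @return integer vector in `{-1, 0, +1}` aligned to the pair order.
#' @export
pair_signs <- function(values, pairs, tie_epsilon = 0) {
  miss_d <- !(pairs$disease_sample %in% names(values))
  miss_c <- !(pairs$control_sample %in% names(values))
  if (any(miss_d | miss_c)) {
    i <- which(miss_d | miss_c)[1L]
    stop(sprintf("pair %s: missing sample value (%s / %s)",
                 pairs$pair_id[i] %||% i, pairs$disease_sample[i],
                 pairs$control_sample[i]))
  }
  d <- values[pairs$disease_sample] - values[pairs$control_sample]
  s <- sign(d)
  s[abs(d) <= tie_epsilon] <- 0L
  as.integer(s)
}

#' Normalized mutual information of two sign vectors
#'
#' Empirical mutual information from the joint contingency of the sign
#' categories (zeros form a genuine third category by default), normalized by
#' `sqrt(H(a) * H(b))` with natural-log entropies. A constant vector has zero
#' entropy; the score is then defined as 0 and flagged degenerate.
#'
#' @param a,b sign vectors of equal length (>= 2). Any discrete categories
#'   work; trend use passes `{-1, 0, +1}`.
#' @param variant `"sqrt"` (default) or `"mean"` normalization
#'   (`(H(a)+H(b))/2`).
#' @param zeros `"category"` (default) or `"drop"` (pairs with a zero in either
#'   vector removed first).
#' @return numeric scalar in `[0, 1]` with attribute `degenerate`.
#' @export
nmi <- function(a, b, variant = c("sqrt", "mean"), zeros = c("category", "drop")) {
  variant <- match.arg(variant)
  zeros <- match.arg(zeros)
  if (length(a) != length(b)) stop("sign vectors must have equal length")
  if (zeros == "drop") {
    keep <- a != 0 & b != 0
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < 2)
    return(structure(0, degenerate = TRUE))
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 || hb == 0)
    return(structure(0, degenerate = TRUE))
  mi <- 0
  for (i in seq_along(pa))
    for (j in seq_along(pb))
      if (pj[i, j] > 0)
        mi <- mi + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
  denom <- if (variant == "sqrt") sqrt(ha * hb) else (ha + hb) / 2
  structure(min(max(mi / denom, 0), 1), degenerate = FALSE)
}

#' Direction consistency of two trends
#'
#' +1 when at least as many pairs move in the same direction as move in
#' opposite directions; pairs with a zero sign in either vector do not vote.
#'
#' @param a,b sign vectors of equal length.
#' @return -1 or +1.
#' @export
direction_sign <- function(a, b) {
  if (length(a) != length(b)) stop("sign vectors must have equal length")
  prod <- a * b
  if (sum(prod > 0) >= sum(prod < 0)) 1L else -1L
}

#' Permutation p-value for an NMI trend association
#'
#' Permutes the entries of `b` uniformly (breaking the pair correspondence),
#' recomputes the NMI each time, and reports the one-sided upper-tail add-one
#' p-value `(#{nmi_perm >= nmi_obs} + 1)/(n_permutations + 1)`. Degenerate
#' (zero-entropy) input short-circuits to p = 1 with no permutations run.
#'
#' @param a,b sign vectors.
#' @param n_permutations default 1000.
#' @param seed RNG seed.
#' @param ... passed to [nmi].
#' @return list: `nmi`, `p_value`, `n_permutations`, `degenerate`.
#' @export
permutation_p <- function(a, b, n_permutations = 1000, seed = 1L, ...) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  obs <- nmi(a, b, ...)
  if (isTRUE(attr(obs, "degenerate")))
    return(list(nmi = 0, p_value = 1, n_permutations = 0L, degenerate = TRUE))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    v <- nmi(a, sample(b), ...)
    if (v >= obs - 1e-12) hits <- hits + 1L
  }
  list(nmi = as.numeric(obs), p_value = (hits + 1) / (n_permutations + 1),
       n_permutations = as.integer(n_permutations), degenerate = FALSE)
}

#' Signed NMI trend-association matrix
#'
#' Scores every feature pair across two tables over a quasi-paired cohort:
#' per-pair change-trend signs, NMI of the two sign vectors, a direction sign
#' from majority concordance, and a permutation p-value. Significance marks use
#' raw p at the configured levels, as in association heatmaps; an optional BH
#' layer across the matrix is available via `fdr = TRUE`.
#'
#' @param table_a,table_b [abundance_table]s sharing the pair set's samples
#'   (e.g. taxa and metabolites).
#' @param pairs a `pair_set`.
#' @param n_permutations permutations per feature pair (default 1000).
#' @param seed RNG seed (deterministic across the whole matrix).
#' @param alpha_levels raw-p significance marks (default 0.05, 0.01).
#' @param tie_epsilon passed to [pair_signs].
#' @param fdr add a `q_value` column (BH across all feature pairs).
#' @param ... passed to [nmi] (normalization variant, zero handling).
#' @return long-format data.frame of class `trend_association`: `feature_a`,
#'   `feature_b`, `nmi`, `sign`, `signed_score`, `p_value`, `significance`,
#'   `degenerate`; attribute `nmi_variant` records the normalization used.
#' @export
associate_trends <- function(table_a, table_b, pairs, n_permutations = 1000,
                             seed = 1L, alpha_levels = c(0.05, 0.01),
                             tie_epsilon = 0, fdr = FALSE, ...) {
  signs_a <- lapply(feature_ids(table_a), function(f) {
    v <- table_a$values[, f]; names(v) <- rownames(table_a$values)
    pair_signs(v, pairs, tie_epsilon)
  })
  names(signs_a) <- feature_ids(table_a)
  signs_b <- lapply(feature_ids(table_b), function(f) {
    v <- table_b$values[, f]; names(v) <- rownames(table_b$values)
    pair_signs(v, pairs, tie_epsilon)
  })
  names(signs_b) <- feature_ids(table_b)
  grid <- expand.grid(feature_a = names(signs_a), feature_b = names(signs_b),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- signs_a[[grid$feature_a[i]]]
    b <- signs_b[[grid$feature_b[i]]]
    pp <- permutation_p(a, b, n_permutations = n_permutations,
                        seed = stream_seed(seed, paste(grid$feature_a[i],
                                                       grid$feature_b[i])), ...)
    sg <- direction_sign(a, b)
    rows[[i]] <- data.frame(
      feature_a = grid$feature_a[i], feature_b = grid$feature_b[i],
      nmi = pp$nmi, sign = sg, signed_score = sg * pp$nmi,
      p_value = pp$p_value, degenerate = pp$degenerate,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  lv <- sort(alpha_levels, decreasing = TRUE)
  out$significance <- ""
  for (i in seq_along(lv))
    out$significance[out$p_value < lv[i] & !out$degenerate] <-
      paste(rep("*", i), collapse = "")
  if (fdr) out$q_value <- bh_fdr(out$p_value)
  attr(out, "nmi_variant") <- if (length(list(...)) && !is.null(list(...)$variant))
    list(...)$variant else "sqrt"
  class(out) <- c("trend_association", "data.frame")
  out
}
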