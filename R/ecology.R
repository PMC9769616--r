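#' Chao1 richness estimator
#'
#' Nonparametric richness from singleton (F1) and doubleton (F2) counts.
#' Bias-corrected (default): `S_obs + F1*(F1-1) / (2*(F2+1))`. Classic:
#' `S_obs + F1^2 / (2*F2)`, with the `F1*(F1-1)/2` fallback when F2 = 0.
#'
#' Requires count-like input (non-negative integers); relative abundances must
#' first go through [to_pseudocounts], which makes the conversion explicit
#' rather than silent.
#'
#' @param counts non-negative integer vector of per-feature counts in one
#'   sample.
#' @param bias_corrected logical, default TRUE.
#' @return the richness estimate (numeric scalar).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("chao1 needs count-like input; convert relative abundances with to_pseudocounts()")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' Convert relative abundances to pseudo-counts
#'
#' Scales each sample to a fixed depth and rounds; the explicit, logged
#' counterpart of the implicit conversions profiling pipelines apply before
#' count-based richness estimators.
#'
#' @param x an [abundance_table] or numeric matrix (samples x features).
#' @param depth target total per sample (default 1e5).
#' @return integer matrix of pseudo-counts.
#' @export
to_pseudocounts <- function(x, depth = 1e5) {
  m <- if (inherits(x, "abundance_table")) x$values else as.matrix(x)
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  round(m / rs * depth)
}

#' Species accumulation curve
#'
#' Mean cumulative number of distinct features observed in the first m samples,
#' averaged over random sample orderings.
#'
#' @param presence samples x features 0/1 (or abundance; nonzero = present)
#'   matrix or [abundance_table].
#' @param n_permutations number of random orderings, or `"all"` for exhaustive
#'   enumeration (feasible for a handful of samples).
#' @param seed RNG seed for the sampled orderings.
#' @return data.frame `n_samples`, `mean_features`; monotone non-decreasing.
#' @export
accumulation_curve <- function(presence, n_permutations = 100, seed = 1L) {
  m <- if (inherits(presence, "abundance_table")) presence$values else as.matrix(presence)
  m <- m > 0
  n <- nrow(m)
  if (n < 1) stop("need at least one sample")
  orders <- if (identical(n_permutations, "all")) {
    all_permutations(n)
  } else {
    set.seed(seed)
    lapply(seq_len(n_permutations), function(i) sample.int(n))
  }
  acc <- matrix(0, length(orders), n)
  for (i in seq_along(orders)) {
    seen <- rep(FALSE, ncol(m))
    ord <- orders[[i]]
    for (j in seq_len(n)) {
      seen <- seen | m[ord[j], ]
      acc[i, j] <- sum(seen)
    }
  }
  data.frame(n_samples = seq_len(n), mean_features = colMeans(acc))
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' Bray-Curtis distance matrix
#'
#' `d(u, v) = sum|u_i - v_i| / sum(u_i + v_i)`; a pair of all-zero samples gets
#' distance 0 with a warning.
#'
#' @param table an [abundance_table] or numeric matrix (samples x features).
#' @return a `dist` object labelled by sample id.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  if (any(m < 0)) stop("values must be non-negative")
  zero <- rowSums(m) == 0
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (any(zero) && anyNA(d)) {
    warning("all-zero sample pair(s); their Bray-Curtis distance set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Unweighted UniFrac distance between two presence sets
#'
#' Fraction of the tree's branch length (on paths from the root to observed
#' leaves) unique to one of the two communities. A root edge above a degree-2
#' root, if present, is ignored.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param present_a,present_b character vectors of leaf names present in each
#'   sample.
#' @return distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, present_a, present_b) {
  validate_phylogeny(tree)
  miss <- setdiff(c(present_a, present_b), tree$tip.label)
  if (length(miss)) stop("feature(s) absent from tree: ", paste(miss, collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  in_a <- in_b <- rep(FALSE, n_node)
  in_a[match(present_a, tree$tip.label)] <- TRUE
  in_b[match(present_b, tree$tip.label)] <- TRUE
  # postorder: accumulate presence up the tree
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  len <- tree$edge.length[ape::postorder(tree)]
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    in_a[p] <- in_a[p] | in_a[ch]
    in_b[p] <- in_b[p] | in_b[ch]
  }
  child <- edge[, 2L]
  either <- in_a[child] | in_b[child]
  both <- in_a[child] & in_b[child]
  union_len <- sum(len[either])
  unique_len <- sum(len[either & !both])
  if (union_len == 0) return(0)
  unique_len / union_len
}

#' Pairwise unweighted UniFrac distance matrix
#'
#' @param table [abundance_table] or matrix; nonzero entries mark presence.
#' @param tree rooted phylogeny whose leaves cover the present features.
#' @return `dist` labelled by sample id.
#' @export
unifrac_matrix <- function(table, tree) {
  m <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  validate_phylogeny(tree)
  present_any <- colnames(m)[colSums(m > 0) > 0]
  miss <- setdiff(present_any, tree$tip.label)
  if (length(miss)) stop("feature(s) absent from tree: ", paste(miss, collapse = ", "))
  ids <- rownames(m)
  n <- nrow(m)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  inc <- matrix(FALSE, n_node, n)
  hit <- match(colnames(m), tree$tip.label)
  ok <- !is.na(hit)
  inc[hit[ok], ] <- t(m[, ok, drop = FALSE] > 0)
  po <- ape::postorder(tree)
  edge <- tree$edge[po, , drop = FALSE]
  len <- tree$edge.length[po]
  for (i in seq_len(nrow(edge)))
    inc[edge[i, 1L], ] <- inc[edge[i, 1L], ] | inc[edge[i, 2L], ]
  E <- inc[edge[, 2L], , drop = FALSE] * 1  # edge x sample incidence
  shared <- crossprod(E, E * len)           # shared branch length per pair
  own <- diag(shared)
  union_len <- outer(own, own, "+") - shared
  d <- (union_len - shared) / union_len
  d[union_len == 0] <- 0
  dimnames(d) <- list(ids, ids)
  diag(d) <- 0
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centred `-D^2/2` eigen-decomposition; negative eigenvalues are
#' clamped to zero in the explained-proportion denominator and noted.
#'
#' @param d a `dist` or symmetric matrix.
#' @param k number of axes requested.
#' @return class `pcoa_result`: `coordinates` (samples x k'), `explained`
#'   (non-increasing proportions), `eigenvalues`, `negative_eigenvalues` note.
#' @export
pcoa_ord <- function(d, k = 2) {
  if (k < 1) stop("k must be >= 1")
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  res <- stats::cmdscale(d, k = min(k, n - 1), eig = TRUE)
  eig <- res$eig
  pos <- pmax(eig, 0)
  keep <- if (is.matrix(res$points)) ncol(res$points) else 0L
  if (keep < k)
    warning(sprintf("distance matrix supports only %d axes; %d requested", keep, k))
  expl <- if (sum(pos) > 0) pos / sum(pos) else rep(0, length(pos))
  coords <- res$points
  if (is.null(coords) || keep == 0) coords <- matrix(0, n, 0)
  rownames(coords) <- attr(d, "Labels")
  structure(list(coordinates = coords,
                 explained = expl[seq_len(max(keep, 1L))],
                 eigenvalues = eig,
                 negative_eigenvalues = sum(eig < -1e-12)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d axes; explained: %s%s\n", ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 3)),
                    collapse = ", "),
              if (x$negative_eigenvalues)
                sprintf(" (%d negative eigenvalues clamped)", x$negative_eigenvalues)
              else ""))
  invisible(x)
}

#' PERMANOVA pseudo-F test on a distance matrix
#'
#' One-way permutational MANOVA: `SS_total = sum(d_ij^2)/n` over all pairs,
#' `SS_within` the analogous per-group sum, pseudo-F their ratio on (a-1) and
#' (n-a) degrees of freedom. The p-value permutes group labels:
#' `(#{F_perm >= F_obs} + 1)/(n_perm + 1)` in sampled mode, or the exact
#' proportion over all distinct label assignments in exhaustive mode.
#'
#' @param d `dist` or symmetric matrix.
#' @param groups factor/character of group labels, aligned to the samples of
#'   `d`; every group must have >= 2 samples.
#' @param n_permutations permutations in sampled mode (default 999).
#' @param seed RNG seed.
#' @param exhaustive enumerate all distinct assignments (2-group case;
#'   feasible for small n).
#' @return list: `pseudo_F`, `p_value`, `n_permutations`, `exhaustive`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L,
                      exhaustive = FALSE) {
  dm <- as.matrix(stats::as.dist(d))
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm)) stop("groups must align with the distance matrix")
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples")
  f_obs <- pseudo_f(dm, groups)
  if (exhaustive) {
    if (length(tab) != 2) stop("exhaustive mode supports 2 groups")
    n <- nrow(dm)
    n1 <- tab[[1L]]
    sets <- utils::combn(n, n1)
    fs <- apply(sets, 2, function(idx) {
      g <- factor(rep(levels(groups)[2L], n), levels = levels(groups))
      g[idx] <- levels(groups)[1L]
      pseudo_f(dm, g)
    })
    p <- mean(fs >= f_obs - 1e-12)
    return(list(pseudo_F = f_obs, p_value = p, n_permutations = ncol(sets),
                exhaustive = TRUE))
  }
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_permutations))
    if (pseudo_f(dm, sample(groups)) >= f_obs - 1e-12) hits <- hits + 1L
  list(pseudo_F = f_obs, p_value = (hits + 1) / (n_permutations + 1),
       n_permutations = n_permutations, exhaustive = FALSE)
}

pseudo_f <- function(dm, groups) {
  n <- nrow(dm)
  a <- nlevels(droplevels(groups))
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(droplevels(groups))) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by enumeration when `nA + nB <= 12` and there are no ties, otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @param exact_max total-n cutoff for the exact computation.
#' @return list: `statistic` (Mann-Whitney U / W), `p_value`, `exact`.
#' @export
rank_sum <- function(a, b, alternative = "two.sided", exact_max = 12) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= exact_max) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Diversity summary of a cohort
#'
#' Per-sample Chao1 (via pseudo-counts), Bray-Curtis and optional unweighted
#' UniFrac matrices, PCoA on Bray-Curtis, and PERMANOVA by group.
#'
#' @param taxa an [abundance_table].
#' @param design a [cohort_design].
#' @param tree optional rooted phylogeny covering the taxa.
#' @param depth pseudo-count depth for Chao1.
#' @param n_permutations,seed PERMANOVA settings.
#' @return list: `alpha` (data.frame sample_id, group, chao1), `bray`,
#'   `unifrac` (or NULL), `pcoa`, `permanova`, plus `alpha_test` (rank-sum of
#'   Chao1 between groups).
#' @export
diversity_summary <- function(taxa, design, tree = NULL, depth = 1e5,
                              n_permutations = 999, seed = 1L) {
  check_design_covers(design, taxa)
  counts <- to_pseudocounts(taxa, depth = depth)
  alpha <- data.frame(sample_id = rownames(counts),
                      group = as.character(design[rownames(counts), "group"]),
                      chao1 = apply(counts, 1, chao1),
                      stringsAsFactors = FALSE)
  bray <- bray_curtis(taxa)
  uf <- if (!is.null(tree)) unifrac_matrix(taxa, tree) else NULL
  grp <- design[labels(bray), "group"]
  list(alpha = alpha,
       alpha_test = rank_sum(alpha$chao1[alpha$group == "disease"],
                             alpha$chao1[alpha$group == "control"]),
       bray = bray, unifrac = uf,
       pcoa = pcoa_ord(bray, k = 2),
       permanova = permanova(bray, grp, n_permutations = n_permutations,
                             seed = seed))
}
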