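#' Principal-component summary of the metabolic background
#'
#' Reduces the pathway relative-abundance table to the principal components
#' that carry the bulk of its variance; these coordinates are the "metabolic
#' background" on which samples are matched.
#'
#' @param pathways an [abundance_table] of functional-pathway relative
#'   abundances (samples x pathways).
#' @param ev_threshold retain the smallest number of components whose
#'   cumulative explained-variance fraction exceeds this (default 0.85).
#' @param scale. unit-variance scaling before PCA; default `FALSE`
#'   (centre-only).
#' @return an object of class `metabolic_background`: `scores` (all PCs),
#'   `explained` (EV fractions), `n_retained`, `center`, `scale`, `rotation`.
#' @export
metabolic_background <- function(pathways, ev_threshold = 0.85, scale. = FALSE) {
  x <- if (inherits(pathways, "abundance_table")) pathways$values else as.matrix(pathways)
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (ncol(x) < 2) stop("need at least 2 pathways")
  sds <- apply(x, 2, stats::sd)
  if (all(sds < .Machine$double.eps * 100)) stop("no variance to decompose")
  if (scale.) x <- x[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) > ev_threshold)[1L]
  if (is.na(k)) k <- length(ev)
  structure(list(scores = pc$x, explained = ev, n_retained = k,
                 ev_threshold = ev_threshold,
                 center = pc$center, scale = pc$scale, rotation = pc$rotation),
            class = "metabolic_background")
}

#' @export
print.metabolic_background <- function(x, ...) {
  cat(sprintf("metabolic_background: %d PCs retained (cumulative EV %.3f > %.2f) of %d\n",
              x$n_retained, sum(x$explained[seq_len(x$n_retained)]),
              x$ev_threshold, length(x$explained)))
  invisible(x)
}

#' Retained background scores
#' @param bg a `metabolic_background`.
#' @return matrix of retained PC coordinates (samples x k).
#' @export
background_scores <- function(bg) {
  bg$scores[, seq_len(bg$n_retained), drop = FALSE]
}

#' Propensity model on the metabolic background
#'
#' Maximum-likelihood logistic regression of disease status on the retained
#' background principal components. Under (quasi-)separation the fit falls back
#' to a lightly ridge-penalised IRLS solution (fixed penalty on slopes) with a
#' warning, so scores stay strictly inside (0, 1).
#'
#' @param bg a [metabolic_background].
#' @param design a [cohort_design] covering the scored samples.
#' @param ridge L2 penalty used by the separation fallback.
#' @return class `propensity_model`: `coefficients`, `scores` (named vector in
#'   (0,1)), `ridged` flag.
#' @export
propensity_model <- function(bg, design, ridge = 1e-2) {
  X <- background_scores(bg)
  ids <- rownames(X)
  miss <- setdiff(ids, design$sample_id)
  if (length(miss)) stop("design is missing samples: ", paste(miss, collapse = ", "))
  y <- as.integer(design[ids, "group"] == "disease")
  if (length(unique(y)) < 2) stop("both groups must be present")
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  p <- stats::fitted(fit)
  separated <- !fit$converged || any(p < 1e-10) || any(p > 1 - 1e-10)
  ridged <- FALSE
  if (separated) {
    warning("quasi-separation in propensity fit; using ridge-penalised solution")
    co <- ridge_logistic(cbind(1, X), y, lambda = ridge)
    p <- stats::plogis(drop(cbind(1, X) %*% co))
    coefs <- stats::setNames(co, c("(Intercept)", colnames(X)))
    ridged <- TRUE
  } else {
    coefs <- stats::coef(fit)
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  names(p) <- ids
  structure(list(coefficients = coefs, scores = p, ridged = ridged,
                 n_pcs = ncol(X)), class = "propensity_model")
}

# Newton/IRLS logistic regression with an L2 penalty on the slopes only.
ridge_logistic <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    g <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("propensity_model on %d background PCs%s; score range [%.3f, %.3f]\n",
              x$n_pcs, if (x$ridged) " (ridge fallback)" else "",
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Nearest-neighbour caliper matching on propensity scores
#'
#' For each disease sample, processed in descending propensity order, the up to
#' `ratio` nearest controls within the caliper are emitted as pairs (nearest
#' first, ties broken by sample id). With `replacement = TRUE` (the default) a
#' control may serve several disease samples. Disease samples with no in-caliper
#' control are dropped and recorded.
#'
#' @param scores either a [propensity_model] or a named numeric vector of
#'   scores in (0, 1) covering all samples.
#' @param design a [cohort_design].
#' @param caliper maximum score distance; interpreted per `caliper_scale`.
#' @param ratio maximum number of controls matched to each disease sample.
#' @param replacement may controls be reused across pairs?
#' @param caliper_scale `"sd"` (default): the caliper is a multiple of the
#'   standard deviation of the scores across all samples — the dominant
#'   convention of propensity-matching software; or `"absolute"`.
#' @param score_transform `"score"` (default) or `"logit"`: the scale on which
#'   distances and the caliper are measured.
#' @return class `pair_set`: data.frame `pair_id`, `disease_sample`,
#'   `control_sample`, `score_distance`, with attributes `caliper`,
#'   `caliper_width`, `ratio`, `replacement`, `dropped_disease`,
#'   `score_transform`.
#' @export
match_pairs <- function(scores, design, caliper = 0.25, ratio = 2,
                        replacement = TRUE,
                        caliper_scale = c("sd", "absolute"),
                        score_transform = c("score", "logit")) {
  caliper_scale <- match.arg(caliper_scale)
  score_transform <- match.arg(score_transform)
  if (caliper <= 0) stop("caliper must be > 0")
  if (ratio < 1) stop("ratio must be >= 1")
  if (inherits(scores, "propensity_model")) scores <- scores$scores
  if (is.null(names(scores))) stop("scores must be named by sample id")
  miss <- setdiff(names(scores), design$sample_id)
  if (length(miss)) stop("design is missing samples: ", paste(miss, collapse = ", "))
  s <- if (score_transform == "logit") stats::qlogis(scores) else scores
  width <- if (caliper_scale == "sd") caliper * stats::sd(s) else caliper
  grp <- design[names(scores), "group"]
  d_ids <- names(scores)[grp == "disease"]
  c_ids <- names(scores)[grp == "control"]
  if (!length(d_ids) || !length(c_ids)) stop("both groups must be present")
  # descending propensity order, lexicographic ids for determinism
  d_ids <- d_ids[order(-s[d_ids], d_ids)]
  pool <- c_ids
  rows <- vector("list", length(d_ids))
  dropped <- character(0)
  for (i in seq_along(d_ids)) {
    di <- d_ids[i]
    if (!length(pool)) { dropped <- c(dropped, di); next }
    dist <- abs(s[pool] - s[di])
    ok <- pool[dist <= width]
    if (!length(ok)) { dropped <- c(dropped, di); next }
    ok <- ok[order(dist[ok], ok)]
    take <- utils::head(ok, ratio)
    rows[[i]] <- data.frame(disease_sample = di, control_sample = take,
                            score_distance = unname(dist[take]),
                            stringsAsFactors = FALSE)
    if (!replacement) pool <- setdiff(pool, take)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(disease_sample = character(0),
                        control_sample = character(0),
                        score_distance = numeric(0), stringsAsFactors = FALSE)
  pairs <- cbind(pair_id = if (nrow(pairs)) sprintf("pair%03d", seq_len(nrow(pairs)))
                 else character(0),
                 pairs)
  rownames(pairs) <- NULL
  structure(pairs,
            caliper = caliper, caliper_width = width, ratio = ratio,
            replacement = replacement, dropped_disease = dropped,
            score_transform = score_transform, caliper_scale = caliper_scale,
            class = c("pair_set", "data.frame"))
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf(
    "pair_set: %d pairs (%d unique disease / %d unique control); %d disease dropped\n",
    nrow(x), length(unique(x$disease_sample)), length(unique(x$control_sample)),
    length(attr(x, "dropped_disease"))))
  cat(sprintf("caliper %g (%s scale, width %.4g), ratio %d, replacement %s\n",
              attr(x, "caliper"), attr(x, "caliper_scale"),
              attr(x, "caliper_width"), attr(x, "ratio"),
              attr(x, "replacement")))
  invisible(x)
}

#' Standardized-mean-difference balance report
#'
#' SMD = (mean_disease - mean_control) / sqrt((var_disease + var_control) / 2),
#' computed for each clinical covariate (categoricals one-hot expanded) and
#' optionally each retained background PC, before matching (all samples) and,
#' when a pair set is given, after matching on the pair-weighted sample (each
#' sample counted once per pair it enters). Post-matching differences are
#' standardized by the unmatched pooled SD, the usual balance-assessment
#' convention, so before/after values share a scale.
#'
#' @param design a [cohort_design].
#' @param bg optional [metabolic_background]; adds per-PC rows.
#' @param pairs optional [match_pairs] result; adds the `smd_after` column.
#' @return class `balance_report`: data.frame `variable`, `smd_before`,
#'   `smd_after` (NA without pairs), plus attributes `n_pairs`,
#'   `n_disease_retained`, `n_control_retained`, `dropped_disease`.
#' @export
balance_report <- function(design, bg = NULL, pairs = NULL) {
  vars <- covariate_frame(design)
  if (!is.null(bg)) {
    pc <- background_scores(bg)
    pc <- as.data.frame(pc[design$sample_id, , drop = FALSE])
    vars <- cbind(vars, pc)
  }
  grp <- design$group
  before <- vapply(vars, function(v) smd(v[grp == "disease"], v[grp == "control"]),
                   numeric(1))
  after <- rep(NA_real_, length(before))
  n_pairs <- 0L; n_d <- NA_integer_; n_c <- NA_integer_; dropped <- character(0)
  if (!is.null(pairs)) {
    n_pairs <- nrow(pairs)
    n_d <- length(unique(pairs$disease_sample))
    n_c <- length(unique(pairs$control_sample))
    dropped <- attr(pairs, "dropped_disease")
    di <- match(pairs$disease_sample, design$sample_id)
    ci <- match(pairs$control_sample, design$sample_id)
    # post-matching mean difference standardized by the UNMATCHED pooled SD
    # (the cobalt/MatchIt convention), so before/after are on the same scale
    # and variance shrinkage from restriction cannot inflate the ratio
    after <- vapply(seq_along(vars), function(j) {
      v <- vars[[j]]
      pooled <- (stats::var(v[grp == "disease"]) +
                   stats::var(v[grp == "control"])) / 2
      md <- mean(v[di]) - mean(v[ci])
      if (pooled <= 0 || is.na(pooled)) {
        if (abs(md) < .Machine$double.eps * 100) 0 else sign(md) * Inf
      } else md / sqrt(pooled)
    }, numeric(1))
  }
  structure(data.frame(variable = names(before), smd_before = unname(before),
                       smd_after = unname(after), stringsAsFactors = FALSE),
            n_pairs = n_pairs, n_disease_retained = n_d, n_control_retained = n_c,
            dropped_disease = dropped,
            class = c("balance_report", "data.frame"))
}

smd <- function(a, b) {
  md <- mean(a) - mean(b)
  pooled <- (stats::var(a) + stats::var(b)) / 2
  if (pooled <= 0 || is.na(pooled)) {
    if (abs(md) < .Machine$double.eps * 100) return(0)
    warning("zero pooled variance with nonzero mean difference; SMD infinite")
    return(sign(md) * Inf)
  }
  md / sqrt(pooled)
}

# numeric covariates kept; categoricals one-hot expanded
covariate_frame <- function(design) {
  out <- list()
  for (nm in design_covariate_names(design)) {
    v <- design[[nm]]
    if (is.numeric(v)) {
      out[[nm]] <- v
    } else {
      for (lv in unique(as.character(v)))
        out[[paste0(nm, "=", lv)]] <- as.numeric(as.character(v) == lv)
    }
  }
  as.data.frame(out, check.names = FALSE,
                row.names = design$sample_id %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("balance_report: %d pairs (%s unique disease / %s unique control)\n",
              attr(x, "n_pairs"), attr(x, "n_disease_retained"),
              attr(x, "n_control_retained")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Scan caliper/ratio candidates by covariate balance
#'
#' Evaluates every (caliper, ratio) candidate, choosing the one with the most
#' variables (covariates and background PCs) at |SMD| < 0.1 after matching;
#' ties broken by smaller mean |SMD|, then larger pair count, then smaller
#' caliper, then smaller ratio.
#'
#' @param model a [propensity_model] (or named score vector).
#' @param design a [cohort_design].
#' @param bg optional [metabolic_background] for per-PC balance.
#' @param calipers,ratios candidate grids.
#' @param ... passed to [match_pairs].
#' @return list: `caliper`, `ratio`, `grid` (one row per candidate with balance
#'   summaries), `pairs` (the winning pair set).
#' @export
scan_match_parameters <- function(model, design, bg = NULL,
                                  calipers = c(0.1, 0.25, 0.5),
                                  ratios = c(1, 2), ...) {
  if (!length(calipers) || !length(ratios)) stop("candidate grids must be non-empty")
  grid <- expand.grid(caliper = calipers, ratio = ratios)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ps <- match_pairs(model, design, caliper = grid$caliper[i],
                      ratio = grid$ratio[i], ...)
    if (nrow(ps) == 0) {
      res[[i]] <- list(n_balanced = -Inf, mean_abs = Inf, n_pairs = 0, pairs = ps)
      next
    }
    bal <- balance_report(design, bg = bg, pairs = ps)
    res[[i]] <- list(n_balanced = sum(abs(bal$smd_after) < 0.1, na.rm = TRUE),
                     mean_abs = mean(abs(bal$smd_after), na.rm = TRUE),
                     n_pairs = nrow(ps), pairs = ps)
  }
  if (all(vapply(res, function(r) r$n_pairs, numeric(1)) == 0))
    stop("all candidates yield empty pair sets; widen the caliper grid ",
         "(score SD = ", signif(stats::sd(if (inherits(model, "propensity_model"))
           model$scores else model), 3), ")")
  grid$n_balanced <- vapply(res, function(r) r$n_balanced, numeric(1))
  grid$mean_abs_smd <- vapply(res, function(r) r$mean_abs, numeric(1))
  grid$n_pairs <- vapply(res, function(r) r$n_pairs, numeric(1))
  ord <- order(-grid$n_balanced, grid$mean_abs_smd, -grid$n_pairs,
               grid$caliper, grid$ratio)
  best <- ord[1L]
  list(caliper = grid$caliper[best], ratio = grid$ratio[best],
       grid = grid, pairs = res[[best]]$pairs)
}

#' Fit a quasi-paired cohort
#'
#' The one-call interface: PCA of the pathway table (the metabolic background),
#' logistic propensity model on the retained components, calipered
#' nearest-neighbour matching, and a covariate/PC balance report.
#'
#' @param pathways an [abundance_table] of pathway relative abundances.
#' @param design a [cohort_design].
#' @param ev_threshold cumulative explained-variance threshold for the retained
#'   PCs (default 0.85).
#' @param caliper,ratio,replacement,caliper_scale,score_transform see
#'   [match_pairs]. Set `caliper`/`ratio` to `NULL` to select them by a balance
#'   scan over `scan_calipers` x `scan_ratios`.
#' @param scan_calipers,scan_ratios candidate grids used when scanning.
#' @param scale. unit-variance scaling before PCA (default centre-only).
#' @return class `quasi_pair`: `background`, `model`, `pairs`, `balance`,
#'   `caliper`, `ratio`, and `scan` (the grid, when a scan ran).
#' @export
quasi_pair <- function(pathways, design, ev_threshold = 0.85,
                       caliper = 0.25, ratio = 2, replacement = TRUE,
                       caliper_scale = "sd", score_transform = "score",
                       scan_calipers = c(0.1, 0.25, 0.5), scan_ratios = c(1, 2),
                       scale. = FALSE) {
  check_design_covers(design, pathways)
  bg <- metabolic_background(pathways, ev_threshold = ev_threshold, scale. = scale.)
  model <- propensity_model(bg, design)
  scan <- NULL
  if (is.null(caliper) || is.null(ratio)) {
    scan <- scan_match_parameters(model, design, bg = bg,
                                  calipers = scan_calipers, ratios = scan_ratios,
                                  replacement = replacement,
                                  caliper_scale = caliper_scale,
                                  score_transform = score_transform)
    caliper <- scan$caliper
    ratio <- scan$ratio
    pairs <- scan$pairs
  } else {
    pairs <- match_pairs(model, design, caliper = caliper, ratio = ratio,
                         replacement = replacement, caliper_scale = caliper_scale,
                         score_transform = score_transform)
  }
  bal <- balance_report(design, bg = bg, pairs = pairs)
  structure(list(background = bg, model = model, pairs = pairs, balance = bal,
                 caliper = caliper, ratio = ratio,
                 scan = if (is.null(scan)) NULL else scan$grid),
            class = "quasi_pair")
}

#' @export
print.quasi_pair <- function(x, ...) {
  cat("Quasi-paired cohort\n")
  print(x$background)
  print(x$model)
  print(x$pairs)
  invisible(x)
}

#' @export
summary.quasi_pair <- function(object, ...) {
  cat("Quasi-paired cohort: covariate balance\n")
  print(object$balance)
  invisible(object$balance)
}

#' @export
coef.quasi_pair <- function(object, ...) object$model$coefficients

#' Propensity scores of a fitted quasi-paired cohort
#' @param object a `quasi_pair`.
#' @param ... ignored.
#' @export
predict.quasi_pair <- function(object, ...) object$model$scores

#' Plot a quasi-paired cohort fit
#'
#' Left: propensity-score distributions by group; right: absolute SMD before vs
#' after matching (the Love-plot view of covariate balance).
#'
#' @param x a `quasi_pair`.
#' @param ... ignored.
#' @export
plot.quasi_pair <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  s <- x$model$scores
  d <- stats::density(s)
  graphics::plot(d, main = "Propensity scores", xlab = "score")
  graphics::rug(s)
  bal <- x$balance
  graphics::plot(abs(bal$smd_before), seq_len(nrow(bal)), pch = 1,
                 xlab = "|SMD|", ylab = "", yaxt = "n", main = "Balance",
                 xlim = range(0, abs(bal$smd_before), abs(bal$smd_after),
                              na.rm = TRUE))
  graphics::points(abs(bal$smd_after), seq_len(nrow(bal)), pch = 16)
  graphics::abline(v = 0.1, lty = 2)
  graphics::axis(2, at = seq_len(nrow(bal)), labels = bal$variable, las = 1,
                 cex.axis = 0.6)
  graphics::legend("topright", pch = c(1, 16), legend = c("before", "after"))
  invisible(x)
}

#' Write a pair set as TSV
#' @param pairs a `pair_set`.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  write_results(as.data.frame(pairs), path)
}

#' Read a pair set written by [write_pairs]
#' @param path TSV with columns pair_id, disease_sample, control_sample,
#'   score_distance.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("pair_id", "disease_sample", "control_sample", "score_distance")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("pair table missing columns: ", paste(miss, collapse = ", "))
  structure(df, class = c("pair_set", "data.frame"))
}
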