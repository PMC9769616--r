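test_that("background retains the smallest PC set crossing the EV threshold", {
  m <- matrix(c(1, 2, 3, 4,
                5, 5, 5, 5,
                2, 2, 2, 2), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("p", 1:3)))
  bg <- metabolic_background(m)
  expect_equal(bg$n_retained, 1L)
  expect_equal(bg$explained[1L], 1.0)

  sim <- default_sim()
  bg2 <- metabolic_background(sim$pathways, ev_threshold = 0.85)
  cum <- cumsum(bg2$explained)
  k <- bg2$n_retained
  expect_gt(cum[k], 0.85)
  if (k > 1) expect_lte(cum[k - 1], 0.85)

  expect_error(metabolic_background(matrix(1, 4, 3,
                                           dimnames = list(paste0("s", 1:4),
                                                           paste0("p", 1:3)))),
               "no variance")
})

test_that("PC coordinates match a covariance eigen-decomposition oracle", {
  set.seed(42)
  m <- matrix(rnorm(4 * 3), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("p", 1:3)))
  bg <- metabolic_background(m, ev_threshold = 0.99)
  centred <- scale(m, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(centred))
  oracle <- centred %*% eg$vectors
  for (j in seq_len(ncol(bg$scores))) {
    diff_same <- max(abs(bg$scores[, j] - oracle[, j]))
    diff_flip <- max(abs(bg$scores[, j] + oracle[, j]))
    expect_lt(min(diff_same, diff_flip), 1e-8)
  }
})

test_that("uninformative background gives prevalence scores; signal is recovered", {
  # perfectly group-symmetric PC: intercept-only solution
  x <- c(-1, 1, -1, 1)
  ids <- paste0("s", 1:4)
  bg <- fake_background(matrix(x, 4, 1, dimnames = list(ids, "PC1")))
  design <- cohort_design(ids, c("disease", "disease", "control", "control"))
  pm <- propensity_model(bg, design)
  expect_equal(unname(pm$scores), rep(0.5, 4), tolerance = 1e-6)
  # monotonicity in the linear predictor
  sim <- default_sim()
  bg2 <- metabolic_background(sim$pathways)
  pm2 <- propensity_model(bg2, sim$design)
  X <- background_scores(bg2)
  lp <- drop(cbind(1, X) %*% pm2$coefficients)
  expect_equal(order(pm2$scores), order(lp))

  # coefficient recovery at n = 2000
  set.seed(9)
  n <- 2000
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 1.2 * x1))
  ids <- paste0("t", seq_len(n))
  bgr <- fake_background(matrix(x1, n, 1, dimnames = list(ids, "PC1")))
  dsn <- cohort_design(ids, ifelse(y == 1, "disease", "control"))
  pmr <- propensity_model(bgr, dsn)
  expect_lt(abs(pmr$coefficients[["PC1"]] - 1.2) / 1.2, 0.15)
})

test_that("perfect separation falls back to a ridge fit instead of crashing", {
  ids <- paste0("s", 1:10)
  x <- c(1:5, 11:15)
  bg <- fake_background(matrix(x, 10, 1, dimnames = list(ids, "PC1")))
  design <- cohort_design(ids, rep(c("control", "disease"), each = 5))
  expect_warning(pm <- propensity_model(bg, design), "separation")
  expect_true(all(pm$scores > 0 & pm$scores < 1))
  expect_true(pm$ridged)
})

test_that("nearest-neighbour matching honours caliper, ratio and ordering", {
  scores <- c(t1 = 0.60, c1 = 0.55, c2 = 0.70, c3 = 0.10)
  design <- cohort_design(names(scores),
                          c("disease", "control", "control", "control"))
  ps <- match_pairs(scores, design, caliper = 0.2, ratio = 2,
                    caliper_scale = "absolute")
  expect_equal(nrow(ps), 2L)
  expect_equal(ps$control_sample, c("c1", "c2"))  # nearest first
  expect_equal(ps$score_distance, c(0.05, 0.10))
  expect_false("c3" %in% ps$control_sample)

  # no control in caliper: empty set, all disease recorded dropped
  far <- c(d1 = 0.9, d2 = 0.8, c1 = 0.1, c2 = 0.15)
  dsn <- cohort_design(names(far), c("disease", "disease", "control", "control"))
  empty <- match_pairs(far, dsn, caliper = 0.05, ratio = 1,
                       caliper_scale = "absolute")
  expect_equal(nrow(empty), 0L)
  expect_setequal(attr(empty, "dropped_disease"), c("d1", "d2"))

  expect_error(match_pairs(scores, design, caliper = 0), "caliper")
  expect_error(match_pairs(scores, design, ratio = 0), "ratio")
})

test_that("matching invariants hold on randomized instances", {
  for (s in 1:10) {
    set.seed(s)
    n_d <- sample(5:15, 1)
    n_c <- sample(5:15, 1)
    ids <- c(paste0("d", seq_len(n_d)), paste0("c", seq_len(n_c)))
    scores <- stats::setNames(runif(n_d + n_c), ids)
    design <- cohort_design(ids, rep(c("disease", "control"), c(n_d, n_c)))
    ratio <- sample(1:3, 1)
    repl <- s %% 2 == 0
    ps <- match_pairs(scores, design, caliper = 0.5, ratio = ratio,
                      replacement = repl)
    if (nrow(ps)) {
      expect_true(all(ps$score_distance <= attr(ps, "caliper_width") + 1e-12))
      expect_true(all(table(ps$disease_sample) <= ratio))
      if (!repl) expect_false(anyDuplicated(ps$control_sample) > 0)
    }
  }
})

test_that("SMD follows its closed form and degenerate cases", {
  ids <- paste0("s", 1:4)
  design <- cohort_design(ids, c("disease", "disease", "control", "control"),
                          data.frame(x = c(1 - 1 / sqrt(2), 1 + 1 / sqrt(2),
                                           -1 / sqrt(2), 1 / sqrt(2)),
                                     same = c(5, 6, 5, 6),
                                     flat = c(3, 3, 3, 3)))
  bal <- balance_report(design)
  expect_equal(bal$smd_before[bal$variable == "x"], 1.0)
  expect_equal(bal$smd_before[bal$variable == "same"], 0)
  expect_equal(bal$smd_before[bal$variable == "flat"], 0)

  d2 <- cohort_design(ids, c("disease", "disease", "control", "control"),
                      data.frame(c0 = c(1, 1, 0, 0)))
  expect_warning(b2 <- balance_report(d2), "zero pooled variance")
  expect_equal(b2$smd_before[1L], Inf)
})

test_that("matching shrinks confounder imbalance on the confounded cohort", {
  sim <- default_sim()
  fit <- quasi_pair(sim$pathways, sim$design)
  bal <- fit$balance
  conf <- bal[bal$variable %in% sim$truth$confounders, ]
  expect_lt(max(abs(conf$smd_after)), max(abs(conf$smd_before)))
  # pair-weighted accounting is explicit
  expect_equal(attr(bal, "n_pairs"), nrow(fit$pairs))
  expect_lte(attr(bal, "n_disease_retained"), sum(sim$design$group == "disease"))
})

test_that("parameter scan equals exhaustive grid evaluation with fixed tie-breaks", {
  sim <- default_sim()
  bg <- metabolic_background(sim$pathways)
  pm <- propensity_model(bg, sim$design)

  one <- scan_match_parameters(pm, sim$design, bg = bg, calipers = 0.25,
                               ratios = 2)
  expect_equal(one$caliper, 0.25)
  expect_equal(one$ratio, 2)

  calipers <- c(0.1, 0.25, 0.5); ratios <- c(1, 2)
  scan <- scan_match_parameters(pm, sim$design, bg = bg, calipers = calipers,
                                ratios = ratios)
  # independent exhaustive oracle over the same grid
  best <- NULL
  for (r in ratios) for (cl in calipers) {
    ps <- match_pairs(pm, sim$design, caliper = cl, ratio = r)
    bal <- balance_report(sim$design, bg = bg, pairs = ps)
    cand <- list(cl = cl, r = r,
                 nb = sum(abs(bal$smd_after) < 0.1, na.rm = TRUE),
                 ma = mean(abs(bal$smd_after), na.rm = TRUE),
                 np = nrow(ps))
    better <- is.null(best) ||
      cand$nb > best$nb ||
      (cand$nb == best$nb && cand$ma < best$ma) ||
      (cand$nb == best$nb && cand$ma == best$ma && cand$np > best$np) ||
      (cand$nb == best$nb && cand$ma == best$ma && cand$np == best$np &&
         cand$cl < best$cl)
    if (better) best <- cand
  }
  expect_equal(scan$caliper, best$cl)
  expect_equal(scan$ratio, best$r)
  # reproducible under re-run
  scan2 <- scan_match_parameters(pm, sim$design, bg = bg, calipers = calipers,
                                 ratios = ratios)
  expect_identical(scan$grid, scan2$grid)
})

test_that("matching a cohort without confounding leaves balance unchanged", {
  cov_null <- data.frame(name = c("age", "FBG"),
                         disease_mean = c(58, 5.7), disease_sd = c(8, 1),
                         control_mean = c(58, 5.7), control_sd = c(8, 1))
  deltas <- sapply(1:50, function(s) {
    sim <- generate_cohort(sim_config(seed = s, n_taxa = 5, n_metabolites = 2,
                                      covariates = cov_null,
                                      taxa_confounding = NULL,
                                      taxa_effects = data.frame(
                                        feature = "sp001", log2_fc = 0)))
    fit <- quasi_pair(sim$pathways, sim$design)
    bal <- fit$balance
    rows <- bal$variable %in% c("age", "FBG")
    mean(abs(bal$smd_after[rows]) - abs(bal$smd_before[rows]))
  })
  bt <- stats::binom.test(sum(deltas > 0), sum(deltas != 0))
  expect_gt(bt$p.value, 0.01)
})

test_that("the quasi_pair object behaves like a fitted model", {
  sim <- default_sim()
  fit <- quasi_pair(sim$pathways, sim$design)
  expect_s3_class(fit, "quasi_pair")
  expect_output(print(fit), "Quasi-paired cohort")
  expect_s3_class(summary(fit), "balance_report")
  expect_named(coef(fit)[1], "(Intercept)")
  expect_true(all(predict(fit) > 0 & predict(fit) < 1))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
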