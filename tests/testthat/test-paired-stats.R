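test_that("prevalence filter uses a strict fraction threshold", {
  m <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10), c("rare", "ok", "zero")))
  m[1, "rare"] <- 5          # 1/10: not > 10%
  m[1:2, "ok"] <- 5          # 2/10: kept
  tab <- abundance_table(m, scale_tag = "percent")
  filt <- prevalence_filter(tab, 0.10)
  expect_equal(feature_ids(filt), "ok")

  filt0 <- prevalence_filter(tab, 0)
  expect_setequal(feature_ids(filt0), c("rare", "ok"))  # all-zero removed

  expect_error(prevalence_filter(tab, 0.9), "removed all features")

  ren <- prevalence_filter(tab, 0, renormalize = TRUE)
  expect_equal(unname(rowSums(ren$values)[1]), 100)
})

test_that("signed-rank exact p matches sign-assignment enumeration", {
  pairs <- make_pairs(paste0("d", 1:3), paste0("c", 1:3))
  v <- c(d1 = 2, d2 = 4, d3 = 7, c1 = 1, c2 = 2, c3 = 4)  # d = 1, 2, 3
  r <- paired_signed_rank(v, pairs)
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 2 / 8)
  expect_equal(r$n_effective, 3L)

  # all-zero differences: degenerate, p = 1
  vz <- c(d1 = 1, d2 = 2, d3 = 3, c1 = 1, c2 = 2, c3 = 3)
  rz <- paired_signed_rank(vz, pairs)
  expect_true(rz$degenerate)
  expect_equal(rz$p_value, 1)
  expect_equal(rz$n_effective, 0L)

  # n = 20 distinct differences: approximation vs the exact signed-rank
  # distribution (psignrank), within 0.02
  set.seed(21)
  d <- round(rnorm(20, 0.3), 3)
  pr20 <- make_pairs(paste0("d", 1:20), paste0("c", 1:20))
  v20 <- c(stats::setNames(d, paste0("d", 1:20)),
           stats::setNames(rep(0, 20), paste0("c", 1:20)))
  ra <- paired_signed_rank(v20, pr20)
  expect_false(anyDuplicated(abs(d)) > 0)
  exact <- {
    w <- ra$statistic
    n <- 20
    lower <- stats::psignrank(w, n)
    upper <- stats::psignrank(w - 1, n, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }
  expect_lt(abs(ra$p_value - exact), 0.02)
})

test_that("signed-rank is antisymmetric in the pair roles", {
  set.seed(5)
  ids_d <- paste0("d", 1:9); ids_c <- paste0("c", 1:9)
  v <- c(stats::setNames(rnorm(9, 1), ids_d), stats::setNames(rnorm(9), ids_c))
  fwd <- paired_signed_rank(v, make_pairs(ids_d, ids_c))
  rev <- paired_signed_rank(v, make_pairs(ids_c, ids_d))
  expect_equal(fwd$p_value, rev$p_value)
  n <- fwd$n_effective
  expect_equal(fwd$statistic + rev$statistic, n * (n + 1) / 2)
})

test_that("pratt zero handling keeps zeros in the ranking", {
  pairs <- make_pairs(paste0("d", 1:5), paste0("c", 1:5))
  v <- c(d1 = 1, d2 = 3, d3 = 5, d4 = 2, d5 = 9,
         c1 = 1, c2 = 1, c3 = 2, c4 = 2, c5 = 4)  # d = 0, 2, 3, 0, 5
  pr <- paired_signed_rank(v, pairs, zero_policy = "pratt")
  expect_equal(pr$n_effective, 3L)
  expect_equal(pr$statistic, sum(rank(c(0, 2, 3, 0, 5))[c(2, 3, 5)]))
})

test_that("BH q-values follow the step-up construction", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(30)^2
  q <- bh_fdr(p)
  # independent step-up oracle: q_i = min_{j: p_j >= p_i} p_j * m / rank_j
  m <- length(p)
  ord <- order(p)
  oracle <- rev(cummin(rev(p[ord] * m / seq_len(m))))[order(ord)]
  expect_equal(q, pmin(oracle, 1), tolerance = 1e-12)
  perm <- sample(30)
  expect_equal(bh_fdr(p[perm]), q[perm])  # order-equivariant
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential table flags nothing when pairs are identical", {
  m <- matrix(rep(1:4, each = 8), 8, 4,
              dimnames = list(c(paste0("d", 1:4), paste0("c", 1:4)),
                              paste0("f", 1:4)))
  tab <- abundance_table(m, scale_tag = "count")
  pairs <- make_pairs(paste0("d", 1:4), paste0("c", 1:4))
  dt <- differential_table(tab, pairs)
  expect_false(any(dt$significant))
  expect_true(all(dt$p_value == 1))
})

test_that("differential direction matches the paired log-ratio sign", {
  sim <- default_sim()
  fit <- quasi_pair(sim$pathways, sim$design)
  dm <- differential_table(sim$metabolites, fit$pairs)
  expect_equal(dm$feature_id, dm$feature_id[order(dm$q_value, dm$feature_id)])
  up <- dm$direction == "disease-up"
  expect_true(all(dm$median_log2_ratio[up] > 0))
  expect_true(all(dm$median_log2_ratio[dm$direction == "disease-down"] < 0))
  expect_true(all(dm$q_value >= dm$p_value - 1e-12))
  # planted metabolite effects recovered in the right direction
  truth <- sim$truth$differential_metabolites
  hit <- dm[match(truth$feature, dm$feature_id), ]
  expect_true(all(sign(hit$median_log2_ratio) == sign(truth$log2_fc)))
})

test_that("hypergeometric enrichment equals pmf summation", {
  bg <- paste0("f", 1:10)
  sel <- paste0("f", 1:4)
  ann <- data.frame(feature = paste0("f", 1:5), term = "T1")
  res <- hypergeom_enrichment(sel, bg, ann)
  expect_equal(res$p_value, 5 / 210)  # C(5,4)C(5,0)/C(10,4)

  # all features annotated: k is forced, p = 1
  ann_all <- data.frame(feature = bg, term = "ALL")
  expect_equal(hypergeom_enrichment(sel, bg, ann_all)$p_value, 1.0)

  # random instances vs explicit pmf summation
  set.seed(9)
  for (i in 1:20) {
    N <- sample(8:25, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    bgi <- paste0("x", seq_len(N))
    seli <- sample(bgi, n)
    anni <- data.frame(feature = sample(bgi, K), term = "t")
    p <- hypergeom_enrichment(seli, bgi, anni)$p_value
    k <- length(intersect(anni$feature, seli))
    oracle <- sum(stats::dhyper(k:min(K, n), K, N - K, n))
    expect_equal(p, oracle, tolerance = 1e-12)
  }

  # unannotated terms skipped
  ann2 <- data.frame(feature = c("f1", "zz"), term = c("T1", "T2"))
  expect_equal(hypergeom_enrichment(sel, bg, ann2)$term_id, "T1")
  expect_error(hypergeom_enrichment(c("f1", "nope"), bg, ann), "subset")
})

test_that("one-sided fisher equals the hypergeometric upper tail", {
  expect_equal(fisher_one_sided(matrix(c(3, 0, 0, 3), 2, 2)), 1 / 20)
  # oracle by pmf summation for the (1,1) cell given margins
  fisher_oracle <- function(tab) {
    k <- tab[1, 1]; K <- sum(tab[1, ]); n <- sum(tab[, 1]); N <- sum(tab)
    sum(stats::dhyper(k:min(K, n), K, N - K, n))
  }
  t1 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(fisher_one_sided(t1), fisher_oracle(t1), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:15) {
    tb <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_one_sided(tb), fisher_oracle(tb), tolerance = 1e-12)
  }
  expect_equal(fisher_one_sided(matrix(c(0, 5, 0, 3), 2, 2)), 1.0)
})
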