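test_that("chao1 matches its closed forms and rejects non-counts", {
  expect_equal(chao1(c(5, 3, 2)), 3.0)
  expect_equal(chao1(c(1, 1, 2, 2, 5)), 5 + 2 * 1 / (2 * 3))
  expect_equal(chao1(c(1, 1, 2, 2, 5), bias_corrected = FALSE), 5 + 4 / 4)
  # classic variant F2 = 0 fallback
  expect_equal(chao1(c(1, 1, 3), bias_corrected = FALSE), 3 + 2 * 1 / 2)
  expect_error(chao1(c(0.5, 1)), "to_pseudocounts")
  counts <- to_pseudocounts(matrix(c(60, 40), 1, 2,
                                   dimnames = list("s", c("a", "b"))),
                            depth = 10)
  expect_equal(unname(counts[1, ]), c(6, 4))
})

test_that("accumulation curve equals exhaustive enumeration and is monotone", {
  one <- matrix(c(1, 0, 1), 1, 3, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(accumulation_curve(one)$mean_features, 2)

  disj <- rbind(s1 = c(1, 1, 1, 0, 0, 0), s2 = c(0, 0, 0, 1, 1, 1))
  colnames(disj) <- letters[1:6]
  expect_equal(accumulation_curve(disj, n_permutations = 10)$mean_features,
               c(3, 6))

  set.seed(4)
  m <- matrix(rbinom(4 * 7, 1, 0.4), 4, 7,
              dimnames = list(paste0("s", 1:4), letters[1:7]))
  got <- accumulation_curve(m, n_permutations = "all")$mean_features
  po <- perms_oracle(4)
  oracle <- colMeans(t(apply(po, 1, function(ord) {
    sapply(seq_len(4), function(k) sum(colSums(m[ord[1:k], , drop = FALSE]) > 0))
  })))
  expect_equal(got, oracle)
  expect_true(all(diff(got) >= 0))
})

test_that("bray-curtis follows its closed form with bounded values", {
  m <- rbind(u = c(2, 2), v = c(1, 3), w = c(2, 2))
  colnames(m) <- c("f1", "f2")
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["u", "v"], 0.25)
  expect_equal(d["u", "w"], 0)
  m2 <- rbind(a = c(1, 0), b = c(0, 1))
  colnames(m2) <- c("f1", "f2")
  expect_equal(as.matrix(bray_curtis(m2))["a", "b"], 1)
  m3 <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  colnames(m3) <- c("f1", "f2")
  expect_warning(d3 <- bray_curtis(m3), "all-zero")
  expect_equal(as.matrix(d3)["a", "b"], 0)
})

test_that("unweighted unifrac matches hand-computed path sets", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(unweighted_unifrac(tree, c("A", "B"), c("C", "D")), 1.0)
  expect_equal(unweighted_unifrac(tree, c("A", "B", "C", "D"), c("A", "B")), 0.5)
  expect_equal(unweighted_unifrac(tree, c("A", "C"), c("A", "C")), 0)
  expect_error(unweighted_unifrac(tree, c("A", "Z"), "B"), "absent.*Z")
})

test_that("unifrac matrix agrees with the pairwise op and the picante oracle", {
  tree <- generate_tree(12, seed = 2, tip_labels = sprintf("sp%02d", 1:12))
  set.seed(8)
  pres <- matrix(rbinom(5 * 12, 1, 0.6), 5, 12,
                 dimnames = list(paste0("s", 1:5), sprintf("sp%02d", 1:12)))
  pres[rowSums(pres) == 0, 1] <- 1
  dm <- as.matrix(unifrac_matrix(pres, tree))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(dm[i, j],
                 unweighted_unifrac(tree,
                                    colnames(pres)[pres[i, ] > 0],
                                    colnames(pres)[pres[j, ] > 0]),
                 tolerance = 1e-12)
  oracle <- as.matrix(picante::unifrac(pres, tree))
  expect_equal(dm[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("distance matrices satisfy metric-style invariants on random data", {
  tab <- toy_table(8, 6, seed = 5)
  for (d in list(bray_curtis(tab),
                 unifrac_matrix(tab$values > 0.5,
                                generate_tree(6, seed = 1,
                                              tip_labels = feature_ids(tab))))) {
    m <- as.matrix(d)
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
  }
})

test_that("pcoa recovers planted configurations", {
  # two points at distance 1
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa_ord(d2, k = 1)
  expect_equal(unname(sort(p2$coordinates[, 1])), c(-0.5, 0.5))
  expect_equal(p2$explained[1], 1.0)

  set.seed(3)
  pts <- matrix(rnorm(12 * 2), 12, 2)
  rownames(pts) <- paste0("s", 1:12)
  rec <- pcoa_ord(stats::dist(pts), k = 2)$coordinates
  pr <- vegan::procrustes(pts, rec, symmetric = TRUE)
  expect_lt(pr$ss, 1e-8)

  dz <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  pz <- suppressWarnings(pcoa_ord(dz, k = 2))
  expect_true(all(abs(pz$coordinates) < 1e-12))
})

test_that("permanova pseudo-F and p behave under enumeration", {
  # label-invariant distances: constant F, exhaustive p = 1
  deq <- matrix(1, 4, 4) - diag(4)
  dimnames(deq) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(deq, c("g1", "g1", "g2", "g2"), exhaustive = TRUE)
  expect_equal(res$p_value, 1.0)

  # two tight clusters: observed split is the best of the 3 distinct splits
  dcl <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(1, 1, 0, 0), c(1, 1, 0, 0))
  dimnames(dcl) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res2 <- permanova(dcl, c("g1", "g1", "g2", "g2"), exhaustive = TRUE)
  expect_equal(res2$p_value, 1 / 3)

  set.seed(12)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  d8 <- stats::dist(pts)
  grp <- rep(c("g1", "g2"), each = 4)
  ex <- permanova(d8, grp, exhaustive = TRUE)
  sm <- permanova(d8, grp, n_permutations = 9999, seed = 3)
  expect_lt(abs(sm$p_value - ex$p_value), 0.05)

  expect_error(permanova(d8, c("g1", rep("g2", 7))), ">= 2 samples")
})

test_that("permanova is exchangeable and agrees with the vegan oracle", {
  sim <- default_sim()
  sub <- sim$taxa$values[c(1:6, 43:48), ]
  d <- bray_curtis(sub)
  grp <- as.character(sim$design[rownames(sub), "group"])
  f1 <- permanova(d, grp, n_permutations = 9)$pseudo_F
  perm <- c(5, 3, 1, 2, 12, 7, 9, 4, 6, 11, 8, 10)  # same 12 samples, shuffled
  dm <- as.matrix(d)[perm, perm]
  f2 <- permanova(dm, grp[perm], n_permutations = 9)$pseudo_F
  expect_equal(f1, f2, tolerance = 1e-12)

  ad <- vegan::adonis2(d ~ g, data = data.frame(g = grp), permutations = 99)
  expect_equal(f1, ad$F[1], tolerance = 1e-10)
})

test_that("rank-sum switches correctly between exact and approximate paths", {
  r <- rank_sum(c(1, 2), c(3, 4))
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 6)

  expect_equal(rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)

  set.seed(6)
  a <- rnorm(7); b <- rnorm(7) + 0.5
  appr <- rank_sum(a, b, exact_max = 12)  # n = 14: approximation
  expect_false(appr$exact)
  exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  expect_lt(abs(appr$p_value - exact), 0.02)
})

test_that("diversity summary assembles alpha, beta and tests coherently", {
  sim <- default_sim()
  idx <- c(1:10, 43:52)
  taxa <- sim$taxa[idx, ]
  design <- sim$design[idx, ]
  class(design) <- c("cohort_design", "data.frame")
  tree <- generate_tree(ncol(taxa$values), seed = 2,
                        tip_labels = feature_ids(taxa))
  res <- diversity_summary(taxa, design, tree = tree, n_permutations = 99)
  expect_equal(nrow(res$alpha), 20L)
  expect_true(all(res$alpha$chao1 >= 0))
  expect_s3_class(res$pcoa, "pcoa_result")
  expect_true(res$permanova$p_value > 0 && res$permanova$p_value <= 1)
  expect_equal(dim(as.matrix(res$unifrac)), c(20L, 20L))
})
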