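test_that("Bonferroni thresholds and stars", {
  thr <- bonferroni_threshold(c(0.001, 0.01, 0.05, 0.1), 1714)
  expect_equal(signif(unname(thr["*"]), 3), 2.92e-5)
  expect_equal(signif(unname(thr["***"]), 3), 5.83e-7)
  expect_equal(signif(unname(bonferroni_threshold(0.05, 1707)), 3), 2.93e-5)
  expect_equal(unname(bonferroni_threshold(0.05, 1)), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("MLM with K = I and no Q degenerates to OLS to 1e-8", {
  fx <- fix_scan(seed = 7)
  res <- mlm_qk_scan(fx$y, fx$g, NULL, fx$K)
  ols <- summary(lm(fx$y ~ fx$x))
  expect_lt(abs(res$p - coef(ols)[2, 4]), 1e-8)
  expect_equal(res$rsq_marker, ols$r.squared, tolerance = 1e-8)
  expect_equal(res$beta, unname(coef(ols)[2, 1]), tolerance = 1e-8)
})

test_that("MLM p matches the brute-force dense REML oracle to 1e-6", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 20
    Z <- matrix(rnorm(n * 30), n, 30)
    K <- tcrossprod(scale(Z, scale = FALSE))
    K <- K / mean(diag(K))
    dimnames(K) <- list(sprintf("i%02d", 1:n), sprintf("i%02d", 1:n))
    u <- drop(chol(K + 1e-8 * diag(n)) %*% rnorm(n))
    x <- rbinom(n, 2, 0.4)
    if (sd(x) == 0) next
    y <- setNames(0.3 * x + u + rnorm(n, 0, 0.5), rownames(K))
    g <- genotype_matrix(matrix(x, n, 1,
                                dimnames = list(rownames(K), "m1")))
    res <- mlm_qk_scan(y, g, NULL, K)
    expect_lt(abs(res$p - oracle_mlm_p(y, x, K)), 1e-6)
  }
})

test_that("p and F satisfy the exact F relation; R2 is monotone in F", {
  set.seed(31)
  n <- 60
  ids <- sprintf("i%03d", 1:n)
  K <- tcrossprod(matrix(rnorm(n * 80), n, 80)) / 80
  dimnames(K) <- list(ids, ids)
  G <- matrix(rbinom(n * 25, 2, 0.3), n, 25,
              dimnames = list(ids, sprintf("m%02d", 1:25)))
  y <- setNames(rnorm(n) + 0.4 * G[, 3], ids)
  res <- mlm_qk_scan(y, genotype_matrix(G), NULL, K)
  ok <- !is.na(res$p)
  expect_equal(res$p[ok],
               pf(res$F[ok], 1, res$n[ok] - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # with K = I the whitening is marker-independent, so R2 ordering must
  # follow the F ordering exactly
  Ki <- diag(n); dimnames(Ki) <- list(ids, ids)
  ri <- mlm_qk_scan(y, genotype_matrix(G), NULL, Ki)
  oki <- !is.na(ri$p)
  expect_equal(order(ri$rsq_marker[oki]), order(ri$F[oki]))
})

test_that("scan is invariant to the kinship scaling convention", {
  set.seed(17)
  g <- fix_genotypes(seed = 17, n = 40, m = 30, maf = 0.35)
  Kv <- centered_ibs_kinship(g, "vanraden")
  Kt <- centered_ibs_kinship(g, "tassel")
  y <- setNames(rnorm(40) + 0.5 * g$geno[, 5], rownames(g$geno))
  gq <- subset_genotypes(g, markers = colnames(g$geno)[1:10])
  r1 <- mlm_qk_scan(y, gq, NULL, Kv)
  r2 <- mlm_qk_scan(y, gq, NULL, Kt)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("causal-SNP recovery: the causal marker ranks first", {
  hits <- 0
  reps <- 25
  for (s in seq_len(reps)) {
    set.seed(400 + s)
    n <- 72; m <- 40
    ids <- sprintf("i%03d", 1:n)
    G <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.5)), n, m, byrow = FALSE,
                dimnames = list(ids, sprintf("m%02d", 1:m)))
    x <- G[, 7]
    # effect sized for ~30% of trait variance
    b <- sqrt(0.3 / (var(x) * 0.7))
    y <- setNames(b * x + rnorm(n), ids)
    K <- diag(n); dimnames(K) <- list(ids, ids)
    res <- mlm_qk_scan(y, genotype_matrix(G), NULL, K)
    if (which.min(res$p) == 7) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("multi-trait scanner equals per-trait scans (incl. missing calls)", {
  set.seed(23)
  n <- 35
  ids <- sprintf("i%03d", 1:n)
  K <- tcrossprod(matrix(rnorm(n * 50), n, 50)) / 50
  dimnames(K) <- list(ids, ids)
  G <- matrix(rbinom(n * 12, 2, 0.3), n, 12,
              dimnames = list(ids, sprintf("m%02d", 1:12)))
  G[sample(length(G), 15)] <- NA
  g <- genotype_matrix(G)
  Q <- cbind(Q1 = runif(n)); Q <- cbind(Q, Q2 = 1 - Q[, 1])
  rownames(Q) <- ids
  traits <- data.frame(tr1 = rnorm(n), tr2 = rnorm(n) + 0.5 * ifelse(is.na(G[, 2]), 0, G[, 2]))
  traits$tr2[c(3, 9)] <- NA
  rownames(traits) <- ids
  multi <- mlm_qk_scan_multi(traits, g, Q, K)
  for (tr in names(traits)) {
    single <- mlm_qk_scan(setNames(traits[[tr]], ids), g, Q, K,
                          trait_name = tr)
    expect_equal(multi[[tr]]$p, single$p, tolerance = 1e-9)
    expect_equal(multi[[tr]]$rsq_marker, single$rsq_marker,
                 tolerance = 1e-9)
    expect_equal(multi[[tr]]$n, single$n)
  }
})

test_that("type-I error under structure is controlled; naive OLS inflates", {
  cfg <- sim_config(seed = 71, provenances = data.frame(
    provenance = c("P1", "P2", "P3", "P4"),
    n_trees = rep(25L, 4)), n_markers = 400L, causal_r2 = numeric(),
    cluster_fst = 0.05)
  gen <- simulate_genotypes(cfg)
  K <- centered_ibs_kinship(gen$genotypes)
  ids <- rownames(gen$genotypes$geno)
  set.seed(72)
  # null trait with strong structure: cluster mean shift + polygenic part
  p_scaled <- scale(gen$genotypes$geno[, 1:200])
  p_scaled[is.na(p_scaled)] <- 0
  y <- setNames(2 * (gen$cluster == "c1") + rowMeans(p_scaled) * 2 +
                  rnorm(length(ids), 0, 0.5), ids)
  res <- mlm_qk_scan(y, gen$genotypes, gen$Q, K)
  m <- sum(!is.na(res$p))
  thr <- 0.05 / m
  expect_lte(sum(res$p < thr, na.rm = TRUE), 2)
  # naive OLS on the same data has a worse (inflated) test-statistic spread
  ols_chi <- apply(gen$genotypes$geno, 2, function(x) {
    ok <- !is.na(x)
    if (sd(x[ok]) == 0) return(NA_real_)
    summary(lm(y[ok] ~ x[ok]))$coefficients[2, 3]^2
  })
  mlm_chi <- qchisq(res$p, 1, lower.tail = FALSE)
  lambda_ols <- median(ols_chi, na.rm = TRUE) / qchisq(0.5, 1,
                                                       lower.tail = FALSE)
  lambda_mlm <- median(mlm_chi, na.rm = TRUE) / qchisq(0.5, 1,
                                                       lower.tail = FALSE)
  expect_gt(lambda_ols, lambda_mlm)
  expect_lt(lambda_mlm, 1.3)
})

test_that("Q-Q data: identity line and uniform simulation", {
  m <- 40
  p <- (seq_len(m) - 0.5) / m
  qq <- qq_data(p)
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
  qq1 <- qq_data(0.5)
  expect_equal(qq1$observed, -log10(0.5))
  expect_equal(qq1$expected, -log10(0.5))
  set.seed(2)
  qqu <- qq_data(runif(10000))
  body <- qqu$expected < 3
  expect_lt(max(abs(qqu$observed[body] - qqu$expected[body])), 0.5)
  expect_error(qq_data(NA_real_), "no p values")
})

test_that("single-extreme-individual flag behaves on constructed fixtures", {
  n <- 40
  ids <- sprintf("i%03d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  set.seed(19)
  # significance driven by one outlier carrier
  x <- c(rep(1L, 3), rep(0L, n - 3))
  y <- setNames(c(8, rnorm(n - 1, 0, 1)), ids)
  g <- genotype_matrix(matrix(x, n, 1, dimnames = list(ids, "m1")))
  p0 <- mlm_qk_scan(y, g, NULL, K)$p
  expect_lt(p0, 0.05)
  fl <- flag_single_individual(y, g, "m1", NULL, K, threshold = 0.05)
  expect_true(fl$flag)
  expect_equal(fl$removed, "i001")
  # effect spread over 12 carriers with no outlier
  x2 <- c(rep(1L, 12), rep(0L, n - 12))
  y2 <- setNames(2.2 * x2 + rnorm(n, 0, 0.8), ids)
  g2 <- genotype_matrix(matrix(x2, n, 1, dimnames = list(ids, "m1")))
  p0 <- mlm_qk_scan(y2, g2, NULL, K)$p
  expect_lt(p0, 0.05)
  fl2 <- flag_single_individual(y2, g2, "m1", NULL, K, threshold = 0.05)
  expect_false(fl2$flag)
  # non-significant input -> precondition error
  y3 <- setNames(rnorm(n), ids)
  expect_error(flag_single_individual(y3, g2, "m1", NULL, K, 1e-4),
               "not significant")
})
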