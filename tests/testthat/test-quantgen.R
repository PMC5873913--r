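test_that("one-way ANOVA matches a hand-computed table and handles edge cases", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5, SSW = 4, F = 1.5/(4/4) = 1.5
  a <- anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, 1.5)
  expect_equal(a$p, pf(1.5, 1, 4, lower.tail = FALSE))
  expect_equal(unname(a$means), c(2, 3))
  # equal group means -> F = 0
  a0 <- anova_oneway(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_equal(a0$F, 0)
  expect_warning(anova_oneway(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "fewer than 2|dropping")
  expect_error(quiet(anova_oneway(c(1, 2, 9), c("a", "a", "c"))),
               ">= 2 usable groups")
})

test_that("ANOVA p-values are uniform on permuted null data", {
  set.seed(77)
  y <- rnorm(60)
  g <- rep(letters[1:4], each = 15)
  ps <- replicate(1000, anova_oneway(y, sample(g))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("repeated-measures ANOVA: oracle match, null rate, power, degeneracy", {
  set.seed(5)
  mk <- function(effect) {
    d <- expand.grid(tree_id = sprintf("t%02d", 1:24), event_year = 1:3)
    d$provenance <- rep(rep(c("P1", "P2"), each = 12), 3)
    d$Rt <- rnorm(nrow(d)) + rep(rep(rnorm(24, 0, 0.5), 3)) +
      (d$provenance == "P2") * effect
    d
  }
  # oracle: stats::aov with an Error stratum
  d <- mk(1)
  r <- rm_anova(d)
  m <- summary(aov(Rt ~ provenance + Error(tree_id), data = d))
  expect_equal(r$F, m[["Error: tree_id"]][[1]]["provenance", "F value"],
               tolerance = 1e-9)
  expect_equal(r$p, m[["Error: tree_id"]][[1]]["provenance", "Pr(>F)"],
               tolerance = 1e-9)
  # type-I error under the null (reduced replicate count; MC tolerance wide)
  rej <- mean(replicate(300, rm_anova(mk(0))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.045)
  # large injected effect -> overwhelming power
  ps <- replicate(50, rm_anova(mk(3))$p)
  expect_gte(mean(ps < 1e-3), 0.98)
  # duplicated event columns reduce to the one-way ANOVA on tree values
  d1 <- expand.grid(tree_id = sprintf("t%02d", 1:20), event_year = 1)
  d1$provenance <- rep(c("P1", "P2"), each = 10)
  d1$Rt <- rnorm(20) + (d1$provenance == "P2")
  d3 <- do.call(rbind, lapply(1:3, function(e) {
    x <- d1; x$event_year <- e; x
  }))
  expect_equal(rm_anova(d3)$F, anova_oneway(d1$Rt, d1$provenance)$F,
               tolerance = 1e-9)
  expect_error(rm_anova(d1), "use anova_oneway")
})

test_that("Duncan letters agree with a step-by-step textbook oracle", {
  means <- c(A = 9.2, B = 8.9, C = 7.1, D = 7.0)
  mse <- 1.1; df <- 36; n <- rep(10, 4); alpha <- 0.05
  # independent implementation: ordered means, protected range tests
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  se <- sqrt(mse / 10)
  sig <- matrix(FALSE, 4, 4)
  homog <- matrix(FALSE, 4, 4); diag(homog) <- TRUE
  for (span in 4:2) {
    for (i in 1:(4 - span + 1)) {
      j <- i + span - 1
      if (homog[i, j]) next
      crit <- qtukey((1 - alpha)^(span - 1), span, df) * se
      if (m[i] - m[j] < crit) homog[i:j, i:j] <- TRUE
    }
  }
  dl <- duncan_letters(means, mse, df, n, alpha)
  share <- function(g1, g2) {
    l1 <- strsplit(dl$letters[dl$group == g1], "")[[1]]
    l2 <- strsplit(dl$letters[dl$group == g2], "")[[1]]
    length(intersect(l1, l2)) > 0
  }
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(share(names(m)[i], names(m)[j]), homog[i, j],
                 info = paste(names(m)[i], names(m)[j]))
  # all means equal -> one letter
  dl <- duncan_letters(c(a = 1, b = 1, c = 1), 0.5, 20, rep(5, 3))
  expect_equal(unique(dl$letters), "a")
  # 10 SE separation -> distinct letters
  dl <- duncan_letters(c(a = 0, b = 10 * sqrt(0.5 / 5)), 0.5, 20, rep(5, 2))
  expect_false(any(grepl("a", dl$letters[2])))
  expect_error(duncan_letters(c(a = 1, b = 2), 0, 10, c(5, 5)), "zero error")
})

test_that("response standardization: log-z within event", {
  ev <- rep(c(1993, 2000), each = 3)
  v <- c(exp(1), exp(2), exp(3), 2, 4, 8)
  z <- standardize_response(v, ev, "Rt")
  expect_equal(z[1:3], scale(1:3)[, 1], tolerance = 1e-12)
  expect_equal(mean(z[4:6]), 0, tolerance = 1e-12)
  expect_equal(sd(z[4:6]), 1, tolerance = 1e-12)
  # rRs is z-scored without log (negatives allowed)
  expect_silent(standardize_response(c(-1, 0, 2, 1, -2, 0), ev, "rRs"))
  expect_error(standardize_response(c(-1, 1, 2, 1, 2, 3), ev, "Rt"), "> 0")
  expect_error(standardize_response(rep(2, 6), ev, "Rt"), "zero variance")
})

test_that("REML equals the balanced closed form and lme4 to 1e-6", {
  skip_if_not_installed("lme4")
  set.seed(42)
  n <- 10; k <- 3
  ind <- rep(sprintf("i%02d", 1:n), each = k)
  y <- rep(rnorm(n, 0, sqrt(0.3)), each = k) + rnorm(n * k, 0, sqrt(0.7))
  est <- reml_repeatability(y, ind)
  msb <- k * var(tapply(y, ind, mean))
  msw <- sum((y - ave(y, ind))^2) / (n * (k - 1))
  expect_equal(est$sigma2_ind, max((msb - msw) / k, 0), tolerance = 1e-6)
  expect_equal(est$sigma2_res, msw, tolerance = 1e-6)
  m <- lme4::lmer(y ~ 1 + (1 | ind), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(est$sigma2_ind, vc[1], tolerance = 1e-6)
  expect_equal(est$sigma2_res, vc[2], tolerance = 1e-6)
})

test_that("REML boundary and degenerate behaviour", {
  set.seed(8)
  # identical within-individual copies -> r = 1, residual 0
  y <- rep(rnorm(8), each = 3)
  est <- quiet(reml_repeatability(y, rep(sprintf("i%d", 1:8), each = 3)))
  expect_equal(est$r, 1)
  expect_equal(est$sigma2_res, 0)
  # published ratio arithmetic incl. the overall-model denominator
  expect_equal(round(repeatability_ratio(0.304, 0.575), 3), 0.346)
  expect_equal(round(repeatability_ratio(0.182, 0.798, 0.022), 3), 0.182)
  expect_error(reml_repeatability(rep(1, 6), rep(1:3, 2)), "5 individuals")
})

test_that("LRT null rate is controlled and estimates recover truth", {
  set.seed(99)
  n <- 30; k <- 3
  ind <- rep(sprintf("i%02d", 1:n), each = k)
  # null: no individual variance
  hits <- 0; reps <- 200
  for (i in 1:reps) {
    est <- reml_repeatability(rnorm(n * k), ind)
    hits <- hits + est$significant
  }
  rate <- hits / reps
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
  # parameter recovery at r in {0.1, 0.5} (reduced replicates; the full
  # 500-replicate recovery at r = 0.35 runs in the acceptance suite)
  for (r_true in c(0.1, 0.5)) {
    ests <- replicate(60, {
      y <- rep(rnorm(n, 0, sqrt(r_true)), each = k) +
        rnorm(n * k, 0, sqrt(1 - r_true))
      reml_repeatability(y, ind)$r
    })
    expect_lt(abs(mean(ests) - r_true),
              max(2 * sd(ests) / sqrt(60), 0.03))
  }
})

test_that("r approximates the mean pairwise inter-event correlation", {
  set.seed(123)
  n <- 200; k <- 3; r_true <- 0.3
  ind <- rep(sprintf("i%03d", 1:n), each = k)
  ev <- rep(1:k, n)
  y <- rep(rnorm(n, 0, sqrt(r_true)), each = k) +
    rnorm(n * k, 0, sqrt(1 - r_true))
  est <- reml_repeatability(y, ind)
  wide <- matrix(y, nrow = n, byrow = TRUE)
  cors <- cor(wide)
  expect_lt(abs(est$r - mean(cors[upper.tri(cors)])), 0.05)
})

test_that("SubsetQD selection reproduces the published pattern", {
  tab <- provenance_trial_varcomp()
  expect_setequal(select_subset_qd(tab),
                  c("R06", "d14", "I19", "Q14", "R13", "S10"))
  none <- tab; none$significant <- FALSE
  expect_warning(out <- select_subset_qd(none), "no provenance")
  expect_length(out, 0)
  all_sig <- tab; all_sig$significant <- TRUE
  expect_setequal(select_subset_qd(all_sig),
                  unique(tab$scope[tab$scope != "Overall"]))
})

test_that("correlation matrices: diagonal, ranges, sparse cells", {
  set.seed(55)
  tr <- data.frame(a = rnorm(40), b = rnorm(40))
  tr$c <- tr$a + rnorm(40, 0, 0.3)
  rownames(tr) <- sprintf("i%02d", 1:40)
  prov <- rep(c("P1", "P2"), each = 20)
  cm <- correlation_matrices(tr, prov)
  expect_equal(diag(cm$overall), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(cm$overall))
  # identical data in both provenances -> zero range
  cm2 <- correlation_matrices(rbind(tr[1:20, ], tr[1:20, ]),
                              rep(c("P1", "P2"), each = 20))
  expect_true(all(abs(cm2$range) < 1e-12, na.rm = TRUE))
  # hand-constructed range: +0.62 and -0.55 -> 1.17
  expect_equal(max(0.62, -0.55) - min(0.62, -0.55), 1.17)
  # cells with < 5 complete pairs degrade to NA
  tr$d <- c(rnorm(3), rep(NA, 37))
  cm3 <- correlation_matrices(tr, prov)
  expect_true(is.na(cm3$overall["a", "d"]))
})
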