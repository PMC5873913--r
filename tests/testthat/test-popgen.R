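test_that("SNP QC removes low-MAF and high-missingness markers", {
  G <- cbind(mono = rep(0L, 10),
             rare = c(1L, rep(0L, 9)),              # MAF 0.05 -> kept
             miss = c(rep(NA, 2), rep(1L, 8)),      # 20% missing -> removed
             ok10 = c(NA, rep(1L, 9)),              # 10% missing -> kept
             good = rep(c(0L, 1L, 2L), length.out = 10))
  rownames(G) <- sprintf("i%02d", 1:10)
  g <- genotype_matrix(G)
  qc <- quiet(snp_qc(g))
  expect_setequal(colnames(qc$genotypes$geno), c("rare", "ok10", "good"))
  expect_equal(qc$stats$kept, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  # hand-filtered 6-marker panel
  g6 <- fix_genotypes(seed = 2, n = 20, m = 6)
  st <- snp_stats(g6)
  hand <- st$marker_id[st$maf >= 0.05 & st$call_rate >= 0.9]
  expect_setequal(colnames(quiet(snp_qc(g6))$genotypes$geno), hand)
  expect_error(quiet(snp_qc(genotype_matrix(
    matrix(0L, 4, 2, dimnames = list(letters[1:4], c("a", "b")))))),
    "no marker")
})

test_that("neutral-marker selection applies context, call-rate and MAF rules", {
  G <- cbind(ex = rep(c(0L, 2L), 10),            # exon -> excluded
             in15 = c(rep(0L, 14), rep(1L, 6)),  # MAF 0.15 exactly -> excluded
             inok = rep(c(0L, 1L, 2L, 1L), 5),   # intron, MAF 0.5 -> kept
             gap = c(NA, rep(1L, 18), 0L),       # missing call -> excluded
             up = rep(c(0L, 1L), 10))            # upstream, MAF 0.25 -> kept
  rownames(G) <- sprintf("i%02d", 1:20)
  g <- genotype_matrix(G, data.frame(
    marker_id = colnames(G), chrom = "1", pos = 1:5,
    alleles = "A/G",
    gene_context = c("exon", "intron", "intron", "intergenic", "upstream")))
  expect_setequal(quiet(select_neutral(g)), c("inok", "up"))
  g$markers$gene_context[2] <- NA
  expect_error(select_neutral(g), "gene_context missing")
})

test_that("centered-IBS kinship matches the hand computation", {
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L, 1L, 1L), 3, 2,
                              dimnames = list(c("a", "b", "c"),
                                              c("m1", "m2"))))
  K <- centered_ibs_kinship(g)
  expect_equal(unname(K), rbind(c(1, 0, -1), c(0, 0, 0), c(-1, 0, 1)),
               tolerance = 1e-12)
  # duplicated individual -> identical rows and diagonals
  g2 <- fix_genotypes(seed = 3, n = 10, m = 40)
  g2$geno[2, ] <- g2$geno[1, ]
  K2 <- centered_ibs_kinship(g2)
  expect_equal(K2[1, ], K2[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(K2[1, 1], K2[2, 2], tolerance = 1e-12)
})

test_that("kinship invariants: symmetry, zero grand sum, PSD; scalings differ by a constant", {
  for (s in 1:5) {
    g <- fix_genotypes(seed = s, n = 15, m = 60, maf = runif(1, 0.1, 0.5))
    g$geno[sample(length(g$geno), 20)] <- NA
    K <- centered_ibs_kinship(g)
    expect_lt(max(abs(K - t(K))), 1e-12)
    expect_lt(abs(sum(K)), 1e-9)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
    Kt <- centered_ibs_kinship(g, scaling = "tassel")
    ratio <- Kt[K != 0] / K[K != 0]
    expect_lt(diff(range(ratio)), 1e-9)
  }
  expect_error(centered_ibs_kinship(genotype_matrix(
    matrix(2L, 4, 3, dimnames = list(letters[1:4], c("a", "b", "c"))))),
    "polymorphic")
})

test_that("HWE exact test matches enumeration and is symmetric", {
  # single attainable configuration
  expect_equal(hwe_exact(7, 0, 0), 1)
  # (1,2,1): enumeration over het in {0,2,4} puts the observed at the mode
  w <- c(`0` = factorial(4) / (factorial(2) * factorial(2)) * 2^0,
         `2` = factorial(4) / (factorial(1) * factorial(1) * factorial(2)) * 2^2,
         `4` = factorial(4) / factorial(4) * 2^4)
  pr <- w / sum(w)
  expect_equal(hwe_exact(1, 2, 1), sum(pr[pr <= pr["2"] + 1e-12]))
  # (8,1,1): observed het = 1 is the minority configuration
  w2 <- c(`1` = factorial(10) / (factorial(8) * factorial(1)) * 2,
          `3` = factorial(10) / (factorial(7) * factorial(3)) * 2^3)
  expect_equal(hwe_exact(8, 1, 1), unname(w2[1] / sum(w2)),
               tolerance = 1e-12)
  # allele relabeling symmetry
  for (cc in list(c(5, 3, 2), c(1, 4, 9), c(0, 3, 7)))
    expect_equal(hwe_exact(cc[1], cc[2], cc[3]),
                 hwe_exact(cc[3], cc[2], cc[1]), tolerance = 1e-12)
})

test_that("Weir-Cockerham theta: limits and an independent hand calculation", {
  # identical frequencies/counts in every population -> ~0
  set.seed(12)
  base <- rbinom(50, 2, 0.4)
  G <- rbind(matrix(base, 50, 20), matrix(base, 50, 20))
  rownames(G) <- sprintf("i%03d", 1:100)
  colnames(G) <- sprintf("m%02d", 1:20)
  th <- global_fst(genotype_matrix(G), rep(c("A", "B"), each = 50))$theta
  expect_lt(abs(th), 0.02)
  # fixed alternative alleles -> 1
  G2 <- rbind(matrix(0L, 20, 10), matrix(2L, 20, 10))
  rownames(G2) <- sprintf("i%03d", 1:40)
  colnames(G2) <- sprintf("m%02d", 1:10)
  expect_equal(global_fst(genotype_matrix(G2),
                          rep(c("A", "B"), each = 20))$theta, 1)
  # independent textbook calculation on a toy two-population locus
  x <- c(rep(0L, 4), rep(1L, 4), rep(2L, 2),   # pop A: p = 0.4, het 0.4
         rep(0L, 1), rep(1L, 3), rep(2L, 6))   # pop B: p = 0.75, het 0.3
  G3 <- matrix(x, 20, 1, dimnames = list(sprintf("i%02d", 1:20), "m1"))
  wc_hand <- local({
    ni <- c(10, 10); pi <- c(0.4, 0.75); hi <- c(0.4, 0.3); r <- 2
    nbar <- 10; nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
  })
  expect_equal(global_fst(genotype_matrix(G3),
                          rep(c("A", "B"), each = 10))$theta,
               wc_hand, tolerance = 1e-12)
})
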