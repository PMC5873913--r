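#' Per-marker QC statistics
#'
#' MAF is computed on non-missing calls (folded to [0, 0.5]); call rate is
#' the fraction of non-missing calls; `hwe_p` is the two-sided exact
#' Hardy-Weinberg test.
#'
#' @param g a `genotype_matrix`.
#' @return data.frame `marker_id, maf, call_rate, monomorphic, hwe_p`.
#' @export
snp_stats <- function(g) {
  G <- g$geno
  n <- nrow(G)
  nm <- colSums(!is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[nm == 0] <- NA_real_
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    hwe_exact(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
              sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  data.frame(marker_id = colnames(G), maf = unname(maf),
             call_rate = unname(nm / n),
             monomorphic = unname(maf == 0 | nm == 0), hwe_p = hwe)
}

#' Filter SNPs on MAF and missingness
#'
#' Markers with MAF below `maf_min` or a missing fraction above
#' `max_missing` are removed (the association-panel QC rule: MAF < 5% or
#' missingness > 10% excluded).
#'
#' @param g a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency kept (default 0.05).
#' @param max_missing maximum missing fraction kept (default 0.10).
#' @return list `genotypes` (filtered `genotype_matrix`), `stats`
#'   (`snp_stats` of the input with a `kept` flag).
#' @export
snp_qc <- function(g, maf_min = 0.05, max_missing = 0.10) {
  st <- snp_stats(g)
  st$kept <- !is.na(st$maf) & st$maf >= maf_min &
    (1 - st$call_rate) <= max_missing + 1e-12
  if (!any(st$kept)) dg_stop("snp-qc", "no marker passes QC")
  dg_log("snp-qc", sum(!st$kept), " of ", nrow(st), " markers removed (",
         sum(st$kept), " kept)")
  list(genotypes = subset_genotypes(g, markers = st$marker_id[st$kept]),
       stats = st)
}

#' Select putatively neutral markers
#'
#' Two-step rule: keep markers located outside exons (gene_context in
#' intron / intergenic / upstream / downstream), then require a 100% call
#' rate and MAF strictly above 0.15.
#'
#' @param g a `genotype_matrix` with `gene_context` metadata.
#' @return character vector of marker ids.
#' @export
select_neutral <- function(g) {
  ctx <- g$markers$gene_context
  if (anyNA(ctx))
    dg_stop("neutral", "gene_context missing for marker(s): ",
            paste(head(g$markers$marker_id[is.na(ctx)], 5), collapse = ", "))
  st <- snp_stats(g)
  keep <- ctx %in% c("intron", "intergenic", "upstream", "downstream") &
    st$call_rate == 1 & !is.na(st$maf) & st$maf > 0.15
  dg_log("neutral", sum(keep), " neutral markers selected")
  g$markers$marker_id[keep]
}

#' Centered-IBS genomic kinship matrix
#'
#' Genotype columns are centered by twice the observed allele frequency;
#' missing calls are imputed to the column mean (i.e. 0 after centering).
#' With `scaling = "vanraden"` (default) K = XX' / sum_j 2 p_j (1 - p_j)
#' (VanRaden method 1); `scaling = "tassel"` divides by m/2 instead — a
#' constant-factor alternative. Downstream mixed-model results are invariant
#' to the choice because the scale is absorbed into the genetic variance.
#'
#' @param g a `genotype_matrix`.
#' @param scaling `"vanraden"` or `"tassel"`.
#' @return a symmetric kinship matrix with individual dimnames.
#' @export
centered_ibs_kinship <- function(g, scaling = c("vanraden", "tassel")) {
  scaling <- match.arg(scaling)
  G <- g$geno
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2)
    dg_stop("kinship", "need >= 2 polymorphic markers")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(G, 2, 2 * p)
  X[is.na(X)] <- 0
  denom <- switch(scaling,
                  vanraden = sum(2 * p * (1 - p)),
                  tassel = ncol(X) / 2)
  K <- tcrossprod(X) / denom
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Two-sided exact Hardy-Weinberg test
#'
#' Conditions on the allele counts and sums the probabilities of all
#' heterozygote configurations no more probable than the observed one
#' (Wigginton-style exact test).
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom — order
#'   does not matter, the test is symmetric under allele relabeling).
#' @return exact p-value.
#' @export
hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n < 1) dg_stop("hwe", "empty sample")
  n_a <- 2 * n_aa + n_ab          # copies of one allele
  rare <- min(n_a, 2 * n - n_a)   # copies of the rarer allele
  hets <- seq(rare %% 2, rare, by = 2)
  # P(het = h | allele counts) up to constant: product form, computed by
  # recurrence from the mode for stability
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) - lgamma(h + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(rare + 1) -
                      lgamma(2 * n - rare + 1))
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_ab, hets)]
  sum(prob[prob <= obs + 1e-12])
}

#' Weir-Cockerham global Fst
#'
#' Per-locus theta components (a, b, c) of Weir & Cockerham (1984) computed
#' from genotype counts per population, combined across loci as a ratio of
#' sums. Loci/populations with all-missing calls contribute nothing.
#'
#' @param g a `genotype_matrix`.
#' @param populations population label per individual (aligned with rows).
#' @return list `theta` (multilocus), `per_locus` (data.frame
#'   `marker_id, a, bc, theta`).
#' @export
global_fst <- function(g, populations) {
  G <- g$geno
  pops <- factor(populations)
  if (nlevels(pops) < 2) dg_stop("fst", "need >= 2 populations")
  per <- data.frame(marker_id = colnames(G), a = NA_real_, bc = NA_real_,
                    theta = NA_real_)
  for (j in seq_len(ncol(G))) {
    x <- G[, j]
    ok <- !is.na(x)
    ni <- tapply(ok, pops, sum)
    use <- !is.na(ni) & ni >= 2
    if (sum(use) < 2) next
    lv <- levels(pops)[use]
    ni <- ni[lv]
    pi <- vapply(lv, function(l) mean(x[ok & pops == l]) / 2, numeric(1))
    hi <- vapply(lv, function(l) mean(x[ok & pops == l] == 1), numeric(1))
    r <- length(lv)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) { per$a[j] <- 0; per$bc[j] <- 0; next }
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    per$a[j] <- a
    per$bc[j] <- b + cc
    tot <- a + b + cc
    per$theta[j] <- if (tot != 0) a / tot else NA_real_
  }
  ok <- !is.na(per$a)
  denom <- sum(per$a[ok] + per$bc[ok])
  list(theta = if (denom != 0) sum(per$a[ok]) / denom else NA_real_,
       per_locus = per)
}
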