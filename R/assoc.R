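# ---- exact per-marker mixed linear model (no compression, no P3D) ----------

# profiled -2*REML criterion (constants dropped) for delta = s2e/s2g on the
# eigenbasis of K: yt = U'y, Xt = U'X, d = eigenvalues.
.mlm_wls <- function(w, yt, Xt) {
  XtW <- Xt * w
  A <- crossprod(Xt, XtW)
  b <- drop(crossprod(XtW, yt))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  rss <- sum(w * yt^2) - sum(b * beta)
  list(beta = beta, rss = max(rss, 1e-300),
       logdetA = 2 * sum(log(diag(ch))), chA = ch)
}

.mlm_crit <- function(log_delta, yt, Xt, d) {
  w <- 1 / (d + exp(log_delta))
  f <- .mlm_wls(w, yt, Xt)
  if (is.null(f)) return(Inf)
  n <- length(yt); p <- ncol(Xt)
  (n - p) * log(f$rss) - sum(log(w)) + f$logdetA
}

# All weighted cross products needed by the REML criterion are linear in the
# weight vector: with Z = [Xt, yt] and C the n x q matrix of columnwise
# products Z[,a]*Z[,b] (a <= b), crossprod(C, w) yields every entry of
# t(Z) W Z in one small dense multiply per delta. This keeps the exact
# per-marker REML scan (tens of evaluations per marker, 87k markers x
# traits) at desk scale.
.mlm_cross <- function(yt, Xt) {
  Z <- cbind(Xt, yt)
  k <- ncol(Z)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  C <- Z[, idx[, 1], drop = FALSE] * Z[, idx[, 2], drop = FALSE]
  list(C = C, idx = idx, k = k, p = ncol(Xt), n = length(yt))
}

# solve the weighted normal equations from packed cross products; returns
# NULL on a singular system
.mlm_solve <- function(cr, w) {
  e <- drop(crossprod(cr$C, w))
  M <- matrix(0, cr$k, cr$k)
  M[cr$idx] <- e
  M[cr$idx[, c(2, 1)]] <- e
  p <- cr$p
  A <- M[1:p, 1:p, drop = FALSE]
  b <- M[1:p, cr$k]
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  rss <- max(M[cr$k, cr$k] - sum(b * beta), 1e-300)
  list(beta = beta, rss = rss, logdetA = 2 * sum(log(diag(ch))), chA = ch)
}

.mlm_crit_cr <- function(log_delta, cr, d) {
  dd <- d + exp(log_delta)
  f <- .mlm_solve(cr, 1 / dd)
  if (is.null(f)) return(Inf)
  (cr$n - cr$p) * log(f$rss) + sum(log(dd)) + f$logdetA
}

# evaluate the REML criterion on a whole log-delta grid at once: weighted
# cross products for every delta come from one dense multiply, and the
# normal equations are reduced by LDL elimination with every scalar step
# vectorized across the grid
.mlm_grid_crit <- function(cr, d, lds) {
  k <- cr$k; p <- cr$p; n <- cr$n
  DD <- outer(d, exp(lds), `+`)            # n x G
  E <- crossprod(cr$C, 1 / DD)             # q x G
  G <- length(lds)
  M <- array(0, c(k, k, G))
  for (r in seq_len(nrow(cr$idx))) {
    a <- cr$idx[r, 1]; b <- cr$idx[r, 2]
    M[a, b, ] <- E[r, ]
    M[b, a, ] <- E[r, ]
  }
  logdet <- numeric(G)
  ok <- rep(TRUE, G)
  for (j in seq_len(p)) {
    pj <- M[j, j, ]
    ok <- ok & (pj > 1e-300)
    pj[!ok] <- 1
    logdet <- logdet + log(pj)
    for (a in seq(j + 1, k)) {
      Laj <- M[j, a, ] / pj
      for (b in a:k) M[a, b, ] <- M[a, b, ] - Laj * M[j, b, ]
    }
  }
  rss <- pmax(M[k, k, ], 1e-300)
  crit <- (n - p) * log(rss) + colSums(log(DD)) + logdet
  crit[!ok] <- Inf
  crit
}

# fit one marker model: three zoomed vectorized grids plus a parabolic step.
# The log-delta window is anchored at the mean eigenvalue so the search (and
# hence the fit) is exactly invariant to a constant rescaling of K.
.mlm_fit <- function(yt, Xt, d, bounds = c(-10, 10)) {
  cr <- .mlm_cross(yt, Xt)
  md <- mean(d)
  if (md > 0) bounds <- bounds + log(md)
  lds <- seq(bounds[1], bounds[2], length.out = 64)
  for (lev in 1:3) {
    cv <- .mlm_grid_crit(cr, d, lds)
    i <- which.min(cv)
    if (!is.finite(cv[i])) return(NULL)
    h <- lds[2] - lds[1]
    if (lev < 3)
      lds <- seq(max(bounds[1], lds[i] - h), min(bounds[2], lds[i] + h),
                 length.out = 33)
  }
  ld <- lds[i]
  if (i > 1 && i < length(lds) && is.finite(cv[i - 1]) &&
      is.finite(cv[i + 1])) {
    den <- cv[i - 1] - 2 * cv[i] + cv[i + 1]
    if (den > 0) ld <- lds[i] + 0.5 * h * (cv[i - 1] - cv[i + 1]) / den
  }
  delta <- exp(ld)
  n <- length(yt); p <- ncol(Xt)
  w <- 1 / (d + delta)
  f <- .mlm_solve(cr, w)
  if (is.null(f)) return(NULL)
  s2g <- f$rss / (n - p)
  XtWX_inv <- chol2inv(f$chA)
  list(delta = delta, log_delta = ld, beta = f$beta,
       vcov_beta = s2g * XtWX_inv, sigma2_g = s2g, sigma2_e = delta * s2g,
       rss = f$rss, w = w, n = n, p = p)
}

#' Bonferroni-corrected significance thresholds
#'
#' @param alpha significance level(s).
#' @param m number of markers tested.
#' @return named vector `alpha/m`; names are the star labels used in the
#'   association tables (`***` 0.001, `**` 0.01, `*` 0.05, `+` 0.1, else the
#'   alpha value).
#' @export
bonferroni_threshold <- function(alpha = c(0.001, 0.01, 0.05, 0.1), m) {
  if (length(m) != 1 || m < 1) dg_stop("bonferroni", "m must be >= 1")
  thr <- alpha / m
  lab <- c(`0.001` = "***", `0.01` = "**", `0.05` = "*", `0.1` = "+")
  names(thr) <- ifelse(as.character(alpha) %in% names(lab),
                       lab[as.character(alpha)], as.character(alpha))
  thr
}

.stars_for <- function(p, thresholds) {
  # most stringent passed level; thresholds named by star label
  thr <- sort(thresholds)
  hit <- which(p < thr)
  if (length(hit)) names(thr)[hit[1]] else ""
}

#' Q-Q plot data for association p-values
#'
#' Observed -log10 p sorted from largest to smallest against the uniform
#' expectation -log10((i - 0.5) / m).
#'
#' @param p vector of p-values.
#' @return data.frame `expected, observed` (both -log10 scale, aligned).
#' @export
qq_data <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) dg_stop("qq", "no p values")
  m <- length(p)
  obs <- sort(-log10(p), decreasing = TRUE)
  expd <- -log10((seq_len(m) - 0.5) / m)
  data.frame(expected = expd, observed = obs)
}

#' Exact MLM+Q+K association scan
#'
#' Per-trait, per-marker mixed linear model
#' y = mu + Q* v + x beta + u + e, with u ~ N(0, s2g K) and e ~ N(0, s2e I).
#' Q* is the admixture matrix with its last column dropped (full rank with
#' the intercept). The variance ratio delta = s2e/s2g is re-estimated for
#' every marker by REML on the spectral decomposition of K (computed once
#' per trait), via a coarse grid plus golden-section refinement of the
#' profiled criterion. beta is tested with an F test at denominator df
#' n - rank(fixed effects). Individuals missing the trait or the marker call
#' are dropped per test; binomial/categorical traits are analyzed on their
#' numeric codes. Marker R2 is computed on the whitened scale at the
#' marker's optimum as (RSS without marker - RSS with marker) / total
#' corrected SS.
#'
#' @param trait named numeric vector (names = individual ids).
#' @param g a `genotype_matrix`.
#' @param Q admixture matrix (rownames = ids) or `NULL` for no structure
#'   covariates.
#' @param K kinship matrix (dimnames = ids).
#' @param trait_name label carried into the result.
#' @param alpha_levels Bonferroni levels for the star labels.
#' @return data.frame, one row per marker: `trait, marker, n, beta, se, F,
#'   p, neglog10p, rsq_marker, sigma2_g, sigma2_e, delta, stars,
#'   flag_single` (flag is `NA` here; see [flag_single_individual()]).
#' @export
mlm_qk_scan <- function(trait, g, Q, K, trait_name = "trait",
                        alpha_levels = c(0.001, 0.01, 0.05, 0.1)) {
  ids <- intersect(rownames(g$geno), rownames(K))
  if (!is.null(Q)) ids <- intersect(ids, rownames(Q))
  ids <- ids[!is.na(trait[ids])]
  if (length(ids) < 10) dg_stop("mlm", "fewer than 10 usable individuals")
  y <- trait[ids]
  if (sd(y) == 0) dg_stop("mlm", "trait is constant")
  Qstar <- NULL
  if (!is.null(Q) && ncol(Q) > 1)
    Qstar <- Q[ids, -ncol(Q), drop = FALSE]
  K1 <- K[ids, ids]
  pre <- .mlm_prepare(y, Qstar, K1)
  G <- g$geno[ids, , drop = FALSE]
  m <- ncol(G)
  thr <- bonferroni_threshold(alpha_levels, m)
  acc <- .scan_acc(m)
  complete <- colSums(is.na(G)) == 0L
  Gt <- crossprod(pre$U, ifelse(is.na(G), 0, G))   # valid for complete markers
  for (j in seq_len(m)) {
    if (complete[j]) {
      fit <- .mlm_marker(pre, Gt[, j])
      nn <- length(ids)
    } else {
      use <- which(!is.na(G[, j]))
      if (length(use) < 10 || sd(y[use]) == 0) next
      Qs <- if (is.null(Qstar)) NULL else Qstar[use, , drop = FALSE]
      pre_j <- .mlm_prepare(y[use], Qs, K1[use, use])
      fit <- .mlm_marker(pre_j, crossprod(pre_j$U, G[use, j]))
      nn <- length(use)
    }
    if (is.null(fit)) next
    acc <- .scan_store(acc, j, fit, nn, thr)
  }
  res <- .scan_result(acc, trait_name, colnames(G))
  attr(res, "thresholds") <- thr
  res
}

# preallocated numeric accumulators (row-wise data.frame writes are too slow
# for an 87k-pair scan)
.scan_acc <- function(m) {
  list(num = matrix(NA_real_, m, 9,
                    dimnames = list(NULL, c("n", "beta", "se", "F", "p",
                                            "rsq_marker", "sigma2_g",
                                            "sigma2_e", "delta"))),
       stars = rep(NA_character_, m))
}

.scan_store <- function(acc, j, fit, nn, thr) {
  acc$num[j, ] <- c(nn, fit$beta, fit$se, fit$F, fit$p, fit$rsq,
                    fit$sigma2_g, fit$sigma2_e, fit$delta)
  acc$stars[j] <- .stars_for(fit$p, thr)
  acc
}

.scan_result <- function(acc, trait_name, markers) {
  data.frame(trait = trait_name, marker = markers,
             n = as.integer(acc$num[, "n"]), beta = acc$num[, "beta"],
             se = acc$num[, "se"], F = acc$num[, "F"], p = acc$num[, "p"],
             neglog10p = -log10(acc$num[, "p"]),
             rsq_marker = acc$num[, "rsq_marker"],
             sigma2_g = acc$num[, "sigma2_g"],
             sigma2_e = acc$num[, "sigma2_e"], delta = acc$num[, "delta"],
             stars = acc$stars, flag_single = NA)
}

# eigen-prepare for a trait subset; errors if K is not PSD beyond tolerance
.mlm_prepare <- function(y, Qstar, K) {
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values), 1))
    dg_stop("mlm", "kinship matrix is not PSD beyond tolerance")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), Qstar)
  yt <- drop(crossprod(U, y))
  X0t <- crossprod(U, X0)
  ones_t <- drop(crossprod(U, rep(1, length(y))))
  list(U = U, d = d, yt = yt, X0t = X0t, ones_t = ones_t,
       cr0 = .mlm_cross(yt, X0t), cr1 = .mlm_cross(yt, cbind(ones_t)))
}

# fit one marker given the prepared eigenbasis; xt = U'x. Rank-deficient
# fixed effects (marker collinear with intercept/Q) surface as singular
# normal equations and yield NULL (recorded as untestable).
.mlm_marker <- function(pre, xt) {
  Xt <- cbind(pre$X0t, marker = xt)
  fit <- .mlm_fit(pre$yt, Xt, pre$d)
  if (is.null(fit)) return(NULL)
  k <- ncol(Xt)
  beta <- fit$beta[[k]]
  se <- sqrt(fit$vcov_beta[k, k])
  Fst <- (beta / se)^2
  df2 <- fit$n - fit$p
  p <- pf(Fst, 1, df2, lower.tail = FALSE)
  # whitened-scale R2 at this marker's optimum
  if (is.null(pre$cr0)) pre$cr0 <- .mlm_cross(pre$yt, pre$X0t)
  if (is.null(pre$cr1)) pre$cr1 <- .mlm_cross(pre$yt, cbind(pre$ones_t))
  f0 <- .mlm_solve(pre$cr0, fit$w)
  f1 <- .mlm_solve(pre$cr1, fit$w)
  if (is.null(f0) || is.null(f1))
    return(c(list(rsq = NA_real_),
             list(beta = beta, se = se, F = Fst, p = p,
                  sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                  delta = fit$delta, n = fit$n, df2 = df2)))
  rss0 <- f0$rss
  tss <- f1$rss
  rsq <- if (tss > 0) (rss0 - fit$rss) / tss else
    dg_stop("mlm", "zero total SS on whitened scale")
  list(beta = beta, se = se, F = Fst, p = p, rsq = max(0, min(1, rsq)),
       sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e, delta = fit$delta,
       n = fit$n, df2 = df2)
}

#' Multi-trait MLM+Q+K scan sharing per-marker eigendecompositions
#'
#' Identical model and estimates to calling [mlm_qk_scan()] per trait, but
#' organized so that markers with missing calls — whose individual subset
#' forces a fresh eigendecomposition of K — are processed marker-outer with
#' the decomposition shared across all traits. This keeps the full
#' markers x traits scan at desk scale without approximating the exact
#' per-marker REML.
#'
#' @param traits data.frame of trait columns (rownames = individual ids).
#' @param g,Q,K,alpha_levels as in [mlm_qk_scan()].
#' @return named list of per-trait result data.frames (same layout as
#'   [mlm_qk_scan()]); traits that are constant or have fewer than 10
#'   usable individuals are skipped with a warning.
#' @export
mlm_qk_scan_multi <- function(traits, g, Q, K,
                              alpha_levels = c(0.001, 0.01, 0.05, 0.1)) {
  ids_all <- intersect(rownames(g$geno), rownames(K))
  if (!is.null(Q)) ids_all <- intersect(ids_all, rownames(Q))
  G <- g$geno[ids_all, , drop = FALSE]
  m <- ncol(G)
  thr <- bonferroni_threshold(alpha_levels, m)
  complete_m <- colSums(is.na(G)) == 0L
  usable <- character()
  ys <- list()
  for (tr in names(traits)) {
    y <- setNames(as.numeric(traits[[tr]]), rownames(traits))[ids_all]
    names(y) <- ids_all
    if (sum(!is.na(y)) < 10 || sd(y, na.rm = TRUE) == 0) {
      dg_warn("mlm", "trait ", tr, " skipped (constant or < 10 values)")
      next
    }
    usable <- c(usable, tr)
    ys[[tr]] <- y
  }
  accs <- lapply(usable, function(tr) .scan_acc(m))
  names(accs) <- usable
  qsub <- function(idx) if (is.null(Q) || ncol(Q) < 2) NULL else
    Q[idx, -ncol(Q), drop = FALSE]
  # complete markers: trait-outer, one eigendecomposition per trait
  for (tr in usable) {
    y <- ys[[tr]]
    keep <- ids_all[!is.na(y)]
    pre <- .mlm_prepare(y[keep], qsub(keep), K[keep, keep])
    Gt <- crossprod(pre$U, G[keep, complete_m, drop = FALSE])
    cols <- which(complete_m)
    for (jj in seq_along(cols)) {
      fit <- .mlm_marker(pre, Gt[, jj])
      if (!is.null(fit))
        accs[[tr]] <- .scan_store(accs[[tr]], cols[[jj]], fit, length(keep),
                                  thr)
    }
  }
  # incomplete markers: marker-outer, eigendecomposition shared over traits
  for (j in which(!complete_m)) {
    use_m <- ids_all[!is.na(G[, j])]
    if (length(use_m) < 10) next
    pre_m <- NULL
    for (tr in usable) {
      y <- ys[[tr]]
      use <- use_m[!is.na(y[use_m])]
      if (length(use) < 10 || sd(y[use]) == 0) next
      if (length(use) == length(use_m)) {
        if (is.null(pre_m))
          pre_m <- .mlm_prepare_multi(qsub(use_m), K[use_m, use_m])
        pre <- pre_m
      } else {
        pre <- .mlm_prepare_multi(qsub(use), K[use, use])
      }
      yt <- drop(crossprod(pre$U, y[pre$ids_local]))
      fit <- .mlm_marker(list(U = pre$U, d = pre$d, yt = yt,
                              X0t = pre$X0t, ones_t = pre$ones_t),
                         drop(crossprod(pre$U, G[pre$ids_local, j])))
      if (!is.null(fit))
        accs[[tr]] <- .scan_store(accs[[tr]], j, fit,
                                  length(pre$ids_local), thr)
    }
  }
  out <- lapply(usable, function(tr) {
    res <- .scan_result(accs[[tr]], tr, colnames(G))
    attr(res, "thresholds") <- thr
    res
  })
  names(out) <- usable
  out
}

.mlm_prepare_multi <- function(Qstar, K) {
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values), 1))
    dg_stop("mlm", "kinship matrix is not PSD beyond tolerance")
  ids <- rownames(K)
  X0 <- cbind(`(Intercept)` = rep(1, nrow(K)), Qstar)
  list(U = eig$vectors, d = pmax(eig$values, 0), X0t = crossprod(eig$vectors, X0),
       ones_t = drop(crossprod(eig$vectors, rep(1, nrow(K)))),
       ids_local = ids)
}

#' Leave-one-out flag for single-individual-driven associations
#'
#' Refits the marker after removing the single most trait-extreme individual
#' among minor-genotype carriers; the flag is `TRUE` when the refit p-value
#' no longer passes `threshold` (the association hinged on one extreme
#' phenotype). If fewer than 10 individuals remain the flag is `TRUE` with
#' reason `"undersized"`.
#'
#' @param trait named numeric vector.
#' @param g a `genotype_matrix`.
#' @param marker marker id (must be significant at `threshold`).
#' @param Q,K as in [mlm_qk_scan()].
#' @param threshold p-value threshold the original fit passed.
#' @return list `flag, p_original, p_refit, removed, reason`.
#' @export
flag_single_individual <- function(trait, g, marker, Q, K, threshold) {
  ids <- intersect(rownames(g$geno), rownames(K))
  if (!is.null(Q)) ids <- intersect(ids, rownames(Q))
  x <- g$geno[ids, marker]
  ids <- ids[!is.na(trait[ids]) & !is.na(x)]
  y <- trait[ids]
  x <- g$geno[ids, marker]
  scan1 <- function(keep) {
    gg <- subset_genotypes(g, individuals = keep, markers = marker)
    r <- mlm_qk_scan(trait[keep], gg,
                     if (is.null(Q)) NULL else Q[keep, , drop = FALSE],
                     K[keep, keep], trait_name = "loo")
    r$p[[1]]
  }
  p0 <- scan1(ids)
  if (is.na(p0) || p0 >= threshold)
    dg_stop("flag-single", "association is not significant at the threshold")
  cls <- table(x)
  minor_class <- as.integer(names(cls)[which.min(cls)])
  carriers <- ids[x == minor_class]
  z <- abs(y - mean(y)) / sd(y)
  names(z) <- ids
  drop_id <- carriers[which.max(z[carriers])]
  keep <- setdiff(ids, drop_id)
  if (length(keep) < 10)
    return(list(flag = TRUE, p_original = p0, p_refit = NA_real_,
                removed = drop_id, reason = "undersized"))
  p1 <- scan1(keep)
  list(flag = is.na(p1) || p1 >= threshold, p_original = p0, p_refit = p1,
       removed = drop_id, reason = NA_character_)
}
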