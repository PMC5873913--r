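#' One-way fixed-effects ANOVA among provenances
#'
#' Standard between/within decomposition with provenance as a fixed effect.
#' Groups with fewer than 2 observations are dropped with a warning.
#'
#' @param values numeric trait values.
#' @param groups group (provenance) labels.
#' @return list `F, p, df_between, df_within, ms_within, means, n` (per-group
#'   means and sizes).
#' @export
anova_oneway <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    dg_warn("anova", "dropping group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  g <- factor(groups)
  if (nlevels(g) < 2) dg_stop("anova", "need >= 2 usable groups")
  n <- length(values)
  means <- setNames(as.numeric(tapply(values, g, mean)), levels(g))
  sizes <- setNames(as.integer(tapply(values, g, length)), levels(g))
  grand <- mean(values)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  dfb <- nlevels(g) - 1L
  dfw <- n - nlevels(g)
  msb <- ssb / dfb
  msw <- ssw / dfw
  F <- if (msw == 0) Inf else msb / msw
  list(F = F, p = pf(F, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw, ms_within = msw,
       means = means, n = sizes)
}

#' Repeated-measures ANOVA for the provenance effect across drought events
#'
#' Drought events are the repeated measure on each tree (random); provenance
#' is fixed. The provenance F uses the between-subject stratum: F =
#' MS(provenance) / MS(trees within provenance). Trees missing any event are
#' excluded (complete-case repeated measures).
#'
#' @param responses data.frame with columns `tree_id, event_year, provenance`
#'   and the response in `value` (or pass `trait` to pick a column such as
#'   `Rt`).
#' @param trait response column name (default `"Rt"`).
#' @return list `F, p, df1, df2, n_trees`.
#' @export
rm_anova <- function(responses, trait = "Rt") {
  d <- responses[, c("tree_id", "event_year", "provenance")]
  d$value <- responses[[trait]]
  d <- d[!is.na(d$value), , drop = FALSE]
  events <- unique(d$event_year)
  if (length(events) < 2)
    dg_stop("rm-anova", "need >= 2 events; use anova_oneway for a single event")
  cnt <- table(d$tree_id)
  complete <- names(cnt)[cnt == length(events)]
  d <- d[d$tree_id %in% complete, , drop = FALSE]
  tree <- factor(d$tree_id)
  prov <- factor(d$provenance[match(levels(tree), d$tree_id)])
  k <- length(events)
  # between-subject stratum on tree means
  tree_means <- tapply(d$value, tree, mean)
  grand <- mean(d$value)
  a <- nlevels(prov)
  prov_means <- tapply(tree_means, prov, mean)
  n_per <- tapply(tree_means, prov, length)
  ss_prov <- k * sum(n_per * (prov_means - grand)^2)
  ss_tree <- k * sum((tree_means - prov_means[prov])^2)
  df1 <- a - 1L
  df2 <- length(tree_means) - a
  F <- (ss_prov / df1) / (ss_tree / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2,
       n_trees = nlevels(tree))
}

#' Duncan's multiple range test with compact letter display
#'
#' Ordered means are compared with range-dependent critical values from the
#' studentized range distribution at protection level 1 - (1 - alpha)^(p-1)
#' for a range spanning p means. Ranges are tested largest-first; a
#' non-significant range declares all spanned means homogeneous and protects
#' its sub-ranges. Unbalanced designs use the harmonic mean group size.
#'
#' @param means named vector of group means.
#' @param mse error mean square from the ANOVA.
#' @param df error degrees of freedom.
#' @param n group sizes (named like `means`).
#' @param alpha significance level (default 0.05).
#' @return data.frame `group, mean, letters`, sorted by decreasing mean.
#' @export
duncan_letters <- function(means, mse, df, n, alpha = 0.05) {
  if (mse <= 0) dg_stop("duncan", "zero error mean square")
  g <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  nh <- g / sum(1 / n)                       # harmonic mean size
  se <- sqrt(mse / nh)
  crit <- vapply(2:max(2, g), function(p)
    qtukey((1 - alpha)^(p - 1), p, df) * se, numeric(1))
  # homogeneous groups: for each start, extend right while range ns
  same <- diag(TRUE, g)
  for (i in seq_len(g - 1)) {
    for (j in seq(i + 1, g)) {
      p <- j - i + 1
      if (abs(m[i] - m[j]) < crit[p - 1]) {
        same[i, i:j] <- TRUE   # whole stretch homogeneous (protection rule)
        same[i:j, i:j][upper.tri(matrix(0, p, p), diag = TRUE)] <- TRUE
      }
    }
  }
  same <- same | t(same)
  # collect maximal homogeneous stretches as letter groups
  stretches <- list()
  for (i in seq_len(g)) {
    j <- i
    while (j < g && same[i, j + 1]) j <- j + 1
    stretches[[i]] <- i:j
  }
  keep <- rep(TRUE, length(stretches))
  for (i in seq_along(stretches)) for (j in seq_along(stretches)) {
    if (i != j && all(stretches[[i]] %in% stretches[[j]]) &&
        length(stretches[[j]]) > length(stretches[[i]])) keep[i] <- FALSE
  }
  stretches <- unique(stretches[keep])
  letters_out <- rep("", g)
  for (s in seq_along(stretches)) {
    lab <- letters[(s - 1) %% 26 + 1]
    letters_out[stretches[[s]]] <- paste0(letters_out[stretches[[s]]], lab)
  }
  data.frame(group = names(m), mean = unname(m), letters = letters_out,
             row.names = NULL)
}

#' Standardize drought response indicators for variance-component analysis
#'
#' Rt, Rc and Rs are strictly positive ratios: they are log-transformed and
#' then z-scored within each drought event (mean 0, sd 1 across trees).
#' rRs can be <= 0 and is z-scored only.
#'
#' @param values numeric indicator values.
#' @param event event labels (z-scoring is within event).
#' @param index_kind one of `"Rt"`, `"Rc"`, `"Rs"`, `"rRs"`.
#' @return numeric vector of transformed values.
#' @export
standardize_response <- function(values, event, index_kind) {
  take_log <- index_kind %in% c("Rt", "Rc", "Rs")
  if (take_log && any(values <= 0, na.rm = TRUE)) {
    bad <- which(values <= 0)[1]
    dg_stop("standardize", index_kind, " must be > 0 (offending index ",
            bad, ", event ", event[bad], ")")
  }
  v <- if (take_log) log(values) else values
  out <- rep(NA_real_, length(v))
  for (ev in unique(event)) {
    i <- which(event == ev & !is.na(v))
    s <- sd(v[i])
    if (is.na(s) || s == 0)
      dg_stop("standardize", "zero variance within event ", ev)
    out[i] <- (v[i] - mean(v[i])) / s
  }
  out
}

# ---- REML engine ------------------------------------------------------------

# Dense-V REML log-likelihood for y = 1*mu + sum_k u_k + e,
# u_k ~ N(0, s2_k Z_k Z_k'), e ~ N(0, s2_e I). theta = c(s2_1..s2_K, s2_e).
.reml_loglik <- function(theta, y, Zs) {
  n <- length(y)
  K <- length(Zs)
  V <- diag(theta[[K + 1L]], n)
  for (k in seq_len(K)) V <- V + theta[[k]] * tcrossprod(Zs[[k]])
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  xvx <- sum(Vi_1)                    # X = 1
  beta <- sum(Vi_y) / xvx
  r <- y - beta
  Vi_r <- Vi_y - beta * Vi_1
  -0.5 * ((n - 1) * log(2 * pi) + logdetV + log(xvx) + sum(r * Vi_r))
}

# fit variance components by bounded REML; returns estimates, loglik, vcov
.reml_fit <- function(y, Zs, lower_floor = NULL) {
  vy <- var(y)
  if (vy == 0) dg_stop("reml", "total variance is zero")
  K <- length(Zs)
  start <- rep(vy / (K + 1), K + 1L)
  lower <- rep(1e-10 * vy, K + 1L)
  lower[K + 1L] <- 1e-8 * vy   # keep V invertible
  negll <- function(th) -.reml_loglik(th, y, Zs)
  fit <- optim(start, negll, method = "L-BFGS-B", lower = lower,
               upper = rep(50 * vy, K + 1L),
               control = list(maxit = 500, factr = 1e3,
                              ndeps = rep(1e-7 * vy, K + 1L)))
  if (fit$convergence != 0 && fit$convergence != 52)
    dg_stop("reml", "REML did not converge: code ", fit$convergence,
            " (", fit$message, ")")
  theta <- fit$par
  boundary <- theta <= lower * 2
  # numeric Hessian of -2*loglik -> asymptotic covariance = 2 * H^-1
  h <- pmax(1e-5 * vy, 1e-3 * theta)
  Hf <- matrix(0, K + 1L, K + 1L)
  f0 <- 2 * negll(theta)
  for (i in seq_len(K + 1L)) for (j in i:(K + 1L)) {
    ei <- ej <- rep(0, K + 1L); ei[i] <- h[i]; ej[j] <- h[j]
    fpp <- 2 * negll(pmax(theta + ei + ej, lower))
    fpm <- 2 * negll(pmax(theta + ei - ej, lower))
    fmp <- 2 * negll(pmax(theta - ei + ej, lower))
    fmm <- 2 * negll(pmax(theta - ei - ej, lower))
    Hf[i, j] <- Hf[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
  }
  vc <- tryCatch(2 * solve(Hf), error = function(e)
    matrix(NA_real_, K + 1L, K + 1L))
  se <- sqrt(pmax(diag(vc), 0))
  se[boundary] <- 0
  theta[boundary] <- 0
  list(theta = theta, se = se, vcov = vc, loglik = -fit$value,
       boundary = boundary)
}

#' Repeatability from REML variance components
#'
#' Fits `y = mu + individual + (provenance) + e` by restricted maximum
#' likelihood with non-negativity constraints on the variance components.
#' Repeatability is the individual-variance fraction
#' r = sigma2_ind / (sigma2_ind + sigma2_res) for a single-provenance fit;
#' the across-provenance ("overall") model adds a provenance random effect
#' and includes sigma2_prov in the denominator. The standard error of r is
#' obtained by the delta method on the inverse observed-information matrix;
#' significance is a likelihood-ratio test of sigma2_ind = 0 against the
#' 50:50 chi0:chi1 mixture at `alpha`.
#'
#' @param y transformed responses (one value per individual x event).
#' @param individual individual ids (>= 2 records for >= 5 individuals).
#' @param provenance provenance ids, or `NULL` for a single-provenance fit.
#' @param alpha LRT level (default 0.05).
#' @return list with `sigma2_prov, sigma2_ind, sigma2_res` (+ `se_*`),
#'   `r, se_r, significant, p_lrt, loglik, boundary, scope, not_estimable`.
#' @export
reml_repeatability <- function(y, individual, provenance = NULL,
                               alpha = 0.05) {
  ok <- !is.na(y)
  y <- y[ok]; individual <- factor(as.character(individual)[ok])
  cnt <- table(individual)
  if (sum(cnt >= 2) < 5)
    dg_stop("reml", "need >= 2 records for >= 5 individuals")
  Z_ind <- outer(individual, levels(individual), `==`) * 1
  Zs <- list(ind = Z_ind)
  overall <- !is.null(provenance)
  if (overall) {
    provenance <- factor(as.character(provenance)[ok])
    Zs$prov <- outer(provenance, levels(provenance), `==`) * 1
    Zs <- Zs[c("prov", "ind")]
  }
  fit <- .reml_fit(y, Zs)
  K <- length(Zs)
  th <- fit$theta; se <- fit$se
  if (overall) {
    s2p <- th[1]; s2a <- th[2]; s2e <- th[3]
    sep <- se[1]; sea <- se[2]; see <- se[3]
    denom_idx <- 1:3
  } else {
    s2p <- NA_real_; s2a <- th[1]; s2e <- th[2]
    sep <- NA_real_; sea <- se[1]; see <- se[2]
    denom_idx <- 1:2
  }
  tot <- sum(th[denom_idx])
  not_estimable <- tot <= 0 || (s2a == 0 && s2e == 0)
  r <- if (not_estimable) NA_real_ else s2a / tot
  # delta method: r = a / T with T the scope denominator
  se_r <- NA_real_
  if (!not_estimable && all(is.finite(fit$vcov))) {
    grad <- rep(0, K + 1L)
    a_idx <- if (overall) 2L else 1L
    for (i in denom_idx) grad[i] <- -s2a / tot^2
    grad[a_idx] <- (tot - s2a) / tot^2
    v <- drop(t(grad) %*% fit$vcov %*% grad)
    se_r <- sqrt(max(v, 0))
  }
  if (!is.na(r) && fit$boundary[if (overall) 2L else 1L]) se_r <- 0
  # LRT of sigma2_ind = 0
  Zs0 <- Zs[setdiff(names(Zs), "ind")]
  ll0 <- if (length(Zs0)) .reml_fit(y, Zs0)$loglik else {
    n <- length(y)
    s2 <- sum((y - mean(y))^2) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi) + n * log(s2) + log(n / s2) + (n - 1))
  }
  lr <- max(0, 2 * (fit$loglik - ll0))
  p_lrt <- 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  if (lr == 0) p_lrt <- 1
  list(sigma2_prov = s2p, sigma2_ind = s2a, sigma2_res = s2e,
       se_prov = sep, se_ind = sea, se_res = see,
       r = r, se_r = se_r, significant = !is.na(r) && p_lrt < alpha,
       p_lrt = p_lrt, loglik = fit$loglik, boundary = fit$boundary,
       scope = if (overall) "overall" else "per-provenance",
       not_estimable = not_estimable)
}

#' Repeatability ratio from (printed or estimated) variance components
#'
#' r = sigma2_ind / (sigma2_prov + sigma2_ind + sigma2_res); the provenance
#' component enters the denominator only for the across-provenance model
#' (pass 0 or leave default for a per-provenance ratio).
#'
#' @param sigma2_ind,sigma2_res,sigma2_prov variance components.
#' @return the ratio, `NA` when the denominator is 0.
#' @export
repeatability_ratio <- function(sigma2_ind, sigma2_res, sigma2_prov = 0) {
  tot <- sigma2_prov + sigma2_ind + sigma2_res
  ifelse(tot > 0, sigma2_ind / tot, NA_real_)
}

#' Per-provenance repeatability table for all four drought indicators
#'
#' @param responses output of [drought_response_table()].
#' @param alpha LRT level.
#' @return data.frame with one row per provenance (plus `"Overall"`) x trait.
#' @export
repeatability_table <- function(responses, alpha = 0.05) {
  traits <- c("Rt", "Rc", "Rs", "rRs")
  rows <- list()
  for (tr in traits) {
    z <- standardize_response(responses[[tr]], responses$event_year, tr)
    for (pv in unique(responses$provenance)) {
      i <- responses$provenance == pv
      est <- tryCatch(reml_repeatability(z[i], responses$tree_id[i],
                                         alpha = alpha),
                      error = function(e) NULL)
      if (is.null(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        scope = pv, trait = tr, sigma2_prov = NA_real_,
        sigma2_ind = est$sigma2_ind, sigma2_res = est$sigma2_res,
        se_ind = est$se_ind, se_res = est$se_res, r = est$r,
        se_r = est$se_r, significant = est$significant, p_lrt = est$p_lrt)
    }
    est <- reml_repeatability(z, responses$tree_id, responses$provenance,
                              alpha = alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "Overall", trait = tr, sigma2_prov = est$sigma2_prov,
      sigma2_ind = est$sigma2_ind, sigma2_res = est$sigma2_res,
      se_ind = est$se_ind, se_res = est$se_res, r = est$r,
      se_r = est$se_r, significant = est$significant, p_lrt = est$p_lrt)
  }
  do.call(rbind, rows)
}

#' Select the subset of provenances with significant Rt repeatability
#'
#' @param rep_table output of [repeatability_table()] (or any data.frame with
#'   `scope`, `trait`, `significant`).
#' @return character vector of provenance labels (SubsetQD).
#' @export
select_subset_qd <- function(rep_table) {
  rt <- rep_table[rep_table$trait == "Rt" & rep_table$scope != "Overall", ]
  out <- rt$scope[which(rt$significant)]
  if (!length(out)) dg_warn("subsetqd", "no provenance has significant Rt repeatability")
  out
}

#' Per-provenance Pearson correlation matrices and their range
#'
#' Pairwise-complete Pearson correlations per provenance and overall; cells
#' with fewer than `min_n` complete pairs are missing. The range matrix is
#' max - min across provenances per cell.
#'
#' @param traits trait data.frame (rownames = individual ids).
#' @param provenance provenance label per row of `traits`.
#' @param min_n minimum complete pairs per cell (default 5).
#' @return list `per_provenance` (named list of matrices), `overall`,
#'   `range`.
#' @export
correlation_matrices <- function(traits, provenance, min_n = 5) {
  X <- as.matrix(data.frame(lapply(traits, as.numeric),
                            check.names = FALSE))
  corm <- function(M) {
    r <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
    npair <- crossprod(!is.na(M))
    r[npair < min_n] <- NA_real_
    diag(r) <- 1
    r
  }
  per <- lapply(split(seq_len(nrow(X)), provenance),
                function(i) corm(X[i, , drop = FALSE]))
  arr <- simplify2array(per)
  rng <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE) - min(v, na.rm = TRUE))
  list(per_provenance = per, overall = corm(X), range = rng)
}
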