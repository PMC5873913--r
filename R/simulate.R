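# ---- synthetic-data generator ----------------------------------------------
# The generator emits a complete, deterministic dataset with the statistical
# structure the pipeline assumes: station climate with embedded extreme
# growing-season droughts, ring series whose drought-year multipliers carry a
# provenance/individual/residual variance decomposition plus causal-marker
# effects, and 2-cluster Balding-Nichols genotypes with low differentiation.

.default_provenances <- function() {
  # 11 provenances, 22-55 trees each (323 total), as in the trial layout;
  # r_target is the per-provenance repeatability of drought resistance the
  # generator aims for (heterogeneous, 0 to 0.44, as observed in the trial)
  data.frame(
    provenance = c("b03", "d04", "d14", "I19", "Q14", "R06", "R13", "S10",
                   "ST", "X05", "Y18"),
    n_trees = c(27L, 34L, 30L, 22L, 32L, 23L, 22L, 24L, 55L, 27L, 27L),
    r_target = c(0.015, 0.000, 0.346, 0.192, 0.389, 0.233, 0.440, 0.408,
                 0.083, 0.071, 0.065))
}

#' Simulation configuration
#'
#' Defaults mirror the trial shape the pipeline targets: 11 provenances with
#' 22-55 trees each, ring series 1978-2011, three growing-season droughts
#' (1993, 2000, 2003) with the 2000 event strongest, a drought-response
#' variance decomposition (provenance/individual/residual log-scale
#' fractions), ~1,700 biallelic SNPs in two weakly differentiated clusters
#' (Fst 0.015) and three causal SNPs with large effects.
#'
#' @param seed mandatory integer seed; all generator randomness derives from
#'   it.
#' @param provenances data.frame `provenance, n_trees` plus an optional
#'   `r_target` column giving each provenance its own target repeatability
#'   of drought resistance (the default mirrors the emulated trial's
#'   heterogeneous pattern; without the column the global
#'   `variance_fractions` apply uniformly).
#' @param years calendar years of the ring record.
#' @param drought_years event years (growing-season extreme droughts).
#' @param drought_multiplier per-event mean growth multiplier in the event
#'   year (ratio scale).
#' @param post_multiplier per-event mean multiplier in the two years after
#'   the event (lasting growth reduction; drives resilience).
#' @param variance_fractions named fractions `prov, ind, res` of the
#'   drought-response log-variance (must be >= 0, sum <= 1).
#' @param drought_logvar total log-scale variance of the drought-year
#'   multiplier.
#' @param annual_sd tree-specific annual lognormal noise (non-drought
#'   growth).
#' @param k_clusters,cluster_fst,n_markers,maf_range genotype model:
#'   Balding-Nichols clusters, target Fst, marker count, ancestral MAF
#'   range.
#' @param causal_r2 target per-marker R2 of the causal SNPs (each in
#'   (0, 0.6); their summed variance must fit inside the (tree-weighted
#'   mean) individual fraction). With per-provenance `r_target`s the marker
#'   effects are scaled by provenance susceptibility,
#'   sqrt(r_target / mean r_target), so provenances without repeatable
#'   drought response also carry no causal-marker signal — the pooled scan
#'   sees the stated R2 on average while the high-repeatability subset
#'   sees proportionally more.
#' @param genotyped_fraction fraction of trees emitted with genotypes,
#'   selected as the phenotype extremes (half highest, half lowest mean
#'   standardized drought resistance), emulating how association panels are
#'   drawn from a larger phenotyped trial.
#' @param missing_rate_range per-marker missing-call rate for the
#'   non-complete markers (60\% of markers are complete).
#' @param pure_clusters logical; `TRUE` makes every individual a pure
#'   cluster member (used by estimator closed-loop tests).
#' @param n_stations,site station-climate settings (site = trial
#'   coordinates).
#' @param climate_beta_p,climate_beta_t log-growth loadings on standardized
#'   May+June precipitation / May-August temperature.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       provenances = .default_provenances(),
                       years = 1978:2011,
                       drought_years = c(1993L, 2000L, 2003L),
                       drought_multiplier = c(0.50, 0.22, 0.60),
                       post_multiplier = c(0.72, 0.27, 0.80),
                       variance_fractions = c(prov = 0.02, ind = 0.18,
                                              res = 0.80),
                       drought_logvar = 0.25,
                       annual_sd = 0.08,
                       k_clusters = 2L,
                       cluster_fst = 0.015,
                       n_markers = 1750L,
                       maf_range = c(0.05, 0.5),
                       causal_r2 = c(0.10, 0.05, 0.03),
                       genotyped_fraction = 0.45,
                       missing_rate_range = c(0.01, 0.08),
                       pure_clusters = FALSE,
                       n_stations = 4L,
                       site = c(lat = 48.548, lon = 16.171),
                       climate_beta_p = 0.12,
                       climate_beta_t = 0.10) {
  if (missing(seed) || is.null(seed)) dg_stop("sim", "seed is mandatory")
  vf <- variance_fractions
  if (any(vf < 0) || sum(vf) > 1 + 1e-12)
    dg_stop("sim", "variance fractions must be >= 0 and sum <= 1")
  if (length(causal_r2) && any(causal_r2 <= 0 | causal_r2 >= 0.6))
    dg_stop("sim", "causal R2 targets must lie in (0, 0.6)")
  if (length(drought_multiplier) != length(drought_years) ||
      length(post_multiplier) != length(drought_years))
    dg_stop("sim", "one multiplier per drought year required")
  ind_frac <- if (!is.null(provenances$r_target)) {
    if (any(provenances$r_target < 0 | provenances$r_target > 0.6))
      dg_stop("sim", "per-provenance r_target must lie in [0, 0.6]")
    sum(provenances$r_target * provenances$n_trees) / sum(provenances$n_trees)
  } else {
    vf[["ind"]] / (vf[["ind"]] + vf[["res"]])
  }
  if (sum(causal_r2) > ind_frac + 1e-12)
    dg_stop("sim", "summed causal-marker R2 (", sum(causal_r2),
            ") exceeds the mean individual fraction (", round(ind_frac, 3), ")")
  structure(list(seed = as.integer(seed), provenances = provenances,
                 years = as.integer(years),
                 drought_years = as.integer(drought_years),
                 drought_multiplier = drought_multiplier,
                 post_multiplier = post_multiplier,
                 variance_fractions = vf, drought_logvar = drought_logvar,
                 annual_sd = annual_sd, k_clusters = as.integer(k_clusters),
                 cluster_fst = cluster_fst, n_markers = as.integer(n_markers),
                 maf_range = maf_range, causal_r2 = causal_r2,
                 genotyped_fraction = genotyped_fraction,
                 missing_rate_range = missing_rate_range,
                 pure_clusters = pure_clusters,
                 n_stations = as.integer(n_stations), site = site,
                 climate_beta_p = climate_beta_p,
                 climate_beta_t = climate_beta_t),
            class = "sim_config")
}

.tree_ids <- function(cfg) {
  unlist(lapply(seq_len(nrow(cfg$provenances)), function(i)
    sprintf("%s_%03d", cfg$provenances$provenance[[i]],
            seq_len(cfg$provenances$n_trees[[i]]))), use.names = FALSE)
}

.tree_prov <- function(cfg) {
  rep(cfg$provenances$provenance, cfg$provenances$n_trees)
}

# seasonal monthly means for the dry lowland site (annual sum ~ 520 mm)
.prcp_monthly_mean <- c(25, 25, 35, 40, 55, 65, 65, 60, 45, 35, 35, 30)
.tmean_monthly_mean <- 9.1 + 10.5 * cos(2 * pi * ((1:12) - 7) / 12)

#' Simulate station climate records
#'
#' Monthly precipitation is gamma per calendar month (shape 4), shared
#' regional weather plus station-level noise; temperature is AR(1) around a
#' seasonal mean. Drought years have their spring/summer precipitation
#' scaled down (May/June hardest) iteratively until the site-interpolated
#' 1- or 3-month SPI falls below -2 in the growing season. Non-drought
#' February-July months share a per-year spring signal (Gaussian copula,
#' rho 0.93) and are drawn from the upper 65% of each month's gamma, so the
#' configured droughts are the only extreme growing-season deficits — the
#' generator deliberately under-disperses non-drought spring precipitation
#' relative to real records (see the methods vignette).
#'
#' @param cfg a `sim_config`.
#' @return list with `stations` (list of `climate_record`), `site`
#'   (IDW-interpolated `climate_record`), and the per-event `spi_min`
#'   reached.
#' @export
simulate_climate <- function(cfg) {
  set.seed(cfg$seed + 11L)
  years <- (min(cfg$years) - 17L):max(cfg$years)  # reference depth pre-trial
  ny <- length(years)
  shape <- 4
  # regional monthly quantiles u[y, m]; growing-season non-drought months
  # avoid the deep-deficit tail
  u <- matrix(runif(ny * 12), ny, 12)
  gs <- 4:7
  is_drought <- years %in% cfg$drought_years
  # Feb-Jul share a per-year wet/dry spring signal (Gaussian copula,
  # rho = 0.93) and non-drought years stay out of the deep-deficit tail:
  # the configured droughts must be the only extreme growing-season
  # deficits, for single months and for the 3-month sums alike
  rho <- 0.93
  z_yr <- rnorm(ny)
  z <- rho * z_yr + sqrt(1 - rho^2) * matrix(rnorm(ny * 6), ny, 6)
  u[, 2:7] <- pnorm(z)
  u[!is_drought, 2:7] <- 0.35 + 0.60 * u[!is_drought, 2:7]
  site_p <- t(vapply(1:12, function(m)
    qgamma(u[, m], shape = shape, rate = shape / .prcp_monthly_mean[[m]]),
    numeric(ny)))                      # 12 x ny
  # temperature: shared AR(1) anomaly
  anom <- numeric(ny * 12)
  for (i in seq_along(anom))
    anom[i] <- 0.3 * (if (i > 1) anom[i - 1] else 0) + rnorm(1, 0, 1.2)
  site_t <- matrix(.tmean_monthly_mean, 12, ny) +
    matrix(anom, 12, ny)
  site_t[5:8, is_drought] <- site_t[5:8, is_drought] + 2.0
  # stations around the site
  st_lat <- cfg$site[["lat"]] + seq(-0.3, 0.3, length.out = cfg$n_stations)
  st_lon <- cfg$site[["lon"]] + rep(c(-0.25, 0.25), length.out = cfg$n_stations)
  st_noise <- lapply(seq_len(cfg$n_stations), function(s)
    matrix(exp(rnorm(12 * ny, 0, 0.05)), 12, ny))
  build_stations <- function(scale_mj) {
    p <- site_p
    p[5:6, is_drought] <- p[5:6, is_drought] * scale_mj
    # spring droughts are season-wide: April and July dry too, more mildly,
    # so every 1- and 3-month growing-season window sees the deficit tail
    p[c(2, 3, 4, 7), is_drought] <- p[c(2, 3, 4, 7), is_drought] *
      sqrt(scale_mj)
    lapply(seq_len(cfg$n_stations), function(s)
      climate_record(sprintf("st%02d", s), st_lat[[s]], st_lon[[s]],
                     200 + 20 * s,
                     year = rep(years, each = 12), month = rep(1:12, ny),
                     prcp_mm = as.vector(p * st_noise[[s]]),
                     tmean_c = as.vector(site_t)))
  }
  scale_mj <- 0.12
  for (it in 1:8) {
    stations <- build_stations(scale_mj)
    site <- idw_interpolate(stations, cfg$site[["lat"]], cfg$site[["lon"]])
    ref <- c(min(years), max(years))
    spi1 <- compute_spi(site, k = 1, reference = ref)
    spi3 <- compute_spi(site, k = 3, reference = ref)
    mins <- vapply(cfg$drought_years, function(y) {
      i1 <- spi1$year == y & spi1$month %in% gs
      i3 <- spi3$year == y & spi3$month %in% gs
      min(c(spi1$spi[i1], spi3$spi[i3]), na.rm = TRUE)
    }, numeric(1))
    if (all(mins <= -2.02)) break
    scale_mj <- scale_mj * 0.55
  }
  list(stations = stations, site = site,
       spi_min = setNames(mins, cfg$drought_years), scale_mj = scale_mj)
}

#' Simulate 2-cluster Balding-Nichols genotypes with admixture
#'
#' Ancestral allele frequencies are uniform on `maf_range`; cluster
#' frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F); an individual's allele
#' frequency mixes the cluster frequencies by its admixture proportion and
#' genotypes are Binomial(2, p). Provenances alternate between
#' mostly-cluster-1 and mostly-cluster-2 ancestry. 60% of markers have a
#' 100% call rate; the rest get a per-marker missing rate from
#' `missing_rate_range`. Causal markers (used by [simulate_rings()]) are
#' chosen among complete exonic markers with MAF >= 0.2.
#'
#' @param cfg a `sim_config`.
#' @return list `genotypes` (a `genotype_matrix`), `Q` (true admixture
#'   matrix), `cluster` (majority-cluster label per individual),
#'   `causal` (data.frame `marker_id, p, r2_target`).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed + 22L)
  ids <- .tree_ids(cfg)
  n <- length(ids)
  m <- cfg$n_markers
  FF <- cfg$cluster_fst
  p_anc <- runif(m, cfg$maf_range[[1]], cfg$maf_range[[2]])
  p_cl <- vapply(seq_len(cfg$k_clusters), function(k)
    rbeta(m, p_anc * (1 - FF) / FF, (1 - p_anc) * (1 - FF) / FF),
    numeric(m))                         # m x K
  prov_q <- rep(c(0.85, 0.15), length.out = nrow(cfg$provenances))
  if (cfg$pure_clusters) prov_q <- rep(c(1, 0), length.out = nrow(cfg$provenances))
  q_ind <- rep(prov_q, cfg$provenances$n_trees)
  if (!cfg$pure_clusters)
    q_ind <- pmin(pmax(q_ind + rnorm(n, 0, 0.08), 0.02), 0.98)
  p_ind <- outer(q_ind, p_cl[, 1]) + outer(1 - q_ind, p_cl[, 2])  # n x m
  G <- matrix(rbinom(n * m, 2L, as.vector(p_ind)), n, m)
  rownames(G) <- ids
  colnames(G) <- sprintf("SNP%05d", seq_len(m))
  ctx <- sample(c("exon", "intron", "intergenic", "upstream", "downstream"),
                m, replace = TRUE, prob = c(0.5, 0.2, 0.15, 0.075, 0.075))
  complete <- runif(m) < 0.6
  miss_rate <- ifelse(complete, 0,
                      runif(m, cfg$missing_rate_range[[1]],
                            cfg$missing_rate_range[[2]]))
  obs_maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
  causal_ok <- which(complete & ctx == "exon" & obs_maf >= 0.2)
  n_causal <- length(cfg$causal_r2)
  causal_idx <- if (n_causal) sort(sample(causal_ok, n_causal)) else integer()
  for (j in which(miss_rate > 0)) {
    hit <- runif(n) < miss_rate[[j]]
    G[hit, j] <- NA_integer_
  }
  markers <- data.frame(marker_id = colnames(G), chrom = "1",
                        pos = 1000L * seq_len(m),
                        alleles = "A/G", gene_context = ctx)
  Q <- cbind(Q1 = q_ind, Q2 = 1 - q_ind)
  rownames(Q) <- ids
  causal <- data.frame(marker_id = colnames(G)[causal_idx],
                       p = colMeans(G, na.rm = TRUE)[causal_idx] / 2,
                       r2_target = cfg$causal_r2[seq_along(causal_idx)])
  list(genotypes = genotype_matrix(G, markers), Q = Q,
       cluster = ifelse(q_ind >= 0.5, "c1", "c2"), causal = causal)
}

#' Simulate two-core ring series with embedded drought response
#'
#' Baseline log ring width = age-trend curve + lognormal tree effect +
#' climate loading (standardized May+June precipitation, May-August
#' temperature) + annual noise. In a drought year the log multiplier is the
#' event mean plus a provenance effect, an individual effect (constant
#' across events; its variance is the individual fraction minus the causal
#' genetic variance), the causal-marker additive effects, and a per-event
#' residual. The two years after an event carry the event's post-multiplier
#' as an event-level constant: individual deviations do not persist into the
#' recovery years, so resilience carries almost no between-individual signal
#' (matching the near-zero Rs repeatabilities of the emulated trial) and —
#' because the 2000 post-window is the 2003 pre-window — consecutive events
#' stay uncorrelated, preserving the compound-symmetry structure the
#' repeatability model assumes.
#' Densities and the EW/LW split follow the drought sign structure (lower
#' RW, higher MAXD in drought years).
#'
#' @param cfg a `sim_config`.
#' @param geno_sim output of [simulate_genotypes()].
#' @param site_climate site `climate_record` from [simulate_climate()]
#'   (optional; omitting it drops the climate loading).
#' @return list `cores` (list of `ring_series`, two per tree), `truth`
#'   (ground-truth record: per-tree effects, causal effects, true
#'   repeatability).
#' @export
simulate_rings <- function(cfg, geno_sim, site_climate = NULL) {
  set.seed(cfg$seed + 33L)
  ids <- .tree_ids(cfg)
  prov <- .tree_prov(cfg)
  if (!setequal(rownames(geno_sim$genotypes$geno), ids))
    dg_stop("sim-rings", "genotype individuals do not match the configured trees")
  n <- length(ids)
  years <- cfg$years
  V <- cfg$drought_logvar
  vf <- cfg$variance_fractions
  vw <- (vf[["ind"]] + vf[["res"]]) * V    # within-provenance log variance
  # per-provenance repeatability targets (heterogeneous when r_target given)
  pv <- cfg$provenances
  r_prov <- if (!is.null(pv$r_target)) setNames(pv$r_target, pv$provenance)
    else setNames(rep(vf[["ind"]] / (vf[["ind"]] + vf[["res"]]),
                      nrow(pv)), pv$provenance)
  r_mean <- sum(r_prov[prov]) / n
  causal <- geno_sim$causal
  # pooled causal variance = sum(r2) * vw; effects scaled per provenance by
  # sqrt(r_p / r_mean) so only susceptible provenances carry marker signal
  beta <- if (nrow(causal))
    sqrt(causal$r2_target * vw / (2 * causal$p * (1 - causal$p))) else numeric()
  var_causal <- if (nrow(causal)) sum(causal$r2_target) * vw else 0
  susc <- if (r_mean > 0) sqrt(r_prov / r_mean) else r_prov * 0
  G <- geno_sim$genotypes$geno
  g_causal <- matrix(0, n, max(1L, nrow(causal)))
  if (nrow(causal)) {
    g_raw <- G[ids, causal$marker_id, drop = FALSE]
    for (j in seq_len(ncol(g_raw))) {   # causal markers are complete by design
      g_causal[, j] <- (g_raw[, j] - 2 * causal$p[[j]]) * beta[[j]] *
        susc[prov]
    }
  }
  # individual noise per provenance: target individual variance minus the
  # causal share attributed to that provenance (floored at 0)
  s2_ind_noise <- pmax(r_prov * vw - (r_prov / max(r_mean, 1e-12)) *
                         var_causal, 0)
  prov_lv <- unique(prov)
  prov_eff <- setNames(rnorm(length(prov_lv), 0, sqrt(vf[["prov"]] * V)),
                       prov_lv)
  ind_eff <- rnorm(n, 0, sqrt(s2_ind_noise[prov])) + rowSums(g_causal)
  # climate loadings
  zP <- zT <- setNames(rep(0, length(years)), years)
  if (!is.null(site_climate)) {
    d <- site_climate$data
    mj <- vapply(years, function(y)
      sum(d$prcp_mm[d$year == y & d$month %in% 5:6]), numeric(1))
    st <- vapply(years, function(y)
      mean(d$tmean_c[d$year == y & d$month %in% 5:8]), numeric(1))
    zP <- setNames(as.vector(scale(mj)), years)
    zT <- setNames(as.vector(scale(st)), years)
  }
  age <- seq_along(years)
  base_curve <- 2.5 * exp(-age / 12) + 1.0
  ev_idx <- setNames(seq_along(cfg$drought_years), cfg$drought_years)
  cores <- list()
  # residual variance completes each provenance's within variance to vw
  s2_res <- pmax(vw - r_prov * vw, 1e-8)
  resid_ev <- matrix(rnorm(n * length(cfg$drought_years), 0,
                           rep(sqrt(s2_res[prov]),
                               length(cfg$drought_years))),
                     n, length(cfg$drought_years))
  for (i in seq_len(n)) {
    tree_scale <- exp(rnorm(1, 0, 0.15))
    log_rw <- log(base_curve * tree_scale) +
      cfg$climate_beta_p * zP[as.character(years)] -
      cfg$climate_beta_t * zT[as.character(years)] +
      rnorm(length(years), 0, cfg$annual_sd)
    for (e in seq_along(cfg$drought_years)) {
      ye <- cfg$drought_years[[e]]
      tree_part <- prov_eff[[prov[[i]]]] + ind_eff[[i]] + resid_ev[i, e]
      k <- match(ye, years)
      if (!is.na(k))
        log_rw[k] <- log_rw[k] + log(cfg$drought_multiplier[[e]]) + tree_part
      for (dy in 1:2) {
        k2 <- match(ye + dy, years)
        if (!is.na(k2))
          log_rw[k2] <- log_rw[k2] + log(cfg$post_multiplier[[e]])
      }
    }
    rw <- exp(log_rw)
    lwp <- pmin(pmax(rnorm(length(years), 25, 4), 5), 60)
    rd_base <- rnorm(1, 450, 25)
    rd <- rd_base + rnorm(length(years), 0, 10)
    drought <- years %in% cfg$drought_years
    rd[drought] <- rd[drought] + 10
    ed <- rd - 60 + rnorm(length(years), 0, 8)
    ld <- rd + 180 + rnorm(length(years), 0, 12)
    maxd <- ld + 80 + rnorm(length(years), 0, 10)
    maxd[drought] <- maxd[drought] + 40
    mind <- ed - 60 + rnorm(length(years), 0, 8)
    for (core in c("a", "b")) {
      rw_c <- rw * exp(rnorm(length(years), 0, 0.05))
      cores[[paste0(ids[[i]], "_", core)]] <- ring_series(
        tree_id = ids[[i]], core_id = paste0(ids[[i]], "_", core),
        provenance = prov[[i]], years = years,
        RW = rw_c, EW = rw_c * (1 - lwp / 100), LW = rw_c * lwp / 100,
        LWP = lwp, RD = rd, ED = ed, LD = ld, MIND = mind, MAXD = maxd)
    }
  }
  truth <- list(event_years = cfg$drought_years,
                causal = cbind(causal, beta = beta),
                true_r_per_provenance = as.list(r_prov),
                true_r_overall = r_mean * vw / (vw + vf[["prov"]] * V),
                variance_fractions = as.list(vf),
                prov_effects = as.list(prov_eff),
                ind_effects = setNames(as.list(ind_eff), ids))
  list(cores = cores, truth = truth)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [simulate_climate()], [simulate_genotypes()] and [simulate_rings()]
#' and writes climate CSVs, a long-form ring CSV and a Tucson .rwl, a VCF
#' with marker metadata CSV, the true Q matrix CSV and a ground-truth JSON
#' into `out_dir`. Deterministic: the same config (incl. seed) yields
#' byte-identical files.
#'
#' @param cfg a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return invisible list of the in-memory objects and file paths.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clim <- simulate_climate(cfg)
  gen <- simulate_genotypes(cfg)
  rings <- simulate_rings(cfg, gen, clim$site)
  # association panel: phenotype extremes (half highest / half lowest mean
  # standardized drought resistance), as panels are drawn from large trials
  ids <- .tree_ids(cfg)
  genotyped <- ids
  if (cfg$genotyped_fraction < 1) {
    by_tree <- split(rings$cores, vapply(rings$cores, function(s) s$tree_id,
                                         character(1)))
    trees <- lapply(by_tree, function(cs) average_cores(cs[[1]], cs[[2]]))
    resp <- drought_response_table(trees, cfg$drought_years)
    z <- standardize_response(resp$Rt, resp$event_year, "Rt")
    mz <- tapply(z, resp$tree_id, mean, na.rm = TRUE)
    mz <- mz[!is.na(mz)]
    n_gen <- round(cfg$genotyped_fraction * length(ids))
    ord <- order(mz)
    genotyped <- names(mz)[c(head(ord, floor(n_gen / 2)),
                             tail(ord, ceiling(n_gen / 2)))]
    genotyped <- ids[ids %in% genotyped]
    gen$genotypes <- subset_genotypes(gen$genotypes,
                                      individuals = genotyped)
    gen$Q <- gen$Q[genotyped, , drop = FALSE]
    gen$cluster <- gen$cluster[match(genotyped, ids)]
  }
  rings$truth$genotyped_ids <- genotyped
  paths <- list(
    climate = file.path(out_dir, "climate.csv"),
    stations = file.path(out_dir, "stations.csv"),
    rings = file.path(out_dir, "rings.csv"),
    rwl = file.path(out_dir, "rings.rwl"),
    vcf = file.path(out_dir, "genotypes.vcf"),
    markers = file.path(out_dir, "markers.csv"),
    q = file.path(out_dir, "qmatrix.csv"),
    truth = file.path(out_dir, "groundtruth.json"))
  write_climate_csv(clim$stations, paths$climate, paths$stations)
  write_long_csv(rings$cores, paths$rings)
  write_rwl(rings$cores, paths$rwl)
  write_vcf(gen$genotypes, paths$vcf)
  data.table::fwrite(gen$genotypes$markers, paths$markers, na = "NA")
  write_q_matrix(gen$Q, paths$q)
  jsonlite::write_json(rings$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  dg_log("simulate", "dataset written to ", out_dir)
  invisible(list(config = cfg, climate = clim, genotypes = gen,
                 rings = rings, paths = paths))
}
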