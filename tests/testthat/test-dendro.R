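test_that("core averaging: mean, fallback, and id guard", {
  a <- ring_series("t1", "c1", years = 1990:1992, RW = c(2, 2, 1.2))
  b <- ring_series("t1", "c2", years = 1990:1991, RW = c(3, 2))
  m <- average_cores(a, b)
  expect_equal(m$data$RW, c(2.5, 2, 1.2))
  expect_equal(average_cores(a, a)$data$RW, a$data$RW)
  expect_error(average_cores(a, ring_series("t2", years = 1990, RW = 1)),
               "different trees")
})

test_that("Lloret indicators: arithmetic, identities, scale invariance", {
  s <- fix_series()   # RW 1,1,4,6,2,3,5,1,1 over 1990:1998
  r <- compute_drought_response(s, 1994)
  expect_equal(r$Rt, 0.4)
  expect_equal(r$Rc, 2.0)
  expect_equal(r$Rs, 0.8)
  expect_equal(r$rRs, 0.4)
  # constant series
  rc <- compute_drought_response(fix_series(rw = rep(2, 9)), 1994)
  expect_equal(c(rc$Rt, rc$Rc, rc$Rs, rc$rRs), c(1, 1, 1, 0))
  # identities + scale invariance on random series
  set.seed(9)
  for (i in 1:20) {
    rw <- runif(9, 0.5, 5)
    r1 <- compute_drought_response(fix_series(rw = rw), 1994)
    r2 <- compute_drought_response(fix_series(rw = rw * 3.7), 1994)
    expect_equal(r1$Rs, r1$Rt * r1$Rc, tolerance = 1e-12)
    expect_equal(r1$rRs, r1$Rs - r1$Rt, tolerance = 1e-12)
    expect_equal(r1$Rt, r2$Rt, tolerance = 1e-12)
    expect_equal(r1$Rs, r2$Rs, tolerance = 1e-12)
  }
  # boundary: event in the second recorded year
  r <- compute_drought_response(s, 1991)
  expect_true(is.na(r$Rt))
  expect_equal(r$reason, "insufficient pre-window")
  # missing ring inside the window
  s2 <- ring_series("t1", years = 1990:1998,
                    RW = c(1, 1, NA, 6, 2, 3, 5, 1, 1))
  r <- compute_drought_response(s2, 1994)
  expect_equal(r$reason, "insufficient pre-window")
})

test_that("mean chronology is a per-tree unit-mean index", {
  one <- ring_series("t1", years = 1:3 + 2000, RW = c(1, 2, 3))
  ch <- build_mean_chronology(list(one))
  expect_equal(ch$index, c(0.5, 1, 1.5))
  two <- build_mean_chronology(list(one, one))
  expect_equal(two$index, ch$index)
  expect_equal(two$depth, c(2L, 2L, 2L))
  # 3-tree fixture vs hand-computed index
  t2 <- ring_series("t2", years = 2001:2003, RW = c(2, 2, 2))
  t3 <- ring_series("t3", years = 2002:2003, RW = c(1, 3))
  ch <- build_mean_chronology(list(one, t2, t3))
  expect_equal(ch$index,
               c(mean(c(0.5, 1)), mean(c(1, 1, 0.5)), mean(c(1.5, 1, 1.5))))
  expect_equal(ch$depth, c(2L, 3L, 3L))
  expect_warning(
    build_mean_chronology(list(one, ring_series("t4", years = 2001,
                                                RW = NA_real_))),
    "all-missing")
})

test_that("climate-growth traits: Fisher z, clipping, screening", {
  set.seed(21)
  yrs <- 1986:2011
  clim <- climate_record("site", 48, 16, NA,
                         rep(1985:2011, each = 12), rep(1:12, 27),
                         rgamma(27 * 12, 4, 0.1), rnorm(27 * 12, 10, 4))
  may_p <- clim$data$prcp_mm[clim$data$month == 5 &
                               clim$data$year %in% yrs]
  # tree 1: RW equal to May precipitation -> r = 1 -> finite clipped z
  t1 <- ring_series("t1", years = yrs, RW = may_p)
  t2 <- ring_series("t2", years = yrs, RW = rnorm(length(yrs), 2, 0.2))
  cg <- climate_growth_traits(list(t1, t2), clim, variables = "CorMayP")
  expect_gt(cg$traits["t1", "CorMayP"], 13)   # atanh(1 - 1e-12)
  expect_true(is.finite(cg$traits["t1", "CorMayP"]))
  # hand-evaluated Pearson/atanh: r = 0.8 -> z = 1.0986
  expect_equal(atanh(cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))),
               1.0986123, tolerance = 1e-6)
  # Fisher z is odd
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(atanh(-r), -atanh(r))
  # screening keeps May precipitation for a precipitation-driven stand
  stand <- lapply(1:6, function(i)
    ring_series(paste0("s", i), years = yrs,
                RW = 0.01 * may_p + rnorm(length(yrs), 2, 0.05)))
  cg <- climate_growth_traits(stand, clim)
  expect_true("CorMayP" %in% cg$selected$variable[
    !is.na(cg$selected$p) & cg$selected$p < 0.05])
})

test_that("trait transforms follow the lower-class tie rule", {
  expect_equal(transform_trait(c(1, 2, 3, 4), "binomial"), c(0L, 0L, 1L, 1L))
  expect_equal(transform_trait(1:9, "categorical"),
               c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L))
  # explicit cutpoint equal to an observed value -> that value goes low
  expect_equal(transform_trait(c(1, 2, 3), "binomial", cutpoints = 2),
               c(0L, 0L, 1L))
  # median of (1, 3, 4) is 3; 3 sits on the cutpoint and goes low
  expect_equal(transform_trait(c(1, NA, 3, 4), "binomial"),
               c(0L, NA, 0L, 1L))
  expect_error(transform_trait(rep(1, 5), "binomial"), "constant")
})

test_that("scenario traits combine two events with documented rules", {
  rt1 <- c(1.2, 0.4, 1.1, 0.5, NA)
  rt2 <- c(1.3, 0.5, 0.4, 1.2, 1.0)
  # medians: 0.8 (rt1 non-NA: 1.2,0.4,1.1,0.5 -> 0.8), rt2 -> 1.0
  expect_equal(scenario_trait(rt1, rt2, "Scen1"), c(1L, 0L, 0L, 0L, NA))
  expect_equal(scenario_trait(rt1, rt2, "Scen2"), c(1L, 0L, 1L, 1L, NA))
  expect_equal(scenario_trait(rt1, rt2, "Scen3"), c(2L, 0L, 1L, 1L, NA))
  expect_error(scenario_trait(rt1, rt2[1:3]), "length mismatch")
})

test_that("assembled trait table has the canonical 51 columns", {
  cfg <- fix_sim_config(seed = 31)
  clim <- quiet(simulate_climate(cfg))
  gen <- simulate_genotypes(cfg)
  rng <- simulate_rings(cfg, gen, clim$site)
  by_tree <- split(rng$cores, vapply(rng$cores, function(s) s$tree_id,
                                     character(1)))
  trees <- lapply(by_tree, function(cs) average_cores(cs[[1]], cs[[2]]))
  resp <- drought_response_table(trees, cfg$drought_years)
  tt <- build_analysis_traits(trees, resp, clim$site)
  expect_equal(ncol(tt), 51)
  expect_true(all(c("Scen1", "Scen4", "Rt93", "rRs03", "CorJunT", "RW",
                    "RWb", "RWt", "MINDt") %in% names(tt)))
  expect_equal(sum(startsWith(names(tt), "Cor")), 8)
  # binomial/categorical columns obey their code sets
  expect_true(all(tt$RWb %in% c(0L, 1L, NA)))
  expect_true(all(tt$RWt %in% c(0L, 1L, 2L, NA)))
})
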