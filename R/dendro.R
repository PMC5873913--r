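#' Average two cores of the same tree
#'
#' Per-year arithmetic mean for each measurement; when one core lacks a year
#' (or a measurement), the other core's value is used. Averaging the two
#' radii damps eccentric-growth artefacts such as compression wood.
#'
#' @param a,b `ring_series` with the same `tree_id`.
#' @return a `ring_series` (core_id `"mean"`).
#' @export
average_cores <- function(a, b) {
  if (!identical(a$tree_id, b$tree_id))
    dg_stop("dendro", "cores belong to different trees: ",
            a$tree_id, " vs ", b$tree_id)
  years <- sort(union(a$data$year, b$data$year))
  ia <- match(years, a$data$year)
  ib <- match(years, b$data$year)
  vals <- lapply(c("RW", "EW", "LW", "LWP", "RD", "ED", "LD", "MIND", "MAXD"),
                 function(m) {
                   va <- a$data[[m]][ia]
                   vb <- b$data[[m]][ib]
                   out <- rowMeans(cbind(va, vb), na.rm = TRUE)
                   out[is.nan(out)] <- NA_real_
                   out
                 })
  names(vals) <- c("RW", "EW", "LW", "LWP", "RD", "ED", "LD", "MIND", "MAXD")
  do.call(ring_series,
          c(list(tree_id = a$tree_id, core_id = "mean",
                 provenance = a$provenance, years = years), vals))
}

#' Lloret drought response indicators for one tree and event
#'
#' From raw ring widths: `Dr` is the drought-year width, `preDr`/`postDr`
#' the mean widths of the `window` years before/after. The indicators are
#' resistance Rt = Dr/preDr, recovery Rc = postDr/Dr, resilience
#' Rs = postDr/preDr and relative resilience rRs = (postDr - Dr)/preDr.
#' If any required year is missing the response is returned as missing with
#' a reason, not as an error, so event tables can degrade gracefully.
#'
#' @param series a `ring_series` (tree level, cores already averaged).
#' @param event_year calendar year of the drought event.
#' @param window years before/after used for preDr/postDr (default 2;
#'   closed interval, so window 2 means exactly the two adjacent years).
#' @return one-row data.frame `tree_id, event_year, Dr, preDr, postDr, Rt,
#'   Rc, Rs, rRs, reason` (reason `NA` when defined).
#' @export
compute_drought_response <- function(series, event_year, window = 2) {
  rw <- setNames(series$data$RW, series$data$year)
  need_pre <- as.character(event_year - seq_len(window))
  need_post <- as.character(event_year + seq_len(window))
  miss <- function(reason) data.frame(
    tree_id = series$tree_id, event_year = event_year, Dr = NA_real_,
    preDr = NA_real_, postDr = NA_real_, Rt = NA_real_, Rc = NA_real_,
    Rs = NA_real_, rRs = NA_real_, reason = reason)
  dr <- rw[as.character(event_year)]
  if (is.na(dr)) return(miss("missing drought-year ring"))
  pre <- rw[need_pre]
  if (anyNA(pre)) return(miss("insufficient pre-window"))
  post <- rw[need_post]
  if (anyNA(post)) return(miss("insufficient post-window"))
  preDr <- mean(pre); postDr <- mean(post)
  data.frame(tree_id = series$tree_id, event_year = event_year,
             Dr = unname(dr), preDr = preDr, postDr = postDr,
             Rt = unname(dr) / preDr, Rc = postDr / unname(dr),
             Rs = postDr / preDr, rRs = (postDr - unname(dr)) / preDr,
             reason = NA_character_)
}

#' Drought response table for many trees and events
#'
#' @param series_list list of tree-level `ring_series`.
#' @param event_years integer vector of drought years.
#' @param window see [compute_drought_response()].
#' @return data.frame with one row per tree x event.
#' @export
drought_response_table <- function(series_list, event_years, window = 2) {
  rows <- lapply(series_list, function(s)
    do.call(rbind, lapply(event_years, function(y)
      compute_drought_response(s, y, window))))
  out <- do.call(rbind, rows)
  out$provenance <- vapply(series_list, function(s) s$provenance,
                           character(1))[match(out$tree_id,
                                               vapply(series_list,
                                                      function(s) s$tree_id,
                                                      character(1)))]
  rownames(out) <- NULL
  out
}

#' Mean ring-width chronology
#'
#' Each tree's RW is divided by its own full-span mean (a dimensionless
#' index with tree-level mean exactly 1), then averaged across trees per
#' year. Sample depth (number of contributing trees) is reported per year.
#'
#' @param series_list list of `ring_series`.
#' @return data.frame `year, index, depth`.
#' @export
build_mean_chronology <- function(series_list) {
  if (!length(series_list)) dg_stop("chron", "no series supplied")
  idx_list <- list()
  for (s in series_list) {
    rw <- s$data$RW
    if (all(is.na(rw))) {
      dg_warn("chron", "tree ", s$tree_id, " has all-missing RW; excluded")
      next
    }
    idx_list[[length(idx_list) + 1L]] <-
      data.frame(year = s$data$year, index = rw / mean(rw, na.rm = TRUE))
  }
  all <- do.call(rbind, idx_list)
  all <- all[!is.na(all$index), , drop = FALSE]
  agg <- split(all$index, all$year)
  data.frame(year = as.integer(names(agg)),
             index = vapply(agg, mean, numeric(1)),
             depth = vapply(agg, length, integer(1)),
             row.names = NULL)
}

# 18-month window: April of the previous year .. September of the current
.cgw_months <- function() {
  data.frame(month = c(4:12, 1:9),
             prev_year = c(rep(TRUE, 9), rep(FALSE, 9)))
}

.cgw_name <- function(month, prev_year, var) {
  paste0("Cor", ifelse(prev_year, "p", ""), month.abb[month],
         c(prcp_mm = "P", tmean_c = "T")[[var]])
}

# matrix of monthly climate values aligned to ring years
.climate_design <- function(climate, years) {
  w <- .cgw_months()
  cols <- list()
  for (var in c("prcp_mm", "tmean_c")) {
    for (i in seq_len(nrow(w))) {
      m <- w$month[[i]]
      yy <- if (w$prev_year[[i]]) years - 1L else years
      v <- climate$data[[var]][match(paste(yy, m),
                                     paste(climate$data$year,
                                           climate$data$month))]
      cols[[.cgw_name(m, w$prev_year[[i]], var)]] <- v
    }
  }
  as.data.frame(cols, check.names = FALSE, row.names = as.character(years))
}

#' Climate-growth correlation traits
#'
#' Two-step procedure. Step 1 screens the 18-month window (April of the
#' previous year to September of the current year, temperature and
#' precipitation) by correlating each monthly variable with the mean
#' chronology and keeping variables with two-sided p < `alpha_select`.
#' Step 2 computes the per-tree Pearson correlation of raw RW with every
#' kept variable and returns its Fisher z transform, `atanh(r)` with |r|
#' clipped to 1 - 1e-12.
#'
#' @param series_list list of tree-level `ring_series`.
#' @param climate site `climate_record`.
#' @param alpha_select screening level (default 0.05).
#' @param variables optional character vector of variable names (e.g.
#'   `"CorJunT"`) to force, bypassing the screening step — used to pin the
#'   trait table to a fixed column set.
#' @return list with `selected` (screening table) and `traits` (data.frame,
#'   rownames = tree ids, one `Cor*` column per kept variable).
#' @export
climate_growth_traits <- function(series_list, climate, alpha_select = 0.05,
                                  variables = NULL) {
  chron <- build_mean_chronology(series_list)
  X <- .climate_design(climate, chron$year)
  ok_years <- complete.cases(X) & !is.na(chron$index)
  if (sum(ok_years) < 10)
    dg_stop("climcorr", "fewer than 10 overlapping years between rings and climate")
  screen <- data.frame(variable = names(X), r = NA_real_, p = NA_real_)
  for (j in seq_along(X)) {
    x <- X[ok_years, j]; y <- chron$index[ok_years]
    if (sd(x) == 0 || sd(y) == 0) next
    ct <- cor.test(x, y)
    screen$r[[j]] <- unname(ct$estimate); screen$p[[j]] <- ct$p.value
  }
  keep <- if (is.null(variables)) {
    screen$variable[!is.na(screen$p) & screen$p < alpha_select]
  } else {
    missing_v <- setdiff(variables, names(X))
    if (length(missing_v)) dg_stop("climcorr", "unknown climate variables: ",
                                   paste(missing_v, collapse = ", "))
    variables
  }
  clip <- 1 - 1e-12
  traits <- lapply(series_list, function(s) {
    rw <- setNames(s$data$RW, s$data$year)
    out <- rep(NA_real_, length(keep))
    for (j in seq_along(keep)) {
      x <- X[[keep[[j]]]]
      y <- rw[as.character(chron$year)]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      r <- cor(x[ok], y[ok])
      out[[j]] <- atanh(pmin(pmax(r, -clip), clip))
    }
    out
  })
  tr <- do.call(rbind, traits)
  rownames(tr) <- vapply(series_list, function(s) s$tree_id, character(1))
  colnames(tr) <- keep
  list(selected = screen, traits = as.data.frame(tr))
}

#' Transform a continuous trait to binomial or categorical codes
#'
#' Binomial default splits at the median (codes 0/1); categorical default
#' uses tertiles (codes 0/1/2). Quantiles use linear interpolation between
#' order statistics; values exactly on a cutpoint go to the lower class;
#' missing propagates.
#'
#' @param values numeric vector.
#' @param mode `"binomial"` or `"categorical"`.
#' @param cutpoints explicit cutpoints (1 for binomial, 2 for categorical);
#'   default quantile-based.
#' @return integer vector of class codes with `NA` preserved.
#' @export
transform_trait <- function(values, mode = c("binomial", "categorical"),
                            cutpoints = NULL) {
  mode <- match.arg(mode)
  obs <- values[!is.na(values)]
  if (length(unique(obs)) < 2)
    dg_stop("transform", "trait is constant; cannot categorize")
  if (is.null(cutpoints)) {
    cutpoints <- if (mode == "binomial") median(obs) else
      quantile(obs, c(1, 2) / 3, names = FALSE, type = 7)
  }
  expected <- if (mode == "binomial") 1L else 2L
  if (length(cutpoints) != expected)
    dg_stop("transform", mode, " transform needs ", expected, " cutpoint(s)")
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  out[ok] <- rowSums(outer(values[ok], cutpoints, `>`))
  out
}

#' Registry of drought-resistance scenario rules
#'
#' Scenarios combine per-event resistance (Rt) of two reference droughts
#' into a single binomial or categorical trait. The event cutoffs printed
#' with the original trial are not recoverable, so the rules are a
#' configurable registry with documented defaults (per-event medians):
#' `Scen1` = 1 when above both medians; `Scen2` = 1 when above either;
#' `Scen3` = number of events above the median (0/1/2);
#' `Scen4` = tertile class of the mean of per-event z-scored Rt.
#'
#' @param rt1,rt2 per-individual Rt for the two combined events (aligned).
#' @param scenario `"Scen1"`..`"Scen4"`.
#' @param cutoffs optional explicit per-event cutoffs `c(c1, c2)` for
#'   Scen1-Scen3 (defaults to the per-event medians).
#' @return integer codes with missing whenever either Rt is missing.
#' @export
scenario_trait <- function(rt1, rt2, scenario = c("Scen1", "Scen2", "Scen3",
                                                  "Scen4"), cutoffs = NULL) {
  scenario <- match.arg(scenario)
  if (length(rt1) != length(rt2)) dg_stop("scenario", "length mismatch")
  if (is.null(cutoffs)) cutoffs <- c(median(rt1, na.rm = TRUE),
                                     median(rt2, na.rm = TRUE))
  hi1 <- rt1 > cutoffs[[1]]
  hi2 <- rt2 > cutoffs[[2]]
  out <- switch(scenario,
    Scen1 = as.integer(hi1 & hi2),
    Scen2 = as.integer(hi1 | hi2),
    Scen3 = as.integer(hi1) + as.integer(hi2),
    Scen4 = {
      z <- (scale(rt1)[, 1] + scale(rt2)[, 1]) / 2
      transform_trait(z, "categorical")
    })
  out[is.na(rt1) | is.na(rt2)] <- NA_integer_
  out
}

.wood_traits <- c("RW", "EW", "LW", "LWP", "RD", "ED", "LD", "MAXD", "MIND")
.climate_trait_names <- c("CorFebP", "CorMayP", "CorJunP", "CorJanT",
                          "CorMarT", "CorMayT", "CorJunT", "CorAugT")

#' Assemble the full 51-column analysis trait table
#'
#' Columns: 4 scenario traits (Scen1-Scen4, combining Rt of the first two
#' events), 12 drought indicators (Rt/Rc/Rs/rRs per event, suffixed with the
#' two-digit event year), 8 climate-growth correlations (fixed to the
#' canonical set unless overridden) and 27 wood-property traits (9 annual
#' means plus their binomial `b` and categorical `t` transforms).
#'
#' @param series_list tree-level `ring_series`.
#' @param responses output of [drought_response_table()].
#' @param climate site `climate_record`.
#' @param climate_vars climate trait columns (default the canonical eight).
#' @param scenario_events two event years combined into the scenarios
#'   (default the first two events; a third event is excluded from scenarios
#'   because of carry-over from the preceding drought).
#' @return data.frame, rownames = tree ids, 51 columns.
#' @export
build_analysis_traits <- function(series_list, responses, climate,
                                  climate_vars = .climate_trait_names,
                                  scenario_events = NULL) {
  ids <- vapply(series_list, function(s) s$tree_id, character(1))
  events <- sort(unique(responses$event_year))
  suff <- sprintf("%02d", events %% 100)
  out <- data.frame(row.names = ids)
  # scenario traits first (order: Scen, drought, climate, wood)
  if (is.null(scenario_events)) scenario_events <- events[1:2]
  rt <- function(ev) responses$Rt[responses$event_year == ev][
    match(ids, responses$tree_id[responses$event_year == ev])]
  rt1 <- rt(scenario_events[[1]]); rt2 <- rt(scenario_events[[2]])
  for (sc in c("Scen1", "Scen2", "Scen3", "Scen4"))
    out[[sc]] <- scenario_trait(rt1, rt2, sc)
  for (i in seq_along(events)) {
    ev <- events[[i]]
    sub <- responses[responses$event_year == ev, , drop = FALSE]
    row <- match(ids, sub$tree_id)
    for (v in c("Rt", "Rc", "Rs", "rRs"))
      out[[paste0(v, suff[[i]])]] <- sub[[v]][row]
  }
  cg <- climate_growth_traits(series_list, climate, variables = climate_vars)
  for (v in climate_vars) out[[v]] <- cg$traits[match(ids, rownames(cg$traits)), v]
  for (w in .wood_traits) {
    vals <- vapply(series_list, function(s) mean(s$data[[w]], na.rm = TRUE),
                   numeric(1))
    vals[is.nan(vals)] <- NA_real_
    out[[w]] <- vals
    out[[paste0(w, "b")]] <- transform_trait(vals, "binomial")
    out[[paste0(w, "t")]] <- transform_trait(vals, "categorical")
  }
  out
}
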