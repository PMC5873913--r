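#' Inverse-distance-weighted site climate interpolation
#'
#' Interpolates a virtual site record from the `n_nearest` stations using
#' weights proportional to great-circle distance to the power `-power`.
#' A station closer than 1 m returns its own value. A (year, month) cell with
#' no station data is missing in the output.
#'
#' @param stations list of `climate_record`.
#' @param lat,lon site coordinates (decimal degrees).
#' @param n_nearest number of stations used (default 4).
#' @param power IDW exponent (default 2).
#' @return a `climate_record` for the site (station_id `"site"`).
#' @export
idw_interpolate <- function(stations, lat, lon, n_nearest = 4, power = 2) {
  if (!length(stations)) dg_stop("idw", "no stations supplied")
  d_km <- vapply(stations, function(s) haversine_km(lat, lon, s$lat, s$lon),
                 numeric(1))
  ord <- order(d_km)[seq_len(min(n_nearest, length(stations)))]
  sel <- stations[ord]
  d_km <- d_km[ord]
  if (d_km[[1]] < 1e-3) {   # < 1 m: the site *is* that station
    s <- sel[[1]]
    return(climate_record("site", lat, lon, s$elev, s$data$year, s$data$month,
                          s$data$prcp_mm, s$data$tmean_c))
  }
  w <- d_km^(-power)
  keys <- unique(do.call(rbind, lapply(sel, function(s)
    s$data[, c("year", "month")])))
  keys <- keys[order(keys$year, keys$month), , drop = FALSE]
  key_id <- paste(keys$year, keys$month)
  acc <- function(var) {
    num <- den <- rep(0, nrow(keys))
    for (i in seq_along(sel)) {
      d <- sel[[i]]$data
      idx <- match(paste(d$year, d$month), key_id)
      v <- d[[var]]
      ok <- !is.na(v)
      num[idx[ok]] <- num[idx[ok]] + w[[i]] * v[ok]
      den[idx[ok]] <- den[idx[ok]] + w[[i]]
    }
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  climate_record("site", lat, lon, NA_real_, keys$year, keys$month,
                 acc("prcp_mm"), acc("tmean_c"))
}

#' McKee drought classification of SPI values
#'
#' Classes partition the real line: `none` (SPI >= 0), `mild` (-1, 0),
#' `moderate` (-1.5, -1], `severe` (-2, -1.5], `extreme` (<= -2).
#'
#' @param spi numeric vector of SPI values.
#' @return character vector of class labels.
#' @export
classify_spi <- function(spi) {
  out <- rep(NA_character_, length(spi))
  out[spi >= 0] <- "none"
  out[spi < 0] <- "mild"
  out[spi <= -1] <- "moderate"
  out[spi <= -1.5] <- "severe"
  out[spi <= -2] <- "extreme"
  out
}

# Thom-initialized gamma MLE on strictly positive values
fit_gamma_mle <- function(x) {
  m <- mean(x)
  a <- log(m) - mean(log(x))
  shape0 <- if (a <= 0) 1 else (1 + sqrt(1 + 4 * a / 3)) / (4 * a)
  par0 <- c(log(shape0), log(shape0 / m))
  nll <- function(p) -sum(dgamma(x, shape = exp(p[1]), rate = exp(p[2]),
                                 log = TRUE))
  fit <- optim(par0, nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  list(shape = exp(fit$par[1]), rate = exp(fit$par[2]))
}

#' Standardized precipitation index (SPI)
#'
#' For each calendar month, the k-month right-aligned precipitation sums over
#' the reference period are fitted with the mixed distribution
#' H(x) = q + (1 - q) G(x), where q is the frequency of zero sums and G a
#' gamma CDF fitted by maximum likelihood (Thom-initialized) to the nonzero
#' sums. SPI is the standard-normal quantile of H evaluated at each sum.
#'
#' @param climate a `climate_record` (site or station).
#' @param k timescale in months (1 or 3 in typical use).
#' @param reference integer vector of two years `c(from, to)` used for
#'   fitting; defaults to the full record.
#' @return object of class `spi_series`: data.frame `year, month, sum_mm,
#'   spi, class` plus the per-month fits in `attr(, "fits")`.
#' @export
compute_spi <- function(climate, k = 1, reference = NULL) {
  if (k < 1) dg_stop("spi", "k must be >= 1")
  d <- climate$data
  if (is.null(reference)) reference <- range(d$year)
  idx <- (d$year - min(d$year)) * 12L + d$month   # contiguous month index
  full <- seq(min(idx), max(idx))
  p <- rep(NA_real_, length(full))
  p[match(idx, full)] <- d$prcp_mm
  # right-aligned k-month sums
  sums <- rep(NA_real_, length(full))
  for (i in seq_along(full)) {
    if (i >= k) sums[i] <- sum(p[(i - k + 1):i])  # NA if window incomplete
  }
  year <- min(d$year) + (full - 1L) %/% 12L
  month <- (full - 1L) %% 12L + 1L
  out <- data.frame(year = year, month = month, sum_mm = sums,
                    spi = NA_real_)
  fits <- vector("list", 12)
  for (m in 1:12) {
    ref <- which(month == m & year >= reference[1] & year <= reference[2] &
                   !is.na(sums))
    xs <- sums[ref]
    nz <- xs[xs > 0]
    if (length(nz) < 10)
      dg_stop("spi", "fewer than 10 nonzero reference values for month ", m)
    q0 <- mean(xs == 0)
    g <- fit_gamma_mle(nz)
    fits[[m]] <- list(q0 = q0, shape = g$shape, rate = g$rate, n_ref = length(xs))
    rows <- which(month == m & !is.na(sums))
    h <- q0 + (1 - q0) * pgamma(sums[rows], shape = g$shape, rate = g$rate)
    h <- pmin(pmax(h, 1e-9), 1 - 1e-9)
    out$spi[rows] <- qnorm(h)
  }
  out$class <- classify_spi(out$spi)
  structure(out, fits = fits, k = k, reference = reference,
            class = c("spi_series", "data.frame"))
}

#' Detect growing-season drought events from SPI series
#'
#' A year is an event when the minimum over growing-season months of either
#' SPI series is at or below `threshold`. Sub-threshold excursions outside
#' the growing season are reported with `in_growing_season = FALSE` and are
#' excluded from downstream defaults (they occur after earlywood formation
#' has slowed and have little effect on ring width).
#'
#' @param spi_1,spi_3 `spi_series` on the same calendar (either may be
#'   `NULL` to use a single timescale).
#' @param threshold SPI event threshold (default -2, "extreme").
#' @param growing_season integer months (default April-July).
#' @return data.frame `year, month, spi, timescale, class,
#'   in_growing_season`, one row per event year.
#' @export
detect_drought_events <- function(spi_1, spi_3 = NULL, threshold = -2,
                                  growing_season = 4:7) {
  if (!length(growing_season)) dg_stop("events", "empty growing-season set")
  ser <- Filter(Negate(is.null), list(spi_1, spi_3))
  all <- do.call(rbind, lapply(ser, function(s)
    data.frame(year = s$year, month = s$month, spi = s$spi,
               timescale = attr(s, "k"))))
  all <- all[!is.na(all$spi), , drop = FALSE]
  hit <- all[all$spi <= threshold, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(year = integer(), month = integer(), spi = numeric(),
                      timescale = integer(), class = character(),
                      in_growing_season = logical()))
  }
  hit$in_growing_season <- hit$month %in% growing_season
  out <- do.call(rbind, lapply(split(hit, hit$year), function(h) {
    gs <- h[h$in_growing_season, , drop = FALSE]
    pick <- if (nrow(gs)) gs[which.min(gs$spi), ] else h[which.min(h$spi), ]
    pick
  }))
  out$class <- classify_spi(out$spi)
  rownames(out) <- NULL
  out[order(out$year),
      c("year", "month", "spi", "timescale", "class", "in_growing_season")]
}
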