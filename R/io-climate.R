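#' Monthly climate record
#'
#' Holds a station's (or interpolated site's) monthly precipitation sums (mm)
#' and mean temperatures (degrees C), indexed by (year, month).
#'
#' @param station_id identifier string.
#' @param lat,lon decimal degrees; `elev` metres (may be `NA` for a virtual
#'   site).
#' @param year,month integer vectors (months in 1..12).
#' @param prcp_mm,tmean_c numeric vectors aligned with `year`/`month`.
#' @return an object of class `climate_record`.
#' @export
climate_record <- function(station_id, lat, lon, elev = NA_real_,
                           year, month, prcp_mm, tmean_c = NA_real_) {
  year <- as.integer(year); month <- as.integer(month)
  if (any(month < 1L | month > 12L))
    dg_stop("climate", "months must be in 1..12")
  if (anyDuplicated(paste(year, month)))
    dg_stop("climate", "duplicate (year, month) in station ", station_id)
  if (any(prcp_mm < 0, na.rm = TRUE))
    dg_stop("climate", "negative precipitation in station ", station_id)
  d <- data.frame(year = year, month = month,
                  prcp_mm = as.numeric(prcp_mm),
                  tmean_c = as.numeric(rep_len(tmean_c, length(year))))
  d <- d[order(d$year, d$month), , drop = FALSE]
  rownames(d) <- NULL
  structure(list(station_id = as.character(station_id),
                 lat = as.numeric(lat), lon = as.numeric(lon),
                 elev = as.numeric(elev), data = d),
            class = "climate_record")
}

#' @export
print.climate_record <- function(x, ...) {
  cat(sprintf("<climate_record %s (%.3f, %.3f) %d months>\n",
              x$station_id, x$lat, x$lon, nrow(x$data)))
  invisible(x)
}

#' Read station climate CSVs
#'
#' `climate_path` holds monthly values with header
#' `station_id,year,month,prcp_mm,tmean_c`; `stations_path` holds coordinates
#' with header `station_id,lat,lon,elev`.
#'
#' @param climate_path,stations_path file paths.
#' @return a named list of `climate_record`, one per station.
#' @export
read_climate_csv <- function(climate_path, stations_path) {
  cl <- data.table::fread(climate_path, na.strings = c("", "NA"),
                          data.table = FALSE)
  st <- data.table::fread(stations_path, na.strings = c("", "NA"),
                          data.table = FALSE)
  need <- c("station_id", "year", "month", "prcp_mm", "tmean_c")
  if (length(setdiff(need, names(cl))))
    dg_stop("climate-csv", "climate file must have columns ",
            paste(need, collapse = ","))
  need2 <- c("station_id", "lat", "lon", "elev")
  if (length(setdiff(need2, names(st))))
    dg_stop("climate-csv", "station file must have columns ",
            paste(need2, collapse = ","))
  out <- lapply(split(cl, cl$station_id), function(d) {
    meta <- st[match(d$station_id[[1]], st$station_id), ]
    if (is.na(meta$station_id))
      dg_stop("climate-csv", "station ", d$station_id[[1]],
              " missing from station file")
    climate_record(meta$station_id, meta$lat, meta$lon, meta$elev,
                   d$year, d$month, d$prcp_mm, d$tmean_c)
  })
  out
}

#' Write station climate CSVs
#'
#' @param records list of `climate_record`.
#' @param climate_path,stations_path output paths.
#' @return invisibly, `climate_path`.
#' @export
write_climate_csv <- function(records, climate_path, stations_path) {
  cl <- do.call(rbind, lapply(records, function(r)
    cbind(data.frame(station_id = r$station_id), r$data)))
  st <- do.call(rbind, lapply(records, function(r)
    data.frame(station_id = r$station_id, lat = r$lat, lon = r$lon,
               elev = r$elev)))
  data.table::fwrite(cl, climate_path, na = "NA")
  data.table::fwrite(st, stations_path, na = "NA")
  invisible(climate_path)
}
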