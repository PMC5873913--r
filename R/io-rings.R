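#' Ring-series container
#'
#' A `ring_series` holds per-tree (or per-core) annual wood measurements:
#' ring width `RW`, earlywood width `EW`, latewood width `LW` (all mm),
#' latewood proportion `LWP` (percent), and the densities `RD`, `ED`, `LD`,
#' `MIND`, `MAXD` (kg/m3). Missing years/measurements are explicit `NA`s,
#' never silent zeros, because the drought-window rules must see the gap.
#'
#' @param tree_id,core_id,provenance identifier strings.
#' @param years integer calendar years, strictly increasing.
#' @param ... named numeric vectors among RW, EW, LW, LWP, RD, ED, LD, MIND,
#'   MAXD, each the same length as `years`.
#' @return an object of class `ring_series`.
#' @export
ring_series <- function(tree_id, core_id = tree_id, provenance = NA_character_,
                        years, ...) {
  meas <- list(...)
  allowed <- c("RW", "EW", "LW", "LWP", "RD", "ED", "LD", "MIND", "MAXD")
  bad <- setdiff(names(meas), allowed)
  if (length(bad)) dg_stop("rings", "unknown measurements: ",
                           paste(bad, collapse = ", "))
  years <- as.integer(years)
  if (anyDuplicated(years) || is.unsorted(years, strictly = TRUE)) {
    dg_stop("rings", "years must be strictly increasing with no duplicates (",
            tree_id, "/", core_id, ")")
  }
  dat <- data.frame(year = years)
  for (m in allowed) {
    v <- meas[[m]]
    if (is.null(v)) v <- rep(NA_real_, length(years))
    if (length(v) != length(years))
      dg_stop("rings", m, " length differs from years")
    dat[[m]] <- as.numeric(v)
  }
  x <- structure(list(tree_id = as.character(tree_id),
                      core_id = as.character(core_id),
                      provenance = as.character(provenance),
                      data = dat),
                 class = "ring_series")
  validate_ring_series(x)
}

#' Validate ring-series invariants
#'
#' Enforces: RW >= 0; EW + LW = RW within 1e-6 mm when all three present;
#' 0 <= LWP <= 100; MIND <= RD <= MAXD when all present. Violations beyond
#' tolerance are reported as warnings (rows are kept).
#'
#' @param x a `ring_series`.
#' @return `x`, invisibly usable in pipes.
#' @export
validate_ring_series <- function(x) {
  d <- x$data
  id <- paste0(x$tree_id, "/", x$core_id)
  if (any(d$RW < 0, na.rm = TRUE))
    dg_warn("rings", "negative RW in ", id)
  ok <- !is.na(d$RW) & !is.na(d$EW) & !is.na(d$LW)
  if (any(abs(d$EW[ok] + d$LW[ok] - d$RW[ok]) > 1e-6))
    dg_warn("rings", "EW + LW != RW beyond 1e-6 mm in ", id)
  if (any(d$LWP < 0 | d$LWP > 100, na.rm = TRUE))
    dg_warn("rings", "LWP outside [0, 100] in ", id)
  ok <- !is.na(d$RD) & !is.na(d$MIND) & !is.na(d$MAXD)
  if (any(d$MIND[ok] > d$RD[ok] | d$RD[ok] > d$MAXD[ok]))
    dg_warn("rings", "density ordering MIND <= RD <= MAXD violated in ", id)
  x
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series %s/%s prov=%s, %d years (%d-%d)>\n",
              x$tree_id, x$core_id, x$provenance, nrow(x$data),
              min(x$data$year), max(x$data$year)))
  invisible(x)
}

#' Read a Tucson-format (.rwl) ring-width file
#'
#' Decadal Tucson format: an 8-character series id, the decade start year,
#' then up to ten values per line. The series terminator encodes the unit:
#' `999` means values are in 0.01 mm, `-9999` means 0.001 mm. Values are
#' returned in mm; the terminator row is excluded. Only `RW` is carried
#' (the format has a single measurement per year).
#'
#' @param path file path.
#' @return a named list of `ring_series` keyed by the 8-character series id.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  series <- list()   # id -> list(years, vals, stop_code)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    id <- trimws(substr(ln, 1, 8))
    rest <- trimws(substr(ln, 9, nchar(ln)))
    fields <- strsplit(rest, "[[:space:]]+")[[1]]
    if (length(fields) < 2 || is.na(suppressWarnings(as.integer(fields[[1]]))))
      dg_stop("rwl", "malformed decade line ", i, " in ", path)
    year0 <- as.integer(fields[[1]])
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals)) dg_stop("rwl", "malformed decade line ", i, " in ", path)
    if (is.null(series[[id]]))
      series[[id]] <- list(years = integer(), vals = numeric(),
                           stop_code = NA_real_)
    s <- series[[id]]
    for (k in seq_along(vals)) {
      v <- vals[[k]]
      if (v == 999 || v == -9999) {
        if (!is.na(s$stop_code) && s$stop_code != v)
          dg_stop("rwl", "mixed terminators within series ", id)
        s$stop_code <- v
      } else {
        if (!is.na(s$stop_code))
          dg_stop("rwl", "values after terminator in series ", id)
        s$years <- c(s$years, year0 + k - 1L)
        s$vals <- c(s$vals, v)
      }
    }
    series[[id]] <- s
  }
  out <- list()
  for (id in names(series)) {
    s <- series[[id]]
    if (is.na(s$stop_code))
      dg_stop("rwl", "series ", id, " has no terminator")
    unit <- if (s$stop_code == 999) 0.01 else 0.001
    rw <- s$vals * unit
    rw[s$vals == -999] <- NA_real_   # conventional missing-ring sentinel
    out[[id]] <- ring_series(tree_id = id, core_id = id,
                             years = s$years, RW = rw)
  }
  dg_log("rwl", "read ", length(out), " series from ", path, level = "debug")
  out
}

#' Write ring-width series to a Tucson-format (.rwl) file
#'
#' Values are written in 0.01 mm with the `999` terminator. Missing rings
#' inside a series are written as `-999`.
#'
#' @param series a list of `ring_series` (only `RW` is written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    id <- sprintf("%-8s", substr(s$core_id, 1, 8))
    yr <- s$data$year
    v <- round(s$data$RW * 100)
    v[is.na(v)] <- -999
    v <- c(v, 999)  # terminator
    yr <- c(yr, max(yr) + 1L)
    i <- 1L
    while (i <= length(v)) {
      y <- yr[i]
      n_in_decade <- min(10L - (y %% 10L), length(v) - i + 1L)
      row <- v[i:(i + n_in_decade - 1L)]
      writeLines(paste0(id, sprintf("%6d", y),
                        paste(sprintf("%6d", row), collapse = "")), con)
      i <- i + n_in_decade
    }
  }
  invisible(path)
}

.long_cols <- c("tree_id", "core_id", "provenance", "year",
                "RW", "EW", "LW", "LWP", "RD", "ED", "LD", "MIND", "MAXD")

#' Read long-form ring measurement CSV
#'
#' Expected header: `tree_id,core_id,provenance,year,RW,EW,LW,LWP,RD,ED,LD,
#' MIND,MAXD`. Empty cells or `NA` are missing. One `ring_series` is built
#' per (tree_id, core_id); ring-series invariants are checked with warnings.
#'
#' @param path file path.
#' @return a list of `ring_series`.
#' @export
read_long_csv <- function(path) {
  d <- data.table::fread(path, sep = ",", na.strings = c("", "NA"),
                         data.table = FALSE)
  missing_cols <- setdiff(.long_cols, names(d))
  if (length(missing_cols))
    dg_stop("rings-csv", "missing mandatory columns: ",
            paste(missing_cols, collapse = ", "))
  key <- paste(d$tree_id, d$core_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(d)), key), function(idx) {
    rows <- d[idx, , drop = FALSE]
    rows <- rows[order(rows$year), , drop = FALSE]
    args <- c(list(tree_id = rows$tree_id[[1]], core_id = rows$core_id[[1]],
                   provenance = rows$provenance[[1]], years = rows$year),
              as.list(rows[, c("RW", "EW", "LW", "LWP", "RD", "ED", "LD",
                               "MIND", "MAXD")]))
    do.call(ring_series, args)
  })
  names(out) <- vapply(out, function(s) paste(s$tree_id, s$core_id, sep = "/"),
                       character(1))
  dg_log("rings-csv", "read ", length(out), " series from ", path,
         level = "debug")
  out
}

#' Write ring series to long-form CSV
#'
#' @param series a list of `ring_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(series, path) {
  rows <- lapply(series, function(s) {
    cbind(data.frame(tree_id = s$tree_id, core_id = s$core_id,
                     provenance = s$provenance), s$data)
  })
  d <- do.call(rbind, rows)
  d <- d[, .long_cols]
  data.table::fwrite(d, path, na = "NA")
  invisible(path)
}
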