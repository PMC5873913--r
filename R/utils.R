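#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov as.formula atanh complete.cases cor cor.test
#'   dgamma lm median na.omit optim optimize p.adjust pchisq pf pgamma pnorm
#'   pbinom ptukey qgamma qnorm qtukey quantile rbeta rbinom rgamma rlnorm
#'   rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head tail
NULL

.dg_env <- new.env(parent = emptyenv())
.dg_env$verbosity <- "info"

.level_num <- function(level) switch(level, quiet = 0L, info = 1L, debug = 2L,
                                     stop("unknown verbosity level: ", level))

#' Set logging verbosity
#'
#' Stage-tagged log messages go to standard error. Levels: `"quiet"` (nothing),
#' `"info"` (stage progress), `"debug"` (everything).
#'
#' @param level one of `"quiet"`, `"info"`, `"debug"`.
#' @return the previous level, invisibly.
#' @export
dg_verbosity <- function(level = c("info", "quiet", "debug")) {
  level <- match.arg(level)
  old <- .dg_env$verbosity
  .dg_env$verbosity <- level
  invisible(old)
}

dg_log <- function(stage, ..., level = "info") {
  if (.level_num(level) <= .level_num(.dg_env$verbosity)) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}

dg_warn <- function(stage, ...) warning(sprintf("[%s] %s", stage, paste0(...)),
                                        call. = FALSE)

dg_stop <- function(stage, ...) stop(sprintf("[%s] %s", stage, paste0(...)),
                                     call. = FALSE)

#' Read a pipeline/simulation configuration file
#'
#' Configuration is a JSON object (one key per setting). Nested objects become
#' nested lists.
#'
#' @param path path to a JSON config file.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) dg_stop("config", "config file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# closed month sequence from (year, month) spans, months 1..12
month_abb3 <- function(m) month.abb[m]

# great-circle distance in km (haversine)
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}
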