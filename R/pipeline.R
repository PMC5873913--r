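#' Marker-trait pair count of an association scan
#'
#' @param n_markers markers after QC.
#' @param n_traits trait columns scanned.
#' @return `n_markers * n_traits`.
#' @export
marker_trait_pairs <- function(n_markers, n_traits) {
  as.integer(n_markers) * as.integer(n_traits)
}

.pipeline_defaults <- list(
  site = c(lat = 48.548, lon = 16.171),
  spi_scales = c(1, 3),
  spi_reference = NULL,
  event_threshold = -2,
  growing_season = 4:7,
  response_window = 2,
  alpha_levels = c(0.1, 0.05, 0.01, 0.001),
  subset_rule = TRUE,
  flag_single = TRUE,
  maf_min = 0.05,
  max_missing = 0.10,
  kinship_scaling = "vanraden",
  seed = 1L)

# stage wrapper: logs, checkpoints the output as RDS-free CSV/JSON where the
# stage writes files; any error aborts with the stage name
.stage <- function(name, out_dir, expr) {
  dg_log("pipeline", "stage ", name)
  tryCatch(expr, error = function(e)
    dg_stop("pipeline", "stage '", name, "' failed: ", conditionMessage(e),
            " (outputs so far are under ", out_dir, " and are reusable)"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates climate interpolation, SPI and drought-event detection,
#' drought response indicators, the 51-column trait table, REML
#' repeatability with SubsetQD selection, SNP QC, neutral-marker selection,
#' centered-IBS kinship, and the MLM+Q+K scans for all provenances and (if
#' the subset rule is on) for SubsetQD with QC re-run on the subset. All
#' stage outputs are written as plain text under `config$out_dir`.
#'
#' @param config named list (or path to a JSON file) with `climate`,
#'   `stations`, `rings`, `genotypes`, `markers` (optional), `q`, `out_dir`
#'   plus any of the settings in the pipeline defaults (`site`,
#'   `spi_scales`, `spi_reference`, `event_threshold`, `growing_season`,
#'   `response_window`, `alpha_levels`, `subset_rule`, `flag_single`,
#'   `maf_min`, `max_missing`, `kinship_scaling`, `seed`).
#' @return the report list, invisibly: counts per stage, significant
#'   associations per star level, repeatability table, Q-Q data and output
#'   paths.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(.pipeline_defaults, config)
  for (f in c("climate", "stations", "rings", "genotypes", "q"))
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      dg_stop("pipeline", "missing input file for '", f, "'")
  alpha <- sort(as.numeric(cfg$alpha_levels), decreasing = TRUE)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  events <- .stage("climate", out_dir, {
    stations <- read_climate_csv(cfg$climate, cfg$stations)
    site <- idw_interpolate(stations, cfg$site[["lat"]], cfg$site[["lon"]])
    ref <- cfg$spi_reference
    spis <- lapply(cfg$spi_scales, function(k)
      compute_spi(site, k = k, reference = ref))
    spi_tab <- data.frame(year = spis[[1]]$year, month = spis[[1]]$month)
    for (i in seq_along(spis)) {
      spi_tab[[paste0("spi_k", cfg$spi_scales[[i]])]] <- spis[[i]]$spi
      spi_tab[[paste0("class_k", cfg$spi_scales[[i]])]] <- spis[[i]]$class
    }
    data.table::fwrite(spi_tab, file.path(out_dir, "spi.csv"), na = "NA")
    ev <- detect_drought_events(spis[[1]],
                                if (length(spis) > 1) spis[[2]] else NULL,
                                threshold = cfg$event_threshold,
                                growing_season = cfg$growing_season)
    data.table::fwrite(ev, file.path(out_dir, "events.csv"))
    list(events = ev, site = site)
  })
  event_years <- events$events$year[events$events$in_growing_season]
  if (!length(event_years))
    dg_stop("pipeline", "no growing-season drought events detected")

  trees <- .stage("rings", out_dir, {
    cores <- read_long_csv(cfg$rings)
    by_tree <- split(cores, vapply(cores, function(s) s$tree_id, character(1)))
    lapply(by_tree, function(cs)
      if (length(cs) >= 2) average_cores(cs[[1]], cs[[2]]) else cs[[1]])
  })

  responses <- .stage("responses", out_dir, {
    resp <- drought_response_table(trees, event_years,
                                   window = cfg$response_window)
    data.table::fwrite(resp, file.path(out_dir, "responses.csv"), na = "NA")
    resp
  })

  traits <- .stage("traits", out_dir, {
    tt <- build_analysis_traits(trees, responses, events$site)
    write_trait_table(tt, file.path(out_dir, "traits.csv"))
    tt
  })

  reptab <- .stage("repeatability", out_dir, {
    rt <- repeatability_table(responses)
    data.table::fwrite(rt, file.path(out_dir, "repeatability.csv"), na = "NA")
    rt
  })
  subset_qd <- if (isTRUE(cfg$subset_rule)) select_subset_qd(reptab)
    else character()

  gen <- .stage("genetics", out_dir, {
    fmt <- if (grepl("\\.vcf$", cfg$genotypes)) "vcf" else "csv"
    g <- read_genotypes(cfg$genotypes, format = fmt,
                        metadata_path = cfg$markers)
    q <- read_q_matrix(cfg$q)
    list(g = g, q = q)
  })

  scan_one <- function(g, q, trait_tab, label) {
    qc <- snp_qc(g, cfg$maf_min, cfg$max_missing)
    data.table::fwrite(qc$stats, file.path(out_dir,
                                           paste0("qc_", label, ".tsv")),
                       sep = "\t", na = "NA")
    neutral <- select_neutral(qc$genotypes)
    gk <- if (length(neutral) >= 2)
      subset_genotypes(qc$genotypes, markers = neutral) else qc$genotypes
    K <- centered_ibs_kinship(gk, scaling = cfg$kinship_scaling)
    write_kinship_csv(K, file.path(out_dir, paste0("kinship_", label, ".csv")))
    kin_mean <- c(with_diagonal = mean(K),
                  off_diagonal = mean(K[row(K) != col(K)]))
    thr <- bonferroni_threshold(alpha, ncol(qc$genotypes$geno))
    res <- mlm_qk_scan_multi(trait_tab, qc$genotypes, q, K,
                             alpha_levels = alpha)
    all_res <- do.call(rbind, res)
    rownames(all_res) <- NULL
    if (isTRUE(cfg$flag_single)) {
      sig <- which(!is.na(all_res$p) & all_res$p < max(thr))
      for (i in sig) {
        fl <- tryCatch(flag_single_individual(
          setNames(as.numeric(trait_tab[[all_res$trait[[i]]]]),
                   rownames(trait_tab)),
          qc$genotypes, all_res$marker[[i]], q, K, threshold = max(thr)),
          error = function(e) NULL)
        if (!is.null(fl)) all_res$flag_single[[i]] <- fl$flag
      }
    }
    data.table::fwrite(all_res, file.path(out_dir,
                                          paste0("gwas_", label, ".tsv")),
                       sep = "\t", na = "NA")
    qq <- qq_data(all_res$p)
    data.table::fwrite(qq, file.path(out_dir, paste0("qq_", label, ".csv")))
    list(results = all_res, thresholds = thr,
         n_markers = ncol(qc$genotypes$geno), n_traits = length(res),
         n_pairs = marker_trait_pairs(ncol(qc$genotypes$geno), length(res)),
         mean_kinship = kin_mean, qq = qq)
  }

  ids_gen <- rownames(gen$g$geno)
  scans <- .stage("scan-all", out_dir,
                  list(all = scan_one(gen$g, gen$q, traits, "all")))
  if (length(subset_qd)) {
    scans$subset <- .stage("scan-subset", out_dir, {
      prov_of <- vapply(trees, function(s) s$provenance, character(1))
      keep <- intersect(ids_gen, names(prov_of)[prov_of %in% subset_qd])
      g_sub <- subset_genotypes(gen$g, individuals = keep)
      scan_one(g_sub, gen$q[keep, , drop = FALSE],
               traits[rownames(traits) %in% keep, , drop = FALSE], "subset")
    })
  }

  report <- .stage("report", out_dir, {
    star_counts <- function(sc) table(factor(
      sc$results$stars[nzchar(sc$results$stars) & !is.na(sc$results$stars)],
      levels = c("***", "**", "*", "+")))
    rep <- list(
      n_trees = length(trees),
      event_years = event_years,
      n_traits = ncol(traits),
      subset_qd = subset_qd,
      panels = lapply(scans, function(sc)
        list(n_markers = sc$n_markers, n_traits = sc$n_traits,
             n_pairs = sc$n_pairs, thresholds = as.list(sc$thresholds),
             mean_kinship = as.list(sc$mean_kinship),
             significant = as.list(star_counts(sc)))))
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    lines <- c(sprintf("trees: %d", rep$n_trees),
               sprintf("events: %s", paste(event_years, collapse = ", ")),
               sprintf("traits: %d", rep$n_traits),
               sprintf("SubsetQD: %s", paste(subset_qd, collapse = ", ")))
    for (nm in names(rep$panels)) {
      p <- rep$panels[[nm]]
      lines <- c(lines, sprintf(
        "panel %s: %d markers x %d traits = %d pairs; significant: %s",
        nm, p$n_markers, p$n_traits, p$n_pairs,
        paste(sprintf("%s=%d", names(p$significant),
                      unlist(p$significant)), collapse = " ")))
    }
    writeLines(lines, file.path(out_dir, "summary.txt"))
    rep
  })
  report$repeatability <- reptab
  report$scans <- scans
  invisible(report)
}
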