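#' Pipeline configuration
#'
#' Collects the input file paths and stage parameters for [run_pipeline()].
#' Input files are checked at run time, not here, so a config can be built
#' before `simulate` has produced the files.
#'
#' @param data_dir directory holding `movements.csv`, `reads.csv`,
#'   `premises.csv`, `parishes.csv` and optionally `census.csv`,
#'   `samples.csv` (individual paths can be overridden).
#' @param out_dir output directory.
#' @param movements,reads,premises,parishes,census,samples explicit paths.
#' @param years study years (`NULL` = all years present).
#' @param cell_area_km2 hexagon area for spatial stages (default 115).
#' @param dedup_window_days market-leg matching window (default 1).
#' @param chi2_threshold representativeness cut-off (default 2).
#' @param seed master seed (used by `simulate`).
#' @param sim optional [sim_config()] for the `simulate` stage.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            movements = file.path(data_dir, "movements.csv"),
                            reads = file.path(data_dir, "reads.csv"),
                            premises = file.path(data_dir, "premises.csv"),
                            parishes = file.path(data_dir, "parishes.csv"),
                            census = file.path(data_dir, "census.csv"),
                            samples = file.path(data_dir, "samples.csv"),
                            years = NULL, cell_area_km2 = 115,
                            dedup_window_days = 1, chi2_threshold = 2,
                            seed = 1L, sim = NULL) {
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 movements = movements, reads = reads, premises = premises,
                 parishes = parishes, census = census, samples = samples,
                 years = years, cell_area_km2 = cell_area_km2,
                 dedup_window_days = dedup_window_days,
                 chi2_threshold = chi2_threshold, seed = as.integer(seed),
                 sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [pipeline_config()] fields (a `sim:` block is
#'   passed to [sim_config()]).
#' @return a `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    for (m in c("batch_mean_by_class", "slaughter_batch_mean_by_class"))
      if (!is.null(raw$sim[[m]])) raw$sim[[m]] <- unlist(raw$sim[[m]])
    if (!is.null(raw$sim$extent)) raw$sim$extent <- unlist(raw$sim$extent)
    raw$sim <- do.call(sim_config, raw$sim)
  }
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("required input not found: ", what, " (", path %||% "<unset>",
         ")", call. = FALSE)
  path
}

load_inputs <- function(config) {
  mv <- read_movements(require_file(config$movements, "movements.csv"))
  rd <- read_reads(require_file(config$reads, "reads.csv"))
  pr <- read_premises(require_file(config$premises, "premises.csv"))
  pa <- read_parishes(require_file(config$parishes, "parishes.csv"))
  reg <- as_premises_registry(pr, pa)
  cen <- if (!is.null(config$census) && file.exists(config$census))
    utils::read.csv(config$census) else NULL
  list(movements = mv, reads = rd, reg = reg, census = cen)
}

write_out <- function(d, config, name) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(config$out_dir, name)
  utils::write.csv(d, p, row.names = FALSE, na = "")
  p
}

#' Run the movement-analysis pipeline
#'
#' Executes one stage or the whole pipeline: `simulate` (write a synthetic
#' dataset into `data_dir`), `summarize` (annual movement summary and
#' batch-vs-read discrepancies), `slaughter` (dedup, populations, rankings,
#' monthly series), `catchment` (hex grid and catchment layers for the
#' top-ranked slaughterhouse), `representativeness` (survey coverage, needs
#' `samples.csv`), `matrix` (regional origin-destination matrices), `glm`
#' (batch-size model), or `all`. Each stage logs one line with record
#' counts in and out, writes its artifacts under `out_dir`, and a run
#' manifest (`manifest.json`) records the config, seed, package version and
#' input checksums.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param stage stage name or `"all"`.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, stage = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- c("simulate", "summarize", "slaughter", "catchment",
              "representativeness", "matrix", "glm")
  stage <- match.arg(stage, c(stages, "all"))
  todo <- if (stage == "all") stages else stage
  artifacts <- list()

  if ("simulate" %in% todo) {
    sim_cfg <- config$sim %||% sim_config(seed = config$seed)
    regy <- generate_premises(sim_cfg)
    sim <- generate_movements(regy, sim_cfg)
    cen <- generate_census(regy, sim_cfg)
    files <- write_sim_data(sim, regy, config$data_dir, census = cen)
    smp <- generate_samples(sim, regy, sim_cfg)
    sp <- file.path(config$data_dir, "samples.csv")
    utils::write.csv(smp, sp, row.names = FALSE)
    files <- c(files, sp)
    stage_log("simulate", nrow(sim$batch), " batch records, ",
              nrow(sim$reads), " reads -> ", config$data_dir)
    artifacts$simulate <- files
    if (stage == "simulate") {
      write_manifest(config, artifacts)
      return(invisible(artifacts))
    }
  }

  inp <- load_inputs(config)
  mv <- inp$movements
  rej <- attr(mv, "rejects")
  if (!is.null(config$years)) {
    yr <- as.integer(format(mv$date, "%Y"))
    mv <- mv[yr %in% config$years, , drop = FALSE]
  }

  if ("summarize" %in% todo) {
    sm <- annual_summary(mv, inp$reg)
    yrs <- attr(sm, "years")
    long <- do.call(rbind, lapply(c("batches", "sheep"), function(w) {
      b <- sm[[w]]
      data.frame(measure = w,
                 year = rep(yrs, each = 3L),
                 class = rep(rownames(b$counts), length(yrs)),
                 count = as.vector(b$counts),
                 pct = as.vector(b$pct))
    }))
    artifacts$summary <- write_out(long, config, "annual_summary.csv")
    disc <- read_discrepancy(mv, inp$reads)
    artifacts$discrepancy <- write_out(disc, config,
                                       "read_discrepancy.csv")
    stage_log("summarize", nrow(mv), " records in (",
              nrow(rej), " quarantined at ingest), ",
              length(yrs), " years summarised")
  }

  dedup <- NULL
  get_dedup <- function() {
    if (is.null(dedup)) {
      sl <- identify_slaughter_moves(mv, inp$reg)
      dedup <<- deduplicate_market_legs(sl, inp$reads, inp$reg,
                                        config$dedup_window_days)
    }
    dedup
  }

  if ("slaughter" %in% todo) {
    dd <- get_dedup()
    audit <- rbind(data.frame(record_id = dd$kept$record_id,
                              status = "kept", matched_record_id = NA,
                              basis = NA),
                   data.frame(record_id = dd$removed$record_id,
                              status = "removed",
                              matched_record_id =
                                dd$removed$matched_record_id,
                              basis = dd$removed$basis))
    artifacts$dedup_audit <- write_out(audit, config, "dedup_audit.csv")
    tagged <- dd$kept
    tagged$population <- classify_population(tagged, inp$reg)
    artifacts$populations <- write_out(tagged, config,
                                       "slaughter_populations.csv")
    if (!is.null(inp$census)) {
      pops <- population_summary(dd$kept, inp$reg, inp$census)
      artifacts$population_summary <-
        write_out(pops, config, "population_summary.csv")
    }
    yrs <- sort(unique(as.integer(format(dd$kept$date, "%Y"))))
    rk <- do.call(rbind, lapply(yrs, function(y)
      cbind(year = y, rank_slaughterhouses(dd$kept, inp$reg, y))))
    artifacts$ranking <- write_out(rk, config, "slaughterhouse_ranking.csv")
    artifacts$monthly <- write_out(monthly_series(dd$kept), config,
                                   "monthly_slaughter_series.csv")
    stage_log("slaughter", nrow(dd$kept) + nrow(dd$removed),
              " slaughter records in, ", nrow(dd$removed),
              " market legs removed, ", nrow(dd$kept), " kept")
  }

  grid <- sh_top <- NULL
  get_grid <- function() {
    if (is.null(grid)) {
      pr <- inp$reg$premises
      sc <- pr[pr$country == "Scotland" & !is.na(pr$easting), ]
      ctr <- inp$reg$parishes
      ex <- c(xmin = min(c(sc$easting, ctr$centroid_easting)),
              ymin = min(c(sc$northing, ctr$centroid_northing)),
              xmax = max(c(sc$easting, ctr$centroid_easting)),
              ymax = max(c(sc$northing, ctr$centroid_northing)))
      grid <<- build_hex_grid(ex, config$cell_area_km2)
    }
    grid
  }
  get_top_sh <- function(dd) {
    y <- min(as.integer(format(dd$kept$date, "%Y")))
    rk <- rank_slaughterhouses(dd$kept, inp$reg, y, reference = "SISP")
    rk <- rk[reg_field(inp$reg, rk$slaughterhouse,
                       "country") == "Scotland", ]
    list(cph = rk$slaughterhouse[1L], year = y)
  }

  if ("catchment" %in% todo) {
    dd <- get_dedup()
    g <- get_grid()
    top <- get_top_sh(dd)
    ct <- compute_catchment(top$cph, dd$kept, inp$reg, g, top$year,
                            reference = "SISP")
    artifacts$catchment_cells <- write_out(ct$cells, config,
                                           "catchment_cells.csv")
    artifacts$catchment_geojson <-
      export_hexgrid_geojson(g, file.path(config$out_dir,
                                          "catchment.geojson"),
                             cell_values = ct$cells)
    qc <- quarterly_catchment(top$cph, dd$kept, inp$reg, g, top$year)
    ql <- do.call(rbind, lapply(names(qc), function(q)
      if (nrow(qc[[q]])) cbind(quarter = q, qc[[q]])))
    artifacts$catchment_quarterly <-
      write_out(ql, config, "catchment_quarterly.csv")
    stage_log("catchment", "slaughterhouse ", top$cph, " year ",
              top$year, ": ", nrow(ct$cells), " cells, ",
              ct$unmappable$n_holdings, " unmappable holdings")
  }

  if ("representativeness" %in% todo &&
      stage == "all" && !file.exists(config$samples %||% "")) {
    stage_log("representativeness", "skipped: no samples file at ",
              config$samples %||% "<unset>")
    todo <- setdiff(todo, "representativeness")
  }
  if ("representativeness" %in% todo) {
    sp <- require_file(config$samples, "samples.csv")
    samples <- utils::read.csv(sp, colClasses = "character")
    dd <- get_dedup()
    g <- get_grid()
    top <- get_top_sh(dd)
    ct <- compute_catchment(top$cph, dd$kept, inp$reg, g, top$year,
                            reference = "SISP")
    cov <- assess_coverage(ct, samples, inp$reg, g,
                           threshold = config$chi2_threshold)
    artifacts$representativeness <-
      write_out(cov$cells, config, "representativeness.csv")
    artifacts$coverage_summary <-
      write_out(cov$summary, config, "coverage_summary.csv")
    artifacts$representativeness_geojson <-
      export_hexgrid_geojson(g, file.path(config$out_dir,
                                          "representativeness.geojson"),
                             cell_values = cov$cells)
    stage_log("representativeness", nrow(samples), " samples, ",
              cov$n_sampled_in_grid, " sampled holdings in catchment, ",
              sum(cov$cells$category == "adequate"), "/",
              nrow(cov$cells), " cells adequate")
  }

  if ("matrix" %in% todo) {
    yrs <- sort(unique(as.integer(format(mv$date, "%Y"))))
    long <- do.call(rbind, lapply(yrs, function(y) {
      m <- build_matrix(mv, inp$reg, period = y)
      cbind(period = as.character(y), matrix_long(m))
    }))
    qs <- quarterly_matrices(mv, inp$reg, yrs[1L])
    longq <- do.call(rbind, lapply(names(qs), function(q)
      cbind(period = paste0(yrs[1L], q), matrix_long(qs[[q]]))))
    artifacts$matrix <- write_out(rbind(long, longq), config,
                                  "movement_matrix.csv")
    stage_log("matrix", length(yrs), " annual matrices + 4 quarterly (",
              yrs[1L], ")")
  }

  if ("glm" %in% todo) {
    cl <- classify_movement(mv, inp$reg)
    ok <- !is.na(cl)
    fit_all <- fit_batch_glm(mv$n_animals[ok], cl[ok])
    dd <- get_dedup()
    cls <- classify_movement(dd$kept, inp$reg)
    fit_sl <- fit_batch_glm(dd$kept$n_animals, cls)
    res <- rbind(cbind(subset = "all", fit_all$table),
                 cbind(subset = "slaughter", fit_sl$table))
    artifacts$glm <- write_out(res, config, "glm_results.csv")
    summ <- rbind(cbind(subset = "all",
                        summarize_batches(mv$n_animals[ok], cl[ok])),
                  cbind(subset = "slaughter",
                        summarize_batches(dd$kept$n_animals, cls)))
    artifacts$batch_summary <- write_out(summ, config,
                                         "batch_summary.csv")
    stage_log("glm", sum(ok), " batches (all), ", nrow(dd$kept),
              " (slaughter)")
  }

  write_manifest(config, artifacts)
  invisible(artifacts)
}

write_manifest <- function(config, artifacts) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(config$movements, config$reads, config$premises,
              config$parishes, config$census, config$samples)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  inputs <- inputs[file.exists(unlist(inputs))]
  manifest <- list(
    package = "ovimove",
    version = as.character(utils::packageVersion("ovimove")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    artifacts = lapply(artifacts, as.character))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
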