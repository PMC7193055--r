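#' Configuration for the synthetic movement-data generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_premises()] and [generate_movements()]. The defaults emulate the
#' statistical structure of national sheep traceability data as reported for
#' the Scottish system: about 35% of holdings without coordinates, a 4%
#' individual mis-read rate, 15% of batch-recorded sheep with no individual
#' read records, dual batch records for moves routed through a market, a
#' September peak / March secondary peak / June trough in monthly movement
#' intensity, 14 agricultural regions, and class-specific mean batch sizes
#' (within-country 15, out-of-country 15, into-country 56 for all moves;
#' 24 / 13 / 107 for moves to slaughter).
#'
#' @param n_holdings number of in-country (Scottish) farm holdings.
#' @param n_markets number of livestock markets (all in-country).
#' @param n_slaughterhouses number of slaughterhouses; about 35% are placed
#'   in-country, the rest in the rest of GB.
#' @param n_regions number of regions partitioning the extent (default 14).
#' @param years calendar years simulated.
#' @param extent named numeric `c(xmin, ymin, xmax, ymax)` planar extent in
#'   metres (British-National-Grid-like plane).
#' @param p_missing_coords proportion of farms with no coordinates (they keep
#'   a valid parish whose centroid is known).
#' @param p_misread probability that an individual EID read at a Critical
#'   Control Point is lost.
#' @param p_batch_only_sheep proportion of batch-recorded sheep with no
#'   individual read records at all.
#' @param p_via_market probability that a slaughter move is routed through a
#'   market, emitting two batch records (the dual-record pattern).
#' @param p_cross_border_out,p_cross_border_in probability that a move leaves
#'   the country / enters it; the remainder moves within country.
#' @param monthly_intensity 12 non-negative weights for allocating moves to
#'   calendar months.
#' @param batch_mean_by_class,slaughter_batch_mean_by_class named numeric
#'   `c(WITHIN=, OUT_OF=, INTO=)` mean batch sizes for non-slaughter and
#'   slaughter moves.
#' @param dispersion negative-binomial size parameter for batch sizes.
#' @param batch_dist `"nbinom"` (default; heavy-tailed, matching observed
#'   maxima near 1,400) or `"poisson"` (for GLM parameter-recovery studies).
#' @param n_moves_per_year number of physical moves generated per year.
#' @param p_slaughter proportion of moves destined for slaughter.
#' @param seed master integer seed; each generator component draws from an
#'   independently derived named substream.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_holdings = 500L,
                       n_markets = 8L,
                       n_slaughterhouses = 20L,
                       n_regions = 14L,
                       years = 2015:2018,
                       extent = c(xmin = 0, ymin = 0,
                                  xmax = 420000, ymax = 700000),
                       p_missing_coords = 0.35,
                       p_misread = 0.04,
                       p_batch_only_sheep = 0.15,
                       p_via_market = 0.5,
                       p_cross_border_out = 0.48,
                       p_cross_border_in = 0.022,
                       monthly_intensity = c(0.70, 0.75, 1.00, 0.70, 0.60,
                                             0.50, 0.70, 0.90, 1.60, 1.20,
                                             0.90, 0.70),
                       batch_mean_by_class = c(WITHIN = 15, OUT_OF = 15,
                                               INTO = 56),
                       slaughter_batch_mean_by_class = c(WITHIN = 24,
                                                         OUT_OF = 13,
                                                         INTO = 107),
                       dispersion = 0.6,
                       batch_dist = c("nbinom", "poisson"),
                       n_moves_per_year = 5000L,
                       p_slaughter = 0.4,
                       seed = 1L) {
  batch_dist <- match.arg(batch_dist)
  cfg <- list(n_holdings = as.integer(n_holdings),
              n_markets = as.integer(n_markets),
              n_slaughterhouses = as.integer(n_slaughterhouses),
              n_regions = as.integer(n_regions),
              years = as.integer(years),
              extent = extent,
              p_missing_coords = p_missing_coords,
              p_misread = p_misread,
              p_batch_only_sheep = p_batch_only_sheep,
              p_via_market = p_via_market,
              p_cross_border_out = p_cross_border_out,
              p_cross_border_in = p_cross_border_in,
              monthly_intensity = as.numeric(monthly_intensity),
              batch_mean_by_class = batch_mean_by_class,
              slaughter_batch_mean_by_class = slaughter_batch_mean_by_class,
              dispersion = dispersion,
              batch_dist = batch_dist,
              n_moves_per_year = as.integer(n_moves_per_year),
              p_slaughter = p_slaughter,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("p_missing_coords", "p_misread", "p_batch_only_sheep",
             "p_via_market", "p_cross_border_out", "p_cross_border_in",
             "p_slaughter")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(p, " must be a proportion in [0, 1]", call. = FALSE)
  }
  if (cfg$p_cross_border_out + cfg$p_cross_border_in > 1)
    stop("p_cross_border_out + p_cross_border_in must not exceed 1",
         call. = FALSE)
  for (n in c("n_holdings", "n_markets", "n_slaughterhouses", "n_regions",
              "n_moves_per_year")) {
    if (cfg[[n]] < 1L) stop(n, " must be >= 1", call. = FALSE)
  }
  ext <- cfg$extent
  if (length(ext) != 4L || !all(c("xmin", "ymin", "xmax", "ymax") %in%
                                names(ext)) ||
      ext["xmax"] <= ext["xmin"] || ext["ymax"] <= ext["ymin"])
    stop("degenerate extent: need xmin < xmax and ymin < ymax",
         call. = FALSE)
  mi <- cfg$monthly_intensity
  if (length(mi) != 12L || any(mi < 0) || all(mi == 0))
    stop("monthly_intensity must be 12 non-negative weights, not all zero",
         call. = FALSE)
  for (m in c("batch_mean_by_class", "slaughter_batch_mean_by_class")) {
    v <- cfg[[m]]
    if (!all(c("WITHIN", "OUT_OF", "INTO") %in% names(v)) || any(v <= 0))
      stop(m, " must name WITHIN/OUT_OF/INTO with positive means",
           call. = FALSE)
  }
  if (length(cfg$years) < 1L) stop("years must be non-empty", call. = FALSE)
  invisible(cfg)
}

#' Read a generator configuration from YAML or JSON
#'
#' Fields absent from the file keep the [sim_config()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (m in c("batch_mean_by_class", "slaughter_batch_mean_by_class"))
    if (!is.null(raw[[m]])) raw[[m]] <- unlist(raw[[m]])
  if (!is.null(raw$extent)) raw$extent <- unlist(raw$extent)
  do.call(sim_config, raw)
}

# the 14 Scottish agricultural region codes used by default
region_codes_default <- c("ARG", "AYR", "BOR", "CLY", "DGA", "ECE", "FIF",
                          "GRA", "HIG", "LOT", "ORK", "SHI", "TAY", "WIS")

region_blocks <- function(extent, n_regions) {
  codes <- if (n_regions == 14L) region_codes_default else
    sprintf("R%02d", seq_len(n_regions))
  nx <- ceiling(sqrt(n_regions))
  ny <- ceiling(n_regions / nx)
  w <- (extent["xmax"] - extent["xmin"]) / nx
  h <- (extent["ymax"] - extent["ymin"]) / ny
  i <- seq_len(n_regions) - 1L
  data.frame(region = codes,
             xmin = unname(extent["xmin"] + (i %% nx) * w),
             xmax = unname(extent["xmin"] + (i %% nx + 1) * w),
             ymin = unname(extent["ymin"] + (i %/% nx) * h),
             ymax = unname(extent["ymin"] + (i %/% nx + 1) * h),
             county = 51L + i)
}

#' Generate a synthetic premises registry
#'
#' Creates farms, markets and slaughterhouses with unique CPH identifiers,
#' each assigned a country (Scotland / rest-of-GB), a region (a rectangular
#' partition of the extent) and a parish. A fraction `p_missing_coords` of
#' in-country farms has no coordinates but a valid parish whose centroid is
#' known, emulating the missing-geography problem of real traceability data.
#' Rest-of-GB premises are placed south of the extent.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `"premises_registry"`: a list with elements
#'   `premises` (data.frame: `cph`, `ptype`, `country`, `region`,
#'   `parish_id`, `easting`, `northing`), `parishes` (data.frame:
#'   `parish_id`, `region`, `area_ha`, `centroid_easting`,
#'   `centroid_northing`), `regions` (the rectangular region blocks) and
#'   `extent`.
#' @export
generate_premises <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "premises"))
  ext <- config$extent
  blocks <- region_blocks(ext, config$n_regions)
  nr <- nrow(blocks)

  # parishes: 4 per region, centroids inside the region block
  npar <- 4L
  par_region <- rep(seq_len(nr), each = npar)
  parishes <- data.frame(
    parish_id = sprintf("%s-%02d", blocks$region[par_region],
                        rep(seq_len(npar), times = nr)),
    region = blocks$region[par_region],
    area_ha = round(stats::runif(nr * npar, 2000, 20000)),
    centroid_easting = stats::runif(nr * npar, blocks$xmin[par_region],
                                    blocks$xmax[par_region]),
    centroid_northing = stats::runif(nr * npar, blocks$ymin[par_region],
                                     blocks$ymax[par_region]))

  rand_in_block <- function(ridx) {
    cbind(stats::runif(length(ridx), blocks$xmin[ridx], blocks$xmax[ridx]),
          stats::runif(length(ridx), blocks$ymin[ridx], blocks$ymax[ridx]))
  }

  # in-country farms
  nh <- config$n_holdings
  f_region <- sample.int(nr, nh, replace = TRUE)
  f_parish <- paste0(blocks$region[f_region], "-",
                     sprintf("%02d", sample.int(npar, nh, replace = TRUE)))
  f_xy <- rand_in_block(f_region)
  n_missing <- round(config$p_missing_coords * nh)
  miss <- sample.int(nh, n_missing)
  f_xy[miss, ] <- NA_real_
  farms <- data.frame(
    cph = format_cph(blocks$county[f_region],
                     as.integer(substr(f_parish, nchar(f_parish) - 1L,
                                       nchar(f_parish))),
                     seq_len(nh)),
    ptype = "farm", country = "Scotland",
    region = blocks$region[f_region], parish_id = f_parish,
    easting = f_xy[, 1L], northing = f_xy[, 2L])

  # rest-of-GB farms, south of the extent
  nrgb <- max(2L, round(0.15 * nh))
  h <- ext["ymax"] - ext["ymin"]
  rgb_xy <- cbind(stats::runif(nrgb, ext["xmin"], ext["xmax"]),
                  stats::runif(nrgb, ext["ymin"] - 0.3 * h,
                               ext["ymin"] - 0.05 * h))
  rgb_farms <- data.frame(
    cph = format_cph(sample.int(49L, nrgb, replace = TRUE), 100L,
                     seq_len(nrgb)),
    ptype = "farm", country = "rest-of-GB", region = NA_character_,
    parish_id = NA_character_,
    easting = rgb_xy[, 1L], northing = rgb_xy[, 2L])

  # markets (in-country)
  nm <- config$n_markets
  m_region <- sample.int(nr, nm, replace = TRUE)
  m_xy <- rand_in_block(m_region)
  markets <- data.frame(
    cph = format_cph(blocks$county[m_region], 900L, seq_len(nm)),
    ptype = "market", country = "Scotland",
    region = blocks$region[m_region],
    parish_id = paste0(blocks$region[m_region], "-01"),
    easting = m_xy[, 1L], northing = m_xy[, 2L])

  # slaughterhouses: ~35% in-country (as observed for GB plants receiving
  # Scottish sheep), remainder rest-of-GB
  ns <- config$n_slaughterhouses
  ns_scot <- max(1L, round(0.35 * ns))
  s_region <- sample.int(nr, ns_scot, replace = TRUE)
  s_xy <- rand_in_block(s_region)
  sh_scot <- data.frame(
    cph = format_cph(blocks$county[s_region], 901L, seq_len(ns_scot)),
    ptype = "slaughterhouse", country = "Scotland",
    region = blocks$region[s_region],
    parish_id = paste0(blocks$region[s_region], "-01"),
    easting = s_xy[, 1L], northing = s_xy[, 2L])
  ns_rgb <- ns - ns_scot
  sh_rgb <- if (ns_rgb > 0L) data.frame(
    cph = format_cph(sample.int(49L, ns_rgb, replace = TRUE), 901L,
                     seq_len(ns_rgb)),
    ptype = "slaughterhouse", country = "rest-of-GB",
    region = NA_character_, parish_id = NA_character_,
    easting = stats::runif(ns_rgb, ext["xmin"], ext["xmax"]),
    northing = stats::runif(ns_rgb, ext["ymin"] - 0.3 * h,
                            ext["ymin"] - 0.05 * h)) else NULL

  premises <- rbind(farms, rgb_farms, markets, sh_scot, sh_rgb)
  rownames(premises) <- NULL
  stopifnot(!anyDuplicated(premises$cph))
  structure(list(premises = premises, parishes = parishes, regions = blocks,
                 extent = ext),
            class = "premises_registry")
}

#' @export
print.premises_registry <- function(x, ...) {
  tab <- table(x$premises$ptype, x$premises$country)
  cat("Premises registry:", nrow(x$premises), "premises,",
      nrow(x$parishes), "parishes,", nrow(x$regions), "regions\n")
  print(tab)
  invisible(x)
}

#' Generate a synthetic June-census sheep table
#'
#' Draws a per-parish sheep density (sheep/hectare, capped at 8, matching the
#' observed national range 0--8) and converts to per-parish sheep counts per
#' year with mild year-to-year variation.
#'
#' @param registry a [generate_premises()] registry.
#' @param config the [sim_config()] used.
#' @return data.frame: `parish_id`, `region`, `year`, `sheep`.
#' @export
generate_census <- function(registry, config) {
  set.seed(substream_seed(config$seed, "census"))
  p <- registry$parishes
  density <- pmin(stats::rgamma(nrow(p), shape = 1.6, scale = 1.4), 8)
  out <- do.call(rbind, lapply(config$years, function(y) {
    data.frame(parish_id = p$parish_id, region = p$region, year = y,
               sheep = round(p$area_ha * density *
                               stats::runif(nrow(p), 0.95, 1.05)))
  }))
  rownames(out) <- NULL
  out
}

# mean of a zero-truncated count distribution, as a function of the
# untruncated mean mu
trunc_mean <- function(mu, dist, size) {
  p0 <- if (dist == "poisson") exp(-mu) else (size / (size + mu))^size
  mu / (1 - p0)
}

# sample n zero-truncated counts whose truncated mean equals target exactly
rtrunc_count <- function(n, target, dist, size) {
  if (n == 0L) return(integer(0))
  mu <- stats::uniroot(function(m) trunc_mean(m, dist, size) - target,
                       lower = 1e-9, upper = target, tol = 1e-10)$root
  draw <- function(k) {
    if (dist == "poisson") stats::rpois(k, mu)
    else stats::rnbinom(k, size = size, mu = mu)
  }
  x <- draw(n)
  while (any(z <- x == 0L)) x[z] <- draw(sum(z))
  x
}

#' Generate synthetic batch movements, individual reads and ground truth
#'
#' Simulates physical sheep moves for each configured year: movement class
#' (within / out of / into country) from the cross-border probabilities,
#' months allocated by `monthly_intensity` (dates uniform within month),
#' batch sizes from a zero-truncated count distribution with class-specific
#' means, and slaughter moves routed through a market with probability
#' `p_via_market`. A via-market slaughter move emits the dual batch-record
#' pattern of real traceability data: record 1 (holding departure, market
#' read location, slaughterhouse destination) and record 2 (market departure,
#' slaughterhouse read location and destination), double-counting the sheep.
#' Individual EID read records are emitted at each Critical Control Point on
#' the route: a fraction `p_batch_only_sheep` of animals has no reads at all,
#' and each remaining read is lost independently with probability
#' `p_misread`.
#'
#' @param registry from [generate_premises()].
#' @param config the same [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{batch}{data.frame of batch movement records: `record_id`,
#'       `departure_cph`, `read_cph`, `destination_cph`, `date`,
#'       `n_animals`, `n_reads`.}
#'     \item{reads}{data.frame of individual reads: `tag_id`, `ccp_cph`,
#'       `date`, `batch_ref`.}
#'     \item{truth}{ground truth: `true_class` (record_id, class),
#'       `true_population` (kept slaughter record_id, population among
#'       SISP/SOSP/POP4), `duplicated_record_pairs` (record1 = first leg,
#'       record2 = market leg), `true_slaughter_count` (slaughterhouse,
#'       year, sheep), `per_holding_supply` (holding, slaughterhouse, year,
#'       quarter, sheep).}
#'   }
#' @export
generate_movements <- function(registry, config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "movements"))
  prem <- registry$premises
  idx <- function(ptype, country) {
    prem$cph[prem$ptype == ptype & prem$country == country]
  }
  scot_farms <- idx("farm", "Scotland")
  rgb_farms <- idx("farm", "rest-of-GB")
  scot_sh <- idx("slaughterhouse", "Scotland")
  rgb_sh <- idx("slaughterhouse", "rest-of-GB")
  markets <- prem$cph[prem$ptype == "market"]
  if (length(rgb_sh) == 0L) rgb_sh <- scot_sh  # degenerate tiny configs

  n_y <- config$n_moves_per_year
  years <- rep(config$years, each = n_y)
  n <- length(years)
  pw <- 1 - config$p_cross_border_out - config$p_cross_border_in
  cls <- sample(c("WITHIN", "OUT_OF", "INTO"), n, replace = TRUE,
                prob = c(pw, config$p_cross_border_out,
                         config$p_cross_border_in))
  slaughter <- stats::runif(n) < config$p_slaughter
  month <- sample.int(12L, n, replace = TRUE,
                      prob = config$monthly_intensity)
  mdays <- function(y, m) {
    as.integer(format(seq(as.Date(sprintf("%d-%02d-01", y, m)),
                          by = "month", length.out = 2L)[2L] - 1, "%d"))
  }
  dim_tab <- outer(config$years, 1:12, Vectorize(mdays))
  nd <- dim_tab[cbind(match(years, config$years), month)]
  day <- 1L + floor(stats::runif(n) * nd)
  date <- as.Date(sprintf("%d-%02d-%02d", years, month, day))

  size <- integer(n)
  for (sl in c(TRUE, FALSE)) {
    means <- if (sl) config$slaughter_batch_mean_by_class else
      config$batch_mean_by_class
    for (cl in c("WITHIN", "OUT_OF", "INTO")) {
      sel <- slaughter == sl & cls == cl
      size[sel] <- rtrunc_count(sum(sel), means[[cl]], config$batch_dist,
                                config$dispersion)
    }
  }

  dep <- character(n)
  dep[cls != "INTO"] <- sample(scot_farms, sum(cls != "INTO"),
                               replace = TRUE)
  dep[cls == "INTO"] <- sample(rgb_farms, sum(cls == "INTO"),
                               replace = TRUE)
  dest <- character(n)
  sel <- slaughter & cls != "OUT_OF"
  dest[sel] <- sample(scot_sh, sum(sel), replace = TRUE)
  sel <- slaughter & cls == "OUT_OF"
  dest[sel] <- sample(rgb_sh, sum(sel), replace = TRUE)
  sel <- !slaughter & cls != "OUT_OF"
  dest[sel] <- sample(scot_farms, sum(sel), replace = TRUE)
  sel <- !slaughter & cls == "OUT_OF"
  dest[sel] <- sample(rgb_farms, sum(sel), replace = TRUE)
  # a farm-to-farm move must change premises
  while (any(bad <- !slaughter & dest == dep)) {
    dest[bad] <- sample(scot_farms, sum(bad), replace = TRUE)
  }

  via <- slaughter & stats::runif(n) < config$p_via_market
  market <- rep(NA_character_, n)
  market[via] <- sample(markets, sum(via), replace = TRUE)

  move_id <- sprintf("M%06d", seq_len(n))
  leg2_id <- ifelse(via, sprintf("D%06d", seq_len(n)), NA_character_)
  leg2_date <- date + ifelse(stats::runif(n) < 0.5, 0L, 1L)

  read_cph <- rep(NA_character_, n)
  read_cph[slaughter & !via] <- dest[slaughter & !via]
  read_cph[via] <- market[via]

  batch1 <- data.frame(record_id = move_id, departure_cph = dep,
                       read_cph = read_cph, destination_cph = dest,
                       date = date, n_animals = size, n_reads = 0L)
  v <- which(via)
  batch2 <- if (length(v)) data.frame(
    record_id = leg2_id[v], departure_cph = market[v],
    read_cph = dest[v], destination_cph = dest[v],
    date = leg2_date[v], n_animals = size[v],
    n_reads = rep(0L, length(v))) else NULL

  # individual reads for slaughter routes
  sl_i <- which(slaughter)
  an_move <- rep(sl_i, size[sl_i])
  n_an <- length(an_move)
  tag <- sprintf("UK%09d", seq_len(n_an))
  batch_only <- stats::runif(n_an) < config$p_batch_only_sheep
  at_market <- via[an_move] & !batch_only &
    stats::runif(n_an) >= config$p_misread
  at_sh <- !batch_only & stats::runif(n_an) >= config$p_misread
  reads_m <- data.frame(tag_id = tag[at_market],
                        ccp_cph = market[an_move[at_market]],
                        date = date[an_move[at_market]],
                        batch_ref = move_id[an_move[at_market]])
  sh_ref <- ifelse(via[an_move], leg2_id[an_move], move_id[an_move])
  sh_date <- date[an_move]
  sh_date[via[an_move]] <- leg2_date[an_move[via[an_move]]]
  reads_s <- data.frame(tag_id = tag[at_sh],
                        ccp_cph = dest[an_move[at_sh]],
                        date = sh_date[at_sh],
                        batch_ref = sh_ref[at_sh])
  reads <- rbind(reads_m, reads_s)
  rownames(reads) <- NULL

  batch <- rbind(batch1, batch2)
  rownames(batch) <- NULL
  cnt <- table(reads$batch_ref)
  batch$n_reads <- as.integer(ifelse(is.na(m <- match(batch$record_id,
                                                      names(cnt))),
                                     0L, cnt[m]))

  # ground truth; a market leg's own class follows its endpoints (the
  # market is in-country, so the second leg of an INTO move is WITHIN)
  leg2_cls <- ifelse(cls[v] == "INTO", "WITHIN", cls[v])
  true_class <- data.frame(
    record_id = c(move_id, leg2_id[v]),
    class = c(cls, leg2_cls))
  pop <- ifelse(cls == "WITHIN", "SISP",
                ifelse(cls == "OUT_OF", "SOSP", "POP4"))
  true_population <- data.frame(record_id = move_id[sl_i],
                                population = pop[sl_i])
  pairs <- data.frame(record1 = move_id[v], record2 = leg2_id[v])
  tsc <- stats::aggregate(list(sheep = size[sl_i]),
                          by = list(slaughterhouse = dest[sl_i],
                                    year = years[sl_i]), FUN = sum)
  quarter <- (month - 1L) %/% 3L + 1L
  phs <- stats::aggregate(list(sheep = size[sl_i]),
                          by = list(holding = dep[sl_i],
                                    slaughterhouse = dest[sl_i],
                                    year = years[sl_i],
                                    quarter = quarter[sl_i]), FUN = sum)
  list(batch = batch, reads = reads,
       truth = list(true_class = true_class,
                    true_population = true_population,
                    duplicated_record_pairs = pairs,
                    true_slaughter_count = tsc,
                    per_holding_supply = phs))
}

#' Generate a synthetic slaughterhouse survey sample
#'
#' Emulates a convenience survey sampled at one slaughterhouse: holdings are
#' drawn (with replacement, so multiplicities arise) with probability
#' proportional to the sheep they supplied to the chosen slaughterhouse,
#' from the generator's ground-truth supply map. By default the
#' slaughterhouse with the largest in-country supply in the first simulated
#' year is surveyed and 388 samples are drawn (the size of the national AMR
#' pilot the structure emulates).
#'
#' @param sim a [generate_movements()] result.
#' @param registry the premises registry.
#' @param config the [sim_config()] used (supplies the seed substream).
#' @param slaughterhouse CPH to survey; default = top in-country plant.
#' @param n_samples number of samples drawn.
#' @param proportional if `FALSE`, a fraction of the catchment is never
#'   sampled (holdings in the lowest-supply half get zero weight),
#'   emulating the patchy coverage of a real convenience sample.
#' @return data.frame: `sample_id`, `holding_cph`, `date`.
#' @export
generate_samples <- function(sim, registry, config, slaughterhouse = NULL,
                             n_samples = 388L, proportional = TRUE) {
  set.seed(substream_seed(config$seed, "samples"))
  phs <- sim$truth$per_holding_supply
  y <- min(phs$year)
  phs <- phs[phs$year == y, , drop = FALSE]
  if (is.null(slaughterhouse)) {
    ctry <- reg_field(registry, phs$slaughterhouse, "country")
    tot <- tapply(phs$sheep[ctry == "Scotland"],
                  phs$slaughterhouse[ctry == "Scotland"], sum)
    slaughterhouse <- names(tot)[which.max(tot)]
  }
  phs <- phs[phs$slaughterhouse == slaughterhouse, , drop = FALSE]
  supply <- tapply(phs$sheep, phs$holding, sum)
  w <- as.numeric(supply)
  if (!proportional) w[w <= stats::median(w)] <- 0
  h <- sample(names(supply), n_samples, replace = TRUE, prob = w)
  data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
             holding_cph = h,
             date = as.Date(sprintf("%d-01-01", y)) +
               sample.int(365L, n_samples, replace = TRUE) - 1L)
}

#' Write a synthetic dataset to the pipeline's CSV schemas
#'
#' Writes `movements.csv`, `reads.csv`, `premises.csv`, `parishes.csv`,
#' `census.csv` and a `truth/` subdirectory of ground-truth CSVs.
#'
#' @param sim result of [generate_movements()].
#' @param registry the [generate_premises()] registry.
#' @param census optional [generate_census()] table.
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_sim_data <- function(sim, registry, dir, census = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) {
    p <- file.path(dir, f)
    utils::write.csv(d, p, row.names = FALSE, na = "")
    p
  }
  files <- c(w(sim$batch, "movements.csv"), w(sim$reads, "reads.csv"),
             w(registry$premises, "premises.csv"),
             w(registry$parishes, "parishes.csv"))
  if (!is.null(census)) files <- c(files, w(census, "census.csv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(sim$truth)) {
    p <- file.path(tdir, paste0(nm, ".csv"))
    utils::write.csv(sim$truth[[nm]], p, row.names = FALSE, na = "")
    files <- c(files, p)
  }
  invisible(files)
}
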