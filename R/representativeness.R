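#' Expected sampled holdings per cell under proportional allocation
#'
#' If `n_sampled_total` sampled holdings were allocated to catchment cells
#' proportionately to the spatial spread of supplying holdings, cell i would
#' receive E_i = n * h_i / sum(h).
#'
#' @param catchment_holdings_per_cell non-negative counts of supplying
#'   holdings per cell (named or not).
#' @param n_sampled_total total number of distinct sampled holdings (> 0).
#' @return numeric vector of expected counts, summing to `n_sampled_total`.
#' @export
expected_counts <- function(catchment_holdings_per_cell, n_sampled_total) {
  h <- catchment_holdings_per_cell
  if (any(h < 0)) stop("holding counts must be >= 0", call. = FALSE)
  if (sum(h) == 0) stop("no holdings in any cell", call. = FALSE)
  if (n_sampled_total <= 0) stop("n_sampled_total must be > 0",
                                 call. = FALSE)
  n_sampled_total * h / sum(h)
}

#' Categorize cells by sampling representativeness
#'
#' Per-cell chi-square statistic (O - E)^2 / E against a fixed threshold
#' (default 2, the cut-off used when the statistic's degrees of freedom are
#' large enough for a normal approximation): cells with no sampled holdings
#' are `not_sampled`; cells with chi2 at or below the threshold are
#' `adequate`; above the threshold, `oversampled` when O > E and
#' `undersampled` when O < E. Set `merge_undersampled = TRUE` for the
#' two-way adequate/oversampled reading, which folds undersampled cells
#' into `oversampled`. A cell with E = 0 but O > 0 has an undefined
#' statistic and is categorized `oversampled` by convention (flagged).
#'
#' @param observed,expected aligned per-cell observed and expected sampled
#'   holding counts.
#' @param threshold chi-square cut-off (> 0), default 2.
#' @param cell_id optional cell identifiers.
#' @param merge_undersampled fold `undersampled` into `oversampled`.
#' @return data.frame: `cell_id`, `observed`, `expected`, `chi2`,
#'   `category`, `flagged`.
#' @export
categorize_cells <- function(observed, expected, threshold = 2,
                             cell_id = seq_along(observed),
                             merge_undersampled = FALSE) {
  stopifnot(length(observed) == length(expected), threshold > 0)
  chi2 <- ifelse(expected > 0, (observed - expected)^2 / expected, NA_real_)
  flagged <- expected == 0 & observed > 0
  category <- ifelse(observed == 0, "not_sampled",
              ifelse(flagged, "oversampled",
              ifelse(chi2 <= threshold, "adequate",
              ifelse(observed > expected, "oversampled", "undersampled"))))
  if (merge_undersampled)
    category[category == "undersampled"] <- "oversampled"
  data.frame(cell_id = cell_id, observed = observed, expected = expected,
             chi2 = chi2, category = category, flagged = flagged)
}

#' Category shares across catchment cells
#'
#' @param cells result of [categorize_cells()].
#' @return data.frame of categories with counts and percentage shares
#'   (summing to 100).
#' @export
coverage_summary <- function(cells) {
  lev <- c("adequate", "not_sampled", "oversampled", "undersampled")
  n <- table(factor(cells$category, levels = lev))
  out <- data.frame(category = lev, n = as.integer(n),
                    share_pct = as.numeric(n) / nrow(cells) * 100)
  out[out$n > 0 | out$category %in% lev[1:3], ]
}

#' Ingest a sampled-specimens table
#'
#' Resolves sample records to distinct holdings, excluding (and counting)
#' samples without a CPH and holdings outside the study country, and
#' summarises per-holding sample multiplicity.
#'
#' @param samples data.frame with `sample_id`, `holding_cph` (and
#'   optionally `date`).
#' @param reg premises registry.
#' @param country study country (default `"Scotland"`).
#' @return list: `holdings` (data.frame `holding_cph`, `n_samples`),
#'   `exclusions` (data.frame `reason`, `n`), `multiplicity` (named summary
#'   min/Q1/median/mean/Q3/max).
#' @export
sample_ingest <- function(samples, reg, country = "Scotland") {
  cph <- samples$holding_cph
  no_cph <- is.na(cph) | trimws(cph) == ""
  ctry <- reg_field(reg, cph, "country")
  outside <- !no_cph & !is.na(ctry) & ctry != country
  keep <- !no_cph & !outside
  tab <- table(cph[keep])
  holdings <- data.frame(holding_cph = names(tab),
                         n_samples = as.integer(tab))
  mult <- as.numeric(tab)
  exclusions <- data.frame(
    reason = c("no CPH identifier", "outside study country"),
    n = c(sum(no_cph), sum(outside)))
  list(holdings = holdings, exclusions = exclusions,
       multiplicity = c(min = min(mult), q1 = unname(stats::quantile(mult,
                                                                     0.25)),
                        median = stats::median(mult), mean = mean(mult),
                        q3 = unname(stats::quantile(mult, 0.75)),
                        max = max(mult)))
}

#' Assess survey coverage of a slaughterhouse catchment
#'
#' End-to-end representativeness stage: the catchment cells (cells with at
#' least one supplying holding) define the denominator; sampled holdings are
#' located and binned on the same grid; expected counts follow proportional
#' allocation; cells are categorized by the chi-square rule and summarised.
#'
#' @param catchment a [compute_catchment()] object.
#' @param samples sampled-specimens table (see [sample_ingest()]).
#' @param reg premises registry.
#' @param grid the grid the catchment was computed on.
#' @param threshold chi-square cut-off, default 2.
#' @param merge_undersampled see [categorize_cells()].
#' @return list: `cells` (per-cell categorization), `summary` (category
#'   shares), `samples` ([sample_ingest()] result), `n_sampled_in_grid`.
#' @export
assess_coverage <- function(catchment, samples, reg, grid, threshold = 2,
                            merge_undersampled = FALSE) {
  si <- sample_ingest(samples, reg)
  loc <- resolve_location(si$holdings$holding_cph, reg)
  ok <- loc$tag != "unmappable"
  cell <- rep(NA_integer_, nrow(si$holdings))
  if (any(ok))
    cell[ok] <- assign_points(cbind(loc$easting[ok], loc$northing[ok]),
                              grid)
  catch_cells <- catchment$cells$cell_id
  obs <- as.integer(table(factor(cell[!is.na(cell) &
                                        cell %in% catch_cells],
                                 levels = catch_cells)))
  expd <- expected_counts(catchment$cells$n_holdings, sum(obs))
  cells <- categorize_cells(obs, expd, threshold = threshold,
                            cell_id = catch_cells,
                            merge_undersampled = merge_undersampled)
  list(cells = cells, summary = coverage_summary(cells), samples = si,
       n_sampled_in_grid = sum(obs))
}
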