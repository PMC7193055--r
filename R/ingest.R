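#' Read pipeline input CSV files
#'
#' Readers for the four standard input schemas:
#' `movements.csv` (`record_id,departure_cph,read_cph,destination_cph,date,`
#' `n_animals,n_reads`), `reads.csv` (`tag_id,ccp_cph,date,batch_ref`),
#' `premises.csv` (`cph,ptype,country,region,parish_id,easting,northing`)
#' and `parishes.csv`
#' (`parish_id,region,area_ha,centroid_easting,centroid_northing`).
#' Dates are parsed as ISO-8601; empty strings become `NA`. Movement records
#' with `n_animals < 1` or an unparseable date are rejected: counted,
#' attached as the `"rejects"` attribute, and never silently dropped.
#'
#' @param path CSV file path.
#' @return a data.frame (for `read_movements()`, with a `"rejects"`
#'   attribute holding the quarantined rows and a `reason` column).
#' @export
read_movements <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("record_id", "departure_cph", "read_cph", "destination_cph",
            "date", "n_animals", "n_reads")
  if (!all(need %in% names(d)))
    stop("movements file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  d$date <- as.Date(d$date, format = "%Y-%m-%d")
  d$n_animals <- suppressWarnings(as.integer(d$n_animals))
  d$n_reads <- suppressWarnings(as.integer(d$n_reads))
  d$read_cph[d$read_cph == ""] <- NA_character_
  reason <- rep(NA_character_, nrow(d))
  reason[is.na(d$date)] <- "unparseable date"
  reason[is.na(d$n_animals) | d$n_animals < 1L] <- "n_animals < 1"
  keep <- is.na(reason)
  out <- d[keep, , drop = FALSE]
  rej <- d[!keep, , drop = FALSE]
  rej$reason <- reason[!keep]
  rownames(out) <- NULL
  attr(out, "rejects") <- rej
  out
}

#' @rdname read_movements
#' @export
read_reads <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  d$date <- as.Date(d$date, format = "%Y-%m-%d")
  d
}

#' @rdname read_movements
#' @export
read_premises <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  d$easting <- suppressWarnings(as.numeric(d$easting))
  d$northing <- suppressWarnings(as.numeric(d$northing))
  d$region[d$region == ""] <- NA_character_
  d$parish_id[d$parish_id == ""] <- NA_character_
  d
}

#' @rdname read_movements
#' @export
read_parishes <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  for (cc in c("area_ha", "centroid_easting", "centroid_northing"))
    d[[cc]] <- suppressWarnings(as.numeric(d[[cc]]))
  d
}

#' Build a premises registry from data frames
#'
#' Wraps a premises table (and optional parish table) in the
#' `"premises_registry"` structure used throughout the pipeline; the
#' synthetic generator's [generate_premises()] produces the same structure
#' directly.
#'
#' @param premises data.frame with at least `cph`, `ptype`, `country`;
#'   optionally `region`, `parish_id`, `easting`, `northing`.
#' @param parishes optional parish data.frame with centroids.
#' @return a `"premises_registry"` object.
#' @export
as_premises_registry <- function(premises, parishes = NULL) {
  stopifnot(all(c("cph", "ptype", "country") %in% names(premises)))
  if (anyDuplicated(premises$cph))
    stop("duplicate CPH in premises table", call. = FALSE)
  structure(list(premises = premises, parishes = parishes,
                 regions = NULL, extent = NULL),
            class = "premises_registry")
}

#' Look up a premises attribute by CPH
#'
#' Vectorised registry lookup; returns `NA` where the CPH is unknown.
#'
#' @param reg a premises registry.
#' @param cph character vector of CPHs.
#' @param field column of the premises table (`"ptype"`, `"country"`,
#'   `"region"`, `"parish_id"`, `"easting"`, `"northing"`).
#' @return vector of attribute values aligned with `cph`.
#' @export
reg_field <- function(reg, cph, field) {
  reg$premises[[field]][match(cph, reg$premises$cph)]
}

#' Resolve premises to plottable planar locations
#'
#' Implements the geography fallback used for national movement data:
#' precise coordinates when available, else the parish centroid, else the
#' premises is flagged unmappable. Every returned point carries a provenance
#' tag.
#'
#' @param cph character vector of premises CPHs.
#' @param reg a premises registry.
#' @param parishes parish table with `parish_id`, `centroid_easting`,
#'   `centroid_northing`; defaults to the registry's own.
#' @return data.frame: `cph`, `easting`, `northing`,
#'   `tag` in `{"precise","centroid","unmappable"}`.
#' @export
resolve_location <- function(cph, reg, parishes = reg$parishes) {
  e <- reg_field(reg, cph, "easting")
  n <- reg_field(reg, cph, "northing")
  tag <- rep("precise", length(cph))
  miss <- is.na(e) | is.na(n)
  if (any(miss)) {
    pid <- reg_field(reg, cph[miss], "parish_id")
    pm <- match(pid, parishes$parish_id)
    e[miss] <- parishes$centroid_easting[pm]
    n[miss] <- parishes$centroid_northing[pm]
    tag[miss] <- ifelse(is.na(pm), "unmappable", "centroid")
  }
  tag[is.na(e) | is.na(n)] <- "unmappable"
  data.frame(cph = cph, easting = e, northing = n, tag = tag)
}

#' Classify movements as within, out of, or into the country
#'
#' A movement is `WITHIN` when both endpoints are in Scotland, `OUT_OF` when
#' it departs Scotland for the rest of GB, and `INTO` for the reverse. (The
#' fourth class of the analysis, "total", is the union of the three.)
#' Records with neither endpoint in Scotland are out of scope for a Scottish
#' extract and raise an error; records with an unresolvable endpoint get
#' `NA`.
#'
#' @param records movement data.frame with `departure_cph` and
#'   `destination_cph`.
#' @param reg premises registry.
#' @return character vector in `{"WITHIN","OUT_OF","INTO"}`.
#' @export
classify_movement <- function(records, reg) {
  dc <- reg_field(reg, records$departure_cph, "country")
  oc <- reg_field(reg, records$destination_cph, "country")
  if (any(bad <- !is.na(dc) & !is.na(oc) &
          dc != "Scotland" & oc != "Scotland"))
    stop("out-of-scope movement: neither endpoint in Scotland (record ",
         records$record_id[which(bad)[1L]], ")", call. = FALSE)
  out <- ifelse(dc == "Scotland" & oc == "Scotland", "WITHIN",
                ifelse(dc == "Scotland", "OUT_OF", "INTO"))
  out[is.na(dc) | is.na(oc)] <- NA_character_
  out
}

summary_block <- function(counts, totals = NULL) {
  # counts: 3 x n_years matrix (WITHIN, OUT_OF, INTO); explicit totals may
  # exceed the class sums when some moves are unclassifiable
  tot <- totals %||% colSums(counts)
  pct <- sweep(counts, 2L, tot, "/") * 100
  mean_counts <- rowMeans(counts)
  list(total = tot, counts = counts, pct = pct,
       mean_total = mean(tot), mean_counts = mean_counts,
       mean_pct = mean_counts / mean(tot) * 100)
}

#' Annual movement summary from printed or computed counts
#'
#' `movement_summary_from_counts()` performs the summary-table arithmetic
#' directly on per-year class counts: percentages of each year's total by
#' class and a final across-year mean column (mean percentages are computed
#' from the mean counts). `annual_summary()` derives those counts from
#' classified movement records, including distinct premises counts, and
#' calls the same arithmetic.
#'
#' @param batch_counts,sheep_counts 3 x n-years numeric matrices with rows
#'   `WITHIN`, `OUT_OF`, `INTO` and one column per year.
#' @param premises_total,premises_within optional per-year distinct-premises
#'   counts (total, and located in Scotland).
#' @param batch_totals,sheep_totals optional explicit per-year totals;
#'   default is the class sums. National summary tables can print totals
#'   slightly above the class sums (moves that could not be classified),
#'   and published percentages are taken of those totals.
#' @return an object of class `"movement_summary"`: per-year class counts,
#'   percentages (1 decimal in print; raw values retained), and across-year
#'   means, for batches, sheep and premises.
#' @export
movement_summary_from_counts <- function(batch_counts, sheep_counts,
                                         premises_total = NULL,
                                         premises_within = NULL,
                                         batch_totals = NULL,
                                         sheep_totals = NULL) {
  stopifnot(nrow(batch_counts) == 3L, nrow(sheep_counts) == 3L)
  res <- list(batches = summary_block(as.matrix(batch_counts),
                                      batch_totals),
              sheep = summary_block(as.matrix(sheep_counts),
                                    sheep_totals))
  if (!is.null(premises_total)) {
    res$premises <- list(total = premises_total, within = premises_within,
                         pct_within = premises_within / premises_total * 100,
                         mean_total = mean(premises_total),
                         mean_within = mean(premises_within),
                         mean_pct_within = mean(premises_within) /
                           mean(premises_total) * 100)
  }
  structure(res, class = "movement_summary")
}

#' @rdname movement_summary_from_counts
#' @param records movement records (see [read_movements()]).
#' @param reg premises registry.
#' @param years calendar years to summarise; empty years yield zeros.
#' @export
annual_summary <- function(records, reg, years = NULL) {
  cl <- classify_movement(records, reg)
  yr <- as.integer(format(records$date, "%Y"))
  if (is.null(years)) years <- sort(unique(yr))
  classes <- c("WITHIN", "OUT_OF", "INTO")
  tab <- function(w) {
    m <- sapply(years, function(y) {
      sel <- yr == y & !is.na(cl)
      vapply(classes, function(k) sum(w[sel & cl == k]), numeric(1))
    })
    m <- matrix(m, nrow = 3L, dimnames = list(classes, years))
    m
  }
  batch_counts <- tab(rep(1, nrow(records)))
  sheep_counts <- tab(records$n_animals)
  prem_tot <- prem_within <- numeric(length(years))
  for (i in seq_along(years)) {
    sel <- yr == years[i]
    ps <- unique(c(records$departure_cph[sel], records$destination_cph[sel]))
    prem_tot[i] <- length(ps)
    prem_within[i] <- sum(reg_field(reg, ps, "country") == "Scotland",
                          na.rm = TRUE)
  }
  out <- movement_summary_from_counts(batch_counts, sheep_counts,
                                      prem_tot, prem_within)
  attr(out, "years") <- years
  out
}

#' @export
print.movement_summary <- function(x, ...) {
  fmt <- function(b, label) {
    cat(label, "\n")
    m <- rbind(Total = b$total, b$counts)
    pm <- rbind(NA, b$pct)
    cols <- c(colnames(b$counts), "Mean")
    m <- cbind(m, c(b$mean_total, b$mean_counts))
    pm <- cbind(pm, c(NA, b$mean_pct))
    for (i in seq_len(nrow(m))) {
      cat(sprintf("  %-8s", rownames(m)[i]),
          paste(sprintf("%12s", ifelse(is.na(pm[i, ]),
                                       format(round(m[i, ]), big.mark = ","),
                                       sprintf("%s (%.1f%%)",
                                               format(round(m[i, ]),
                                                      big.mark = ","),
                                               pm[i, ]))),
                collapse = " "), "\n")
    }
  }
  cat("Annual movement summary\n")
  fmt(x$batches, "Batch movements")
  fmt(x$sheep, "Sheep numbers moved")
  invisible(x)
}

#' Batch-versus-read data discrepancy statistics
#'
#' Quantifies the data-quality gap between batch-level and individual-level
#' recording, per year: the percentage excess of batch-recorded sheep over
#' distinct read animals, the analogous excess of batches over batches with
#' at least one read, the share of batch sheep with no associated reads, and
#' an estimate of the individual mis-read probability. The mis-read estimate
#' uses routes with two Critical Control Points: if each read is lost
#' independently with probability p, the share f of tags read at exactly one
#' of the two CCPs among tags read at either satisfies f = 2p/(1+p), so
#' p = f/(2-f).
#'
#' @param batch deduplicated or raw batch movement records.
#' @param reads individual read records with `batch_ref`.
#' @param pairs optional data.frame (`record1`, `record2`) of dual-record
#'   market-leg pairs, enabling the mis-read estimate.
#' @return data.frame per year: `batch_sheep`, `read_animals`,
#'   `sheep_excess_pct`, `batch_excess_pct`, `batch_only_share`,
#'   `est_misread`. Excesses are `NA` when there are no reads.
#' @export
read_discrepancy <- function(batch, reads, pairs = NULL) {
  yr <- as.integer(format(batch$date, "%Y"))
  years <- sort(unique(yr))
  out <- data.frame(year = years, batch_sheep = NA_real_,
                    read_animals = NA_real_, sheep_excess_pct = NA_real_,
                    batch_excess_pct = NA_real_,
                    batch_only_share = NA_real_, est_misread = NA_real_)
  ryr <- as.integer(format(reads$date, "%Y"))
  for (i in seq_along(years)) {
    y <- years[i]
    bs <- sum(batch$n_animals[yr == y])
    ra <- length(unique(reads$tag_id[ryr == y]))
    out$batch_sheep[i] <- bs
    out$read_animals[i] <- ra
    if (ra > 0) out$sheep_excess_pct[i] <- (bs - ra) / ra * 100
    nb <- sum(yr == y)
    nbr <- sum(batch$n_reads[yr == y] > 0)
    if (nbr > 0) out$batch_excess_pct[i] <- (nb - nbr) / nbr * 100
    if (bs > 0) out$batch_only_share[i] <- (bs - ra) / bs
  }
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    tag_by_ref <- split(reads$tag_id, reads$batch_ref)
    one <- both <- 0
    for (k in seq_len(nrow(pairs))) {
      t1 <- tag_by_ref[[pairs$record1[k]]]
      t2 <- tag_by_ref[[pairs$record2[k]]]
      nb <- length(intersect(t1, t2))
      nu <- length(union(t1, t2))
      both <- both + nb
      one <- one + (nu - nb)
    }
    if (one + both > 0) {
      f <- one / (one + both)
      out$est_misread <- f / (2 - f)
    }
  }
  out
}
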