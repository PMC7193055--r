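#' Identify moves contributing to the slaughter population
#'
#' A batch movement contributes to the slaughter population exactly when its
#' destination premises is a slaughterhouse (anywhere in GB).
#'
#' @param records movement records.
#' @param reg premises registry.
#' @return the subset of `records` with slaughterhouse destinations.
#' @export
identify_slaughter_moves <- function(records, reg) {
  sel <- reg_field(reg, records$destination_cph, "ptype") == "slaughterhouse"
  sel[is.na(sel)] <- FALSE
  out <- records[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove dual-recorded market legs from slaughter moves
#'
#' Sheep sold through a market on the way to slaughter appear twice in batch
#' data: record 1 (holding departure, market read location, slaughterhouse
#' destination) and record 2 (market departure, slaughterhouse read location
#' and destination). Keeping both double-counts the sheep, so the market leg
#' (record 2) is removed when a matching first leg exists: same market, same
#' destination slaughterhouse, dates within `window_days`, and either
#' overlapping EID tags read at the two Critical Control Points (basis
#' `"eid"`) or, when reads are unavailable on either side, equal animal
#' counts (basis `"count"`, logged as lower confidence). Matching is greedy
#' in date order and one-to-one.
#'
#' @param slaughter_records the slaughter-destination subset (see
#'   [identify_slaughter_moves()]).
#' @param reads individual read records (`batch_ref` links to records).
#' @param reg premises registry.
#' @param window_days maximum days between the two legs (default 1:
#'   lairage transit is same-or-next-day).
#' @return an object of class `"dedup_result"`: list with `kept` (records),
#'   `removed` (data.frame `record_id`, `matched_record_id`, `basis`).
#' @export
deduplicate_market_legs <- function(slaughter_records, reads, reg,
                                    window_days = 1L) {
  if (window_days < 0) stop("window_days must be >= 0", call. = FALSE)
  r <- slaughter_records
  dep_type <- reg_field(reg, r$departure_cph, "ptype")
  read_type <- reg_field(reg, r$read_cph, "ptype")
  is_r2 <- dep_type == "market"
  is_r1 <- !is.na(read_type) & read_type == "market" & dep_type != "market"
  tag_by_ref <- split(reads$tag_id, reads$batch_ref)
  tags_of <- function(id) tag_by_ref[[id]] %||% character(0)

  rm_id <- rm_match <- rm_basis <- character(0)
  if (any(is_r2) && any(is_r1)) {
    r2 <- which(is_r2)
    r2 <- r2[order(r$date[r2], r$record_id[r2])]
    # candidate first legs grouped by (market, destination)
    key <- function(i, mk) paste(mk[i], r$destination_cph[i], sep = "|")
    r1_key <- key(which(is_r1), r$read_cph)
    r1_pool <- split(which(is_r1), r1_key)
    used <- new.env(parent = emptyenv())
    nrem <- 0L
    rm_id <- rm_match <- rm_basis <- character(length(r2))
    for (j in r2) {
      cand <- r1_pool[[key(j, r$departure_cph)]]
      cand <- cand[!vapply(r$record_id[cand], exists, logical(1),
                           envir = used, inherits = FALSE)]
      cand <- cand[abs(as.numeric(r$date[j] - r$date[cand])) <= window_days]
      if (length(cand) == 0L) next
      cand <- cand[order(r$date[cand], r$record_id[cand])]
      t2 <- tags_of(r$record_id[j])
      basis <- NA_character_
      pick <- NA_integer_
      for (i in cand) {
        t1 <- tags_of(r$record_id[i])
        if (length(t1) && length(t2)) {
          if (length(intersect(t1, t2))) { pick <- i; basis <- "eid"; break }
        } else if (r$n_animals[i] == r$n_animals[j]) {
          if (is.na(pick)) { pick <- i; basis <- "count" }
        }
      }
      if (!is.na(pick)) {
        assign(r$record_id[pick], TRUE, envir = used)
        nrem <- nrem + 1L
        rm_id[nrem] <- r$record_id[j]
        rm_match[nrem] <- r$record_id[pick]
        rm_basis[nrem] <- basis
      }
    }
    rm_id <- rm_id[seq_len(nrem)]
    rm_match <- rm_match[seq_len(nrem)]
    rm_basis <- rm_basis[seq_len(nrem)]
  }
  removed <- data.frame(record_id = rm_id, matched_record_id = rm_match,
                        basis = rm_basis)
  kept <- r[!(r$record_id %in% removed$record_id), , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(kept = kept, removed = removed), class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("Dedup result:", nrow(x$kept), "records kept,",
      nrow(x$removed), "market legs removed")
  if (nrow(x$removed))
    cat(" (", sum(x$removed$basis == "eid"), "by EID overlap,",
        sum(x$removed$basis == "count"), "by count equality)")
  cat("\n")
  invisible(x)
}

#' Classify deduplicated slaughter moves into slaughter populations
#'
#' Population labels follow the national definitions: `SISP` (Scottish
#' origin, slaughtered in Scotland) and `SOSP` (Scottish origin, slaughtered
#' in the rest of GB) partition the Scottish Sheep Slaughter Population
#' (`SSSP`); `POP4` is non-Scottish-origin sheep slaughtered in Scotland,
#' excluded from SSSP totals. Origin is the departure premises of the move
#' immediately prior to slaughter (no lifetime tracing).
#'
#' @param records deduplicated slaughter moves.
#' @param reg premises registry.
#' @return character vector in `{"SISP","SOSP","POP4"}`.
#' @export
classify_population <- function(records, reg) {
  dc <- reg_field(reg, records$departure_cph, "country")
  oc <- reg_field(reg, records$destination_cph, "country")
  if (any(bad <- !is.na(dc) & !is.na(oc) &
          dc != "Scotland" & oc != "Scotland"))
    stop("out-of-scope slaughter move: neither endpoint in Scotland ",
         "(record ", records$record_id[which(bad)[1L]], ")", call. = FALSE)
  ifelse(dc == "Scotland" & oc == "Scotland", "SISP",
         ifelse(dc == "Scotland", "SOSP", "POP4"))
}

#' Slaughter-population table arithmetic
#'
#' `slaughter_population_table()` computes, from per-year sheep counts, the
#' SSSP as a percentage of the census sheep population and the SISP/SOSP
#' shares of SSSP. `population_summary()` derives the counts from
#' deduplicated, population-classified records plus a census table and calls
#' the same arithmetic.
#'
#' @param years integer vector of years.
#' @param sisp,sosp per-year sheep counts in each subset.
#' @param census_total per-year census sheep population (`NA` allowed; the
#'   percentage is then reported absent).
#' @return data.frame per year: `sssp`, `sssp_pct_census`, `sisp`,
#'   `sisp_pct_sssp`, `sosp`, `sosp_pct_sssp`.
#' @export
slaughter_population_table <- function(years, sisp, sosp, census_total) {
  sssp <- sisp + sosp
  data.frame(year = years, sssp = sssp,
             sssp_pct_census = sssp / census_total * 100,
             sisp = sisp, sisp_pct_sssp = sisp / sssp * 100,
             sosp = sosp, sosp_pct_sssp = sosp / sssp * 100)
}

#' @rdname slaughter_population_table
#' @param deduped deduplicated slaughter records (the `kept` element of a
#'   [deduplicate_market_legs()] result).
#' @param reg premises registry.
#' @param census data.frame with `year` and `sheep` (parish- or
#'   region-level rows are summed per year).
#' @export
population_summary <- function(deduped, reg, census) {
  pop <- classify_population(deduped, reg)
  yr <- as.integer(format(deduped$date, "%Y"))
  years <- sort(unique(yr))
  agg <- function(p) vapply(years, function(y)
    sum(deduped$n_animals[yr == y & pop == p]), numeric(1))
  cens <- vapply(years, function(y) {
    s <- census$sheep[census$year == y]
    if (length(s) == 0L) NA_real_ else sum(s)
  }, numeric(1))
  slaughter_population_table(years, agg("SISP"), agg("SOSP"), cens)
}

#' Rank slaughterhouses by throughput
#'
#' Ranks slaughterhouses by annual deduplicated throughput, in sheep numbers
#' or batch movements, with each plant's share of the reference population
#' (SSSP by default, SISP on request). Ties are broken by slaughterhouse CPH
#' for reproducibility.
#'
#' @param deduped deduplicated slaughter records.
#' @param reg premises registry.
#' @param year year to rank; unknown years yield an empty ranking.
#' @param by `"sheep"` or `"batches"`.
#' @param reference `"SSSP"` (SISP + SOSP) or `"SISP"`.
#' @return data.frame: `rank`, `slaughterhouse`, `throughput`, `share_pct`.
#' @export
rank_slaughterhouses <- function(deduped, reg, year,
                                 by = c("sheep", "batches"),
                                 reference = c("SSSP", "SISP")) {
  by <- match.arg(by)
  reference <- match.arg(reference)
  pop <- classify_population(deduped, reg)
  yr <- as.integer(format(deduped$date, "%Y"))
  keep_pop <- if (reference == "SSSP") c("SISP", "SOSP") else "SISP"
  sel <- yr == year & pop %in% keep_pop
  if (!any(sel))
    return(data.frame(rank = integer(0), slaughterhouse = character(0),
                      throughput = numeric(0), share_pct = numeric(0)))
  w <- if (by == "sheep") deduped$n_animals[sel] else rep(1L, sum(sel))
  agg <- stats::aggregate(list(throughput = w),
                          by = list(slaughterhouse =
                                      deduped$destination_cph[sel]),
                          FUN = sum)
  agg <- agg[order(-agg$throughput, agg$slaughterhouse), ]
  agg$share_pct <- agg$throughput / sum(agg$throughput) * 100
  data.frame(rank = seq_len(nrow(agg)), agg, row.names = NULL)
}

#' Supplier overlap between Scottish and rest-of-GB slaughterhouses
#'
#' Classifies each supplying holding by whether it sent sheep to Scottish
#' slaughterhouses only, rest-of-GB slaughterhouses only, or both, per year
#' and pooled across years.
#'
#' @param deduped deduplicated slaughter records.
#' @param reg premises registry.
#' @return data.frame per period (`"all"` = pooled): counts and percentage
#'   shares of holdings in each category.
#' @export
supplier_overlap <- function(deduped, reg) {
  dest_scot <- reg_field(reg, deduped$destination_cph,
                         "country") == "Scotland"
  yr <- as.integer(format(deduped$date, "%Y"))
  one <- function(sel, label) {
    h <- deduped$departure_cph[sel]
    any_scot <- tapply(dest_scot[sel], h, any)
    any_rgb <- tapply(!dest_scot[sel], h, any)
    cat3 <- ifelse(any_scot & any_rgb, "both",
                   ifelse(any_scot, "scotland_only", "rest_of_gb_only"))
    n <- c(scotland_only = sum(cat3 == "scotland_only"),
           rest_of_gb_only = sum(cat3 == "rest_of_gb_only"),
           both = sum(cat3 == "both"))
    data.frame(period = label, category = names(n), n = as.integer(n),
               share_pct = as.numeric(n) / sum(n) * 100)
  }
  out <- do.call(rbind, lapply(sort(unique(yr)),
                               function(y) one(yr == y, as.character(y))))
  rbind(out, one(rep(TRUE, nrow(deduped)), "all"))
}

#' Monthly sheep-movement time series
#'
#' Counts sheep moved per calendar month and year, for all moves or the
#' slaughter subset (which should be deduplicated first).
#'
#' @param records movement records.
#' @return data.frame: `year`, `month`, `sheep`.
#' @export
monthly_series <- function(records) {
  yr <- as.integer(format(records$date, "%Y"))
  mo <- as.integer(format(records$date, "%m"))
  grid <- expand.grid(month = 1:12, year = sort(unique(yr)))
  grid$sheep <- mapply(function(y, m)
    sum(records$n_animals[yr == y & mo == m]), grid$year, grid$month)
  grid[, c("year", "month", "sheep")]
}
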