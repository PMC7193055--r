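#' Regional origin-destination matrix of non-slaughter moves
#'
#' Builds the within-country regional movement matrix: cell (i, j) holds the
#' number of sheep moved from departure region i to destination region j in
#' the period. Only `WITHIN`-class moves enter; moves to slaughter are
#' excluded by default. Records whose endpoints have no resolvable region
#' are quarantined and counted, never silently dropped. The region order is
#' fixed alphabetically so heat-map twins are comparable across runs.
#'
#' @param records classified movement records.
#' @param reg premises registry (supplies `region` per CPH).
#' @param period a year, or `c(year, quarter)` restricting to one calendar
#'   quarter; `NULL` uses all records.
#' @param exclude_slaughter drop slaughterhouse-destination moves
#'   (default `TRUE`).
#' @param regions region codes defining the matrix axes; defaults to all
#'   regions present in the registry.
#' @return object of class `"region_matrix"`: the counts matrix with
#'   attributes `period`, `total`, `n_quarantined`.
#' @export
build_matrix <- function(records, reg, period = NULL,
                         exclude_slaughter = TRUE, regions = NULL) {
  cl <- classify_movement(records, reg)
  sel <- !is.na(cl) & cl == "WITHIN"
  if (exclude_slaughter) {
    dt <- reg_field(reg, records$destination_cph, "ptype")
    sel <- sel & (is.na(dt) | dt != "slaughterhouse")
  }
  if (!is.null(period)) {
    yr <- as.integer(format(records$date, "%Y"))
    sel <- sel & yr == period[1]
    if (length(period) > 1L) {
      qq <- (as.integer(format(records$date, "%m")) - 1L) %/% 3L + 1L
      sel <- sel & qq == period[2]
    }
  }
  dep_r <- reg_field(reg, records$departure_cph, "region")
  dst_r <- reg_field(reg, records$destination_cph, "region")
  if (is.null(regions))
    regions <- sort(unique(stats::na.omit(reg$premises$region)))
  quarantined <- sel & (is.na(dep_r) | is.na(dst_r))
  sel <- sel & !quarantined
  m <- matrix(0, length(regions), length(regions),
              dimnames = list(departure = regions, destination = regions))
  if (any(sel)) {
    t3 <- tapply(records$n_animals[sel],
                 list(factor(dep_r[sel], levels = regions),
                      factor(dst_r[sel], levels = regions)), sum)
    t3[is.na(t3)] <- 0
    m[] <- t3
  }
  structure(m, class = c("region_matrix", "matrix"), period = period,
            total = sum(m), n_quarantined = sum(quarantined))
}

#' @export
print.region_matrix <- function(x, ...) {
  cat("Regional O-D matrix (", nrow(x), "x", ncol(x), "), total",
      format(attr(x, "total"), big.mark = ","), "sheep")
  if (!is.null(attr(x, "period")))
    cat(", period", paste(attr(x, "period"), collapse = " Q"))
  if (attr(x, "n_quarantined") > 0)
    cat(",", attr(x, "n_quarantined"), "records quarantined (no region)")
  cat("\n")
  print(unclass(x)[seq_len(nrow(x)), seq_len(ncol(x))])
  invisible(x)
}

#' Normalize an origin-destination matrix to percentages
#'
#' `mode = "departure"`: each cell as a percentage of its departure row
#' total (rows sum to 100; all-zero rows become `NA`). `mode =
#' "destination"`: column-wise analogue.
#'
#' @param m a [build_matrix()] result (or plain matrix).
#' @param mode `"departure"` or `"destination"`.
#' @return a percentage matrix with the same dimnames.
#' @export
normalize_matrix <- function(m, mode = c("departure", "destination")) {
  mode <- match.arg(mode)
  mm <- unclass(m)
  attr(mm, "period") <- attr(mm, "total") <- attr(mm, "n_quarantined") <-
    NULL
  if (mode == "departure") {
    tot <- rowSums(mm)
    out <- sweep(mm, 1L, ifelse(tot == 0, NA, tot), "/") * 100
  } else {
    tot <- colSums(mm)
    out <- sweep(mm, 2L, ifelse(tot == 0, NA, tot), "/") * 100
  }
  out
}

#' Quartile categories for matrix entries
#'
#' Assigns each nonzero entry to Q1–Q4 by the empirical quartiles (type-7
#' quantiles at 0.25/0.5/0.75, half-open bins) of the nonzero entries;
#' zeros form a distinct `"none"` category.
#'
#' @param m numeric matrix (or vector).
#' @return list: `bins` (character matrix/vector in
#'   `{"none","Q1","Q2","Q3","Q4"}`), `breaks` (the quartile boundaries).
#' @export
quartile_bins <- function(m) {
  v <- as.vector(m)
  nz <- v[v != 0 & !is.na(v)]
  if (length(nz) == 0L) {
    bins <- ifelse(is.na(v), NA_character_, "none")
  } else {
    br <- unname(stats::quantile(nz, c(0.25, 0.5, 0.75), type = 7))
    idx <- findInterval(v, vec = br, left.open = TRUE) + 1L
    bins <- paste0("Q", idx)
    bins[v == 0] <- "none"
    bins[is.na(v)] <- NA_character_
  }
  out <- bins
  if (is.matrix(m)) out <- matrix(bins, nrow(m), dimnames = dimnames(m))
  list(bins = out,
       breaks = if (length(nz)) stats::quantile(nz, c(0.25, 0.5, 0.75),
                                                type = 7) else NULL)
}

#' Quarterly origin-destination matrices
#'
#' One matrix per calendar quarter of the year; their entry-wise sum equals
#' the annual matrix exactly.
#'
#' @inheritParams build_matrix
#' @param year calendar year.
#' @return named list `Q1`..`Q4` of `"region_matrix"` objects.
#' @export
quarterly_matrices <- function(records, reg, year, exclude_slaughter = TRUE,
                               regions = NULL) {
  out <- lapply(1:4, function(q)
    build_matrix(records, reg, period = c(year, q),
                 exclude_slaughter = exclude_slaughter, regions = regions))
  names(out) <- paste0("Q", 1:4)
  out
}

#' Long-format export of a regional matrix
#'
#' @param m a [build_matrix()] result.
#' @return data.frame: `departure`, `destination`, `sheep`,
#'   `pct_departure`, `pct_destination`, `quartile_bin`.
#' @export
matrix_long <- function(m) {
  pd <- normalize_matrix(m, "departure")
  ps <- normalize_matrix(m, "destination")
  qb <- quartile_bins(unclass(m))$bins
  regions <- rownames(m)
  data.frame(departure = rep(regions, times = length(regions)),
             destination = rep(regions, each = length(regions)),
             sheep = as.vector(unclass(m)),
             pct_departure = as.vector(pd),
             pct_destination = as.vector(ps),
             quartile_bin = as.vector(qb))
}

#' Heat-map plot of a regional matrix
#'
#' @param x a `"region_matrix"` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.region_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "period") <- attr(m, "total") <- attr(m, "n_quarantined") <- NULL
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "destination", ylab = "departure",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE),
                  ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
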