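#' Parse County Parish Holding identifiers
#'
#' A CPH ("County Parish Holding") number identifies a livestock premises in
#' Great Britain as three numeric components, written `"CC/PPP/HHHH"`.
#' `parse_cph()` validates and decomposes one or more CPH strings;
#' `format_cph()` renders the canonical zero-padded string form, so that
#' `format_cph(parse_cph(x))` round-trips.
#'
#' @param x character vector of CPH strings. Surrounding whitespace is
#'   tolerated.
#' @return `parse_cph()`: a data.frame with integer columns `county`,
#'   `parish`, `holding` and one row per input. `format_cph()`: a character
#'   vector.
#' @examples
#' parse_cph("66/123/0001")
#' format_cph(66, 123, 1)
#' @export
parse_cph <- function(x) {
  x0 <- trimws(as.character(x))
  parts <- strsplit(x0, "/", fixed = TRUE)
  n <- lengths(parts)
  if (any(bad <- n != 3L)) {
    stop("invalid CPH '", x0[which(bad)[1L]], "': expected 3 components",
         call. = FALSE)
  }
  m <- matrix(trimws(unlist(parts)), ncol = 3L, byrow = TRUE)
  if (any(bad <- !grepl("^[0-9]+$", m))) {
    stop("invalid CPH '", x0[ceiling(which(bad)[1L] / 3)][1L],
         "': non-numeric component", call. = FALSE)
  }
  data.frame(county  = as.integer(m[, 1L]),
             parish  = as.integer(m[, 2L]),
             holding = as.integer(m[, 3L]))
}

#' @rdname parse_cph
#' @param county,parish,holding integer components; alternatively pass the
#'   data.frame returned by [parse_cph()] as `county`.
#' @export
format_cph <- function(county, parish = NULL, holding = NULL) {
  if (is.data.frame(county)) {
    parish <- county$parish
    holding <- county$holding
    county <- county$county
  }
  sprintf("%02d/%03d/%04d", as.integer(county), as.integer(parish),
          as.integer(holding))
}

# deterministic sub-seed for a named RNG substream, < 2^31 - 1
substream_seed <- function(master, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
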