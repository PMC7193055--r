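# Shared fixtures, built in code. The memoised simulations are generated
# once per test run.

tiny_registry <- function() {
  premises <- data.frame(
    cph = c("66/001/0001", "66/001/0002", "66/001/0003", "01/100/0001",
            "66/900/0001", "66/901/0001", "02/901/0001"),
    ptype = c("farm", "farm", "farm", "farm", "market", "slaughterhouse",
              "slaughterhouse"),
    country = c("Scotland", "Scotland", "Scotland", "rest-of-GB",
                "Scotland", "Scotland", "rest-of-GB"),
    region = c("GRA", "GRA", "HIG", NA, "GRA", "GRA", NA),
    parish_id = c("P1", "P1", NA, NA, "P1", "P1", NA),
    easting = c(10000, NA, NA, 5000, 20000, 30000, 40000),
    northing = c(10000, NA, NA, -90000, 20000, 30000, -90000))
  parishes <- data.frame(parish_id = "P1", region = "GRA", area_ha = 10000,
                         centroid_easting = 15000,
                         centroid_northing = 15000)
  as_premises_registry(premises, parishes)
}

tiny_move <- function(record_id, dep, dest, read = NA_character_,
                      date = as.Date("2017-06-15"), n_animals = 10L,
                      n_reads = 0L) {
  data.frame(record_id = record_id, departure_cph = dep, read_cph = read,
             destination_cph = dest, date = date,
             n_animals = as.integer(n_animals),
             n_reads = as.integer(n_reads))
}

# small simulation with the generator defaults (mis-reads, batch-only
# sheep, dual market legs all active)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_holdings = 300L, n_moves_per_year = 3000L,
                        years = 2017L, seed = 101L)
      reg <- generate_premises(cfg)
      cache <<- list(cfg = cfg, reg = reg,
                     sim = generate_movements(reg, cfg))
    }
    cache
  }
})

# larger clean simulation (no mis-reads) for dedup/conservation oracles
clean_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_holdings = 400L, n_moves_per_year = 10000L,
                        years = 2017L, p_via_market = 0.5, p_misread = 0,
                        seed = 202L)
      reg <- generate_premises(cfg)
      cache <<- list(cfg = cfg, reg = reg,
                     sim = generate_movements(reg, cfg))
    }
    cache
  }
})

# shoelace polygon area
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - y * c(x[-1], x[1]))) / 2
}
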