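test_that("slaughter moves are exactly the slaughterhouse-destination subset", {
  reg <- tiny_registry()
  r <- rbind(tiny_move("a", "66/001/0001", "66/901/0001"),
             tiny_move("b", "66/001/0001", "66/900/0001"),  # to market
             tiny_move("c", "66/001/0001", "66/001/0002"))  # to farm
  expect_equal(identify_slaughter_moves(r, reg)$record_id, "a")
  expect_equal(nrow(identify_slaughter_moves(r[0, ], reg)), 0L)
})

test_that("a market leg is removed so sheep are counted once", {
  reg <- tiny_registry()
  d <- as.Date("2017-06-15")
  r1 <- tiny_move("r1", "66/001/0001", "66/901/0001", read = "66/900/0001",
                  date = d, n_animals = 40L)
  r2 <- tiny_move("r2", "66/900/0001", "66/901/0001", read = "66/901/0001",
                  date = d, n_animals = 40L)
  direct <- tiny_move("r3", "66/001/0002", "66/901/0001",
                      read = "66/901/0001", date = d, n_animals = 12L)
  dd <- deduplicate_market_legs(rbind(r1, r2, direct),
                                data.frame(tag_id = character(0),
                                           ccp_cph = character(0),
                                           date = as.Date(character(0)),
                                           batch_ref = character(0)),
                                reg, window_days = 1L)
  expect_setequal(dd$kept$record_id, c("r1", "r3"))
  expect_equal(dd$removed$record_id, "r2")
  expect_equal(dd$removed$basis, "count")  # no reads available
  expect_equal(sum(dd$kept$n_animals), 52L)
  # EID overlap beats count equality when reads exist
  reads <- data.frame(tag_id = rep(sprintf("UK%02d", 1:5), 2),
                      ccp_cph = rep(c("66/900/0001", "66/901/0001"),
                                    each = 5),
                      date = d, batch_ref = rep(c("r1", "r2"), each = 5))
  dd2 <- deduplicate_market_legs(rbind(r1, r2, direct), reads, reg, 1L)
  expect_equal(dd2$removed$basis, "eid")
  # outside the window the leg is kept
  r2late <- r2; r2late$date <- d + 3
  dd3 <- deduplicate_market_legs(rbind(r1, r2late, direct),
                                 reads[0, ], reg, 1L)
  expect_equal(nrow(dd3$removed), 0L)
  expect_error(deduplicate_market_legs(r1, reads[0, ], reg, -1),
               "window_days")
})

test_that("dedup matches the generator's ground truth exactly without mis-reads", {
  x <- clean_sim()
  sl <- identify_slaughter_moves(x$sim$batch, x$reg)
  dd <- deduplicate_market_legs(sl, x$sim$reads, x$reg, 1L)
  truth_pairs <- x$sim$truth$duplicated_record_pairs
  expect_setequal(dd$removed$record_id, truth_pairs$record2)
  # recomputed slaughterhouse totals equal the true slaughter counts
  yr <- as.integer(format(dd$kept$date, "%Y"))
  tot <- stats::aggregate(list(sheep = dd$kept$n_animals),
                          by = list(slaughterhouse =
                                      dd$kept$destination_cph,
                                    year = yr), FUN = sum)
  truth <- x$sim$truth$true_slaughter_count
  m <- merge(tot, truth, by = c("slaughterhouse", "year"),
             suffixes = c("", ".true"), all = TRUE)
  expect_false(anyNA(m$sheep))
  expect_equal(m$sheep, m$sheep.true)
})

test_that("dedup is idempotent", {
  x <- default_sim()
  sl <- identify_slaughter_moves(x$sim$batch, x$reg)
  dd1 <- deduplicate_market_legs(sl, x$sim$reads, x$reg, 1L)
  dd2 <- deduplicate_market_legs(dd1$kept, x$sim$reads, x$reg, 1L)
  expect_equal(nrow(dd2$removed), 0L)
  expect_equal(dd2$kept$record_id, dd1$kept$record_id)
})

test_that("population classification follows origin and destination country", {
  reg <- tiny_registry()
  r <- rbind(tiny_move("a", "66/001/0001", "66/901/0001"),  # Scot -> Scot
             tiny_move("b", "66/001/0001", "02/901/0001"),  # Scot -> rGB
             tiny_move("c", "01/100/0001", "66/901/0001"))  # rGB -> Scot
  expect_equal(classify_population(r, reg), c("SISP", "SOSP", "POP4"))
})

test_that("population table arithmetic: shares of census and of SSSP", {
  t <- slaughter_population_table(2015L, sisp = 1107763,
                                  sosp = 1146499, census_total = 6701376)
  expect_equal(t$sssp, 2254262)
  expect_equal(round(t$sssp_pct_census, 1), 33.6)
  expect_equal(round(t$sisp_pct_sssp, 1), 49.1)
  expect_equal(t$sisp_pct_sssp + t$sosp_pct_sssp, 100)
  # missing census year -> percentage absent
  t2 <- slaughter_population_table(2015L, 10, 10, NA)
  expect_true(is.na(t2$sssp_pct_census))
})

test_that("population summary on synthetic data partitions SSSP", {
  x <- default_sim()
  sl <- identify_slaughter_moves(x$sim$batch, x$reg)
  dd <- deduplicate_market_legs(sl, x$sim$reads, x$reg, 1L)
  cen <- generate_census(x$reg, x$cfg)
  ps <- population_summary(dd$kept, x$reg, cen)
  expect_equal(ps$sisp + ps$sosp, ps$sssp)
  expect_equal(ps$sisp_pct_sssp + ps$sosp_pct_sssp,
               rep(100, nrow(ps)))
})

test_that("rankings order by throughput with reproducible tie-breaks", {
  reg <- tiny_registry()
  d <- as.Date("2017-06-01")
  r <- rbind(tiny_move("a", "66/001/0001", "66/901/0001", date = d,
                       n_animals = 50L),
             tiny_move("b", "66/001/0002", "02/901/0001", date = d,
                       n_animals = 30L),
             tiny_move("c", "66/001/0001", "02/901/0001", date = d,
                       n_animals = 30L))
  rk <- rank_slaughterhouses(r, reg, 2017L)
  expect_equal(rk$slaughterhouse, c("02/901/0001", "66/901/0001"))
  expect_equal(rk$share_pct, c(60 / 110, 50 / 110) * 100)
  # ranking by batches can invert a sheep-based ranking
  rkb <- rank_slaughterhouses(r, reg, 2017L, by = "batches")
  expect_equal(rkb$slaughterhouse[1], "02/901/0001")
  expect_equal(rkb$throughput, c(2, 1))
  # unknown year -> empty ranking
  expect_equal(nrow(rank_slaughterhouses(r, reg, 1999L)), 0L)
})

test_that("sheep- and batch-based rankings diverge when batch sizes differ by destination", {
  # many small batches to plant A, few large batches to plant B
  reg <- tiny_registry()
  d <- as.Date("2017-06-01")
  small <- do.call(rbind, lapply(1:10, function(i)
    tiny_move(paste0("s", i), "66/001/0001", "66/901/0001", date = d,
              n_animals = 5L)))
  big <- do.call(rbind, lapply(1:2, function(i)
    tiny_move(paste0("b", i), "66/001/0001", "02/901/0001", date = d,
              n_animals = 100L)))
  r <- rbind(small, big)
  by_sheep <- rank_slaughterhouses(r, reg, 2017L, by = "sheep")
  by_batch <- rank_slaughterhouses(r, reg, 2017L, by = "batches")
  expect_equal(by_sheep$slaughterhouse[1], "02/901/0001")
  expect_equal(by_batch$slaughterhouse[1], "66/901/0001")
})

test_that("supplier overlap categories partition supplying holdings", {
  reg <- tiny_registry()
  d <- as.Date("2017-06-01")
  r <- rbind(tiny_move("a", "66/001/0001", "66/901/0001", date = d),
             tiny_move("b", "66/001/0001", "02/901/0001", date = d),
             tiny_move("c", "66/001/0002", "66/901/0001", date = d),
             tiny_move("d", "66/001/0003", "02/901/0001", date = d))
  ov <- supplier_overlap(r, reg)
  all_row <- ov[ov$period == "all", ]
  expect_equal(sum(all_row$n), 3L)
  expect_equal(all_row$n[all_row$category == "both"], 1L)
  expect_equal(sum(all_row$share_pct), 100)
})

test_that("supplier overlap agrees with the ground-truth supply map", {
  x <- clean_sim()
  sl <- identify_slaughter_moves(x$sim$batch, x$reg)
  dd <- deduplicate_market_legs(sl, x$sim$reads, x$reg, 1L)
  ov <- supplier_overlap(dd$kept, x$reg)
  all_row <- ov[ov$period == "all", ]
  phs <- x$sim$truth$per_holding_supply
  sh_scot <- reg_country <- x$reg$premises$country[
    match(phs$slaughterhouse, x$reg$premises$cph)] == "Scotland"
  any_s <- tapply(sh_scot, phs$holding, any)
  any_r <- tapply(!sh_scot, phs$holding, any)
  expect_equal(all_row$n[all_row$category == "both"],
               sum(any_s & any_r))
  expect_equal(all_row$n[all_row$category == "scotland_only"],
               sum(any_s & !any_r))
})

test_that("monthly series conserve annual totals and peak in September", {
  x <- clean_sim()
  keep <- !(x$sim$batch$record_id %in%
              x$sim$truth$duplicated_record_pairs$record2)
  ms <- monthly_series(x$sim$batch[keep, ])
  y1 <- ms[ms$year == 2017, ]
  expect_equal(sum(y1$sheep),
               sum(x$sim$batch$n_animals[keep][
                 format(x$sim$batch$date[keep], "%Y") == "2017"]))
  expect_equal(y1$month[which.max(y1$sheep)], 9L)
})
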