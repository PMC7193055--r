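test_that("config validation rejects bad proportions, extents and means", {
  expect_error(sim_config(p_misread = 1.2), "proportion")
  expect_error(sim_config(extent = c(xmin = 0, ymin = 0, xmax = 0,
                                     ymax = 10)), "degenerate extent")
  expect_error(sim_config(monthly_intensity = rep(0, 12)), "not all zero")
  expect_error(sim_config(monthly_intensity = rep(1, 11)), "12")
  expect_error(sim_config(batch_mean_by_class = c(WITHIN = -1, OUT_OF = 2,
                                                  INTO = 3)), "positive")
})

test_that("premises generation applies the missing-coordinate fraction exactly", {
  cfg <- sim_config(n_holdings = 100L, p_missing_coords = 0.35, seed = 1L)
  reg <- generate_premises(cfg)
  farms <- reg$premises[reg$premises$ptype == "farm" &
                          reg$premises$country == "Scotland", ]
  expect_equal(nrow(farms), 100L)
  expect_equal(sum(is.na(farms$easting)), 35L)
  # every coordinate-less farm still has a parish with a known centroid
  miss <- farms[is.na(farms$easting), ]
  expect_true(all(miss$parish_id %in% reg$parishes$parish_id))
  # every farm's region is one of the 14 region codes
  expect_equal(length(unique(reg$regions$region)), 14L)
  expect_true(all(farms$region %in% reg$regions$region))
  expect_false(anyDuplicated(reg$premises$cph) > 0)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_holdings = 50L, n_moves_per_year = 200L,
                    years = 2016L, seed = 9L)
  r1 <- generate_premises(cfg)
  r2 <- generate_premises(cfg)
  expect_identical(r1, r2)
  s1 <- generate_movements(r1, cfg)
  s2 <- generate_movements(r2, cfg)
  expect_identical(s1, s2)
})

test_that("market routing emits the dual-record pattern with matching counts", {
  x <- default_sim()
  pairs <- x$sim$truth$duplicated_record_pairs
  b <- x$sim$batch
  expect_gt(nrow(pairs), 0)
  i1 <- match(pairs$record1, b$record_id)
  i2 <- match(pairs$record2, b$record_id)
  # record 1's read location (a market) is record 2's departure
  expect_equal(b$read_cph[i1], b$departure_cph[i2])
  expect_true(all(reg_ptype <- x$reg$premises$ptype[
    match(b$departure_cph[i2], x$reg$premises$cph)] == "market"))
  # same destination slaughterhouse and equal animal counts on both legs
  expect_equal(b$destination_cph[i1], b$destination_cph[i2])
  expect_equal(b$n_animals[i1], b$n_animals[i2])
  # no market routing -> no duplicate pairs
  cfg0 <- sim_config(n_holdings = 50L, n_moves_per_year = 300L,
                     years = 2017L, p_via_market = 0, seed = 3L)
  reg0 <- generate_premises(cfg0)
  s0 <- generate_movements(reg0, cfg0)
  expect_equal(nrow(s0$truth$duplicated_record_pairs), 0L)
})

test_that("every read occurs at a market or slaughterhouse in the registry", {
  x <- default_sim()
  pt <- x$reg$premises$ptype[match(x$sim$reads$ccp_cph,
                                   x$reg$premises$cph)]
  expect_true(all(pt %in% c("market", "slaughterhouse")))
})

test_that("with no read loss, slaughterhouse reads match deduplicated batch sheep", {
  cfg <- sim_config(n_holdings = 100L, n_moves_per_year = 1500L,
                    years = 2017L, p_misread = 0, p_batch_only_sheep = 0,
                    seed = 17L)
  reg <- generate_premises(cfg)
  s <- generate_movements(reg, cfg)
  sh <- reg$premises$cph[reg$premises$ptype == "slaughterhouse"]
  n_sh_reads <- sum(s$reads$ccp_cph %in% sh)
  dedup_sheep <- sum(s$truth$true_slaughter_count$sheep)
  expect_equal(n_sh_reads, dedup_sheep)
})

test_that("batch-only sheep share matches the configured rate", {
  cfg <- sim_config(n_holdings = 200L, n_moves_per_year = 4000L,
                    years = 2017L, p_misread = 0, seed = 23L)
  reg <- generate_premises(cfg)
  s <- generate_movements(reg, cfg)
  # deduplicated slaughter sheep vs distinct read animals
  keep <- !(s$batch$record_id %in% s$truth$duplicated_record_pairs$record2)
  sl <- identify_slaughter_moves(s$batch[keep, ], reg)
  n_animals <- sum(sl$n_animals)
  n_read <- length(unique(s$reads$tag_id))
  share <- (n_animals - n_read) / n_animals
  se <- sqrt(0.15 * 0.85 / n_animals)
  expect_lt(abs(share - 0.15), 4 * se)
})

test_that("monthly allocation follows the configured intensity profile", {
  x <- clean_sim()
  keep <- !(x$sim$batch$record_id %in%
              x$sim$truth$duplicated_record_pairs$record2)
  mo <- as.integer(format(x$sim$batch$date[keep], "%m"))
  obs <- tabulate(mo, 12L)
  p <- x$cfg$monthly_intensity / sum(x$cfg$monthly_intensity)
  gof <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
  # September is the modal month, June the minimum
  expect_equal(which.max(obs), 9L)
})

test_that("per-class batch-size means approach the configured means", {
  x <- clean_sim()
  b <- x$sim$batch
  keep <- !(b$record_id %in% x$sim$truth$duplicated_record_pairs$record2)
  b <- b[keep, ]
  cl <- x$sim$truth$true_class$class[match(b$record_id,
                                           x$sim$truth$true_class$record_id)]
  slaughter <- b$record_id %in% x$sim$truth$true_population$record_id
  m_into <- mean(b$n_animals[!slaughter & cl == "INTO"])
  expect_lt(abs(m_into - 56) / 56, 0.25)  # heavy-tailed, few INTO moves
  m_within <- mean(b$n_animals[!slaughter & cl == "WITHIN"])
  expect_lt(abs(m_within - 15) / 15, 0.05)
  m_sl_within <- mean(b$n_animals[slaughter & cl == "WITHIN"])
  expect_lt(abs(m_sl_within - 24) / 24, 0.05)
})

test_that("sim data round-trips through the CSV schemas", {
  x <- default_sim()
  d <- withr::local_tempdir()
  write_sim_data(x$sim, x$reg, d)
  mv <- read_movements(file.path(d, "movements.csv"))
  expect_equal(nrow(mv) + nrow(attr(mv, "rejects")), nrow(x$sim$batch))
  expect_equal(nrow(attr(mv, "rejects")), 0L)
  expect_equal(sum(mv$n_animals), sum(x$sim$batch$n_animals))
  rd <- read_reads(file.path(d, "reads.csv"))
  expect_equal(nrow(rd), nrow(x$sim$reads))
  pr <- read_premises(file.path(d, "premises.csv"))
  expect_equal(sum(is.na(pr$easting)),
               sum(is.na(x$reg$premises$easting)))
})
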