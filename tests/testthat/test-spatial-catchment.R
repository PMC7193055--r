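test_that("hexagon geometry follows from the configured cell area", {
  ext <- c(xmin = 0, ymin = 0, xmax = 100000, ymax = 80000)
  g <- build_hex_grid(ext, 115)
  # closed form R = sqrt(2A / (3 sqrt 3)), independently evaluated
  expect_equal(g$R, 6653.084, tolerance = 1e-6)
  # every cell's polygon area equals the configured area to 1e-6 relative
  v <- hex_vertices(g, g$cells$cell_id[c(1, 17, nrow(g$cells))])
  for (vv in v)
    expect_equal(polygon_area(vv) / 1e6, 115, tolerance = 1e-6)
  expect_error(build_hex_grid(ext, -3), "cell_area_km2")
})

test_that("the grid covers the extent, even when smaller than one cell", {
  tiny <- build_hex_grid(c(xmin = 0, ymin = 0, xmax = 500, ymax = 500),
                         115)
  expect_gte(nrow(tiny$cells), 1L)
  a <- assign_points(cbind(c(10, 250, 499), c(10, 250, 499)), tiny)
  expect_false(anyNA(a))
  # union of cell areas at least covers the extent area
  g <- build_hex_grid(c(xmin = 0, ymin = 0, xmax = 50000, ymax = 40000),
                      115)
  expect_gte(nrow(g$cells) * 115e6, 50000 * 40000)
})

test_that("point assignment agrees with a brute-force containment oracle", {
  ext <- c(xmin = 0, ymin = 0, xmax = 120000, ymax = 90000)
  for (orient in c("flat-top", "pointy-top")) {
    g <- build_hex_grid(ext, 115, orientation = orient)
    set.seed(4242)
    pts <- cbind(runif(2500, ext["xmin"], ext["xmax"]),
                 runif(2500, ext["ymin"], ext["ymax"]))
    a <- assign_points(pts, g)
    verts <- hex_vertices(g)
    oracle <- rep(NA_integer_, nrow(pts))
    for (i in seq_along(verts)) {
      inside <- ovimove:::point_in_polygon(pts[, 1], pts[, 2], verts[[i]])
      take <- inside & is.na(oracle)
      oracle[take] <- g$cells$cell_id[i]
    }
    expect_false(anyNA(a))
    expect_equal(as.integer(a), oracle)
  }
})

test_that("assignment is a function and boundary ties go to the lowest cell id", {
  ext <- c(xmin = 0, ymin = 0, xmax = 60000, ymax = 60000)
  g <- build_hex_grid(ext, 115)
  # cell centre maps to its own cell
  expect_equal(as.integer(assign_points(
    g$cells[5, c("center_x", "center_y")], g)), 5L)
  # midpoint of a shared edge: both incident cells contain it; lowest wins
  v <- hex_vertices(g, 1L)[[1]]
  mid <- colMeans(v[1:2, ])
  id <- as.integer(assign_points(rbind(mid), g))
  d <- sqrt((g$cells$center_x - mid[1])^2 + (g$cells$center_y - mid[2])^2)
  incident <- g$cells$cell_id[abs(d - min(d)) < 1e-6]
  expect_gte(length(incident), 2L)
  expect_equal(id, min(incident))
  # total assigned + outside = number of points
  set.seed(7)
  pts <- cbind(runif(1000, -50000, 110000), runif(1000, -50000, 110000))
  a <- assign_points(pts, g)
  expect_equal(sum(!is.na(a)) + attr(a, "n_outside"), 1000L)
})

test_that("per-cell counts are invariant to translating grid and points", {
  ext <- c(xmin = 0, ymin = 0, xmax = 80000, ymax = 60000)
  g1 <- build_hex_grid(ext, 115)
  set.seed(11)
  pts <- cbind(runif(800, 0, 80000), runif(800, 0, 60000))
  shift <- c(123456, -98765)
  ext2 <- c(xmin = ext["xmin"] + shift[1], ymin = ext["ymin"] + shift[2],
            xmax = ext["xmax"] + shift[1], ymax = ext["ymax"] + shift[2])
  names(ext2) <- names(ext)
  g2 <- build_hex_grid(ext2, 115)
  a1 <- assign_points(pts, g1)
  a2 <- assign_points(sweep(pts, 2, -shift), g2)
  expect_equal(sort(as.vector(table(a1))), sort(as.vector(table(a2))))
})

test_that("a clip polygon drops cells with centres outside it", {
  ext <- c(xmin = 0, ymin = 0, xmax = 60000, ymax = 60000)
  full <- build_hex_grid(ext, 115)
  tri <- cbind(c(0, 60000, 0), c(0, 0, 60000))
  clipped <- build_hex_grid(ext, 115, clip_polygon = tri)
  expect_lt(nrow(clipped$cells), nrow(full$cells))
  expect_true(all(clipped$cells$center_x + clipped$cells$center_y <=
                    60000 + 1e-9))
})

test_that("parish densities are sheep per hectare with absent areas flagged", {
  parishes <- data.frame(parish_id = c("P1", "P2", "P3"),
                         area_ha = c(400, 0, 1000))
  census <- data.frame(parish_id = c("P1", "P2", "P3"),
                       year = 2017L, sheep = c(800, 10, 0))
  expect_warning(d <- parish_density(census, parishes), "absent")
  expect_equal(d$density, c(2.0, NA, 0))
})

test_that("synthetic parish densities span the observed 0-8 range", {
  x <- default_sim()
  cen <- generate_census(x$reg, x$cfg)
  d <- parish_density(cen, x$reg$parishes)
  expect_true(all(d$density <= 8 + 1e-9))
  expect_gt(max(d$density), 5)
})

test_that("catchment cells conserve throughput and respect the reference", {
  x <- clean_sim()
  sl <- identify_slaughter_moves(x$sim$batch, x$reg)
  dd <- deduplicate_market_legs(sl, x$sim$reads, x$reg, 1L)
  g <- build_hex_grid(x$cfg$extent, 115)
  rk <- rank_slaughterhouses(dd$kept, x$reg, 2017L, reference = "SISP")
  sh <- rk$slaughterhouse[x$reg$premises$country[
    match(rk$slaughterhouse, x$reg$premises$cph)] == "Scotland"][1]
  ct <- compute_catchment(sh, dd$kept, x$reg, g, 2017L,
                          reference = "SISP")
  # mapped + unmapped sheep = slaughterhouse throughput
  expect_equal(sum(ct$cells$n_sheep) + ct$unmappable$sheep,
               ct$throughput)
  # per-cell sheep equal the ground-truth supply aggregated on the grid
  phs <- x$sim$truth$per_holding_supply
  phs <- phs[phs$slaughterhouse == sh & phs$year == 2017L, ]
  supply <- tapply(phs$sheep, phs$holding, sum)
  loc <- resolve_location(names(supply), x$reg)
  cell <- assign_points(cbind(loc$easting, loc$northing), g)
  truth_cells <- tapply(as.numeric(supply)[!is.na(cell)],
                        cell[!is.na(cell)], sum)
  expect_equal(ct$cells$n_sheep,
               as.numeric(truth_cells[as.character(ct$cells$cell_id)]))
  # catchment total cannot exceed the reference population
  expect_lte(sum(ct$cells$n_sheep), ct$ref_total)
  expect_equal(sum(ct$cells$pct_of_reference),
               sum(ct$cells$n_sheep) / ct$ref_total * 100)
  expect_error(compute_catchment("66/001/0001", dd$kept, x$reg, g, 2017L),
               "unknown slaughterhouse")
})

test_that("quarterly catchment layers decompose the annual throughput", {
  x <- clean_sim()
  sl <- identify_slaughter_moves(x$sim$batch, x$reg)
  dd <- deduplicate_market_legs(sl, x$sim$reads, x$reg, 1L)
  g <- build_hex_grid(x$cfg$extent, 115)
  rk <- rank_slaughterhouses(dd$kept, x$reg, 2017L)
  sh <- rk$slaughterhouse[x$reg$premises$country[
    match(rk$slaughterhouse, x$reg$premises$cph)] == "Scotland"][1]
  qc <- quarterly_catchment(sh, dd$kept, x$reg, g, 2017L)
  grand <- sum(vapply(qc, function(l) sum(l$pct_of_annual), numeric(1)))
  ct <- compute_catchment(sh, dd$kept, x$reg, g, 2017L)
  mappable_pct <- sum(ct$cells$n_sheep) / ct$throughput * 100
  expect_equal(grand, mappable_pct, tolerance = 1e-9)
})

test_that("hex grid exports to GeoJSON with cell properties", {
  g <- build_hex_grid(c(xmin = 0, ymin = 0, xmax = 30000, ymax = 30000),
                      115)
  f <- withr::local_tempfile(fileext = ".geojson")
  vals <- data.frame(cell_id = g$cells$cell_id[1:2], n_sheep = c(5, 9))
  export_hexgrid_geojson(g, f, vals)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(g$cells))
  expect_equal(gj$features[[1]]$properties$n_sheep, 5)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(length(ring), 7L)  # closed hexagon
})
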