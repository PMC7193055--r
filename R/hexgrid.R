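#' Build a fixed-area hexagonal grid over a planar extent
#'
#' Tessellates the extent with congruent regular hexagons of the given area
#' (default 115 km2, the cell size used for national catchment mapping).
#' The circumradius follows from the area: A = (3*sqrt(3)/2) * R^2, so
#' R = sqrt(2A / (3*sqrt(3))). Cells are laid out flat-top (or pointy-top)
#' from an origin at the extent's lower-left corner; every cell whose
#' bounding circle intersects the extent is retained, so the grid covers the
#' extent. If a clip polygon is supplied, cells whose centres fall outside
#' it are dropped (a planar stand-in for coastline trimming).
#'
#' @param extent named numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param cell_area_km2 hexagon area in square kilometres (> 0).
#' @param orientation `"flat-top"` (default) or `"pointy-top"`.
#' @param clip_polygon optional two-column matrix of polygon vertices;
#'   cells with centres outside it are dropped.
#' @return an object of class `"hex_grid"`: list with `cells` (data.frame
#'   `cell_id`, `col`, `row`, `center_x`, `center_y`), `R` (circumradius,
#'   m), `cell_area_km2`, `orientation`, `origin`, `extent`.
#' @export
build_hex_grid <- function(extent, cell_area_km2 = 115,
                           orientation = c("flat-top", "pointy-top"),
                           clip_polygon = NULL) {
  orientation <- match.arg(orientation)
  if (!is.numeric(cell_area_km2) || cell_area_km2 <= 0)
    stop("cell_area_km2 must be > 0", call. = FALSE)
  ext <- extent
  if (ext["xmax"] <= ext["xmin"] || ext["ymax"] <= ext["ymin"])
    stop("degenerate extent", call. = FALSE)
  R <- sqrt(2 * cell_area_km2 * 1e6 / (3 * sqrt(3)))
  origin <- c(x = unname(ext["xmin"]), y = unname(ext["ymin"]))
  # work in flat-top frame; pointy-top swaps axes
  flip <- orientation == "pointy-top"
  fx <- function(x, y) if (flip) list(x = y, y = x) else list(x = x, y = y)
  lo <- fx(ext["xmin"] - origin["x"], ext["ymin"] - origin["y"])
  hi <- fx(ext["xmax"] - origin["x"], ext["ymax"] - origin["y"])
  imin <- floor((lo$x - R) / (1.5 * R))
  imax <- ceiling((hi$x + R) / (1.5 * R))
  jmin <- floor((lo$y - R) / (sqrt(3) * R)) - 1L
  jmax <- ceiling((hi$y + R) / (sqrt(3) * R)) + 1L
  g <- expand.grid(col = imin:imax, row = jmin:jmax)
  cx <- 1.5 * R * g$col
  cy <- sqrt(3) * R * (g$row + 0.5 * (g$col %% 2 != 0))
  keep <- cx >= lo$x - R & cx <= hi$x + R & cy >= lo$y - R & cy <= hi$y + R
  g <- g[keep, , drop = FALSE]; cx <- cx[keep]; cy <- cy[keep]
  back <- fx(cx, cy)  # involution
  cxx <- back$x + origin["x"]; cyy <- back$y + origin["y"]
  if (!is.null(clip_polygon)) {
    inside <- point_in_polygon(cxx, cyy, clip_polygon)
    g <- g[inside, , drop = FALSE]; cxx <- cxx[inside]; cyy <- cyy[inside]
  }
  o <- order(g$col, g$row)
  cells <- data.frame(cell_id = seq_along(o), col = g$col[o], row = g$row[o],
                      center_x = unname(cxx[o]), center_y = unname(cyy[o]))
  structure(list(cells = cells, R = R, cell_area_km2 = cell_area_km2,
                 orientation = orientation, origin = origin, extent = ext),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat("Hexagonal grid:", nrow(x$cells), "cells of", x$cell_area_km2,
      "km2 (circumradius", round(x$R), "m,", x$orientation, ")\n")
  invisible(x)
}

#' Hexagon vertex coordinates
#'
#' @param grid a [build_hex_grid()] object.
#' @param cell_ids cells to return (default all).
#' @return list of two-column matrices (6 vertices each), named by cell_id.
#' @export
hex_vertices <- function(grid, cell_ids = grid$cells$cell_id) {
  ang0 <- if (grid$orientation == "flat-top") 0 else pi / 6
  ang <- ang0 + (0:5) * pi / 3
  m <- match(cell_ids, grid$cells$cell_id)
  out <- lapply(m, function(i) {
    cbind(x = grid$cells$center_x[i] + grid$R * cos(ang),
          y = grid$cells$center_y[i] + grid$R * sin(ang))
  })
  names(out) <- cell_ids
  out
}

# ray-casting point-in-polygon (boundary counted inside)
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Assign planar points to hexagonal grid cells
#'
#' A regular hexagon tiling is the Voronoi diagram of its centres, so a
#' point's containing cell is the cell with the nearest centre. The lattice
#' cell is located by axial-coordinate rounding and then checked against its
#' six neighbours; points equidistant from two or more centres (cell
#' boundaries) are assigned to the lowest incident `cell_id`. Points whose
#' containing cell is not part of the grid are flagged outside-grid (`NA`).
#'
#' @param points two-column matrix or data.frame of x/y coordinates.
#' @param grid a [build_hex_grid()] object.
#' @return integer vector of cell_ids (`NA` = outside grid), with the count
#'   of outside-grid points in attribute `"n_outside"`.
#' @export
assign_points <- function(points, grid) {
  points <- as.matrix(points)
  R <- grid$R
  flip <- grid$orientation == "pointy-top"
  x <- points[, 1] - grid$origin["x"]
  y <- points[, 2] - grid$origin["y"]
  if (flip) { tmp <- x; x <- y; y <- tmp }
  # axial coordinates (flat-top), cube rounding
  q <- (2 / 3) * x / R
  rr <- (-1 / 3 * x + sqrt(3) / 3 * y) / R
  cz <- rr; cx <- q; cy <- -cx - cz
  rx <- round(cx); ry <- round(cy); rz <- round(cz)
  dx <- abs(rx - cx); dy <- abs(ry - cy); dz <- abs(rz - cz)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  qi <- as.integer(rx)
  ji <- as.integer(rz + floor(rx / 2))  # offset row from axial
  # candidate = located cell + 6 neighbours; resolve by nearest centre,
  # ties to lowest cell_id
  even <- qi %% 2 == 0
  nbr_even <- list(c(0, 0), c(0, 1), c(0, -1), c(1, 0), c(1, -1),
                   c(-1, 0), c(-1, -1))
  nbr_odd <- list(c(0, 0), c(0, 1), c(0, -1), c(1, 1), c(1, 0),
                  c(-1, 1), c(-1, 0))
  key <- paste(grid$cells$col, grid$cells$row)
  n <- length(x)
  best_id <- rep(NA_integer_, n)
  best_d <- rep(Inf, n)
  tol <- 1e-7 * R
  for (k in 1:7) {
    dq_e <- nbr_even[[k]][1]; dj_e <- nbr_even[[k]][2]
    dq_o <- nbr_odd[[k]][1]; dj_o <- nbr_odd[[k]][2]
    cq <- qi + ifelse(even, dq_e, dq_o)
    cj <- ji + ifelse(even, dj_e, dj_o)
    id <- match(paste(cq, cj), key)
    ccx <- 1.5 * R * cq
    ccy <- sqrt(3) * R * (cj + 0.5 * (cq %% 2 != 0))
    d <- sqrt((x - ccx)^2 + (y - ccy)^2)
    better <- !is.na(id) & (d < best_d - tol |
                              (abs(d - best_d) <= tol &
                                 (is.na(best_id) | id < best_id)))
    best_id[better] <- grid$cells$cell_id[id[better]]
    best_d[better] <- pmin(d[better], best_d[better])
  }
  structure(best_id, n_outside = sum(is.na(best_id)))
}

#' Parish-level sheep density
#'
#' Sheep per hectare per parish per year, from a census table and parish
#' areas. Parishes with zero or missing area get `NA` density with a
#' warning.
#'
#' @param census data.frame with `parish_id`, `year`, `sheep`.
#' @param parishes parish table with `parish_id`, `area_ha`.
#' @return data.frame: `parish_id`, `year`, `sheep`, `area_ha`, `density`.
#' @export
parish_density <- function(census, parishes) {
  area <- parishes$area_ha[match(census$parish_id, parishes$parish_id)]
  bad <- is.na(area) | area <= 0
  if (any(bad))
    warning(sum(bad), " parish-years with zero or missing area; ",
            "density reported absent", call. = FALSE)
  density <- ifelse(bad, NA_real_, census$sheep / area)
  data.frame(parish_id = census$parish_id, year = census$year,
             sheep = census$sheep, area_ha = area, density = density)
}

#' Slaughterhouse catchment area on the hexagonal grid
#'
#' A slaughterhouse's catchment area is the spatial distribution of the
#' holdings from which it receives its annual throughput. Supplying holdings
#' are located (precise coordinates, else parish centroid), binned into grid
#' cells, and each cell's sheep count is expressed as a percentage of the
#' reference population (SISP or SSSP) for that year. Holdings that cannot
#' be mapped, or fall outside the grid, are tallied separately — never
#' silently dropped.
#'
#' @param slaughterhouse destination CPH (must be a slaughterhouse in the
#'   registry).
#' @param deduped deduplicated slaughter records.
#' @param reg premises registry.
#' @param grid a [build_hex_grid()] object.
#' @param year calendar year.
#' @param reference `"SISP"` or `"SSSP"`.
#' @return object of class `"catchment"`: list with `cells` (data.frame
#'   `cell_id`, `n_holdings`, `n_sheep`, `pct_of_reference`), `holdings`
#'   (per-holding sheep, location tag and cell), `unmappable` (holdings and
#'   sheep not mapped), `throughput`, `ref_total`, plus identifiers.
#' @export
compute_catchment <- function(slaughterhouse, deduped, reg, grid, year,
                              reference = c("SISP", "SSSP")) {
  reference <- match.arg(reference)
  pt <- reg_field(reg, slaughterhouse, "ptype")
  if (is.na(pt) || pt != "slaughterhouse")
    stop("unknown slaughterhouse: ", slaughterhouse, call. = FALSE)
  pop <- classify_population(deduped, reg)
  yr <- as.integer(format(deduped$date, "%Y"))
  ref_pop <- if (reference == "SISP") "SISP" else c("SISP", "SOSP")
  ref_total <- sum(deduped$n_animals[yr == year & pop %in% ref_pop])
  sel <- yr == year & deduped$destination_cph == slaughterhouse
  agg <- stats::aggregate(list(sheep = deduped$n_animals[sel]),
                          by = list(holding = deduped$departure_cph[sel]),
                          FUN = sum)
  loc <- resolve_location(agg$holding, reg)
  cell <- rep(NA_integer_, nrow(agg))
  mappable <- loc$tag != "unmappable"
  if (any(mappable))
    cell[mappable] <- assign_points(cbind(loc$easting[mappable],
                                          loc$northing[mappable]), grid)
  holdings <- data.frame(holding = agg$holding, sheep = agg$sheep,
                         tag = loc$tag, cell_id = cell)
  ok <- !is.na(cell)
  cells <- if (any(ok)) {
    a <- stats::aggregate(cbind(n_holdings = rep(1L, sum(ok)),
                                n_sheep = agg$sheep[ok]),
                          by = list(cell_id = cell[ok]), FUN = sum)
    a$pct_of_reference <- if (ref_total > 0)
      a$n_sheep / ref_total * 100 else NA_real_
    a[order(a$cell_id), ]
  } else {
    data.frame(cell_id = integer(0), n_holdings = integer(0),
               n_sheep = numeric(0), pct_of_reference = numeric(0))
  }
  structure(list(slaughterhouse = slaughterhouse, year = year,
                 reference = reference, ref_total = ref_total,
                 throughput = sum(agg$sheep),
                 cells = cells, holdings = holdings,
                 unmappable = list(n_holdings = sum(!ok),
                                   sheep = sum(agg$sheep[!ok]))),
            class = "catchment")
}

#' @export
print.catchment <- function(x, ...) {
  cat("Catchment of", x$slaughterhouse, "in", x$year, ":",
      nrow(x$cells), "grid cells,", sum(x$cells$n_holdings),
      "mapped holdings,", x$throughput, "sheep (",
      sprintf("%.1f%%", sum(x$cells$n_sheep) / max(x$ref_total, 1) * 100),
      "of", x$reference, ");", x$unmappable$n_holdings,
      "holdings unmapped\n")
  invisible(x)
}

#' Quarterly decomposition of a slaughterhouse catchment
#'
#' Per calendar quarter (Jan–Mar, Apr–Jun, Jul–Sep, Oct–Dec), sheep supplied
#' from each grid cell as a percentage of the slaughterhouse's annual
#' throughput, so the four layers' grand totals sum to the mappable share of
#' 100%.
#'
#' @inheritParams compute_catchment
#' @return list of 4 data.frames (`cell_id`, `n_sheep`, `pct_of_annual`),
#'   with attributes `annual_throughput`, `slaughterhouse`, `year`.
#' @export
quarterly_catchment <- function(slaughterhouse, deduped, reg, grid, year) {
  pt <- reg_field(reg, slaughterhouse, "ptype")
  if (is.na(pt) || pt != "slaughterhouse")
    stop("unknown slaughterhouse: ", slaughterhouse, call. = FALSE)
  yr <- as.integer(format(deduped$date, "%Y"))
  sel <- yr == year & deduped$destination_cph == slaughterhouse
  r <- deduped[sel, , drop = FALSE]
  annual <- sum(r$n_animals)
  qtr <- (as.integer(format(r$date, "%m")) - 1L) %/% 3L + 1L
  loc <- resolve_location(r$departure_cph, reg)
  cell <- rep(NA_integer_, nrow(r))
  mappable <- loc$tag != "unmappable"
  if (any(mappable))
    cell[mappable] <- assign_points(cbind(loc$easting[mappable],
                                          loc$northing[mappable]), grid)
  layers <- lapply(1:4, function(qq) {
    ok <- qtr == qq & !is.na(cell)
    if (!any(ok))
      return(data.frame(cell_id = integer(0), n_sheep = numeric(0),
                        pct_of_annual = numeric(0)))
    a <- stats::aggregate(list(n_sheep = r$n_animals[ok]),
                          by = list(cell_id = cell[ok]), FUN = sum)
    a$pct_of_annual <- if (annual > 0) a$n_sheep / annual * 100 else NA_real_
    a[order(a$cell_id), ]
  })
  names(layers) <- paste0("Q", 1:4)
  attr(layers, "annual_throughput") <- annual
  attr(layers, "slaughterhouse") <- slaughterhouse
  attr(layers, "year") <- year
  layers
}

#' Export a hexagonal grid (with optional cell values) as GeoJSON
#'
#' Writes a FeatureCollection of hexagon polygons; any columns of
#' `cell_values` (matched by `cell_id`) become feature properties.
#'
#' @param grid a [build_hex_grid()] object.
#' @param path output file.
#' @param cell_values optional data.frame with a `cell_id` column.
#' @return invisibly, `path`.
#' @export
export_hexgrid_geojson <- function(grid, path, cell_values = NULL) {
  verts <- hex_vertices(grid)
  feats <- lapply(seq_len(nrow(grid$cells)), function(i) {
    v <- verts[[i]]
    ring <- rbind(v, v[1, , drop = FALSE])
    props <- list(cell_id = grid$cells$cell_id[i])
    if (!is.null(cell_values)) {
      j <- match(grid$cells$cell_id[i], cell_values$cell_id)
      if (!is.na(j))
        for (cc in setdiff(names(cell_values), "cell_id"))
          props[[cc]] <- cell_values[[cc]][j]
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k)
                                                     unname(ring[k, ])))))
  })
  fc <- list(type = "FeatureCollection",
             metadata = list(cell_area_km2 = grid$cell_area_km2,
                             orientation = grid$orientation,
                             origin = as.list(grid$origin)),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a catchment as shaded hexagons
#'
#' @param x a `"catchment"` object.
#' @param grid the grid the catchment was computed on.
#' @param ... passed to [graphics::plot()].
#' @export
plot.catchment <- function(x, grid, ...) {
  ext <- grid$extent
  graphics::plot(NA, xlim = ext[c("xmin", "xmax")],
                 ylim = ext[c("ymin", "ymax")], asp = 1,
                 xlab = "easting (m)", ylab = "northing (m)",
                 main = paste("Catchment of", x$slaughterhouse, x$year), ...)
  if (nrow(x$cells) == 0L) return(invisible(x))
  v <- hex_vertices(grid, x$cells$cell_id)
  shade <- x$cells$n_sheep / max(x$cells$n_sheep)
  for (i in seq_along(v))
    graphics::polygon(v[[i]], col = grDevices::gray(1 - 0.8 * shade[i]),
                      border = "grey40")
  invisible(x)
}
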