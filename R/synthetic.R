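# Reproducible synthetic geographies: residential areas with lognormal
# populations and nested units, typed facilities with differing densities,
# a grid road network, and unit adjacency. Stands in for national
# residential-area and facility registers so every pipeline stage is
# testable without external data.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.default_facility_spec <- function(n_areas) {
  # per-type densities loosely mirroring French primary-care supply:
  # GPs and nurses densest, dentists sparsest; one tertiary type
  data.frame(
    facility_type = c("gp", "nurse", "physiotherapist", "pharmacist",
                      "dentist", "emergency"),
    range_class = c(rep("proximity", 5), "tertiary"),
    count = pmax(2L, as.integer(round(
      n_areas * c(0.08, 0.07, 0.06, 0.04, 0.035, 0.008)))),
    placement = c("population_biased", "population_biased",
                  "population_biased", "population_biased",
                  "population_biased", "uniform"),
    stringsAsFactors = FALSE)
}

#' Synthetic-geography configuration
#'
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @param extent bounding box `c(xmin, ymin, xmax, ymax)` in meters.
#' @param n_areas number of residential areas.
#' @param layout `"clustered"` (settlement-like) or `"uniform"`.
#' @param n_clusters,cluster_sd cluster count and Gaussian spread (m) for
#'   the clustered layout.
#' @param pop_meanlog,pop_sdlog lognormal population parameters (the
#'   right-skew of real settlement sizes; defaults give a median of ~55
#'   persons per area).
#' @param facility_spec data frame `facility_type, range_class, count,
#'   placement` (`placement` in `uniform`/`population_biased`); the default
#'   catalogue has five proximity types of differing density plus one
#'   sparse tertiary type.
#' @param network list `rows, cols, speed_kmh` for a grid road network, or
#'   NULL for none.
#' @param units list `regions = c(nx, ny), communes = c(nx, ny),
#'   iris = c(nx, ny)`: nested rectangular partition (communes per region,
#'   IRIS per commune).
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         extent = c(0, 0, 50000, 50000),
                         n_areas = 500,
                         layout = c("clustered", "uniform"),
                         n_clusters = 5, cluster_sd = 2500,
                         pop_meanlog = 4, pop_sdlog = 1,
                         facility_spec = NULL,
                         network = list(rows = 11, cols = 11,
                                        speed_kmh = 50),
                         units = list(regions = c(2, 2),
                                      communes = c(3, 3),
                                      iris = c(2, 2))) {
  layout <- match.arg(layout)
  if (is.null(facility_spec)) facility_spec <- .default_facility_spec(n_areas)
  if (any(facility_spec$count < 1))
    stop_schema("synth_config: every declared facility type needs count >= 1")
  structure(list(seed = seed, extent = extent, n_areas = n_areas,
                 layout = layout, n_clusters = n_clusters,
                 cluster_sd = cluster_sd, pop_meanlog = pop_meanlog,
                 pop_sdlog = pop_sdlog, facility_spec = facility_spec,
                 network = network, units = units),
            class = "synth_config")
}

# cell index of points in an n-cell grid over [lo, hi)
.grid_cell <- function(v, lo, hi, n) {
  pmin(n, pmax(1L, 1L + as.integer(floor((v - lo) / (hi - lo) * n))))
}

.unit_ids <- function(x, y, extent, units) {
  rx <- units$regions[1]; ry <- units$regions[2]
  cx <- units$communes[1]; cy <- units$communes[2]
  ix <- units$iris[1]; iy <- units$iris[2]
  gx <- .grid_cell(x, extent[1], extent[3], rx * cx * ix)
  gy <- .grid_cell(y, extent[2], extent[4], ry * cy * iy)
  reg_x <- (gx - 1L) %/% (cx * ix); reg_y <- (gy - 1L) %/% (cy * iy)
  com_x <- (gx - 1L) %/% ix; com_y <- (gy - 1L) %/% iy
  region <- sprintf("R%02d", reg_y * rx + reg_x + 1L)
  commune <- sprintf("%s-C%02d",
                     region,
                     (com_y %% cy) * cx + (com_x %% cx) + 1L)
  iris <- sprintf("%s-I%02d",
                  commune,
                  ((gy - 1L) %% iy) * ix + ((gx - 1L) %% ix) + 1L)
  list(region = region, commune = commune, iris = iris)
}

# rook adjacency of an nx-by-ny grid of unit ids (row-major, id_fun(ix, iy))
.grid_adjacency <- function(nx, ny, id_fun, level) {
  out <- list()
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    here <- id_fun(ix, iy)
    if (ix < nx) out[[length(out) + 1]] <-
        data.frame(unit_id = here, neighbor_id = id_fun(ix + 1, iy),
                   level = level, stringsAsFactors = FALSE)
    if (iy < ny) out[[length(out) + 1]] <-
        data.frame(unit_id = here, neighbor_id = id_fun(ix, iy + 1),
                   level = level, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic geography
#'
#' Draws residential areas (uniform or clustered point process) with
#' lognormal populations, assigns nested IRIS/commune/region identifiers
#' from a rectangular partition of the extent, places facilities per the
#' type catalogue (uniformly or biased toward population), builds a grid
#' road network with per-edge speed variation, and derives unit adjacency.
#' Deterministic under `config$seed`.
#'
#' @param config a [synth_config()].
#' @return a `synth_geography` list: `areas`, `facilities`, `network`
#'   (`road_network` or NULL), `adjacency`, `commune_dept` (identity map:
#'   the commune layer doubles as the department layer), `config`.
#' @export
synth_geography <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    e <- config$extent
    n <- config$n_areas
    if (config$layout == "uniform") {
      x <- runif(n, e[1], e[3]); y <- runif(n, e[2], e[4])
    } else {
      cxs <- runif(config$n_clusters, e[1], e[3])
      cys <- runif(config$n_clusters, e[2], e[4])
      k <- sample.int(config$n_clusters, n, replace = TRUE)
      x <- pmin(e[3] - 1, pmax(e[1], cxs[k] + rnorm(n, 0, config$cluster_sd)))
      y <- pmin(e[4] - 1, pmax(e[2], cys[k] + rnorm(n, 0, config$cluster_sd)))
    }
    u <- .unit_ids(x, y, e, config$units)
    areas <- data.frame(
      area_id = sprintf("A%05d", seq_len(n)), x = x, y = y,
      population = round(rlnorm(n, config$pop_meanlog, config$pop_sdlog)),
      iris_id = u$iris, commune_id = u$commune, region_id = u$region,
      stringsAsFactors = FALSE)

    spec <- config$facility_spec
    fac <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
      ct <- spec$count[i]
      if (spec$placement[i] == "uniform") {
        fx <- runif(ct, e[1], e[3]); fy <- runif(ct, e[2], e[4])
      } else {
        at <- sample.int(n, ct, replace = TRUE, prob = areas$population + 1)
        fx <- pmin(e[3] - 1, pmax(e[1], areas$x[at] + rnorm(ct, 0, 500)))
        fy <- pmin(e[4] - 1, pmax(e[2], areas$y[at] + rnorm(ct, 0, 500)))
      }
      data.frame(
        facility_id = sprintf("F-%s-%03d", spec$facility_type[i],
                              seq_len(ct)),
        x = fx, y = fy, facility_type = spec$facility_type[i],
        range_class = spec$range_class[i],
        n_professionals = sample(1:3, ct, replace = TRUE,
                                 prob = c(0.7, 0.2, 0.1)),
        stringsAsFactors = FALSE)
    }))

    network <- NULL
    if (!is.null(config$network)) {
      nc <- config$network
      gx <- seq(e[1], e[3], length.out = nc$cols)
      gy <- seq(e[2], e[4], length.out = nc$rows)
      nodes <- expand.grid(cx = seq_len(nc$cols), cy = seq_len(nc$rows))
      nodes <- data.frame(
        node_id = sprintf("N%03d", seq_len(nrow(nodes))),
        x = gx[nodes$cx], y = gy[nodes$cy],
        cx = nodes$cx, cy = nodes$cy, stringsAsFactors = FALSE)
      id_at <- function(cx, cy) nodes$node_id[(cy - 1) * nc$cols + cx]
      edges <- list()
      for (cy in seq_len(nc$rows)) for (cx in seq_len(nc$cols)) {
        if (cx < nc$cols) edges[[length(edges) + 1]] <-
            data.frame(from_node = id_at(cx, cy),
                       to_node = id_at(cx + 1, cy),
                       length_m = gx[cx + 1] - gx[cx],
                       stringsAsFactors = FALSE)
        if (cy < nc$rows) edges[[length(edges) + 1]] <-
            data.frame(from_node = id_at(cx, cy),
                       to_node = id_at(cx, cy + 1),
                       length_m = gy[cy + 1] - gy[cy],
                       stringsAsFactors = FALSE)
      }
      edges <- do.call(rbind, edges)
      speed <- nc$speed_kmh * runif(nrow(edges), 0.8, 1.2)
      edges$travel_time_min <- edges$length_m / 1000 / speed * 60
      network <- make_network(nodes[, c("node_id", "x", "y")], edges)
    }

    un <- config$units
    adj_region <- .grid_adjacency(
      un$regions[1], un$regions[2],
      function(ix, iy) sprintf("R%02d", (iy - 1) * un$regions[1] + ix),
      "region")
    # commune layer doubles as the department layer in this hierarchy
    ncx <- un$regions[1] * un$communes[1]
    ncy <- un$regions[2] * un$communes[2]
    com_id <- function(ix, iy) {
      rx <- (ix - 1) %/% un$communes[1]; ry <- (iy - 1) %/% un$communes[2]
      sprintf("R%02d-C%02d", ry * un$regions[1] + rx + 1,
              ((iy - 1) %% un$communes[2]) * un$communes[1] +
                ((ix - 1) %% un$communes[1]) + 1)
    }
    adj_dept <- .grid_adjacency(ncx, ncy, com_id, "department")
    adjacency <- rbind(adj_region, adj_dept)
    communes <- sort(unique(areas$commune_id))
    commune_dept <- data.frame(commune_id = communes,
                               department_id = communes,
                               stringsAsFactors = FALSE)

    structure(list(areas = validate_areas(areas),
                   facilities = validate_facilities(fac),
                   network = network, adjacency = adjacency,
                   commune_dept = commune_dept, config = config),
              class = "synth_geography")
  })
}

#' Gradient fixture: a dense city and a sparse rural margin
#'
#' Generates a geography with planted accessibility structure: a compact
#' city cluster holding most facilities, and a rural margin whose few
#' facilities are distant. Every area carries a ground-truth `zone` label
#' (`"city"` or `"rural"`), so an end-to-end run must rank the city's
#' accessibility above the rural margin's.
#'
#' @param seed RNG seed.
#' @param n_city,n_rural areas per zone.
#' @param extent bounding box (meters).
#' @return a `synth_geography` whose `areas` carry a `zone` column.
#' @export
synth_gradient <- function(seed = 1, n_city = 150, n_rural = 100,
                           extent = c(0, 0, 40000, 40000)) {
  with_seed(seed, {
    e <- extent
    city_c <- c(e[1] + 0.25 * (e[3] - e[1]), e[2] + 0.25 * (e[4] - e[2]))
    cx <- pmax(e[1], pmin(e[3] - 1, city_c[1] + rnorm(n_city, 0, 1500)))
    cy <- pmax(e[2], pmin(e[4] - 1, city_c[2] + rnorm(n_city, 0, 1500)))
    rx <- runif(n_rural, e[1] + 0.55 * (e[3] - e[1]), e[3])
    ry <- runif(n_rural, e[2] + 0.55 * (e[4] - e[2]), e[4])
    x <- c(cx, rx); y <- c(cy, ry)
    u <- .unit_ids(x, y, e, list(regions = c(2, 2), communes = c(2, 2),
                                 iris = c(2, 2)))
    areas <- data.frame(
      area_id = sprintf("A%05d", seq_along(x)), x = x, y = y,
      population = round(rlnorm(length(x), 4, 1)),
      iris_id = u$iris, commune_id = u$commune, region_id = u$region,
      zone = rep(c("city", "rural"), c(n_city, n_rural)),
      stringsAsFactors = FALSE)
    n_cf <- 20; n_rf <- 3
    fx <- c(city_c[1] + rnorm(n_cf, 0, 2000),
            runif(n_rf, e[1] + 0.55 * (e[3] - e[1]), e[3]))
    fy <- c(city_c[2] + rnorm(n_cf, 0, 2000),
            runif(n_rf, e[2] + 0.55 * (e[4] - e[2]), e[4]))
    fac <- data.frame(
      facility_id = sprintf("F-gp-%03d", seq_along(fx)),
      x = pmax(e[1], pmin(e[3] - 1, fx)),
      y = pmax(e[2], pmin(e[4] - 1, fy)),
      facility_type = "gp", range_class = "proximity",
      n_professionals = 1L, stringsAsFactors = FALSE)
    structure(list(areas = validate_areas(areas),
                   facilities = validate_facilities(fac),
                   network = NULL, adjacency = NULL, commune_dept = NULL,
                   config = list(seed = seed)),
              class = "synth_geography")
  })
}

#' Write a synthetic geography to a directory
#'
#' Emits `areas.csv`, `facilities.csv`, and when present `nodes.csv`,
#' `edges.csv`, `adjacency.csv` — the exact formats the readers accept.
#'
#' @param geo a `synth_geography`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(geo, dir) {
  stopifnot(inherits(geo, "synth_geography"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(geo$areas, file.path(dir, "areas.csv"))
  write_results(geo$facilities, file.path(dir, "facilities.csv"))
  if (!is.null(geo$network)) {
    write_results(geo$network$nodes, file.path(dir, "nodes.csv"))
    write_results(geo$network$edges, file.path(dir, "edges.csv"))
  }
  if (!is.null(geo$adjacency))
    write_results(geo$adjacency, file.path(dir, "adjacency.csv"))
  invisible(dir)
}
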