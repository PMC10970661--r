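# Origin-destination travel costs between residential areas and
# facilities: straight-line fallback or shortest path on the road graph,
# plus the region-wise chunk plan that restricts candidate facilities.

new_od <- function(time, dist, metric) {
  stopifnot(identical(dim(time), dim(dist)))
  structure(list(time = time, dist = dist, metric = metric),
            class = "od_matrix")
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("od_matrix (%s): %d origins x %d destinations, %d unreachable\n",
              x$metric, nrow(x$time), ncol(x$time), sum(!is.finite(x$time))))
  invisible(x)
}

#' Straight-line travel costs
#'
#' Euclidean distance between every area and facility, converted to minutes
#' at a constant speed. This is the legacy metric that the network travel
#' time replaces; it remains useful when no road network is available.
#'
#' @param areas validated residential-area data frame.
#' @param facilities validated facility data frame.
#' @param speed_kmh constant travel speed in km/h (> 0).
#' @return an `od_matrix` with `metric = "euclidean"`.
#' @export
euclidean_costs <- function(areas, facilities, speed_kmh = 50) {
  if (!is.numeric(speed_kmh) || length(speed_kmh) != 1 || speed_kmh <= 0)
    stop_schema("euclidean_costs: speed_kmh must be a positive number")
  dx <- outer(areas$x, facilities$x, "-")
  dy <- outer(areas$y, facilities$y, "-")
  dist <- sqrt(dx^2 + dy^2)
  dimnames(dist) <- list(areas$area_id, facilities$facility_id)
  time <- dist / 1000 / speed_kmh * 60
  new_od(time, dist, "euclidean")
}

#' Snap points to the nearest network node
#'
#' @param x,y point coordinates.
#' @param network a `road_network`.
#' @param max_snap_m maximum allowed snap distance in meters; beyond it an
#'   error names the offending point.
#' @param ids optional point identifiers for error messages.
#' @return data frame `node_id`, `snap_dist_m`.
#' @export
snap_to_network <- function(x, y, network, max_snap_m = 5000, ids = NULL) {
  nd <- network$nodes
  idx <- vapply(seq_along(x), function(i) {
    which.min((nd$x - x[i])^2 + (nd$y - y[i])^2)
  }, integer(1))
  d <- sqrt((nd$x[idx] - x)^2 + (nd$y[idx] - y)^2)
  if (any(d > max_snap_m)) {
    bad <- if (is.null(ids)) which(d > max_snap_m) else ids[d > max_snap_m]
    stop_schema("snap distance exceeds %g m for point(s): %s",
                max_snap_m, paste(bad, collapse = ", "))
  }
  data.frame(node_id = nd$node_id[idx], snap_dist_m = d,
             stringsAsFactors = FALSE)
}

#' Shortest-path travel costs on the road network
#'
#' Areas and facilities are snapped to their nearest network node and costs
#' are shortest-path sums of the chosen impedance between snapped nodes.
#' Snap legs contribute zero cost by default; `snap_speed_kmh` adds them as
#' straight-line legs at that speed.
#'
#' @param areas,facilities validated point tables.
#' @param network a `road_network`.
#' @param impedance `"travel_time"` (minutes) or `"length"` (meters); the
#'   other quantity is computed along its own shortest path as well.
#' @param max_snap_m maximum snap distance (meters).
#' @param allow_unreachable keep unreachable pairs as `Inf` instead of
#'   erroring.
#' @param snap_speed_kmh if non-NULL, add snap legs to the travel time at
#'   this speed (and to the distance as straight-line meters).
#' @return an `od_matrix` with `metric = "network"`.
#' @export
network_costs <- function(areas, facilities, network,
                          impedance = c("travel_time", "length"),
                          max_snap_m = 5000, allow_unreachable = FALSE,
                          snap_speed_kmh = NULL) {
  impedance <- match.arg(impedance)
  g <- network_graph(network$nodes, network$edges)
  sa <- snap_to_network(areas$x, areas$y, network, max_snap_m, areas$area_id)
  sf <- snap_to_network(facilities$x, facilities$y, network, max_snap_m,
                        facilities$facility_id)
  uo <- unique(sa$node_id); ud <- unique(sf$node_id)
  tt <- igraph::distances(g, v = uo, to = ud,
                          weights = igraph::E(g)$travel_time_min,
                          mode = "out")
  dd <- igraph::distances(g, v = uo, to = ud,
                          weights = igraph::E(g)$length_m,
                          mode = "out")
  io <- match(sa$node_id, uo); id <- match(sf$node_id, ud)
  time <- tt[io, id, drop = FALSE]
  dist <- dd[io, id, drop = FALSE]
  dimnames(time) <- dimnames(dist) <-
    list(areas$area_id, facilities$facility_id)
  if (!is.null(snap_speed_kmh)) {
    leg <- outer(sa$snap_dist_m, sf$snap_dist_m, "+")
    dist <- dist + leg
    time <- time + leg / 1000 / snap_speed_kmh * 60
  }
  if (!allow_unreachable && any(!is.finite(time))) {
    bad <- which(!is.finite(time), arr.ind = TRUE)
    pairs <- paste0(rownames(time)[bad[, 1]], "->",
                    colnames(time)[bad[, 2]])
    stop_schema("unreachable pair(s): %s",
                paste(head(pairs, 10), collapse = ", "))
  }
  od <- new_od(time, dist, "network")
  if (impedance == "length") od <- structure(
    list(time = dist, dist = dist, metric = "network"), class = "od_matrix")
  od
}

#' Subset an OD matrix
#'
#' @param od an `od_matrix`.
#' @param origins,destinations id vectors (NULL keeps all).
#' @return the restricted `od_matrix`.
#' @export
od_subset <- function(od, origins = NULL, destinations = NULL) {
  o <- if (is.null(origins)) rownames(od$time) else origins
  d <- if (is.null(destinations)) colnames(od$time) else destinations
  missing_o <- setdiff(o, rownames(od$time))
  missing_d <- setdiff(d, colnames(od$time))
  if (length(missing_o) || length(missing_d))
    stop_schema("od_subset: unknown ids: %s",
                paste(c(missing_o, missing_d), collapse = ", "))
  new_od(od$time[o, d, drop = FALSE], od$dist[o, d, drop = FALSE], od$metric)
}

# neighbors of a set of units at one adjacency level, symmetric closure
.neighbors_of <- function(units, adjacency, lvl) {
  a <- adjacency[adjacency$level == lvl, , drop = FALSE]
  unique(c(a$neighbor_id[a$unit_id %in% units],
           a$unit_id[a$neighbor_id %in% units]))
}

#' Attribute facilities to administrative units
#'
#' Facility layers carry no unit identifiers; each facility inherits the
#' commune and region of its nearest residential area (straight-line).
#'
#' @param facilities,areas validated point tables.
#' @return `facilities` with `commune_id` and `region_id` columns added.
#' @export
facility_units <- function(facilities, areas) {
  idx <- vapply(seq_len(nrow(facilities)), function(i) {
    which.min((areas$x - facilities$x[i])^2 + (areas$y - facilities$y[i])^2)
  }, integer(1))
  facilities$commune_id <- areas$commune_id[idx]
  facilities$region_id <- areas$region_id[idx]
  facilities
}

#' Plan region-wise processing chunks
#'
#' Residential areas are processed by region; the candidate facilities of a
#' chunk are those in the region plus, for the proximity range, those in
#' neighboring departments, and for the tertiary range, those in
#' neighboring regions. Department membership comes from an optional
#' commune-to-department map (`commune_dept`); without one, each commune is
#' its own department.
#'
#' @param areas validated area table.
#' @param facilities validated facility table (unit ids are attributed via
#'   [facility_units()] if absent).
#' @param adjacency adjacency data frame (`unit_id,neighbor_id,level`).
#' @param commune_dept optional data frame `commune_id,department_id`.
#' @return list of chunk plans, one per region: each a list with
#'   `region_id`, `area_ids`, and `candidates` (a list with `proximity` and
#'   `tertiary` facility-id vectors).
#' @export
plan_chunks <- function(areas, facilities, adjacency, commune_dept = NULL) {
  if (!all(c("commune_id", "region_id") %in% names(facilities)))
    facilities <- facility_units(facilities, areas)
  known_regions <- unique(c(
    adjacency$unit_id[adjacency$level == "region"],
    adjacency$neighbor_id[adjacency$level == "region"]))
  dept_of <- function(commune) {
    if (is.null(commune_dept)) return(commune)
    m <- commune_dept$department_id[match(commune, commune_dept$commune_id)]
    ifelse(is.na(m), commune, m)
  }
  regions <- sort(unique(areas$region_id))
  missing <- setdiff(regions, known_regions)
  if (length(missing) > 0 && nrow(adjacency[adjacency$level == "region", ]) > 0)
    stop_schema("plan_chunks: region(s) absent from adjacency: %s",
                paste(missing, collapse = ", "))
  fac_dept <- dept_of(facilities$commune_id)
  lapply(regions, function(r) {
    in_region <- facilities$region_id == r
    region_depts <- unique(dept_of(areas$commune_id[areas$region_id == r]))
    nb_depts <- .neighbors_of(region_depts, adjacency, "department")
    prox <- in_region | fac_dept %in% setdiff(nb_depts, region_depts)
    nb_regions <- .neighbors_of(r, adjacency, "region")
    tert <- in_region | facilities$region_id %in% setdiff(nb_regions, r)
    list(region_id = r,
         area_ids = areas$area_id[areas$region_id == r],
         candidates = list(
           proximity = facilities$facility_id[prox],
           tertiary = facilities$facility_id[tert]))
  })
}
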