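# Reading, validation and writing of the point layers, road network,
# OD matrices and result tables. All geometry must be in one projected
# planar CRS (coordinates in meters); lon/lat input is refused.

.area_fields <- c("area_id", "x", "y", "population",
                  "iris_id", "commune_id", "region_id")
.facility_fields <- c("facility_id", "x", "y", "facility_type",
                      "range_class", "n_professionals")

stop_schema <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("scaleaccess_schema_error", "scaleaccess_error")))
}

stop_crs <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("scaleaccess_crs_error", "scaleaccess_error")))
}

.check_planar <- function(df, what) {
  if (nrow(df) > 0 && all(abs(df$x) <= 180) && all(abs(df$y) <= 90))
    stop_crs(paste0("%s coordinates look like lon/lat degrees ",
                    "(all |x| <= 180 and |y| <= 90); a projected planar CRS ",
                    "in meters is required"), what)
  invisible(df)
}

.require_fields <- function(df, fields, what) {
  missing <- setdiff(fields, names(df))
  if (length(missing) > 0)
    stop_schema("%s: missing required field(s): %s",
                what, paste(missing, collapse = ", "))
  invisible(df)
}

#' Validate a residential-area table
#'
#' Checks the invariants of the residential-area layer: unique `area_id`,
#' non-negative population, non-empty `iris_id`, consistent nesting
#' (one commune per IRIS, one region per commune) and planar coordinates.
#'
#' @param areas data frame with columns `area_id`, `x`, `y`, `population`,
#'   `iris_id`, `commune_id`, `region_id`.
#' @return the validated data frame, invisibly coerced to canonical types.
#' @export
validate_areas <- function(areas) {
  .require_fields(areas, .area_fields, "areas")
  areas$area_id <- as.character(areas$area_id)
  for (f in c("iris_id", "commune_id", "region_id"))
    areas[[f]] <- as.character(areas[[f]])
  if (anyDuplicated(areas$area_id))
    stop_schema("areas: duplicated area_id: %s",
                paste(unique(areas$area_id[duplicated(areas$area_id)]),
                      collapse = ", "))
  if (any(!is.finite(areas$population)) || any(areas$population < 0))
    stop_schema("areas: population must be finite and >= 0")
  if (any(is.na(areas$iris_id) | areas$iris_id == ""))
    stop_schema("areas: every area needs a non-empty iris_id")
  .check_planar(areas, "areas")
  # nesting: one commune per iris, one region per commune
  by_iris <- tapply(areas$commune_id, areas$iris_id,
                    function(v) length(unique(v)))
  if (any(by_iris > 1))
    stop_schema("areas: iris mapped to multiple communes: %s",
                paste(names(by_iris)[by_iris > 1], collapse = ", "))
  by_com <- tapply(areas$region_id, areas$commune_id,
                   function(v) length(unique(v)))
  if (any(by_com > 1))
    stop_schema("areas: commune mapped to multiple regions: %s",
                paste(names(by_com)[by_com > 1], collapse = ", "))
  areas
}

#' Validate a facility table
#'
#' @param facilities data frame with columns `facility_id`, `x`, `y`,
#'   `facility_type`, `range_class`, `n_professionals`.
#' @param catalogue optional character vector of admissible facility types;
#'   an unknown type raises a schema error.
#' @return the validated data frame.
#' @export
validate_facilities <- function(facilities, catalogue = NULL) {
  if (!"n_professionals" %in% names(facilities))
    facilities$n_professionals <- 1L
  .require_fields(facilities, .facility_fields, "facilities")
  facilities$facility_id <- as.character(facilities$facility_id)
  facilities$facility_type <- as.character(facilities$facility_type)
  facilities$range_class <- as.character(facilities$range_class)
  if (anyDuplicated(facilities$facility_id))
    stop_schema("facilities: duplicated facility_id: %s",
                paste(unique(facilities$facility_id[
                  duplicated(facilities$facility_id)]), collapse = ", "))
  if (any(!facilities$range_class %in% c("proximity", "tertiary")))
    stop_schema("facilities: range_class must be 'proximity' or 'tertiary'")
  np <- facilities$n_professionals
  if (any(!is.finite(np)) || any(np < 1) || any(np != round(np)))
    stop_schema("facilities: n_professionals must be an integer >= 1")
  if (!is.null(catalogue)) {
    bad <- setdiff(unique(facilities$facility_type), catalogue)
    if (length(bad) > 0)
      stop_schema("facilities: facility_type not in catalogue: %s",
                  paste(bad, collapse = ", "))
  }
  .check_planar(facilities, "facilities")
  facilities
}

.read_point_layer <- function(path, format, id_field) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE))
      "geojson" else "csv"
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else if (format == "geojson") {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(gj$features))
      stop_schema("%s: not a GeoJSON FeatureCollection", path)
    rows <- lapply(gj$features, function(f) {
      if (is.null(f$geometry) || !identical(f$geometry$type, "Point"))
        stop_schema("%s: only Point features are supported", path)
      props <- f$properties
      props$x <- f$geometry$coordinates[[1]]
      props$y <- f$geometry$coordinates[[2]]
      as.data.frame(props, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else stop_schema("unknown format: %s", format)
  if (is.null(df) || nrow(df) == 0)
    stop_schema("%s: no records", path)
  df
}

#' Read a residential-area layer
#'
#' Reads residential-area points (population located at the centroid of
#' each residential area) from CSV or GeoJSON and validates them.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"geojson"`.
#' @return a validated data frame of residential areas.
#' @export
read_areas <- function(path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  validate_areas(.read_point_layer(path, format, "area_id"))
}

#' Read a facility layer
#'
#' @inheritParams read_areas
#' @param catalogue optional vector of admissible facility types.
#' @return a validated data frame of facilities.
#' @export
read_facilities <- function(path, format = c("auto", "csv", "geojson"),
                            catalogue = NULL) {
  format <- match.arg(format)
  validate_facilities(.read_point_layer(path, format, "facility_id"),
                      catalogue = catalogue)
}

#' Read a road network from node and edge CSV files
#'
#' Nodes: `node_id,x,y`. Edges: `from_node,to_node,length_m,travel_time_min`
#' with an optional `oneway` (0/1) column; edges are bidirectional unless
#' `oneway` is 1. A connected-component report is attached.
#'
#' @param nodes_path path to the node CSV.
#' @param edges_path path to the edge CSV.
#' @return an object of class `road_network`: a list with `nodes`, `edges`,
#'   and `components` (the [igraph::components()] report).
#' @export
read_network <- function(nodes_path, edges_path) {
  if (!file.exists(nodes_path)) stop_schema("file not found: %s", nodes_path)
  if (!file.exists(edges_path)) stop_schema("file not found: %s", edges_path)
  nodes <- read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- read.csv(edges_path, stringsAsFactors = FALSE)
  .require_fields(nodes, c("node_id", "x", "y"), "network nodes")
  .require_fields(edges, c("from_node", "to_node", "length_m",
                           "travel_time_min"), "network edges")
  make_network(nodes, edges)
}

#' Build a road-network object from node and edge tables
#'
#' @param nodes data frame `node_id,x,y`.
#' @param edges data frame `from_node,to_node,length_m,travel_time_min`
#'   (+ optional `oneway`).
#' @return an object of class `road_network`.
#' @export
make_network <- function(nodes, edges) {
  if (nrow(edges) == 0) stop_schema("empty network")
  nodes$node_id <- as.character(nodes$node_id)
  edges$from_node <- as.character(edges$from_node)
  edges$to_node <- as.character(edges$to_node)
  if (anyDuplicated(nodes$node_id))
    stop_schema("network: duplicated node_id")
  unknown <- setdiff(c(edges$from_node, edges$to_node), nodes$node_id)
  if (length(unknown) > 0)
    stop_schema("network: edge references unknown node(s): %s",
                paste(unknown, collapse = ", "))
  if (any(edges$length_m <= 0) || any(edges$travel_time_min <= 0))
    stop_schema("network: length_m and travel_time_min must be > 0")
  if (!"oneway" %in% names(edges)) edges$oneway <- 0L
  g <- network_graph(nodes, edges)
  structure(list(nodes = nodes, edges = edges,
                 components = igraph::components(g)),
            class = "road_network")
}

# igraph object; undirected edges are entered in both directions so that a
# mixed one-way network stays a single directed graph
network_graph <- function(nodes, edges) {
  two_way <- edges[edges$oneway == 0, , drop = FALSE]
  rev <- two_way
  rev$from_node <- two_way$to_node
  rev$to_node <- two_way$from_node
  all_e <- rbind(edges, rev)
  g <- igraph::graph_from_data_frame(
    all_e[, c("from_node", "to_node", "length_m", "travel_time_min")],
    directed = TRUE,
    vertices = nodes[, c("node_id", "x", "y")])
  g
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("road network: %d nodes, %d edges, %d connected component(s)\n",
              nrow(x$nodes), nrow(x$edges), x$components$no))
  invisible(x)
}

#' Read a long-format OD matrix CSV
#'
#' Columns: `origin_id,destination_id,travel_time_min,distance_m`. Pairs
#' absent from the file are unreachable (`Inf`).
#'
#' @param path file path.
#' @param metric tag recorded on the matrix (`"euclidean"` or `"network"`).
#' @return an `od_matrix` object.
#' @export
read_od <- function(path, metric = "network") {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_fields(df, c("origin_id", "destination_id", "travel_time_min",
                        "distance_m"), "od matrix")
  o <- sort(unique(as.character(df$origin_id)))
  d <- sort(unique(as.character(df$destination_id)))
  tt <- matrix(Inf, length(o), length(d), dimnames = list(o, d))
  dd <- tt
  idx <- cbind(match(as.character(df$origin_id), o),
               match(as.character(df$destination_id), d))
  tt[idx] <- df$travel_time_min
  dd[idx] <- df$distance_m
  new_od(tt, dd, metric)
}

#' Write an OD matrix to long-format CSV
#'
#' @param od an `od_matrix`.
#' @param path output path.
#' @param drop_unreachable omit infinite-cost pairs (default TRUE).
#' @export
write_od <- function(od, path, drop_unreachable = TRUE) {
  stopifnot(inherits(od, "od_matrix"))
  df <- data.frame(
    origin_id = rep(rownames(od$time), times = ncol(od$time)),
    destination_id = rep(colnames(od$time), each = nrow(od$time)),
    travel_time_min = as.vector(od$time),
    distance_m = as.vector(od$dist),
    stringsAsFactors = FALSE)
  if (drop_unreachable) df <- df[is.finite(df$travel_time_min), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table to CSV or GeoJSON
#'
#' CSV writes the table as-is. GeoJSON requires `x`/`y` columns and writes
#' Point features with the remaining columns as properties. A write/read
#' round trip reproduces all numeric values to better than 1e-9 relative.
#'
#' @param results non-empty data frame.
#' @param path output path.
#' @param format `"csv"` or `"geojson"`.
#' @export
write_results <- function(results, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (is.null(results) || nrow(results) == 0)
    stop_schema("write_results: empty results")
  if (format == "csv") {
    out <- results
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) sprintf("%.12g", v))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!all(c("x", "y") %in% names(results)))
      stop_schema("write_results: geojson output needs x and y columns")
    props <- setdiff(names(results), c("x", "y"))
    feats <- lapply(seq_len(nrow(results)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(results$x[i], results$y[i])),
           properties = as.list(results[i, props, drop = FALSE]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an adjacency table for regions and departments
#'
#' Long CSV `unit_id,neighbor_id,level` with `level` in
#' `{region, department}`. Neighborhood is treated as symmetric.
#'
#' @param path file path.
#' @return the adjacency data frame.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  adj <- read.csv(path, stringsAsFactors = FALSE)
  .require_fields(adj, c("unit_id", "neighbor_id", "level"), "adjacency")
  if (any(!adj$level %in% c("region", "department")))
    stop_schema("adjacency: level must be 'region' or 'department'")
  adj
}
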