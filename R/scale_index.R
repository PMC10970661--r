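# The SCALE index fit: orchestrates catchment radii, ZAPs, pressure,
# PADs, normal-score standardization and linear combination, and returns
# a classed object with the usual accessor methods.

#' Compute the SCALE spatial accessibility index
#'
#' Runs the five-step computation for every residential area: (1) per
#' (IRIS, facility type), the catchment radius is the longest travel time
#' to the nearest facility among the unit's areas; (2) the radius delimits
#' each area's potential accessibility area (ZAP); (3) facility pressure
#' is estimated by travel-cost Voronoi assignment of population, per
#' professional; (4) the potential accessibility distance (PAD) is the
#' pressure-weighted mean cost to the ZAP members; (5) PADs are
#' transformed to standard-normal scores per type and combined linearly,
#' with decile categorization (decile 1 = best accessibility under the
#' default sign convention).
#'
#' @param areas residential-area data frame (validated on entry).
#' @param facilities facility data frame (validated on entry).
#' @param od optional precomputed `od_matrix` covering all (area,
#'   facility) pairs; if NULL, costs are computed from `network` (when
#'   given and `metric = "network"`) or by straight line.
#' @param network optional `road_network`.
#' @param metric `"auto"` (network if available), `"euclidean"` or
#'   `"network"`.
#' @param speed_kmh speed for the euclidean metric.
#' @param impedance `"travel_time"` or `"length"` for network costs.
#' @param adjacency optional adjacency table enabling region-wise
#'   candidate restriction (proximity types: region + neighboring
#'   departments; tertiary types: region + neighboring regions).
#' @param commune_dept optional commune-to-department map for the
#'   proximity rule.
#' @param weight_mode PAD weighting: `"pressure"` (default) or
#'   `"inverse_pressure"`.
#' @param normalization `"rank_normal"` (Blom scores, default) or
#'   `"zscore"`.
#' @param sign_convention `-1` (default: larger SCALE = better access)
#'   or `1`.
#' @param weights optional named per-type weights for the combination
#'   (default: equal).
#' @param radius_scope `"per_type"` (default: one radius per (IRIS,
#'   type)) or `"global"` (one radius per IRIS, the max across types,
#'   shared by all types).
#' @param max_snap_m maximum network snap distance (meters).
#' @return an object of class `scale_index` with components `results`
#'   (area-level table: ids, coordinates, `pad_<type>`, `z_<type>`,
#'   `scale_value`, `decile`), `pads`, `zaps`, `pressure`, `nearest`,
#'   `radii`, `od`, and `config`.
#' @seealso [aggregate.scale_index()], [run_pipeline()]
#' @examples
#' geo <- synth_geography(synth_config(seed = 7, n_areas = 120,
#'   facility_spec = data.frame(facility_type = c("gp", "pharmacist"),
#'     range_class = "proximity", count = c(10, 5),
#'     placement = "population_biased"), network = NULL))
#' fit <- scale_index(geo$areas, geo$facilities)
#' fit
#' head(fit$results)
#' @export
scale_index <- function(areas, facilities, od = NULL, network = NULL,
                        metric = c("auto", "euclidean", "network"),
                        speed_kmh = 50,
                        impedance = c("travel_time", "length"),
                        adjacency = NULL, commune_dept = NULL,
                        weight_mode = c("pressure", "inverse_pressure"),
                        normalization = c("rank_normal", "zscore"),
                        sign_convention = -1, weights = NULL,
                        radius_scope = c("per_type", "global"),
                        max_snap_m = 5000) {
  metric <- match.arg(metric)
  impedance <- match.arg(impedance)
  weight_mode <- match.arg(weight_mode)
  normalization <- match.arg(normalization)
  radius_scope <- match.arg(radius_scope)
  areas <- validate_areas(areas)
  facilities <- validate_facilities(facilities)

  if (is.null(od)) {
    use_network <- !is.null(network) && metric != "euclidean"
    if (metric == "network" && is.null(network))
      stop_schema("scale_index: metric = 'network' requires a network")
    od <- if (use_network)
      network_costs(areas, facilities, network, impedance = impedance,
                    max_snap_m = max_snap_m)
    else euclidean_costs(areas, facilities, speed_kmh = speed_kmh)
  }

  chunks <- if (is.null(adjacency)) {
    list(list(region_id = NA_character_, area_ids = areas$area_id,
              candidates = list(proximity = facilities$facility_id,
                                tertiary = facilities$facility_id)))
  } else plan_chunks(areas, facilities, adjacency, commune_dept)

  types <- sort(unique(facilities$facility_type))
  # candidate facilities of one type for one chunk; a region whose
  # neighborhood holds no facility of the type falls back to the full
  # set (chunking is an optimization, not a reachability constraint)
  chunk_candidates <- function(ch, fac_t) {
    cand <- intersect(ch$candidates[[fac_t$range_class[1]]],
                      fac_t$facility_id)
    if (length(cand) == 0) {
      warning(sprintf(
        "no candidate '%s' facility near region %s; using the full set",
        fac_t$facility_type[1], ch$region_id), call. = FALSE)
      cand <- fac_t$facility_id
    }
    cand
  }
  nearest_l <- list(); radii_l <- list(); zap_l <- list()
  pressure_l <- list()
  for (ty in types) {
    fac_t <- facilities[facilities$facility_type == ty, , drop = FALSE]
    nn <- do.call(rbind, lapply(chunks, function(ch) {
      nearest_per_area(od_subset(od, ch$area_ids,
                                 chunk_candidates(ch, fac_t)), ty)
    }))
    radii_l[[ty]] <- iris_radius(nn, areas)
    nearest_l[[ty]] <- nn
    # pressure on the full candidate set of the type, not ZAP-restricted
    pressure_l[[ty]] <- compute_pressure(
      areas, fac_t, od_subset(od, NULL, fac_t$facility_id))
  }
  if (radius_scope == "global") {
    all_r <- do.call(rbind, radii_l)
    gmax <- tapply(all_r$radius, all_r$iris_id, max)
    radii_l <- lapply(radii_l, function(r) {
      r$radius <- as.numeric(gmax[r$iris_id]); r })
  }
  for (ty in types) {
    fac_t <- facilities[facilities$facility_type == ty, , drop = FALSE]
    zap_l[[ty]] <- do.call(rbind, suppressWarnings(lapply(
      chunks, function(ch)
        zap_members(od_subset(od, ch$area_ids,
                              chunk_candidates(ch, fac_t)),
                    radii_l[[ty]], areas, ty))))
  }

  pads <- pad_all(zap_l, od, pressure_l, weight_mode)
  pad_wide <- stats::reshape(pads, idvar = "area_id",
                             timevar = "facility_type", direction = "wide")
  names(pad_wide) <- sub("^pad\\.", "pad_", names(pad_wide))
  pad_wide <- pad_wide[match(areas$area_id, pad_wide$area_id), , drop = FALSE]

  z <- sapply(types, function(ty)
    normal_scores(pad_wide[[paste0("pad_", ty)]], normalization))
  if (is.null(dim(z))) z <- matrix(z, ncol = length(types))
  dimnames(z) <- list(areas$area_id, types)
  sv <- combine_scores(z, weights, sign_convention)

  results <- data.frame(
    area_id = areas$area_id, x = areas$x, y = areas$y,
    population = areas$population, iris_id = areas$iris_id,
    commune_id = areas$commune_id, region_id = areas$region_id,
    stringsAsFactors = FALSE)
  for (ty in types) results[[paste0("pad_", ty)]] <-
    pad_wide[[paste0("pad_", ty)]]
  for (ty in types) results[[paste0("z_", ty)]] <- z[, ty]
  results$scale_value <- as.numeric(sv)
  results$decile <- if (nrow(results) >= 10)
    decile_classify(results$scale_value) else NA_integer_

  structure(list(results = results, pads = pads, zaps = zap_l,
                 pressure = do.call(rbind, pressure_l),
                 nearest = do.call(rbind, nearest_l),
                 radii = radii_l, od = od,
                 config = list(metric = od$metric, impedance = impedance,
                               weight_mode = weight_mode,
                               normalization = normalization,
                               sign_convention = sign_convention,
                               weights = weights,
                               radius_scope = radius_scope),
                 call = match.call()),
            class = "scale_index")
}

#' @export
print.scale_index <- function(x, ...) {
  cat("SCALE spatial accessibility index\n")
  cat(sprintf("  %d residential areas, %d facility types, metric: %s\n",
              nrow(x$results),
              length(unique(x$pads$facility_type)), x$config$metric))
  cat(sprintf("  weight mode: %s, normalization: %s, sign: %+d\n",
              x$config$weight_mode, x$config$normalization,
              x$config$sign_convention))
  cat(sprintf("  scale_value range: [%.3f, %.3f]\n",
              min(x$results$scale_value), max(x$results$scale_value)))
  invisible(x)
}

#' @export
summary.scale_index <- function(object, ...) {
  types <- sort(unique(object$pads$facility_type))
  pad_summary <- t(sapply(types, function(ty)
    summary(object$pads$pad[object$pads$facility_type == ty])))
  out <- list(n_areas = nrow(object$results), types = types,
              pad_summary = pad_summary,
              scale_summary = summary(object$results$scale_value),
              decile_counts = table(object$results$decile),
              config = object$config)
  class(out) <- "summary.scale_index"
  out
}

#' @export
print.summary.scale_index <- function(x, ...) {
  cat(sprintf("SCALE index over %d residential areas\n", x$n_areas))
  cat("\nPAD (potential accessibility distance) by facility type:\n")
  print(round(x$pad_summary, 3))
  cat("\nscale_value:\n")
  print(x$scale_summary)
  cat("\ndecile counts (1 = best accessibility):\n")
  print(x$decile_counts)
  invisible(x)
}

#' Map of the index
#'
#' Plots the residential areas colored by decile (decile 1 = best
#' accessibility, green; decile 10 = worst, red).
#'
#' @param x a `scale_index` fit.
#' @param ... passed to [plot()].
#' @export
plot.scale_index <- function(x, ...) {
  r <- x$results
  pal <- hcl.colors(10, "RdYlGn", rev = TRUE)
  plot(r$x, r$y, col = pal[r$decile], pch = 16, asp = 1,
       xlab = "x (m)", ylab = "y (m)",
       main = "SCALE index (decile 1 = best accessibility)", ...)
  legend("topright", legend = c("D1 (best)", "D5", "D10 (worst)"),
         col = pal[c(1, 5, 10)], pch = 16, bty = "n")
  invisible(x)
}

#' Aggregate a SCALE fit to a larger geographical unit
#'
#' @param x a `scale_index` fit.
#' @param level `"iris"`, `"commune"` or `"region"`.
#' @param criterion `"min"`, `"max"`, `"mean"` or `"weighted_mean"`.
#' @param ... unused.
#' @return see [aggregate_index()].
#' @export
aggregate.scale_index <- function(x, level = "iris", criterion = "mean",
                                  ...) {
  aggregate_index(x$results, x$results, level = level,
                  criterion = criterion)
}

#' @export
as.data.frame.scale_index <- function(x, ...) x$results
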