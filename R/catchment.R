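# Catchment construction: nearest facility per area, IRIS-level potential
# accessibility radius (the longest nearest-facility travel time among the
# IRIS's areas), and the per-area ZAP facility set.

#' Nearest facility per residential area
#'
#' For one facility type, the minimum travel cost over the candidate
#' facilities; ties are broken by the lexicographically smallest
#' facility_id so output is reproducible.
#'
#' @param od an `od_matrix` already restricted to facilities of one type
#'   (and to the chunk's candidate set, if chunking is used).
#' @param facility_type label recorded on the output.
#' @return data frame `area_id, facility_type, nearest_facility_id,
#'   nearest_cost`.
#' @export
nearest_per_area <- function(od, facility_type = NA_character_) {
  tt <- od$time
  if (ncol(tt) == 0)
    stop_schema("nearest_per_area: no candidate facilities")
  ord <- order(colnames(tt))
  tt <- tt[, ord, drop = FALSE]
  unreachable <- rowSums(is.finite(tt)) == 0
  if (any(unreachable))
    stop_schema("no reachable facility of type '%s' for area(s): %s",
                facility_type,
                paste(rownames(tt)[unreachable], collapse = ", "))
  j <- apply(tt, 1, which.min)  # first minimum = smallest id after ordering
  data.frame(area_id = rownames(tt),
             facility_type = facility_type,
             nearest_facility_id = colnames(tt)[j],
             nearest_cost = tt[cbind(seq_len(nrow(tt)), j)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' IRIS-level catchment radius
#'
#' The radius of an IRIS, for one facility type, is the longest travel
#' time to the nearest facility among the IRIS's residential areas: it
#' guarantees that every area of the unit can reach at least one facility
#' within the radius.
#'
#' @param nearest output of [nearest_per_area()].
#' @param areas validated area table (provides `iris_id`).
#' @return data frame `iris_id, facility_type, radius`.
#' @export
iris_radius <- function(nearest, areas) {
  iris <- areas$iris_id[match(nearest$area_id, areas$area_id)]
  if (anyNA(iris))
    stop_schema("iris_radius: areas missing from the area table: %s",
                paste(nearest$area_id[is.na(iris)], collapse = ", "))
  r <- tapply(nearest$nearest_cost, iris, max)
  data.frame(iris_id = names(r),
             facility_type = nearest$facility_type[1],
             radius = as.numeric(r),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ZAP membership per residential area
#'
#' The potential accessibility area (ZAP) of a residential area, for one
#' facility type, is the set of candidate facilities whose travel cost is
#' at most the radius of the area's IRIS. The threshold is inclusive, so
#' the facility that defines the radius is itself a member, and the set is
#' never empty (it always contains the area's nearest facility).
#'
#' @param od `od_matrix` restricted to the type's candidate facilities.
#' @param radii output of [iris_radius()].
#' @param areas validated area table.
#' @param facility_type label recorded on the output.
#' @return data frame `area_id, facility_type, radius` with a list column
#'   `members` of facility-id vectors.
#' @export
zap_members <- function(od, radii, areas, facility_type = NA_character_) {
  tt <- od$time
  iris <- areas$iris_id[match(rownames(tt), areas$area_id)]
  r <- radii$radius[match(iris, radii$iris_id)]
  if (anyNA(r))
    stop_schema("zap_members: no radius for iris: %s",
                paste(unique(iris[is.na(r)]), collapse = ", "))
  members <- lapply(seq_len(nrow(tt)), function(i) {
    m <- colnames(tt)[is.finite(tt[i, ]) & tt[i, ] <= r[i]]
    stopifnot(length(m) > 0)  # radius >= own nearest cost by construction
    sort(m)
  })
  out <- data.frame(area_id = rownames(tt),
                    facility_type = facility_type,
                    radius = r, stringsAsFactors = FALSE, row.names = NULL)
  out$members <- members
  out
}
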