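# Demand pressure by travel-cost Voronoi assignment and the
# pressure-weighted potential accessibility distance (PAD).

#' Facility pressure by Voronoi population assignment
#'
#' Every residential area's full population is assigned to its single
#' nearest facility of the type (a Voronoi mosaic under the travel metric
#' of the OD matrix); pressure is the assigned population per professional.
#' Facilities that capture no population get pressure 0.
#'
#' @param areas validated area table (provides populations).
#' @param facilities facilities of one type.
#' @param od `od_matrix` restricted to those facilities.
#' @return data frame `facility_id, facility_type, assigned_population,
#'   pressure`.
#' @export
compute_pressure <- function(areas, facilities, od) {
  nn <- nearest_per_area(od, facility_type = facilities$facility_type[1])
  pop <- areas$population[match(nn$area_id, areas$area_id)]
  assigned <- tapply(pop, nn$nearest_facility_id, sum)
  out <- data.frame(facility_id = facilities$facility_id,
                    facility_type = facilities$facility_type,
                    stringsAsFactors = FALSE)
  out$assigned_population <- as.numeric(assigned[out$facility_id])
  out$assigned_population[is.na(out$assigned_population)] <- 0
  out$pressure <- out$assigned_population / facilities$n_professionals
  out
}

#' Potential accessibility distance for one area
#'
#' The PAD is the weighted mean travel cost from the area to the members
#' of its ZAP. Under the default `weight_mode = "pressure"` the weight of
#' member j is its pressure, so heavily loaded facilities dominate the
#' mean; `"inverse_pressure"` uses 1/pressure, so available facilities
#' dominate. If all weights are zero the unweighted mean is used.
#'
#' @param costs named numeric vector of travel costs to the ZAP members.
#' @param pressures named numeric vector of member pressures (same names).
#' @param weight_mode `"pressure"` or `"inverse_pressure"`.
#' @return the PAD (same unit as `costs`).
#' @export
compute_pad <- function(costs, pressures,
                        weight_mode = c("pressure", "inverse_pressure")) {
  weight_mode <- match.arg(weight_mode)
  if (length(costs) == 0) stop_schema("compute_pad: empty ZAP")
  p <- pressures[names(costs)]
  if (anyNA(p))
    stop_schema("compute_pad: missing pressure for member(s): %s",
                paste(names(costs)[is.na(p)], collapse = ", "))
  w <- if (weight_mode == "pressure") p else {
    # invert positive pressures; zero-pressure members take the largest
    # inverse weight present so they stay maximally available
    inv <- ifelse(p > 0, 1 / p, NA_real_)
    if (all(is.na(inv))) rep(0, length(p))
    else { inv[is.na(inv)] <- max(inv, na.rm = TRUE); inv }
  }
  if (sum(w) <= 0) return(mean(costs))
  sum(w * costs) / sum(w)
}

#' PAD table over all areas and facility types
#'
#' @param zaps list of ZAP tables (one per facility type, from
#'   [zap_members()]).
#' @param od full `od_matrix` (all facilities).
#' @param pressures list (or row-bound data frame) of pressure tables.
#' @param weight_mode passed to [compute_pad()].
#' @return data frame `area_id, facility_type, pad`, one row per
#'   (area, type).
#' @export
pad_all <- function(zaps, od, pressures,
                    weight_mode = c("pressure", "inverse_pressure")) {
  weight_mode <- match.arg(weight_mode)
  if (is.data.frame(pressures)) pressures <- list(pressures)
  if (is.data.frame(zaps)) zaps <- list(zaps)
  ptab <- do.call(rbind, lapply(pressures, function(p)
    p[, c("facility_id", "pressure")]))
  pvec <- setNames(ptab$pressure, ptab$facility_id)
  out <- lapply(zaps, function(z) {
    pad <- vapply(seq_len(nrow(z)), function(i) {
      m <- z$members[[i]]
      compute_pad(setNames(od$time[z$area_id[i], m], m), pvec, weight_mode)
    }, numeric(1))
    data.frame(area_id = z$area_id, facility_type = z$facility_type,
               pad = pad, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
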