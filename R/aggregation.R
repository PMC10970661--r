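# Multiscalar aggregation of area-level SCALE values to IRIS, commune or
# region under four criteria, with decile re-categorization per version
# and between-version ranking agreement.

.unit_col <- c(iris = "iris_id", commune = "commune_id", region = "region_id")

#' Aggregate SCALE values to a larger geographical unit
#'
#' Per-unit statistic over the member residential areas: minimum, maximum,
#' mean, or population-weighted mean. Deciles are recomputed from the
#' aggregated version's own distribution, so each (level, criterion)
#' version has its own categorization.
#'
#' @param results data frame with `area_id` and `scale_value` (e.g. the
#'   `results` table of a [scale_index()] fit).
#' @param areas validated area table (unit ids and populations).
#' @param level `"iris"`, `"commune"` or `"region"`.
#' @param criterion `"min"`, `"max"`, `"mean"` or `"weighted_mean"`.
#' @param deciles recompute deciles when the level has >= 10 units
#'   (default TRUE; fewer units leave the decile column NA).
#' @return data frame `unit_id, level, criterion, value, decile`.
#' @export
aggregate_index <- function(results, areas,
                            level = c("iris", "commune", "region"),
                            criterion = c("min", "max", "mean",
                                          "weighted_mean"),
                            deciles = TRUE) {
  level <- match.arg(level)
  criterion <- match.arg(criterion)
  m <- match(results$area_id, areas$area_id)
  if (anyNA(m))
    stop_schema("aggregate_index: unknown area(s): %s",
                paste(results$area_id[is.na(m)], collapse = ", "))
  unit <- areas[[.unit_col[level]]][m]
  pop <- areas$population[m]
  v <- split(results$scale_value, unit)
  p <- split(pop, unit)
  value <- switch(criterion,
    min = vapply(v, min, numeric(1)),
    max = vapply(v, max, numeric(1)),
    mean = vapply(v, mean, numeric(1)),
    weighted_mean = mapply(function(vi, pi) {
      if (sum(pi) == 0) {
        warning("aggregate_index: unit with zero total population; ",
                "falling back to plain mean")
        mean(vi)
      } else sum(vi * pi) / sum(pi)
    }, v, p))
  out <- data.frame(unit_id = names(v), level = level,
                    criterion = criterion, value = as.numeric(value),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$decile <- if (deciles && nrow(out) >= 10)
    decile_classify(out$value) else NA_integer_
  out
}

#' Percent of units identically ranked by two index versions
#'
#' Compares the decile labels of the same units under two aggregation
#' versions and returns the percentage classified identically.
#'
#' @param deciles_a,deciles_b named integer vectors (names = unit ids) or
#'   data frames with `unit_id` and `decile`.
#' @return percentage in 0..100.
#' @export
agreement <- function(deciles_a, deciles_b) {
  as_vec <- function(d) {
    if (is.data.frame(d)) setNames(d$decile, d$unit_id) else d
  }
  a <- as_vec(deciles_a); b <- as_vec(deciles_b)
  if (is.null(names(a)) || is.null(names(b)))
    stop_schema("agreement: decile vectors must be named by unit_id")
  if (!setequal(names(a), names(b)))
    stop_schema("agreement: unit sets differ")
  b <- b[names(a)]
  100 * mean(a == b)
}

#' Pairwise agreement matrix across aggregation criteria
#'
#' @param results,areas,level as in [aggregate_index()].
#' @param criteria criteria to compare.
#' @return data frame `level, criterion_a, criterion_b, percent_identical`
#'   covering all ordered pairs (symmetric, diagonal 100).
#' @export
agreement_matrix <- function(results, areas, level = "iris",
                             criteria = c("min", "max", "mean",
                                          "weighted_mean")) {
  versions <- lapply(criteria, function(cr)
    aggregate_index(results, areas, level, cr))
  names(versions) <- criteria
  grid <- expand.grid(criterion_a = criteria, criterion_b = criteria,
                      stringsAsFactors = FALSE)
  grid$level <- level
  grid$percent_identical <- mapply(function(a, b)
    agreement(versions[[a]][, c("unit_id", "decile")],
              versions[[b]][, c("unit_id", "decile")]),
    grid$criterion_a, grid$criterion_b)
  grid[, c("level", "criterion_a", "criterion_b", "percent_identical")]
}
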