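# Standardization of PADs to normal scores, linear combination into the
# SCALE index, and decile categorization.

#' Rank-based inverse-normal (Blom) scores
#'
#' Transforms a PAD vector to a reduced centered normal distribution via
#' qnorm((r - 3/8) / (n + 1/4)) on midranks. Strictly monotone in the
#' input; mean 0 by the symmetry of the plotting positions. `"zscore"`
#' gives plain standardization instead.
#'
#' @param x numeric vector, length >= 2, not all values identical.
#' @param normalization `"rank_normal"` (default) or `"zscore"`.
#' @return numeric vector of scores.
#' @export
normal_scores <- function(x, normalization = c("rank_normal", "zscore")) {
  normalization <- match.arg(normalization)
  if (length(x) < 2) stop_schema("normal_scores: need at least 2 values")
  if (diff(range(x)) == 0)
    stop_schema("normal_scores: constant vector carries no ordering")
  if (normalization == "zscore") return(as.numeric(scale(x)))
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Combine standardized scores into the SCALE value
#'
#' scale_value_i = s * sum_k w_k * z_ik. The default sign convention
#' s = -1 makes shorter (better) weighted distances score higher, so a
#' larger SCALE value means better accessibility.
#'
#' @param z matrix of normal scores, one column per facility type, rows
#'   named by area_id.
#' @param weights named non-negative weights per facility type (default:
#'   1 for every column); not all zero.
#' @param sign_convention `-1` (default) or `1`.
#' @return named numeric vector of SCALE values.
#' @export
combine_scores <- function(z, weights = NULL, sign_convention = -1) {
  z <- as.matrix(z)
  if (anyNA(z)) stop_schema("combine_scores: missing z score cell(s)")
  if (is.null(weights)) weights <- setNames(rep(1, ncol(z)), colnames(z))
  w <- weights[colnames(z)]
  if (anyNA(w))
    stop_schema("combine_scores: no weight for type(s): %s",
                paste(colnames(z)[is.na(w)], collapse = ", "))
  if (any(w < 0) || sum(w) == 0)
    stop_schema("combine_scores: weights must be >= 0 and not all zero")
  if (!sign_convention %in% c(-1, 1))
    stop_schema("combine_scores: sign_convention must be -1 or 1")
  drop(sign_convention * (z %*% w))
}

#' Decile categorization
#'
#' Labels 1..10 with label 1 the top decile of the value (highest
#' accessibility). Boundaries are the empirical deciles; tied values share
#' the lower-numbered (better) label of their boundary side.
#'
#' @param values numeric vector, length >= 10.
#' @return integer vector of decile labels.
#' @export
decile_classify <- function(values) {
  n <- length(values)
  if (n < 10) stop_schema("decile_classify: need at least 10 values")
  if (diff(range(values)) == 0) {
    warning("decile_classify: all values equal; single class")
    return(rep(1L, n))
  }
  r <- rank(-values, ties.method = "min")  # 1 = best
  as.integer(ceiling(r * 10 / n))
}
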