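#' Weighted kappa for ordinal rater agreement
#'
#' Chance-corrected agreement between two raters scoring the same items on an
#' ordinal scale, penalizing larger disagreements more:
#' `kappa = 1 - sum(w * O) / sum(w * E)` with disagreement weights
#' `w_ij = |i - j|` (linear, the default) or `(i - j)^2` (quadratic), `O` the
#' observed and `E` the chance-expected cell proportions. The verbal label
#' follows the Landis-Koch convention as commonly printed for skeletal-scoring
#' studies: 0.61-0.79 "substantial", 0.80-1.00 "almost perfect".
#'
#' @param ratings1,ratings2 integer vectors of equal length (>= 2) with
#'   stages in `0:(n_categories - 1)`.
#' @param n_categories number of ordinal categories `K`; defaults to
#'   `max(ratings) + 1`.
#' @param weighting `"linear"` or `"quadratic"`.
#' @return list with `kappa` (NA with `undefined = TRUE` when chance
#'   disagreement is zero, i.e. both raters constant on one category),
#'   `label`, `weighting`, `n`.
#' @examples
#' weighted_kappa(c(0, 1, 2, 2), c(0, 1, 2, 1))
#' @export
weighted_kappa <- function(ratings1, ratings2, n_categories = NULL,
                           weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  stopifnot(length(ratings1) == length(ratings2), length(ratings1) >= 2)
  if (is.null(n_categories)) {
    n_categories <- max(ratings1, ratings2) + 1L
  }
  k <- as.integer(n_categories)
  stopifnot(all(ratings1 %in% 0:(k - 1)), all(ratings2 %in% 0:(k - 1)))
  lev <- 0:(k - 1)
  o <- table(factor(ratings1, levels = lev), factor(ratings2, levels = lev))
  o <- o / sum(o)
  rowm <- rowSums(o); colm <- colSums(o)
  e <- outer(rowm, colm)
  d <- abs(outer(lev, lev, "-"))
  w <- if (weighting == "linear") d else d^2
  denom <- sum(w * e)
  if (denom == 0) {
    return(list(kappa = NA_real_, label = NA_character_,
                weighting = weighting, n = length(ratings1),
                undefined = TRUE))
  }
  kap <- 1 - sum(w * o) / denom
  list(kappa = kap, label = landis_koch_label(kap), weighting = weighting,
       n = length(ratings1), undefined = FALSE)
}

#' @rdname weighted_kappa
#' @param kappa a kappa value.
#' @export
landis_koch_label <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa < 0.80) "substantial"
  else "almost perfect"
}
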