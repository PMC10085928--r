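#' Bias and absolute error of age estimates
#'
#' Bias is the mean signed difference `estimated - chronological` (positive =
#' overestimation, negative = underestimation); absolute error is the mean
#' unsigned difference and measures the magnitude of the method's inaccuracy
#' irrespective of direction. Both are in years.
#'
#' @param pairs data.frame with columns `age` (chronological, years) and
#'   `point_estimate` (years), e.g. the estimated rows of an
#'   [estimate_batch()] result.
#' @return Years (scalar).
#' @export
bias <- function(pairs) {
  stopifnot(nrow(pairs) > 0)
  mean(pairs$point_estimate - pairs$age)
}

#' @rdname bias
#' @export
absolute_error <- function(pairs) {
  stopifnot(nrow(pairs) > 0)
  mean(abs(pairs$point_estimate - pairs$age))
}

#' Default wide age bands for inaccuracy reporting
#'
#' Three bands on chronological age: 15-39, 40-64 and 65+ years. Band edges
#' are closed on the left, so age 64 falls in the middle band and 65 in the
#' oldest.
#'
#' @return data.frame with columns `scope`, `lower`, `upper`.
#' @export
default_age_bands <- function() {
  data.frame(scope = c("15-39", "40-64", ">65"),
             lower = c(15, 40, 65),
             upper = c(39, 64, Inf),
             stringsAsFactors = FALSE)
}

#' Inaccuracy report by age band
#'
#' Summarizes bias and absolute error globally and within wide bands of
#' chronological age. Individuals with a "no estimation" outcome are excluded
#' from the means and reported separately as counts, attributed to bands by
#' their chronological age.
#'
#' @param estimates an [estimate_batch()] result (or any data.frame with
#'   `age`, `status`, `point_estimate`).
#' @param bands band definition as in [default_age_bands()]; must partition
#'   the age axis.
#' @return data.frame with one row per band plus a `"global"` row: `scope`,
#'   `n` (estimated individuals), `bias`, `absolute_error` (years; `NA` when
#'   `n = 0`), `no_estimation_count`.
#' @export
band_report <- function(estimates, bands = default_age_bands()) {
  band_of <- function(age) {
    i <- which(age >= bands$lower & age <= bands$upper)
    if (length(i) != 1) stop("age ", age, " not covered by exactly one band",
                             call. = FALSE)
    bands$scope[i]
  }
  scopes <- vapply(estimates$age, band_of, character(1))
  est <- estimates$status == "estimated"
  one <- function(scope, rows) {
    ok <- rows & est
    data.frame(
      scope = scope,
      n = sum(ok),
      bias = if (any(ok)) bias(estimates[ok, ]) else NA_real_,
      absolute_error = if (any(ok)) absolute_error(estimates[ok, ]) else NA_real_,
      no_estimation_count = sum(rows & !est),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(bands$scope, function(s) one(s, scopes == s)))
  rbind(out, one("global", rep(TRUE, nrow(estimates))))
}
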