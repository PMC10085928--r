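#' Published per-stage age summaries for the acetabular variables
#'
#' Descriptive statistics of chronological age at every stage of the seven
#' acetabular variables, as published for the two documented collections the
#' method has been evaluated on: the Portuguese Luis Lopes collection
#' (population `"PT"`) and the European-American Bass collection
#' (population `"NA"`), separately by sex. Stages never observed in a sample
#' have no row. These summaries calibrate the synthetic-collection presets
#' (see [aging_model_from_anchors()]) and serve as worked-example inputs.
#'
#' @return data.frame with columns `population`, `sex`, `variable`, `stage`,
#'   `n`, `mean_age`, `sd` (years; `sd` is `NA` when `n = 1`).
#' @export
stage_age_anchors <- function() {
  ptm <- rbind(
    data.frame(variable = "v1", stage = 0:3,
               n = c(5, 131, 131, 27),
               mean_age = c(17.40, 48.04, 60.61, 74.74),
               sd = c(2.51, 19.16, 16.25, 9.20)),
    data.frame(variable = "v2", stage = 0:6,
               n = c(4, 20, 33, 39, 130, 52, 16),
               mean_age = c(21.50, 24.20, 32.64, 50.67, 60.19, 70.67, 75.94),
               sd = c(3.87, 9.20, 12.11, 16.13, 13.85, 11.40, 7.15)),
    data.frame(variable = "v3", stage = 0:5,
               n = c(10, 17, 51, 120, 61, 35),
               mean_age = c(17.00, 24.88, 37.84, 57.13, 71.02, 75.09),
               sd = c(1.56, 5.80, 12.01, 12.44, 11.54, 9.42)),
    data.frame(variable = "v4", stage = 0:4,
               n = c(17, 79, 119, 45, 34),
               mean_age = c(24.71, 39.09, 59.49, 71.40, 74.65),
               sd = c(6.25, 14.79, 13.36, 12.93, 9.56)),
    data.frame(variable = "v5", stage = 0:2,
               n = c(174, 102, 18),
               mean_age = c(45.15, 69.58, 76.94),
               sd = c(16.80, 12.21, 8.63)),
    data.frame(variable = "v6", stage = 0:3,
               n = c(26, 47, 177, 44),
               mean_age = c(22.58, 42.85, 59.16, 74.20),
               sd = c(7.51, 15.59, 15.43, 10.05)),
    data.frame(variable = "v7", stage = 0:4,
               n = c(21, 34, 142, 27, 70),
               mean_age = c(21.29, 40.91, 53.56, 67.67, 72.40),
               sd = c(3.89, 15.36, 15.53, 12.89, 11.75))
  )
  nam <- rbind(
    data.frame(variable = "v1", stage = 0:3,
               n = c(6, 250, 157, 43),
               mean_age = c(28.86, 55.90, 65.68, 74.00),
               sd = c(6.27, 15.68, 12.98, 12.09)),
    data.frame(variable = "v2", stage = 1:6,
               n = c(4, 11, 49, 226, 134, 32),
               mean_age = c(25.50, 37.18, 44.73, 60.09, 67.05, 74.16),
               sd = c(5.00, 15.10, 12.18, 13.78, 13.92, 11.90)),
    data.frame(variable = "v3", stage = 1:5,
               n = c(4, 30, 191, 126, 105),
               mean_age = c(30.25, 36.73, 53.55, 68.59, 71.90),
               sd = c(5.74, 9.17, 11.98, 12.49, 12.43)),
    data.frame(variable = "v4", stage = 0:4,
               n = c(3, 52, 196, 114, 91),
               mean_age = c(28.67, 41.92, 58.01, 66.04, 71.19),
               sd = c(8.08, 11.33, 14.27, 12.94, 13.26)),
    data.frame(variable = "v5", stage = 0:2,
               n = c(217, 196, 43),
               mean_age = c(51.24, 67.85, 74.98),
               sd = c(13.83, 12.65, 12.41)),
    data.frame(variable = "v6", stage = 0:3,
               n = c(11, 59, 259, 127),
               mean_age = c(33.55, 48.54, 59.22, 71.43),
               sd = c(7.79, 14.95, 14.60, 11.49)),
    data.frame(variable = "v7", stage = 0:4,
               n = c(7, 35, 170, 44, 200),
               mean_age = c(39.43, 44.43, 53.35, 62.30, 70.00),
               sd = c(7.74, 11.31, 14.74, 13.61, 12.03))
  )
  ptf <- rbind(
    data.frame(variable = "v1", stage = 0:3,
               n = c(4, 157, 115, 41),
               mean_age = c(17.50, 54.89, 69.09, 79.51),
               sd = c(3.00, 21.82, 14.76, 9.28)),
    data.frame(variable = "v2", stage = 0:6,
               n = c(1, 16, 17, 51, 158, 63, 11),
               mean_age = c(15.00, 23.38, 23.88, 52.61, 69.05, 74.11, 75.91),
               sd = c(NA, 6.98, 9.17, 18.92, 14.00, 12.72, 12.47)),
    data.frame(variable = "v3", stage = 0:5,
               n = c(4, 14, 42, 128, 85, 44),
               mean_age = c(17.50, 25.07, 33.00, 63.49, 75.02, 81.39),
               sd = c(1.73, 6.71, 14.20, 13.69, 9.90, 7.38)),
    data.frame(variable = "v4", stage = 0:4,
               n = c(29, 69, 130, 52, 37),
               mean_age = c(26.76, 46.59, 70.62, 73.50, 78.35),
               sd = c(11.06, 19.07, 11.58, 12.84, 10.72)),
    data.frame(variable = "v5", stage = 0:2,
               n = c(134, 158, 25),
               mean_age = c(46.54, 73.56, 81.28),
               sd = c(20.03, 11.09, 8.60)),
    data.frame(variable = "v6", stage = 0:3,
               n = c(33, 21, 168, 95),
               mean_age = c(24.61, 34.76, 65.14, 77.97),
               sd = c(7.67, 12.42, 15.05, 8.27)),
    data.frame(variable = "v7", stage = 0:4,
               n = c(14, 38, 90, 53, 122),
               mean_age = c(20.07, 32.21, 57.28, 70.09, 78.01),
               sd = c(4.16, 12.74, 14.99, 9.47, 9.46))
  )
  naf <- rbind(
    data.frame(variable = "v1", stage = 1:3,
               n = c(172, 146, 52),
               mean_age = c(60.29, 67.86, 72.60),
               sd = c(14.36, 12.43, 14.93)),
    data.frame(variable = "v2", stage = 2:6,
               n = c(1, 25, 200, 116, 28),
               mean_age = c(33.00, 47.04, 64.78, 69.07, 66.96),
               sd = c(NA, 11.91, 13.24, 14.14, 13.11)),
    data.frame(variable = "v3", stage = 2:5,
               n = c(9, 159, 129, 73),
               mean_age = c(37.44, 59.64, 69.39, 72.34),
               sd = c(5.43, 12.15, 12.69, 14.46)),
    data.frame(variable = "v4", stage = 0:4,
               n = c(4, 31, 171, 87, 77),
               mean_age = c(49.75, 48.84, 64.73, 67.36, 70.26),
               sd = c(16.66, 12.76, 13.70, 13.44, 12.67)),
    data.frame(variable = "v5", stage = 0:2,
               n = c(111, 211, 48),
               mean_age = c(55.29, 68.78, 70.90),
               sd = c(12.66, 12.93, 13.96)),
    data.frame(variable = "v6", stage = 0:3,
               n = c(7, 19, 189, 155),
               mean_age = c(44.00, 54.63, 60.48, 72.74),
               sd = c(13.61, 12.02, 13.62, 11.44)),
    data.frame(variable = "v7", stage = 0:4,
               n = c(6, 15, 109, 44, 196),
               mean_age = c(36.17, 46.67, 56.85, 68.89, 70.95),
               sd = c(8.33, 12.02, 11.23, 11.37, 12.53))
  )
  out <- rbind(
    cbind(population = "PT", sex = "M", ptm),
    cbind(population = "NA", sex = "M", nam),
    cbind(population = "PT", sex = "F", ptf),
    cbind(population = "NA", sex = "F", naf)
  )
  rownames(out) <- NULL
  out
}

#' Published age structure of the two documented collections
#'
#' Decade-bin counts of analyzed individuals by population and sex, as
#' published for the Luis Lopes (`"PT"`) and Bass (`"NA"`) collections. These
#' counts weight the age sampler of the synthetic-collection presets and give
#' the documented sample totals.
#'
#' @return data.frame with columns `population`, `sex`, `bin_lower`,
#'   `bin_upper` (inclusive years) and `n`.
#' @export
collection_age_structure <- function() {
  bins_lower <- c(15L, seq(20L, 90L, by = 10L))
  bins_upper <- c(19L, seq(29L, 99L, by = 10L))
  counts <- list(
    PT_M = c(12, 24, 24, 48, 57, 48, 40, 41, 0),
    PT_F = c(13, 25, 14, 18, 47, 45, 85, 60, 10),
    NA_M = c(1, 9, 40, 74, 84, 101, 89, 51, 7),
    NA_F = c(0, 2, 14, 38, 75, 98, 78, 48, 17)
  )
  out <- do.call(rbind, lapply(names(counts), function(k) {
    ps <- strsplit(k, "_", fixed = TRUE)[[1]]
    data.frame(population = ps[1], sex = ps[2],
               bin_lower = bins_lower, bin_upper = bins_upper,
               n = counts[[k]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Published reference/test split sizes
#'
#' Sizes of the reference and test samples used in the four crossed
#' reference/test experiments on the documented collections.
#'
#' @return data.frame with columns `population`, `sex`, `reference`, `test`.
#' @export
reference_test_sizes <- function() {
  data.frame(
    population = c("PT", "PT", "NA", "NA"),
    sex = c("M", "F", "M", "F"),
    reference = c(184L, 201L, 300L, 220L),
    test = c(110L, 116L, 156L, 150L),
    stringsAsFactors = FALSE
  )
}

#' Published no-estimation counts per test/reference pairing
#'
#' Number of individuals for which the estimator returned "no estimation"
#' in each of the eight test-sample / reference-sample pairings of the
#' documented-collection study (four population-matched, four crossed).
#'
#' @return data.frame with columns `test_population`, `test_sex`,
#'   `reference_population`, `reference_sex`, `arm` (`"matched"` or
#'   `"crossed"`) and `no_estimation_count`.
#' @export
published_no_estimation_counts <- function() {
  data.frame(
    test_population = c("PT", "PT", "NA", "NA", "PT", "PT", "NA", "NA"),
    test_sex = c("F", "M", "F", "M", "F", "M", "F", "M"),
    reference_population = c("PT", "PT", "NA", "NA", "NA", "NA", "PT", "PT"),
    reference_sex = c("F", "M", "F", "M", "F", "M", "F", "M"),
    arm = rep(c("matched", "crossed"), each = 4),
    no_estimation_count = c(0L, 1L, 1L, 2L, 14L, 6L, 4L, 3L),
    stringsAsFactors = FALSE
  )
}
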