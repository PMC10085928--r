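#' Per-stage chronological-age summaries
#'
#' For every (variable, stage) combination observed in a collection, reports
#' the number of individuals, their mean chronological age and the sample SD
#' (`NA` when only one individual attained the stage). Missing scores are
#' excluded per variable. This is the timing table used to compare the aging
#' rate of different populations.
#'
#' @param records collection data.frame.
#' @param catalog a [variable_catalog()].
#' @return data.frame with columns `variable`, `stage`, `n`, `mean_age`, `sd`.
#' @export
stage_timing_summary <- function(records, catalog = acetabular_catalog()) {
  rows <- list()
  for (v in names(catalog)) {
    scored <- !is.na(records[[v]])
    if (!any(scored)) next
    ages <- records$age[scored]
    stages <- records[[v]][scored]
    for (s in sort(unique(stages))) {
      a <- ages[stages == s]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stage = as.integer(s), n = length(a),
        mean_age = mean(a),
        sd = if (length(a) > 1) stats::sd(a) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    stop("no scored variables in the collection", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare stage-attainment timing between two populations
#'
#' For every (variable, stage) observed in either collection, summarizes the
#' chronological ages in each and, where the stage occurs in both, applies a
#' two-sided Mann-Whitney U test to the two age samples. A lower mean age at
#' the same stage means that population reaches the stage earlier, i.e. ages
#' faster.
#'
#' @param popA,popB collection data.frames (conventionally one population
#'   each, already restricted to one sex).
#' @param catalog a [variable_catalog()].
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame with columns `variable`, `stage`, `n_a`, `mean_a`,
#'   `sd_a`, `n_b`, `mean_b`, `sd_b`, `u`, `p_value`, `applicable` (FALSE when
#'   the stage occurs in only one population), `significant`.
#' @export
compare_stage_timing <- function(popA, popB, catalog = acetabular_catalog(),
                                 alpha = 0.05) {
  sa <- stage_timing_summary(popA, catalog)
  sb <- stage_timing_summary(popB, catalog)
  keys <- unique(rbind(sa[c("variable", "stage")], sb[c("variable", "stage")]))
  keys <- keys[order(match(keys$variable, names(catalog)), keys$stage), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    v <- keys$variable[i]; s <- keys$stage[i]
    ra <- sa[sa$variable == v & sa$stage == s, ]
    rb <- sb[sb$variable == v & sb$stage == s, ]
    out <- data.frame(
      variable = v, stage = s,
      n_a = if (nrow(ra)) ra$n else 0L,
      mean_a = if (nrow(ra)) ra$mean_age else NA_real_,
      sd_a = if (nrow(ra)) ra$sd else NA_real_,
      n_b = if (nrow(rb)) rb$n else 0L,
      mean_b = if (nrow(rb)) rb$mean_age else NA_real_,
      sd_b = if (nrow(rb)) rb$sd else NA_real_,
      u = NA_real_, p_value = NA_real_,
      applicable = nrow(ra) > 0 && nrow(rb) > 0,
      significant = NA,
      stringsAsFactors = FALSE)
    if (out$applicable) {
      test <- mann_whitney_u(popA$age[!is.na(popA[[v]]) & popA[[v]] == s],
                             popB$age[!is.na(popB[[v]]) & popB[[v]] == s])
      out$u <- test$statistic
      out$p_value <- test$p_value
      out$significant <- test$p_value < alpha
    }
    out
  })
  do.call(rbind, rows)
}

#' Five-number box-plot summaries of age per stage
#'
#' Minimum, first quartile, median, third quartile and maximum of
#' chronological age for every observed (variable, stage). Quartiles use
#' linear interpolation between order statistics (quantile type 7), so the
#' summaries are reproducible.
#'
#' @param records collection data.frame.
#' @param catalog a [variable_catalog()].
#' @return data.frame with columns `variable`, `stage`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
boxplot_summary <- function(records, catalog = acetabular_catalog()) {
  rows <- list()
  for (v in names(catalog)) {
    scored <- !is.na(records[[v]])
    if (!any(scored)) next
    ages <- records$age[scored]
    stages <- records[[v]][scored]
    for (s in sort(unique(stages))) {
      a <- ages[stages == s]
      q <- stats::quantile(a, probs = c(0, 0.25, 0.5, 0.75, 1),
                           type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stage = as.integer(s), n = length(a),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
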