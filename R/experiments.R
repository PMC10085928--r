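#' Run one reference/test estimation experiment
#'
#' Builds the reference frequency table from a (sex-specific) reference
#' sample, estimates every test individual, and summarizes inaccuracy
#' globally and by wide age band. Individuals with a "no estimation" outcome
#' are excluded from the bias / absolute-error means and reported as counts.
#'
#' @param reference,test collection data.frames; their sexes must agree
#'   (estimation is sex-specific throughout).
#' @param smoothing additive smoothing constant (default 0, reproducing the
#'   no-estimation behavior for unseen stage combinations).
#' @param grid an [age_class_grid()].
#' @param catalog a [variable_catalog()].
#' @param bands age bands as in [default_age_bands()].
#' @return list with `table` (the `reference_table`), `estimates` (the
#'   [estimate_batch()] data.frame) and `report` (the [band_report()]
#'   data.frame).
#' @export
run_experiment <- function(reference, test, smoothing = 0,
                           grid = age_class_grid(),
                           catalog = acetabular_catalog(),
                           bands = default_age_bands()) {
  stopifnot(nrow(reference) > 0, nrow(test) > 0)
  if (!setequal(unique(reference$sex), unique(test$sex))) {
    stop("reference and test sexes differ; estimation is sex-specific",
         call. = FALSE)
  }
  tab <- build_reference_table(reference, grid, catalog)
  if (all(tab$class_count == 0)) {
    stop("reference too sparse: no age class is populated", call. = FALSE)
  }
  est <- estimate_batch(test, tab, smoothing)
  list(table = tab, estimates = est, report = band_report(est, bands))
}

#' Run the four-experiment crossed reference/test design
#'
#' Orchestrates the full design that quantifies the cost of a geographically
#' distant reference sample: per sex, each population's test sample is
#' estimated twice — with its own (matched) reference and with the other
#' population's (crossed) reference — and the two arms are compared on the
#' same individuals with paired Wilcoxon signed-rank tests, per age band and
#' globally. Individuals unestimated in either arm are excluded from that
#' paired comparison; no-estimation outcomes are tallied per pairing.
#'
#' @param ref_a,test_a,ref_b,test_b collection data.frames for populations A
#'   and B; each may contain both sexes, which are analyzed separately.
#' @param smoothing additive smoothing constant (default 0).
#' @param grid an [age_class_grid()].
#' @param catalog a [variable_catalog()].
#' @param bands age bands as in [default_age_bands()].
#' @param alpha significance threshold for the Wilcoxon flags.
#' @return Object of class `crossed_design`: list with
#'   \describe{
#'   \item{inaccuracy}{data.frame per (sex, test population, arm, scope):
#'     `n`, `bias`, `absolute_error`, `no_estimation_count`.}
#'   \item{comparisons}{data.frame per (sex, test population, scope, metric):
#'     matched and crossed means, paired `n`, Wilcoxon statistic, `z`,
#'     `p_value`, `significant`.}
#'   \item{no_estimation}{data.frame per test/reference pairing with the
#'     no-estimation count and `arm` label.}
#'   \item{estimates}{nested list of the four [estimate_batch()] results per
#'     sex.}
#'   }
#' @export
run_crossed_design <- function(ref_a, test_a, ref_b, test_b, smoothing = 0,
                               grid = age_class_grid(),
                               catalog = acetabular_catalog(),
                               bands = default_age_bands(), alpha = 0.05) {
  for (x in list(ref_a, test_a, ref_b, test_b)) stopifnot(nrow(x) > 0)
  sexes <- Reduce(intersect, list(unique(ref_a$sex), unique(test_a$sex),
                                  unique(ref_b$sex), unique(test_b$sex)))
  if (length(sexes) == 0) stop("no sex present in all eight collections",
                               call. = FALSE)
  pop_of <- function(x) paste(sort(unique(x$population)), collapse = "+")
  inaccuracy <- list(); comparisons <- list(); noest <- list()
  estimates <- list()
  band_of <- function(age) {
    vapply(age, function(a) {
      bands$scope[which(a >= bands$lower & a <= bands$upper)]
    }, character(1))
  }
  for (sx in sexes) {
    sub <- function(x) x[x$sex == sx, , drop = FALSE]
    tabs <- list(a = build_reference_table(sub(ref_a), grid, catalog),
                 b = build_reference_table(sub(ref_b), grid, catalog))
    arms <- list(
      list(test = "a", ref = "a", arm = "matched",
           test_pop = pop_of(test_a), ref_pop = pop_of(ref_a)),
      list(test = "b", ref = "b", arm = "matched",
           test_pop = pop_of(test_b), ref_pop = pop_of(ref_b)),
      list(test = "a", ref = "b", arm = "crossed",
           test_pop = pop_of(test_a), ref_pop = pop_of(ref_b)),
      list(test = "b", ref = "a", arm = "crossed",
           test_pop = pop_of(test_b), ref_pop = pop_of(ref_a))
    )
    tests <- list(a = sub(test_a), b = sub(test_b))
    ests <- list()
    for (spec in arms) {
      est <- estimate_batch(tests[[spec$test]], tabs[[spec$ref]], smoothing)
      key <- paste(spec$test, spec$arm, sep = ".")
      ests[[key]] <- est
      rep <- band_report(est, bands)
      rep <- cbind(sex = sx, test_population = spec$test_pop,
                   reference_population = spec$ref_pop, arm = spec$arm, rep)
      inaccuracy[[length(inaccuracy) + 1L]] <- rep
      noest[[length(noest) + 1L]] <- data.frame(
        test_population = spec$test_pop, test_sex = sx,
        reference_population = spec$ref_pop, reference_sex = sx,
        arm = spec$arm,
        no_estimation_count = sum(est$status == "no_estimation"),
        stringsAsFactors = FALSE)
    }
    estimates[[sx]] <- ests
    # paired matched-vs-crossed comparison on the same test individuals
    for (side in c("a", "b")) {
      m <- ests[[paste(side, "matched", sep = ".")]]
      x <- ests[[paste(side, "crossed", sep = ".")]]
      both <- m$status == "estimated" & x$status == "estimated"
      err_m <- m$point_estimate - m$age
      err_x <- x$point_estimate - x$age
      scopes <- band_of(m$age)
      for (scope in c(bands$scope, "global")) {
        sel <- both & (if (scope == "global") TRUE else scopes == scope)
        for (metric in c("bias", "absolute_error")) {
          vm <- if (metric == "bias") err_m[sel] else abs(err_m[sel])
          vx <- if (metric == "bias") err_x[sel] else abs(err_x[sel])
          row <- data.frame(
            sex = sx, test_population = pop_of(tests[[side]]),
            scope = scope, metric = metric, n_paired = sum(sel),
            matched_mean = if (any(sel)) mean(vm) else NA_real_,
            crossed_mean = if (any(sel)) mean(vx) else NA_real_,
            statistic = NA_real_, z = NA_real_, p_value = NA_real_,
            significant = NA, stringsAsFactors = FALSE)
          if (sum(sel) >= 1) {
            w <- wilcoxon_signed_rank(vm, vx)
            row$statistic <- w$statistic
            row$z <- w$z
            row$p_value <- w$p_value
            row$significant <- w$p_value < alpha
          }
          comparisons[[length(comparisons) + 1L]] <- row
        }
      }
    }
  }
  out <- list(inaccuracy = do.call(rbind, inaccuracy),
              comparisons = do.call(rbind, comparisons),
              no_estimation = do.call(rbind, noest),
              estimates = estimates)
  class(out) <- "crossed_design"
  out
}

#' Summarize no-estimation counts by pairing
#'
#' One row per (test sample, reference sample) pairing with its count of
#' individuals the estimator could not place, plus the mean count over the
#' population-matched pairings and over the crossed pairings. Accepts either
#' a [run_crossed_design()] result or a data.frame with columns `arm` and
#' `no_estimation_count` (e.g. counts transcribed from a published study).
#'
#' @param results a `crossed_design` or a compatible data.frame.
#' @return list with `table` (the per-pairing data.frame), `matched_mean`
#'   and `crossed_mean`.
#' @export
summarize_no_estimates <- function(results) {
  tab <- if (inherits(results, "crossed_design")) {
    results$no_estimation
  } else {
    results
  }
  stopifnot(all(c("arm", "no_estimation_count") %in% names(tab)))
  list(table = tab,
       matched_mean = mean(tab$no_estimation_count[tab$arm == "matched"]),
       crossed_mean = mean(tab$no_estimation_count[tab$arm == "crossed"]))
}

#' @export
print.crossed_design <- function(x, ...) {
  cat("Crossed reference/test design:",
      length(unique(x$inaccuracy$sex)), "sex(es),",
      nrow(x$no_estimation), "test/reference pairings\n")
  g <- x$inaccuracy[x$inaccuracy$scope == "global", ]
  print(g[, c("sex", "test_population", "reference_population", "arm",
              "n", "bias", "absolute_error", "no_estimation_count")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
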