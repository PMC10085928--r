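#' Cumulative-logit aging model for one ordinal variable
#'
#' The generator's model of how an ordinal trait progresses with age: stage
#' attainment is monotone, with `P(stage >= k | age) = logistic((age -
#' (tau_k + shift)) / scale)` for attainment thresholds `tau_1 < ... <
#' tau_{K-1}` (years). `scale` (years) sets the spread of the transition; a
#' negative `shift` moves every threshold earlier, i.e. makes the population
#' age faster. Stage probabilities are the successive differences of the
#' cumulative terms, so they are non-negative and sum to one by construction.
#'
#' @param thresholds strictly increasing numeric vector of attainment
#'   thresholds (years), one per transition `0->1, ..., (K-2)->(K-1)`.
#' @param scale logistic transition scale in years (> 0).
#' @return Object of class `aging_model`.
#' @export
aging_model <- function(thresholds, scale = 8) {
  stopifnot(length(thresholds) >= 1, scale > 0)
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  structure(list(tau = as.numeric(thresholds), scale = scale),
            class = "aging_model")
}

#' @rdname aging_model
#' @param age age in years (scalar).
#' @param model an `aging_model`.
#' @param shift additive threshold shift in years (negative = faster aging).
#' @return `stage_probabilities` returns a probability vector over stages
#'   `0:(K-1)`.
#' @export
stage_probabilities <- function(age, model, shift = 0) {
  cum <- stats::plogis((age - (model$tau + shift)) / model$scale)
  p <- c(1, cum) - c(cum, 0)
  names(p) <- 0:length(model$tau)
  p
}

#' Calibrate an aging model from per-stage mean-age anchors
#'
#' Sets each attainment threshold to the midpoint between consecutive anchor
#' stage mean ages: with anchors `m_0 < m_1 < ... < m_{K-1}`, threshold
#' `tau_k = (m_{k-1} + m_k) / 2`. Anchors must be strictly increasing in
#' stage.
#'
#' @param mean_ages numeric vector of per-stage mean ages, ordered by stage.
#' @param scale logistic transition scale in years.
#' @param variable variable id used in error messages.
#' @return An `aging_model` with `length(mean_ages) - 1` thresholds.
#' @examples
#' aging_model_from_anchors(c(17.40, 48.04, 60.61, 74.74))$tau
#' # 32.720 54.325 67.675
#' @export
aging_model_from_anchors <- function(mean_ages, scale = 8, variable = "") {
  if (any(diff(mean_ages) <= 0)) {
    stop("anchor mean ages are not strictly increasing in stage",
         if (nzchar(variable)) paste0(" for variable ", variable) else "",
         call. = FALSE)
  }
  tau <- (mean_ages[-length(mean_ages)] + mean_ages[-1]) / 2
  aging_model(tau, scale)
}

#' Preset aging models for the seven acetabular variables
#'
#' One `aging_model` per acetabular variable, calibrated by sex from the
#' published Portuguese per-stage mean ages (see [stage_age_anchors()]): the
#' Portuguese columns are the only ones with complete, monotone anchors for
#' every stage of every variable. Population differences in aging rate are
#' expressed through the additive threshold `shift`, not through separate
#' threshold sets (see [population_config()]).
#'
#' @param sex `"M"` or `"F"`.
#' @param scale logistic transition scale in years (default 8, which puts
#'   simulated per-stage age SDs in the published 8-19-year range).
#' @return Named list of `aging_model`s (`v1` ... `v7`).
#' @export
preset_aging_models <- function(sex = c("M", "F"), scale = 8) {
  sex <- match.arg(sex)
  anchors <- stage_age_anchors()
  anchors <- anchors[anchors$population == "PT" & anchors$sex == sex, ]
  models <- lapply(split(anchors, anchors$variable), function(a) {
    a <- a[order(a$stage), ]
    aging_model_from_anchors(a$mean_age, scale, variable = a$variable[1])
  })
  models[paste0("v", 1:7)]
}

#' Configuration of one simulated population sample
#'
#' Describes a synthetic documented-collection sample: its label, sex, size,
#' aging-rate shift, age structure, per-variable missingness and seed.
#' Populations `"PT"` and `"NA"` come preconfigured ("PT-like" and "NA-like"):
#' age-structure weights follow the published decade-bin counts of the
#' corresponding documented collection, and the default shift is 0 for the
#' Portuguese-like and -5 years for the faster-aging North-American-like
#' population.
#'
#' @param population label; `"PT"` and `"NA"` select the presets, any other
#'   label requires explicit `age_weights`.
#' @param sex `"M"` or `"F"`.
#' @param n number of individuals.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   identical collection.
#' @param shift aging-rate shift in years (negative = attains stages earlier
#'   = ages faster); `NULL` picks the preset default.
#' @param age_weights data.frame with columns `bin_lower`, `bin_upper`, `n`
#'   (weights need not be normalized); `NULL` picks the preset age structure.
#' @param missingness per-variable probability that a score is missing;
#'   scalar or named vector (`v1` ...).
#' @param frailty_sd SD (years) of an individual-level shift shared by all
#'   seven variables; > 0 induces dependence between variables beyond age,
#'   deliberately violating the estimator's conditional-independence
#'   assumption for robustness checks.
#' @return Object of class `population_config`.
#' @export
population_config <- function(population, sex, n, seed,
                              shift = NULL, age_weights = NULL,
                              missingness = 0, frailty_sd = 0) {
  stopifnot(n >= 1, all(missingness >= 0), all(missingness < 1),
            frailty_sd >= 0)
  if (is.null(shift)) {
    shift <- switch(population, PT = 0, `NA` = -5,
                    stop("no preset shift for population '", population,
                         "'; supply `shift`", call. = FALSE))
  }
  if (is.null(age_weights)) {
    s <- collection_age_structure()
    age_weights <- s[s$population == population & s$sex == sex,
                     c("bin_lower", "bin_upper", "n")]
    if (nrow(age_weights) == 0) {
      stop("no preset age structure for population '", population,
           "'; supply `age_weights`", call. = FALSE)
    }
  }
  stopifnot(sum(age_weights$n) > 0,
            all(age_weights$bin_lower >= 15), all(age_weights$bin_upper <= 104))
  structure(list(population = population, sex = sex, n = as.integer(n),
                 shift = shift, age_weights = age_weights,
                 missingness = missingness, frailty_sd = frailty_sd,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Simulate a documented-collection-like skeletal sample
#'
#' Draws `n` individuals: chronological age from the configured
#' piecewise-uniform decade-bin distribution, then each variable's stage
#' independently from its cumulative-logit [stage_probabilities()] at that
#' age (plus the population shift and any individual frailty shift), then
#' per-variable missingness. Identical configuration and seed give an
#' identical collection.
#'
#' @param config a [population_config()].
#' @param models named list of `aging_model`s; defaults to the sex-matched
#'   presets.
#' @param catalog a [variable_catalog()]; must match `models`.
#' @return Collection data.frame (see [skeletal_collection()]).
#' @export
simulate_collection <- function(config,
                                models = preset_aging_models(config$sex),
                                catalog = acetabular_catalog()) {
  stopifnot(setequal(names(models), names(catalog)))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n
  w <- config$age_weights
  bin <- sample.int(nrow(w), n, replace = TRUE, prob = w$n / sum(w$n))
  age <- w$bin_lower[bin] +
    floor(stats::runif(n) * (w$bin_upper[bin] - w$bin_lower[bin] + 1))
  frailty <- if (config$frailty_sd > 0) {
    stats::rnorm(n, 0, config$frailty_sd)
  } else {
    numeric(n)
  }
  miss <- config$missingness
  if (length(miss) == 1 && is.null(names(miss))) {
    miss <- stats::setNames(rep(miss, length(catalog)), names(catalog))
  }
  stages <- lapply(names(catalog), function(v) {
    k <- n_stages(catalog, v)
    s <- vapply(seq_len(n), function(i) {
      p <- stage_probabilities(age[i], models[[v]],
                               shift = config$shift + frailty[i])
      sample.int(k, 1, prob = p) - 1L
    }, integer(1))
    rate <- if (v %in% names(miss)) miss[[v]] else 0
    if (rate > 0) s[stats::runif(n) < rate] <- NA_integer_
    s
  })
  names(stages) <- names(catalog)
  skeletal_collection(
    individual_id = sprintf("%s-%s-%04d", config$population, config$sex,
                            seq_len(n)),
    collection = "synthetic",
    population = config$population, sex = config$sex,
    age = age, side = "L", stages = stages, catalog = catalog
  )
}
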