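#' Posterior age-class distribution for a stage profile
#'
#' Computes the Bayesian posterior over 5-year age-at-death classes for one
#' individual's stage profile. The unnormalized mass of class `c` is the
#' reference-fraction prior times the product, over the scored variables, of
#' the conditional stage frequency in `c` (the variables are treated as
#' conditionally independent given the age class). Missing variables
#' contribute no factor. If every class gets zero mass — a stage combination
#' never observed together with any populated class under `smoothing = 0` —
#' the outcome is an explicit "no estimation".
#'
#' @param profile named list or vector of integer stage scores (`NA` =
#'   missing), names matching catalog variables; at least one score present.
#' @param table a `reference_table`.
#' @param smoothing additive smoothing constant passed to
#'   [stage_likelihood()].
#' @return Object of class `age_posterior` (list with `prob` over classes and
#'   `grid`) when estimable, or the sentinel `no_estimation()` object when
#'   the posterior mass is zero everywhere.
#' @examples
#' ref <- simulate_collection(population_config("PT", "M", n = 200, seed = 1))
#' tab <- build_reference_table(ref)
#' post <- posterior(list(v1 = 1, v5 = 0), tab)
#' point_estimate(post)
#' @export
posterior <- function(profile, table, smoothing = 0) {
  profile <- unlist(profile)
  scored <- names(profile)[!is.na(profile)]
  scored <- intersect(scored, names(table$stage_count))
  if (length(scored) == 0) {
    stop("profile has no scored variables; nothing to condition on",
         call. = FALSE)
  }
  mass <- class_prior(table)
  for (v in scored) {
    mass <- mass * stage_likelihood(table, v, profile[[v]], smoothing)
  }
  total <- sum(mass)
  if (total == 0) {
    return(no_estimation())
  }
  out <- list(prob = mass / total, grid = table$grid)
  class(out) <- "age_posterior"
  out
}

#' @rdname posterior
#' @export
no_estimation <- function() {
  structure(list(), class = "no_estimation")
}

#' @rdname posterior
#' @param x object to test.
#' @export
is_no_estimation <- function(x) inherits(x, "no_estimation")

#' @export
print.age_posterior <- function(x, ...) {
  cat("Age posterior over", length(x$prob), "classes; point estimate",
      round(point_estimate(x), 2), "years\n")
  nz <- which(x$prob > 1e-6)
  df <- data.frame(class = x$grid$label[nz], prob = round(x$prob[nz], 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Single-year point estimate of age at death
#'
#' The expected value of the posterior distribution, attributing to each
#' 5-year age class its central age (the interval midpoint).
#'
#' @param post an `age_posterior`.
#' @return Age in years (real-valued, not rounded).
#' @export
point_estimate <- function(post) {
  stopifnot(inherits(post, "age_posterior"))
  sum(post$prob * post$grid$central)
}

#' Estimate age at death for a batch of individuals
#'
#' Applies [posterior()] and [point_estimate()] to every record, preserving
#' input order. Individuals whose stage profile has zero posterior mass get
#' status `"no_estimation"` and an `NA` point estimate; they remain countable
#' in the output.
#'
#' @param test collection data.frame of individuals to estimate.
#' @param table a `reference_table` (typically built from a sex-matched
#'   reference sample).
#' @param smoothing additive smoothing constant (default 0).
#' @param keep_posterior if `TRUE`, append one column of posterior probability
#'   per age class (`p_15-19`, ...).
#' @return data.frame with columns `individual_id`, `age` (chronological,
#'   years), `status` (`"estimated"` or `"no_estimation"`), `point_estimate`
#'   (years, `NA` when not estimated), plus posterior columns on request.
#' @export
estimate_batch <- function(test, table, smoothing = 0,
                           keep_posterior = FALSE) {
  stopifnot(nrow(test) > 0)
  vars <- names(table$stage_count)
  k <- nrow(table$grid)
  status <- character(nrow(test))
  est <- rep(NA_real_, nrow(test))
  pp <- if (keep_posterior) matrix(NA_real_, nrow(test), k) else NULL
  for (i in seq_len(nrow(test))) {
    prof <- as.list(test[i, vars, drop = FALSE])
    post <- posterior(prof, table, smoothing)
    if (is_no_estimation(post)) {
      status[i] <- "no_estimation"
    } else {
      status[i] <- "estimated"
      est[i] <- point_estimate(post)
      if (keep_posterior) pp[i, ] <- post$prob
    }
  }
  out <- data.frame(individual_id = test$individual_id,
                    age = test$age,
                    status = status,
                    point_estimate = est,
                    stringsAsFactors = FALSE)
  if (keep_posterior) {
    colnames(pp) <- paste0("p_", table$grid$label)
    out <- cbind(out, as.data.frame(pp))
  }
  out
}
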