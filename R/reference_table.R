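#' Build a reference frequency table
#'
#' Tabulates a documented reference collection over the age-class grid: the
#' number of reference individuals per 5-year age-at-death class (the prior's
#' numerator) and, per variable and class, the number of individuals observed
#' at each stage (the likelihood's numerator). Individuals with a missing
#' score on a variable are excluded from that variable's stage counts only;
#' they still count toward their age class.
#'
#' @param reference collection data.frame (see [skeletal_collection()]); all
#'   ages must fall inside the grid span.
#' @param grid an [age_class_grid()].
#' @param catalog a [variable_catalog()].
#' @return Object of class `reference_table`: list with `grid`, `class_count`
#'   (integer per class), `stage_count` (per variable, a classes x stages
#'   integer matrix), `n` and `metadata` (population/sex/collection labels,
#'   collapsed from the records).
#' @export
build_reference_table <- function(reference, grid = age_class_grid(),
                                  catalog = acetabular_catalog()) {
  if (nrow(reference) == 0) {
    stop("empty reference collection: no prior can be formed", call. = FALSE)
  }
  idx <- age_class_index(reference$age, grid)
  k <- nrow(grid)
  class_count <- tabulate(idx, nbins = k)
  stage_count <- lapply(names(catalog), function(v) {
    m <- matrix(0L, nrow = k, ncol = n_stages(catalog, v),
                dimnames = list(grid$label, catalog[[v]]$min:catalog[[v]]$max))
    scored <- !is.na(reference[[v]])
    if (any(scored)) {
      t2 <- table(factor(idx[scored], levels = seq_len(k)),
                  factor(reference[[v]][scored],
                         levels = catalog[[v]]$min:catalog[[v]]$max))
      m[] <- as.integer(t2)
    }
    m
  })
  names(stage_count) <- names(catalog)
  collapse <- function(x) paste(sort(unique(x)), collapse = "+")
  out <- list(
    grid = grid,
    class_count = as.integer(class_count),
    stage_count = stage_count,
    n = nrow(reference),
    metadata = list(population = collapse(reference$population),
                    sex = collapse(reference$sex),
                    collection = collapse(reference$collection))
  )
  class(out) <- "reference_table"
  out
}

#' @export
print.reference_table <- function(x, ...) {
  cat("Reference table: n =", x$n,
      "| population:", x$metadata$population,
      "| sex:", x$metadata$sex, "\n")
  cat("  ", nrow(x$grid), " age classes (", x$grid$label[1], " ... ",
      x$grid$label[nrow(x$grid)], "), ",
      length(x$stage_count), " variables\n", sep = "")
  invisible(x)
}

#' Prior over age classes from reference frequencies
#'
#' The a priori probability of each 5-year age-at-death class is the fraction
#' of reference individuals in that class; classes without reference
#' individuals get prior 0.
#'
#' @param table a `reference_table`.
#' @return Numeric vector over age classes, summing to 1.
#' @export
class_prior <- function(table) {
  stopifnot(table$n > 0)
  table$class_count / table$n
}

#' Conditional stage frequency per age class
#'
#' For one variable and stage, returns per class the (optionally smoothed)
#' fraction of scored reference individuals observed at that stage:
#' `(count + alpha) / (scored + alpha * K)` with `K` the variable's stage
#' count. Classes with no scored individuals return 0 regardless of
#' smoothing.
#'
#' @param table a `reference_table`.
#' @param variable variable id.
#' @param stage integer stage within the variable's range.
#' @param smoothing additive smoothing constant `alpha >= 0` (default 0, so
#'   stages never observed in a class have likelihood 0 there).
#' @return Numeric vector over age classes.
#' @export
stage_likelihood <- function(table, variable, stage, smoothing = 0) {
  m <- table$stage_count[[variable]]
  if (is.null(m)) stop("unknown variable: ", variable, call. = FALSE)
  stages <- as.integer(colnames(m))
  j <- match(as.integer(stage), stages)
  if (is.na(j)) {
    stop("stage ", stage, " outside range ", min(stages), "-", max(stages),
         " for ", variable, call. = FALSE)
  }
  scored <- rowSums(m)
  k <- ncol(m)
  out <- ifelse(scored > 0,
                (m[, j] + smoothing) / (scored + smoothing * k),
                0)
  unname(out)
}

#' Serialize a reference table to JSON
#'
#' The JSON form carries the grid definition, class counts, nested per-variable
#' stage counts and metadata, so a table can be shared and reloaded without the
#' underlying individual records.
#'
#' @param table a `reference_table`.
#' @param path file path.
#' @return `write_reference_table` returns `path` invisibly;
#'   `read_reference_table` returns a `reference_table`.
#' @export
write_reference_table <- function(table, path) {
  x <- list(
    grid = list(min_age = table$grid$lower[1],
                max_age = table$grid$upper[nrow(table$grid)],
                width = table$grid$upper[1] - table$grid$lower[1] + 1L),
    n = table$n,
    class_count = table$class_count,
    stage_count = table$stage_count,
    metadata = table$metadata
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- age_class_grid(x$grid$min_age, x$grid$max_age, x$grid$width)
  stage_count <- lapply(x$stage_count, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    rownames(m) <- grid$label
    colnames(m) <- seq_len(ncol(m)) - 1L
    m
  })
  out <- list(grid = grid,
              class_count = as.integer(x$class_count),
              stage_count = stage_count,
              n = as.integer(x$n),
              metadata = as.list(x$metadata))
  class(out) <- "reference_table"
  out
}
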