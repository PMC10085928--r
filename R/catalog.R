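#' Catalog of ordinal age-related variables
#'
#' A variable catalog fixes, for each ordinal trait, the inclusive integer
#' stage range used for scoring. The default catalog describes the seven
#' acetabular variables of the revised acetabular aging method: V1 acetabular
#' groove (stages 0-3), V2 acetabular rim shape (0-6), V3 acetabular rim
#' porosity (0-5), V4 apex activity (0-4), V5 activity on the outer acetabular
#' fossa (0-2), V6 activity of the acetabular fossa (0-3) and V7 porosities of
#' the acetabular fossa (0-4).
#'
#' @param ranges named list mapping variable id to `c(min_stage, max_stage)`.
#'   Ranges must be contiguous integer intervals starting at 0.
#' @return An object of class `variable_catalog`: a named list with integer
#'   elements `min` and `max` per variable.
#' @examples
#' cat7 <- acetabular_catalog()
#' n_stages(cat7, "v2")  # 7
#' @export
variable_catalog <- function(ranges) {
  stopifnot(is.list(ranges), length(ranges) >= 1, !is.null(names(ranges)))
  out <- lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || r[1] != 0L || r[2] < r[1]) {
      stop("each stage range must be c(0, max) with max >= 0", call. = FALSE)
    }
    list(min = r[1], max = r[2])
  })
  class(out) <- "variable_catalog"
  out
}

#' @rdname variable_catalog
#' @export
acetabular_catalog <- function() {
  variable_catalog(list(
    v1 = c(0, 3), v2 = c(0, 6), v3 = c(0, 5),
    v4 = c(0, 4), v5 = c(0, 2), v6 = c(0, 3), v7 = c(0, 4)
  ))
}

#' Number of stages of a catalog variable
#'
#' @param catalog a `variable_catalog`.
#' @param variable variable id, e.g. `"v1"`.
#' @return Integer count of stages (max stage + 1).
#' @export
n_stages <- function(catalog, variable) {
  v <- catalog[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable, call. = FALSE)
  v$max - v$min + 1L
}

#' @export
print.variable_catalog <- function(x, ...) {
  cat("Variable catalog (", length(x), " ordinal variables)\n", sep = "")
  for (v in names(x)) {
    cat("  ", v, ": stages ", x[[v]]$min, "-", x[[v]]$max, "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a variable catalog as JSON
#'
#' The JSON form maps each variable id to `{"min_stage": 0, "max_stage": k}`.
#'
#' @param catalog a `variable_catalog`.
#' @param path file path.
#' @return `read_catalog` returns a `variable_catalog`; `write_catalog`
#'   returns `path` invisibly.
#' @export
write_catalog <- function(catalog, path) {
  x <- lapply(catalog, function(v) list(min_stage = v$min, max_stage = v$max))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- jsonlite::read_json(path)
  variable_catalog(lapply(x, function(v) c(v$min_stage, v$max_stage)))
}

#' Grid of 5-year age-at-death classes
#'
#' Builds the ordered grid of inclusive 5-year age-at-death classes
#' (15-19, 20-24, ...) over which posteriors are expressed. The central age of
#' a class is the arithmetic midpoint of the inclusive interval (15-19 -> 17).
#'
#' @param min_age lower bound of the first class (years).
#' @param max_age upper bound of the last class (years); `max_age - min_age + 1`
#'   must be a multiple of `width`.
#' @param width class width in years.
#' @return A data.frame of class `age_class_grid` with columns `lower`,
#'   `upper`, `central` and `label`.
#' @examples
#' g <- age_class_grid()
#' head(g$label)  # "15-19" "20-24" ...
#' @export
age_class_grid <- function(min_age = 15L, max_age = 104L, width = 5L) {
  min_age <- as.integer(min_age); max_age <- as.integer(max_age)
  width <- as.integer(width)
  span <- max_age - min_age + 1L
  if (span <= 0L || span %% width != 0L) {
    stop("grid span must be a positive multiple of the class width", call. = FALSE)
  }
  lower <- seq.int(min_age, max_age, by = width)
  upper <- lower + width - 1L
  g <- data.frame(
    lower = lower, upper = upper,
    central = (lower + upper) / 2,
    label = paste0(lower, "-", upper),
    stringsAsFactors = FALSE
  )
  class(g) <- c("age_class_grid", "data.frame")
  g
}

#' Map ages to age-class indices
#'
#' Assignment is total and unique for every age inside the grid span.
#'
#' @param age numeric vector of ages in years.
#' @param grid an `age_class_grid`.
#' @return Integer vector of 1-based class indices.
#' @export
age_class_index <- function(age, grid) {
  width <- grid$upper[1] - grid$lower[1] + 1L
  idx <- (as.numeric(age) - grid$lower[1]) %/% width + 1L
  bad <- age < grid$lower[1] | age > grid$upper[nrow(grid)]
  if (any(bad, na.rm = TRUE)) {
    stop("age(s) outside grid span [", grid$lower[1], ", ",
         grid$upper[nrow(grid)], "]: ",
         paste(utils::head(age[which(bad)], 5), collapse = ", "),
         call. = FALSE)
  }
  as.integer(idx)
}
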