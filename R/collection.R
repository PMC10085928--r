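#' Skeletal collection tables
#'
#' A collection is a plain data.frame with one row per documented (or
#' simulated) individual and columns
#' `individual_id, collection, population, sex, age, side` followed by one
#' integer stage column per catalog variable (`v1 ... v7` for the acetabular
#' catalog). `NA` in a stage column means the variable could not be scored.
#'
#' @param individual_id character ids.
#' @param collection,population,sex,side character metadata; `sex` in
#'   `c("M","F")`, `side` in `c("L","R")` (left is scored by default; the
#'   right side stands in when the left is damaged).
#' @param age integer chronological ages in whole years.
#' @param stages data.frame or named list of integer stage scores, one column
#'   per catalog variable.
#' @param catalog a `variable_catalog`.
#' @return A collection data.frame.
#' @export
skeletal_collection <- function(individual_id, collection = "synthetic",
                                population, sex, age, side = "L",
                                stages, catalog = acetabular_catalog()) {
  n <- length(individual_id)
  out <- data.frame(
    individual_id = as.character(individual_id),
    collection = rep_len(as.character(collection), n),
    population = rep_len(as.character(population), n),
    sex = rep_len(as.character(sex), n),
    age = as.integer(age),
    side = rep_len(as.character(side), n),
    stringsAsFactors = FALSE
  )
  stages <- as.data.frame(stages)
  for (v in names(catalog)) {
    out[[v]] <- if (v %in% names(stages)) as.integer(stages[[v]]) else NA_integer_
  }
  out
}

collection_columns <- function(catalog) {
  c("individual_id", "collection", "population", "sex", "age", "side",
    names(catalog))
}

#' Read a skeletal collection from CSV
#'
#' Expects the documented schema
#' `individual_id,collection,population,sex,age,side,v1,...` with blank stage
#' cells meaning "not scored". Row order is preserved. Stage scores and ages
#' are validated against the catalog; violations abort with a message naming
#' the row and field.
#'
#' @param source file path or connection.
#' @param catalog a `variable_catalog`.
#' @param min_age,max_age admissible chronological age range in years.
#' @return A collection data.frame (zero rows for a header-only file).
#' @export
read_collection <- function(source, catalog = acetabular_catalog(),
                            min_age = 15, max_age = 110) {
  expected <- collection_columns(catalog)
  x <- utils::read.csv(source, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing_cols <- setdiff(expected, names(x))
  if (length(missing_cols) > 0) {
    stop("collection header is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, expected, drop = FALSE]
  x$age <- suppressWarnings(as.integer(x$age))
  for (v in names(catalog)) {
    blank <- is.na(x[[v]]) | trimws(x[[v]]) == ""
    parsed <- suppressWarnings(as.integer(x[[v]]))
    parsed[blank] <- NA_integer_
    x[[v]] <- parsed
  }
  viol <- validate_records(x, catalog, min_age = min_age, max_age = max_age)
  if (nrow(viol) > 0) {
    stop("invalid collection: ",
         paste(sprintf("row %d [%s] %s", viol$row, viol$field, viol$message),
               collapse = "; "),
         call. = FALSE)
  }
  x
}

#' Write a skeletal collection to CSV
#'
#' Missing stage scores become blank cells, so `read_collection()` of the
#' output reproduces the input field for field.
#'
#' @param records collection data.frame.
#' @param sink file path or connection.
#' @return `sink`, invisibly.
#' @export
write_collection <- function(records, sink) {
  utils::write.csv(records, sink, row.names = FALSE, na = "", quote = FALSE)
  invisible(sink)
}

#' Validate skeletal records against a catalog
#'
#' Violations are returned, not raised: one row per problem, naming the
#' offending record (row number and id) and field. A record with every stage
#' missing is flagged, as it carries no age information.
#'
#' @param records collection data.frame.
#' @param catalog a `variable_catalog`.
#' @param min_age,max_age admissible chronological age range in years.
#' @return data.frame with columns `row`, `individual_id`, `field`, `message`;
#'   zero rows when all records are valid.
#' @export
validate_records <- function(records, catalog = acetabular_catalog(),
                             min_age = 15, max_age = 110) {
  out <- list()
  add <- function(row, field, message) {
    out[[length(out) + 1L]] <<- data.frame(
      row = row,
      individual_id = as.character(records$individual_id[row]),
      field = field, message = message, stringsAsFactors = FALSE)
  }
  n <- nrow(records)
  if (n > 0) {
    for (i in seq_len(n)) {
      age <- records$age[i]
      if (is.na(age) || age < min_age || age > max_age) {
        add(i, "age", sprintf("age must be an integer in [%s, %s]",
                              min_age, max_age))
      }
      if (is.na(records$sex[i]) || !nzchar(records$sex[i]) ||
          !records$sex[i] %in% c("M", "F")) {
        add(i, "sex", "sex must be 'M' or 'F'")
      }
      if (is.na(records$population[i]) || !nzchar(records$population[i])) {
        add(i, "population", "population must be non-empty")
      }
      if (!is.na(records$side[i]) && nzchar(records$side[i]) &&
          !records$side[i] %in% c("L", "R")) {
        add(i, "side", "side must be 'L' or 'R'")
      }
      all_missing <- TRUE
      for (v in names(catalog)) {
        s <- records[[v]][i]
        if (!is.na(s)) {
          all_missing <- FALSE
          if (s < catalog[[v]]$min || s > catalog[[v]]$max) {
            add(i, v, sprintf("stage %d outside range %d-%d", s,
                              catalog[[v]]$min, catalog[[v]]$max))
          }
        }
      }
      if (all_missing) {
        add(i, "profile", "all stage scores are missing")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(row = integer(), individual_id = character(),
                      field = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' @rdname validate_records
#' @param record a single-row collection data.frame.
#' @export
validate_record <- function(record, catalog = acetabular_catalog(),
                            min_age = 15, max_age = 110) {
  validate_records(record[1, , drop = FALSE], catalog,
                   min_age = min_age, max_age = max_age)
}

#' Split a collection into reference and test samples
#'
#' Produces an exhaustive, disjoint partition. Within each stratum the
#' reference receives `round(reference_fraction * stratum size)` records,
#' sampled without replacement; the same seed reproduces the same split.
#' Strata with fewer than 2 records go wholly to the reference, with a
#' warning.
#'
#' @param records collection data.frame.
#' @param reference_fraction proportion in (0, 1) assigned to the reference.
#' @param seed integer seed controlling the split.
#' @param stratify_by character vector of column names (or `"age_class"` to
#'   stratify by 5-year age class on `grid`); `NULL` for a single stratum.
#' @param grid `age_class_grid` used when stratifying by age class.
#' @return list with elements `reference` and `test` (collection data.frames).
#' @export
split_reference_test <- function(records, reference_fraction, seed,
                                 stratify_by = NULL,
                                 grid = age_class_grid()) {
  stopifnot(reference_fraction > 0, reference_fraction < 1)
  n <- nrow(records)
  key <- rep("all", n)
  if (!is.null(stratify_by) && n > 0) {
    parts <- lapply(stratify_by, function(col) {
      if (col == "age_class") {
        grid$label[age_class_index(records$age, grid)]
      } else {
        as.character(records[[col]])
      }
    })
    key <- do.call(paste, c(parts, sep = "|"))
  }
  ref_idx <- integer(0)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (s in unique(key)) {
    idx <- which(key == s)
    if (length(idx) < 2) {
      warning("stratum '", s, "' has fewer than 2 records; assigned to reference",
              call. = FALSE)
      ref_idx <- c(ref_idx, idx)
      next
    }
    k <- round(reference_fraction * length(idx))
    k <- max(1L, min(length(idx) - 1L, k))
    ref_idx <- c(ref_idx, sample(idx, k))
  }
  ref_idx <- sort(ref_idx)
  list(reference = records[ref_idx, , drop = FALSE],
       test = records[setdiff(seq_len(n), ref_idx), , drop = FALSE])
}
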