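#' Read and validate a behaviour-series CSV
#'
#' Dialect: columns `animal_id`, `hour` (0-based within the week; pre-partum
#' hour 167 is the hour before calving, post-partum hour 0 the first after),
#' then `lying`, `ruminating`, `inactive`, `active`, `highly_active` in
#' minutes per hour. Validates the \[0, 60\] range, the 60-minute activity
#' budget (`inactive + active + highly_active = 60` within `budget_tol`), and
#' duplicate `(animal_id, hour)` pairs. Hours absent for an animal are
#' reported in the `"gaps"` attribute (a tibble `animal_id`, `missing_hours`).
#'
#' @param path CSV path.
#' @param series_length Expected number of hourly bins (default 168).
#' @param budget_tol Tolerance on the activity budget (default 1e-6).
#' @return A tibble in the dialect above, with attribute `"gaps"`.
#' @export
read_series_csv <- function(path, series_length = 168, budget_tol = 1e-6) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("animal_id", "hour", .stream_names)
  if (!identical(names(df), needed)) {
    stop("malformed series header in ", path, "; expected columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  df$animal_id <- as.character(df$animal_id)
  for (s in .stream_names) {
    bad <- which(!is.na(df[[s]]) & (df[[s]] < 0 | df[[s]] > 60))
    if (length(bad) > 0) {
      stop("stream '", s, "' outside [0, 60] at row(s) ",
           paste(head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
    }
  }
  if (anyDuplicated(df[c("animal_id", "hour")]) > 0) {
    stop("duplicate (animal_id, hour) rows in ", path, call. = FALSE)
  }
  budget <- df$inactive + df$active + df$highly_active
  bad <- which(!is.na(budget) & abs(budget - 60) > budget_tol)
  if (length(bad) > 0) {
    stop("activity budget != 60 min at row(s) ",
         paste(head(bad, 5), collapse = ", "), " of ", path, call. = FALSE)
  }
  gaps <- df |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      missing_hours = series_length - dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$missing_hours > 0)
  attr(df, "gaps") <- gaps
  df
}

#' @rdname read_series_csv
#' @param series Series tibble in the documented dialect.
#' @export
write_series_csv <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}

#' Read and validate a feature-table CSV
#'
#' Dialect: one row per animal, column `animal_id` plus the canonical
#' feature names of [feature_schema()] (all 20, or the 11 non-location ones
#' when location features are excluded). An empty cell is an explicit missing
#' value, never zero. Parity is coerced to -1/+1; values outside a feature's
#' schema bounds are rejected.
#'
#' @param path CSV path.
#' @return A tibble `animal_id` + feature columns, `NA` = missing.
#' @export
read_features_csv <- function(path) {
  schema <- feature_schema()
  df <- readr::read_csv(path, show_col_types = FALSE,
                        na = c("", "NA"))
  if (names(df)[1] != "animal_id") {
    stop("first column of ", path, " must be animal_id", call. = FALSE)
  }
  unknown <- setdiff(names(df)[-1], schema$feature)
  if (length(unknown) > 0) {
    stop("unknown feature column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  df$animal_id <- as.character(df$animal_id)
  if (anyDuplicated(df$animal_id) > 0) {
    stop("duplicate animal_id in ", path, call. = FALSE)
  }
  for (f in intersect(schema$feature, names(df))) {
    v <- df[[f]]
    if (!is.numeric(v)) stop("feature '", f, "' is not numeric", call. = FALSE)
    if (f == "parity") {
      ok <- is.na(v) | v %in% c(-1, 1)
      if (!all(ok)) {
        stop("parity must be -1 (primiparous) or +1 (multiparous)", call. = FALSE)
      }
    } else {
      row <- schema[schema$feature == f, ]
      lo <- if (is.na(row$lower)) -Inf else row$lower
      hi <- if (is.na(row$upper)) Inf else row$upper
      bad <- which(!is.na(v) & (v < lo | v > hi))
      if (length(bad) > 0) {
        stop("feature '", f, "' outside [", lo, ", ", hi, "] at row(s) ",
             paste(head(bad, 5), collapse = ", "), call. = FALSE)
      }
    }
  }
  df
}

#' @rdname read_features_csv
#' @param features Feature tibble (`animal_id` + schema columns).
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path, na = "")
  invisible(path)
}

#' Read / write a labels CSV (`animal_id`, `label`)
#'
#' @param path CSV path.
#' @return A tibble `animal_id`, `label`.
#' @export
read_labels_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          animal_id = readr::col_character(),
                          label = readr::col_character()
                        ))
  if (!identical(names(df), c("animal_id", "label"))) {
    stop("labels file must have columns animal_id, label", call. = FALSE)
  }
  .assert_labels(df$label)
  df
}

#' @rdname read_labels_csv
#' @param labels Labels tibble.
#' @export
write_labels_csv <- function(labels, path) {
  readr::write_csv(labels, path)
  invisible(path)
}

#' Write / read a whole cohort as a CSV bundle
#'
#' `write_cohort()` writes `series_pre.csv`, `series_post.csv`,
#' `features.csv`, `labels.csv` (and `bhb.csv` when present) plus a
#' `meta.json` with the seed, into `dir`. `read_cohort()` reads and
#' validates them back into an `sck_cohort`; animal ids must be consistent
#' across tables.
#'
#' @param cohort An `sck_cohort`.
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` an
#'   `sck_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sck_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_series_csv(cohort$series_pre, file.path(dir, "series_pre.csv"))
  write_series_csv(cohort$series_post, file.path(dir, "series_post.csv"))
  write_features_csv(cohort$features, file.path(dir, "features.csv"))
  write_labels_csv(cohort$labels, file.path(dir, "labels.csv"))
  if (!is.null(cohort$bhb)) {
    readr::write_csv(cohort$bhb, file.path(dir, "bhb.csv"), na = "")
  }
  meta <- list(seed = cohort$seed, n_animals = nrow(cohort$labels),
               series_length = cohort$spec$series_length %||% 168L,
               created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  series_length <- as.integer(meta$series_length %||% 168L)
  series_pre <- read_series_csv(file.path(dir, "series_pre.csv"), series_length)
  series_post <- read_series_csv(file.path(dir, "series_post.csv"), series_length)
  features <- read_features_csv(file.path(dir, "features.csv"))
  labels <- read_labels_csv(file.path(dir, "labels.csv"))
  ids <- labels$animal_id
  for (tbl in list(series_pre, series_post)) {
    if (!setequal(unique(tbl$animal_id), ids)) {
      stop("animal ids inconsistent across tables in ", dir, call. = FALSE)
    }
  }
  if (!setequal(features$animal_id, ids)) {
    stop("animal ids inconsistent across tables in ", dir, call. = FALSE)
  }
  bhb_path <- file.path(dir, "bhb.csv")
  bhb <- if (file.exists(bhb_path)) {
    readr::read_csv(bhb_path, show_col_types = FALSE, na = c("", "NA"))
  } else NULL
  structure(
    list(series_pre = series_pre, series_post = series_post,
         features = features, labels = labels, bhb = bhb,
         spec = list(series_length = series_length),
         seed = as.integer(meta$seed %||% NA_integer_)),
    class = "sck_cohort"
  )
}

# long series tibble -> named list of animal x hour matrices, one per stream,
# rows ordered like `ids`
.stream_matrices <- function(series, ids, series_length = 168) {
  out <- list()
  ord <- order(match(series$animal_id, ids), series$hour)
  s <- series[ord, ]
  n <- length(ids)
  complete <- nrow(s) == n * series_length &&
    all(s$hour == rep(seq_len(series_length) - 1L, n))
  for (nm in .stream_names) {
    if (complete) {
      m <- matrix(s[[nm]], nrow = n, ncol = series_length, byrow = TRUE)
    } else {
      m <- matrix(NA_real_, n, series_length)
      m[cbind(match(s$animal_id, ids), s$hour + 1L)] <- s[[nm]]
    }
    rownames(m) <- ids
    out[[nm]] <- m
  }
  out
}
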