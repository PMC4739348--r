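## Tabular I/O for the central population record and the pipeline's result
## tables. Everything is a plain tibble; undefined proportions are NA and
## serialize as empty CSV fields.

#' Read a mapped population from CSV
#'
#' Expects at least `plant_id`, `sex`, `x`, `y`; sex tokens are normalized
#' via [normalize_sex()] (so `F`/`H`, `female`/`hermaphrodite` and 0/1 files
#' all load). Duplicate ids and unknown sex tokens are input errors that name
#' the offending rows.
#'
#' @param path CSV file path.
#' @param population_id optional label; defaults to a `population_id` column
#'   if present, else the file name without extension.
#' @return tibble with columns `plant_id`, `sex`, `x`, `y`, `population_id`.
#' @export
read_population <- function(path, population_id = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("plant_id", "sex", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0(path, " lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (is.null(population_id)) {
    population_id <- if ("population_id" %in% names(df)) {
      as.character(df$population_id)
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  out <- tibble::tibble(
    plant_id = as.character(df$plant_id),
    sex = normalize_sex(df$sex),
    x = as.numeric(df$x),
    y = as.numeric(df$y),
    population_id = as.character(population_id)
  )
  check_population_map(out)
  out
}

#' Per-population summary (size and hermaphrodite frequency)
#'
#' @param map population map tibble (one or more populations).
#' @return tibble with `population_id`, `n`, `n_hermaphrodite`,
#'   `herm_frequency`.
#' @export
population_summary <- function(map) {
  check_population_map(map)
  if (!"population_id" %in% names(map)) map$population_id <- "pop"
  map |>
    dplyr::group_by(.data$population_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_hermaphrodite = sum(sex_code(.data$sex)),
      herm_frequency = mean(sex_code(.data$sex)),
      .groups = "drop"
    )
}

#' Pool several populations' hermaphrodite frequency
#'
#' Individual-weighted pooling: total hermaphrodites over total plants.
#' Accepts either a population map or printed per-population sizes and
#' frequencies.
#'
#' @param n integer vector of population sizes.
#' @param freq hermaphrodite frequency of each population.
#' @return pooled hermaphrodite frequency.
#' @examples
#' pooled_frequency(c(278, 390), c(0.658, 0.590))
#' @export
pooled_frequency <- function(n, freq) {
  stopifnot(length(n) == length(freq), all(n > 0), all(freq >= 0 & freq <= 1))
  sum(n * freq) / sum(n)
}

#' Write a result table to CSV (or JSON) at full precision
#'
#' Numbers round-trip losslessly (`read_results(write_results(x))` is the
#' identity up to column type); undefined values (`NA`) are written as empty
#' fields, not the text "NaN", for cross-tool safety.
#'
#' @param table data frame to write.
#' @param path output file; format from extension unless given.
#' @param format `"csv"` or `"json"`.
#' @param allow_empty permit writing a zero-row table (header-only CSV).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("auto", "csv", "json"),
                          allow_empty = FALSE) {
  stopifnot(is.data.frame(table))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (nrow(table) == 0 && !allow_empty) {
    abort("refusing to write an empty table (use allow_empty = TRUE)")
  }
  if (format == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("jsonlite is required for JSON output")
    }
    jsonlite::write_json(table, path, auto_unbox = TRUE, digits = I(17), na = "null")
  } else {
    # format doubles at 17 significant digits so the round trip is lossless
    out <- dplyr::mutate(table, dplyr::across(
      dplyr::where(is.double),
      \(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    ))
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}

#' Read back a table written by [write_results()]
#'
#' @param path file written by [write_results()].
#' @return tibble; empty CSV fields come back as `NA` (undefined).
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("jsonlite is required for JSON input")
    }
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, na = "", show_col_types = FALSE, progress = FALSE)
  }
}
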