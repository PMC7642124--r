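#' Read line-probe intensity profiles from CSV
#'
#' Reads a study of 1-D line-probe intensity profiles sampled on orthoslices
#' of a contrast-enhanced micro-CT volume. One row per sampled point; profiles
#' are keyed by species, specimen, slice and staining time. The returned
#' tibble is validated (strictly increasing, uniformly spaced positions; equal
#' profile lengths within each probe; unique sample indices) and sorted by key
#' then position.
#'
#' @param path Path to a CSV file with columns `species`, `specimen`, `slice`,
#'   `time_h`, `index`, `position_mm`, `intensity_hu` (names remappable via
#'   `schema`).
#' @param schema Optional named character vector mapping the standard column
#'   names to the names used in the file, e.g.
#'   `c(position_mm = "x", intensity_hu = "hu")`.
#' @return A tibble with the standard columns, one row per sampled point,
#'   sorted by (species, specimen, slice, time_h, position_mm).
#' @seealso [write_profiles()], [validate_profiles()]
#' @export
read_profiles <- function(path, schema = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df)) {
        abort(sprintf("schema maps '%s' to column '%s', which is not in the file",
                      std, schema[[std]]), class = "dicect_schema_error")
      }
    }
    df <- rename(df, !!!rlang::set_names(unname(schema), names(schema)))
  }
  validate_profiles(df)
}

#' Validate a profiles table
#'
#' Checks the invariants every downstream stage assumes: required columns
#' present, sample indices unique within each probe, positions strictly
#' increasing and uniformly spaced, at least 16 samples per profile, equal
#' numbers of samples across profiles, and finite intensities.
#'
#' @param df A data frame of sampled points (see [read_profiles()] for the
#'   column contract). Extra columns are kept untouched.
#' @return The validated tibble, sorted by key then position.
#' @export
validate_profiles <- function(df) {
  check_columns(df, c("species", "specimen", "slice", "time_h", "index",
                      "position_mm", "intensity_hu"), "profiles table")
  df <- as_tibble(df) %>%
    mutate(slice = as.integer(.data$slice)) %>%
    arrange(.data$species, .data$specimen, .data$slice, .data$time_h,
            .data$position_mm)
  dup <- df %>%
    dplyr::count(.data$species, .data$specimen, .data$slice, .data$time_h,
                 .data$index) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicated (specimen, slice, time, index) rows, e.g. %s/%s slice %d t=%g index %d",
      dup$species[1], dup$specimen[1], dup$slice[1], dup$time_h[1], dup$index[1]
    ), class = "dicect_validation_error")
  }
  lens <- integer(0)
  for (g in split(df, paste(df$species, df$specimen, df$slice, df$time_h,
                            sep = "\r"))) {
    key <- sprintf("%s/%s slice %d t=%g h", g$species[1], g$specimen[1],
                   g$slice[1], g$time_h[1])
    if (nrow(g) < 16) {
      abort(sprintf("profile %s has %d samples; at least 16 required",
                    key, nrow(g)), class = "dicect_validation_error")
    }
    if (any(!is.finite(g$intensity_hu))) {
      abort(sprintf("profile %s contains non-finite intensities", key),
            class = "dicect_validation_error")
    }
    if (any(g$time_h < 0)) {
      abort(sprintf("profile %s has negative staining time", key),
            class = "dicect_validation_error")
    }
    uniform_spacing(g$position_mm, context = sprintf("positions of %s", key))
    lens <- c(lens, nrow(g))
  }
  if (length(unique(lens)) > 1) {
    abort("profiles have unequal sample counts across the study",
          class = "dicect_validation_error")
  }
  df
}

#' Write a profiles table to CSV
#'
#' Inverse of [read_profiles()]; comma separated, LF line endings, header row.
#'
#' @param df A validated profiles tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(df, path) {
  df <- validate_profiles(df)
  readr::write_csv(df, path, eol = "\n", progress = FALSE)
  invisible(path)
}

# Column order of the extracted-parameter (segment) table.
extracted_columns <- c(
  "species", "specimen", "slice", "time_h", "segment_index", "segment_label",
  "region", "x_left_mm", "x_right_mm", "edge_strength_left",
  "edge_strength_right", "mean_hu", "median_hu", "sd_hu", "iqr_hu",
  "width_mm", "n_samples"
)

#' Write an extracted-parameter table to CSV
#'
#' One row per (profile, segment): edge positions and strengths plus summary
#' statistics of the smoothed intensity within each inter-edge interval, in
#' the layout produced by [extract_profile()] / [run_pipeline()]. A header-only
#' file is written for an empty table.
#'
#' @param records Tibble of segment records (see [extract_profile()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_extracted()]
#' @export
write_extracted <- function(records, path) {
  if (nrow(records) == 0) {
    records <- tibble(
      species = character(), specimen = character(), slice = integer(),
      time_h = double(), segment_index = integer(), segment_label = character(),
      region = character(), x_left_mm = double(), x_right_mm = double(),
      edge_strength_left = double(), edge_strength_right = double(),
      mean_hu = double(), median_hu = double(), sd_hu = double(),
      iqr_hu = double(), width_mm = double(), n_samples = integer()
    )
  }
  check_columns(records, extracted_columns, "extracted table")
  readr::write_csv(records[extracted_columns], path, eol = "\n",
                   progress = FALSE)
  invisible(path)
}

#' Read an extracted-parameter table from CSV
#'
#' Reads a per-segment parameter table as written by [write_extracted()], or a
#' compatible file with remapped column names. Unrecognized extra columns are
#' kept; rows are sorted by key then segment index.
#'
#' @inheritParams read_profiles
#' @return A tibble with the standard segment columns.
#' @export
read_extracted <- function(path, schema = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df)) {
        abort(sprintf("schema maps '%s' to column '%s', which is not in the file",
                      std, schema[[std]]), class = "dicect_schema_error")
      }
    }
    df <- rename(df, !!!rlang::set_names(unname(schema), names(schema)))
  }
  if (!"region" %in% names(df)) df$region <- NA_character_
  if (!"n_samples" %in% names(df)) df$n_samples <- NA_integer_
  check_columns(df, setdiff(extracted_columns, c("region", "n_samples")),
                "extracted table")
  as_tibble(df) %>%
    mutate(slice = as.integer(.data$slice),
           segment_index = as.integer(.data$segment_index)) %>%
    arrange(.data$species, .data$specimen, .data$slice, .data$time_h,
            .data$segment_index)
}
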