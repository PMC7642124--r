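# End-to-end driver: profiles -> peak analysis -> slice metrics ->
# whole-brain series -> optimal times -> shrinkage report.

#' Read a declarative edge-override table
#'
#' Replaces the original workflow's interactive adjustment of edge selection:
#' a CSV with columns `species`, `specimen`, `slice`, `time_h`, `edge_index`,
#' `position_mm` listing, for specific profiles, the desired edge positions
#' (e.g. where an understained tissue's central trough produces spurious
#' interior peaks). Each listed profile must supply its full set of edges.
#'
#' @param path CSV file path.
#' @return A tibble of override rows.
#' @export
read_overrides <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("species", "specimen", "slice", "time_h", "edge_index",
                      "position_mm"), "override table")
  as_tibble(df) %>% mutate(slice = as.integer(.data$slice))
}

lookup_override <- function(overrides, species, specimen, slice, time_h) {
  if (is.null(overrides)) return(NULL)
  hit <- filter(overrides, .data$species == !!species,
                .data$specimen == !!specimen, .data$slice == !!slice,
                .data$time_h == !!time_h)
  if (nrow(hit) == 0) return(NULL)
  hit$position_mm[order(hit$edge_index)]
}

slice_config_for <- function(config, species, slice) {
  slices <- if (!is.null(config$slices)) config$slices
            else config[[species]]$slices
  sc <- slices[[as.character(slice)]]
  if (is.null(sc) || is.null(sc$labels)) {
    abort(sprintf("no segment-label configuration for species %s slice %s",
                  species, slice), class = "dicect_config_error")
  }
  if (is.null(sc$regions)) sc$regions <- rep(NA_character_, length(sc$labels))
  sc
}

#' Run the full stain-uptake analysis pipeline
#'
#' Applies, per profile: optional Hounsfield calibration, cubic-smoothing-
#' spline peak analysis ([extract_profile()]) and slice metrics
#' ([compute_slice_metrics()]); then pools per specimen
#' ([aggregate_whole_brain()]), selects optimal staining times at slice and
#' whole-brain level, and quantifies per-region shrinkage. A failure in one
#' profile (e.g. too few detectable edges) is recorded with its key and stage
#' and does not stop the rest of the study.
#'
#' @param profiles Long profiles tibble (see [read_profiles()]).
#' @param config Study configuration: a list with a `slices` element, itself
#'   a named list (by slice index) of `list(labels =, regions =)` segment
#'   configurations; [generate_study()] returns a matching `config`. May
#'   alternatively be keyed by species.
#' @param overrides Optional override table from [read_overrides()].
#' @param calibration Optional [phantom_calibration()]; when supplied the
#'   intensity column is converted to HU before analysis.
#' @param smoothing,min_prominence,prominence_k,min_separation Peak-analysis
#'   settings (see [smooth_profile()], [detect_edge_peaks()]).
#' @param p1_threshold,onset_fraction Optimal-time settings (see
#'   [slice_optimal_time()], [whole_brain_optimal_time()]).
#' @param region_map,exclude_regions Shrinkage settings (see
#'   [compute_region_shrinkage()]).
#' @return A list of class `dicect_run`: `extracted` (segment table),
#'   `slice_metrics`, `whole_brain`, `shrinkage`, `shrinkage_summary`,
#'   `slice_decisions` and `whole_brain_decisions` (lists of
#'   `optimal_time_decision`), `decisions` (their [glance()] rows),
#'   `failures`, and a `manifest` of the settings used (including each
#'   profile's selected smoothing parameter).
#' @export
run_pipeline <- function(profiles, config, overrides = NULL,
                         calibration = NULL, smoothing = "gcv",
                         min_prominence = "auto", prominence_k = 3,
                         min_separation = 5, p1_threshold = "auto",
                         onset_fraction = 0.1,
                         region_map = c(`1` = "OBs", `2` = "Tel", `3` = "Cer",
                                        `4` = "Med"),
                         exclude_regions = "Tel1") {
  profiles <- validate_profiles(profiles)
  if (!is.null(calibration)) {
    profiles$intensity_hu <- to_hounsfield(profiles$intensity_hu, calibration)
  }
  keys <- distinct(profiles, .data$species, .data$specimen, .data$slice,
                   .data$time_h)
  extracted <- list()
  slice_metrics <- list()
  spar_log <- list()
  failures <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    prof <- filter(profiles, .data$species == k$species,
                   .data$specimen == k$specimen, .data$slice == k$slice,
                   .data$time_h == k$time_h)
    res <- tryCatch({
      sc <- slice_config_for(config, k$species, k$slice)
      ov <- lookup_override(overrides, k$species, k$specimen, k$slice,
                            k$time_h)
      ex <- extract_profile(prof, labels = sc$labels, regions = sc$regions,
                            smoothing = smoothing,
                            min_prominence = min_prominence,
                            prominence_k = prominence_k,
                            min_separation = min_separation, override = ov)
      seg <- dplyr::bind_cols(k[rep(1, nrow(ex$segments)), ], ex$segments)
      sm <- compute_slice_metrics(seg, smoothed = ex$smoothed)
      list(segments = seg, metrics = sm,
           spar = attr(ex$smoothed, "spar"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- dplyr::bind_cols(
        k, tibble(stage = "peak_analysis",
                  message = conditionMessage(res)))
    } else {
      extracted[[length(extracted) + 1]] <- res$segments
      slice_metrics[[length(slice_metrics) + 1]] <- res$metrics
      spar_log[[length(spar_log) + 1]] <- dplyr::bind_cols(
        k, tibble(spar = res$spar))
    }
  }
  extracted <- bind_rows(extracted)
  slice_metrics <- bind_rows(slice_metrics)
  failures <- if (length(failures)) bind_rows(failures) else
    tibble(species = character(), specimen = character(), slice = integer(),
           time_h = double(), stage = character(), message = character())

  whole_brain <- list()
  wb_decisions <- list()
  slice_decisions <- list()
  if (nrow(slice_metrics) > 0) {
    for (g in slice_metrics %>%
           group_by(.data$species, .data$specimen, .data$slice) %>%
           dplyr::group_split()) {
      d <- tryCatch(slice_optimal_time(g, p1_threshold = p1_threshold),
                    error = function(e) e)
      if (inherits(d, "error")) {
        failures <- bind_rows(failures, dplyr::bind_cols(
          g[1, c("species", "specimen", "slice")],
          tibble(time_h = NA_real_, stage = "slice_optimal_time",
                 message = conditionMessage(d))))
      } else slice_decisions[[length(slice_decisions) + 1]] <- d
    }
    for (g in slice_metrics %>%
           group_by(.data$species, .data$specimen) %>%
           dplyr::group_split()) {
      # restrict pooling to times at which every slice was analysed, so a
      # profile failure at one time (e.g. undetectable unstained edges) does
      # not take the whole specimen down
      n_slices <- dplyr::n_distinct(g$slice)
      complete <- g %>%
        group_by(.data$time_h) %>%
        summarise(n = dplyr::n_distinct(.data$slice), .groups = "drop")
      dropped <- complete$time_h[complete$n < n_slices]
      if (length(dropped) > 0) {
        failures <- bind_rows(failures, tibble(
          species = g$species[1], specimen = g$specimen[1],
          slice = NA_integer_, time_h = dropped, stage = "coverage",
          message = "time point dropped from pooling: not all slices analysed"))
        g <- filter(g, !.data$time_h %in% dropped)
      }
      res <- tryCatch({
        wb <- aggregate_whole_brain(g, exclude_regions = exclude_regions)
        list(wb = wb,
             dec = whole_brain_optimal_time(wb,
                                            onset_fraction = onset_fraction))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- bind_rows(failures, dplyr::bind_cols(
          g[1, c("species", "specimen")],
          tibble(slice = NA_integer_, time_h = NA_real_,
                 stage = "whole_brain", message = conditionMessage(res))))
      } else {
        whole_brain[[length(whole_brain) + 1]] <- res$wb
        wb_decisions[[length(wb_decisions) + 1]] <- res$dec
      }
    }
  }
  whole_brain <- bind_rows(whole_brain)
  if (nrow(whole_brain) > 0) {
    class(whole_brain) <- c("whole_brain_series", class(whole_brain))
  }

  # shrinkage per (specimen, slice) group so one slice missing an endpoint
  # time does not void the rest; the study-wide first/last times define the
  # endpoints for every group
  shrinkage <- list()
  if (nrow(slice_metrics) > 0) {
    t_ends <- range(slice_metrics$time_h)
    for (g in slice_metrics %>%
           group_by(.data$species, .data$specimen, .data$slice) %>%
           dplyr::group_split()) {
      res <- tryCatch({
        if (!all(t_ends %in% g$time_h)) {
          abort(sprintf("missing the first (%g h) or last (%g h) time point",
                        t_ends[1], t_ends[2]),
                class = "dicect_coverage_error")
        }
        compute_region_shrinkage(g, region_map = region_map,
                                 exclude_regions = exclude_regions)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- bind_rows(failures, dplyr::bind_cols(
          g[1, c("species", "specimen", "slice")],
          tibble(time_h = NA_real_, stage = "shrinkage",
                 message = conditionMessage(res))))
      } else {
        shrinkage[[length(shrinkage) + 1]] <- res
      }
    }
  }
  shrinkage <- bind_rows(shrinkage)
  shrinkage_summary <- if (nrow(shrinkage) > 0) summarize_shrinkage(shrinkage)
                       else tibble()

  decisions <- bind_rows(
    purrr::map_dfr(slice_decisions, glance),
    purrr::map_dfr(wb_decisions, glance)
  )
  settings <- list(smoothing = smoothing, min_prominence = min_prominence,
                   prominence_k = prominence_k,
                   min_separation = min_separation,
                   p1_threshold = p1_threshold,
                   onset_fraction = onset_fraction,
                   region_map = as.list(region_map),
                   exclude_regions = exclude_regions,
                   calibrated = !is.null(calibration))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dicect")),
    settings = settings,
    settings_hash = rlang::hash(settings),
    n_profiles = nrow(keys), n_failed = nrow(failures),
    smoothing_parameters = bind_rows(spar_log)
  )
  structure(list(extracted = extracted, slice_metrics = slice_metrics,
                 whole_brain = whole_brain, shrinkage = shrinkage,
                 shrinkage_summary = shrinkage_summary,
                 slice_decisions = slice_decisions,
                 whole_brain_decisions = wb_decisions,
                 decisions = decisions, failures = failures,
                 manifest = manifest),
            class = "dicect_run")
}

#' @export
print.dicect_run <- function(x, ...) {
  cat(sprintf("<dicect_run> %d profile(s) analysed, %d failure(s)\n",
              x$manifest$n_profiles - x$manifest$n_failed,
              x$manifest$n_failed))
  if (nrow(x$decisions) > 0) {
    wb <- filter(x$decisions, .data$level == "whole_brain")
    for (i in seq_len(nrow(wb))) {
      cat(sprintf("  %s/%s whole-brain optimal time: %s h (%s)\n",
                  wb$species[i], wb$specimen[i],
                  format(wb$chosen_time_h[i]), wb$flag[i]))
    }
  }
  invisible(x)
}

#' Write the pipeline's artifact set to a directory
#'
#' Writes the extracted segment table, slice metrics (scalar columns),
#' whole-brain series, shrinkage tables, decision report and run manifest as
#' CSV/YAML files. Deterministic stages rewrite bit-identical files on rerun.
#'
#' @param run A `dicect_run` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_extracted(run$extracted, file.path(dir, "extracted.csv"))
  sm <- select(run$slice_metrics,
               -dplyr::any_of(c("p1_values", "p4_widths", "regions")))
  readr::write_csv(sm, file.path(dir, "slice_metrics.csv"), eol = "\n",
                   progress = FALSE)
  readr::write_csv(as_tibble(run$whole_brain),
                   file.path(dir, "whole_brain.csv"), eol = "\n",
                   progress = FALSE)
  readr::write_csv(run$shrinkage, file.path(dir, "shrinkage.csv"),
                   eol = "\n", progress = FALSE)
  readr::write_csv(run$shrinkage_summary,
                   file.path(dir, "shrinkage_summary.csv"), eol = "\n",
                   progress = FALSE)
  readr::write_csv(run$decisions, file.path(dir, "decisions.csv"),
                   eol = "\n", progress = FALSE)
  readr::write_csv(run$failures, file.path(dir, "failures.csv"),
                   eol = "\n", progress = FALSE)
  manifest <- run$manifest
  manifest$smoothing_parameters <- NULL
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  readr::write_csv(run$manifest$smoothing_parameters,
                   file.path(dir, "smoothing_parameters.csv"), eol = "\n",
                   progress = FALSE)
  invisible(dir)
}
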