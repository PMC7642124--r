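#' Per-slice staining parameters P1, P2, P3 and tissue widths
#'
#' Computes the slice-level stain-uptake parameters from an extracted segment
#' table:
#' \describe{
#'   \item{P1}{edge strength (absolute derivative peak height, HU/mm) at every
#'     brain-tissue edge on the slice — a proxy for inter-tissue boundary
#'     contrast;}
#'   \item{P2}{mean smoothed intensity pooled over brain-tissue samples minus
#'     the mean pooled over background (brain case) samples, in HU — the
#'     inter-tissue contrast proxy;}
#'   \item{P3}{interquartile range of the smoothed intensity pooled across the
#'     slice's brain-tissue samples, in HU — the intra-tissue staining
#'     homogeneity proxy (lower is more homogeneous);}
#'   \item{widths}{per-brain-segment tissue width `x_right - x_left`, mm.}
#' }
#' Segments labelled `excluded_nerve` (e.g. the vagus nerve on the hindbrain
#' slice) are omitted from P2 and P3. Pooling uses sample values, not segment
#' means: P2 weights segment means by their sample counts (algebraically the
#' pooled-sample mean), and P3 on a multi-segment slice is computed from the
#' smoothed samples, which must then be supplied via `smoothed`. Without
#' samples, a single-brain-segment slice falls back to that segment's stored
#' IQR.
#'
#' @param segments Segment tibble for one profile (one slice at one time),
#'   as produced by [extract_profile()]; key columns, if present, are carried
#'   through.
#' @param smoothed Optional `smoothed_profile` for the same probe, required
#'   for pooled P3 when the slice has more than one brain-tissue segment.
#' @return A one-row tibble with scalar columns `p1_mean`, `p1_min`, `p2`,
#'   `p3`, `width_mean` and list columns `p1_values`, `p4_widths`, `regions`
#'   (region label per brain segment).
#' @export
compute_slice_metrics <- function(segments, smoothed = NULL) {
  check_columns(segments, c("segment_label", "x_left_mm", "x_right_mm",
                            "edge_strength_left", "edge_strength_right",
                            "mean_hu", "iqr_hu", "width_mm", "n_samples"),
                "segment table")
  brain <- filter(segments, .data$segment_label == "brain_tissue")
  backg <- filter(segments, .data$segment_label == "background")
  if (nrow(brain) == 0) {
    abort("no segment labelled brain_tissue", class = "dicect_labeling_error")
  }
  if (nrow(backg) == 0) {
    abort("no segment labelled background", class = "dicect_labeling_error")
  }

  edge_tbl <- bind_rows(
    tibble(position = brain$x_left_mm, strength = brain$edge_strength_left),
    tibble(position = brain$x_right_mm, strength = brain$edge_strength_right)
  ) %>%
    distinct(.data$position, .keep_all = TRUE) %>%
    arrange(.data$position)
  p1_values <- edge_tbl$strength

  p2 <- stats::weighted.mean(brain$mean_hu, brain$n_samples) -
    stats::weighted.mean(backg$mean_hu, backg$n_samples)

  if (!is.null(smoothed)) {
    check_columns(smoothed, c("position_mm", "smoothed_hu"), "smoothed profile")
    pooled <- unlist(purrr::map2(brain$x_left_mm, brain$x_right_mm, function(a, b) {
      smoothed$smoothed_hu[smoothed$position_mm > a & smoothed$position_mm < b]
    }))
    p3 <- unname(quantile(pooled, 0.75, type = 7) -
                   quantile(pooled, 0.25, type = 7))
  } else if (nrow(brain) == 1) {
    p3 <- brain$iqr_hu
  } else {
    abort(paste("pooled P3 for a multi-segment slice requires the smoothed",
                "profile samples; supply `smoothed`"),
          class = "dicect_validation_error")
  }

  keys <- intersect(c("species", "specimen", "slice", "time_h"),
                    names(segments))
  out <- tibble(
    p1_mean = mean(p1_values),
    p1_min = min(p1_values),
    p2 = p2,
    p3 = p3,
    width_mean = mean(brain$width_mm),
    p1_values = list(p1_values),
    p4_widths = list(brain$width_mm),
    regions = list(if ("region" %in% names(brain)) brain$region
                   else rep(NA_character_, nrow(brain)))
  )
  if (length(keys) > 0) {
    out <- dplyr::bind_cols(segments[1, keys, drop = FALSE], out)
  }
  out
}

#' Linear shrinkage percentage
#'
#' `100 * (start - end) / start`: the percentage by which a tissue width has
#' decreased between the start and end of staining. Negative values indicate
#' swelling and are reported with their sign, never clamped.
#'
#' @param start_width_mm Starting width(s), mm; must be positive.
#' @param end_width_mm Ending width(s), mm.
#' @return Shrinkage percentage(s).
#' @export
#' @examples
#' shrinkage_percent(5.46, 4.78) # ~12.45
shrinkage_percent <- function(start_width_mm, end_width_mm) {
  if (any(!is.finite(start_width_mm)) || any(start_width_mm <= 0)) {
    abort("start_width_mm must be positive", class = "dicect_domain_error")
  }
  100 * (start_width_mm - end_width_mm) / start_width_mm
}

#' Per-region linear shrinkage between first and last staining time
#'
#' For each specimen and brain region (one region per slice), takes the
#' brain-tissue width at the first (unstained) time point as the starting
#' width, the width at the last time point as the ending width, and applies
#' [shrinkage_percent()]. When a slice carries several brain segments, the
#' widths of the non-excluded segments are averaged per slice before the
#' formula. Segments whose region label is in `exclude_regions` (by default
#' the anterior telencephalon sliver on the olfactory-bulb slice, where
#' shrinkage is also rostro-caudal and would bias the transverse measure)
#' are dropped.
#'
#' @param slice_metrics Tibble from [compute_slice_metrics()] rows covering
#'   one or more specimens over the full time grid (needs key columns and the
#'   `p4_widths` / `regions` list columns).
#' @param region_map Named character vector mapping slice index to region
#'   name.
#' @param exclude_regions Region labels dropped from width averaging.
#' @return A tibble: `species`, `specimen`, `region`, `start_width_mm`,
#'   `end_width_mm`, `percent`.
#' @export
compute_region_shrinkage <- function(slice_metrics,
                                     region_map = c(`1` = "OBs", `2` = "Tel",
                                                    `3` = "Cer", `4` = "Med"),
                                     exclude_regions = "Tel1") {
  check_columns(slice_metrics, c("species", "specimen", "slice", "time_h",
                                 "p4_widths", "regions"), "slice metrics")
  t0 <- min(slice_metrics$time_h)
  t_end <- max(slice_metrics$time_h)
  slice_width <- function(row) {
    w <- row$p4_widths[[1]]
    r <- row$regions[[1]]
    keep <- is.na(r) | !(r %in% exclude_regions)
    if (!any(keep)) return(NA_real_)
    mean(w[keep])
  }
  groups <- slice_metrics %>%
    group_by(.data$species, .data$specimen, .data$slice) %>%
    dplyr::group_split()
  purrr::map_dfr(groups, function(g) {
    key <- sprintf("%s/%s slice %d", g$species[1], g$specimen[1], g$slice[1])
    if (!any(g$time_h == t0) || !any(g$time_h == t_end)) {
      abort(sprintf("%s is missing the first (%g h) or last (%g h) time point",
                    key, t0, t_end), class = "dicect_coverage_error")
    }
    start <- slice_width(g[g$time_h == t0, ][1, ])
    end <- slice_width(g[g$time_h == t_end, ][1, ])
    region <- region_map[as.character(g$slice[1])]
    tibble(
      species = g$species[1], specimen = g$specimen[1],
      region = if (is.na(region)) sprintf("slice%d", g$slice[1]) else unname(region),
      start_width_mm = start, end_width_mm = end,
      percent = shrinkage_percent(start, end)
    )
  })
}

#' Pool slice metrics into a whole-brain time series
#'
#' Two-stage unweighted averaging of each parameter: within a slice first
#' (when a slice has more than one P1 value or tissue width), then across the
#' slices at each time point. Width pooling drops segments whose region is in
#' `exclude_regions`.
#'
#' @inheritParams compute_region_shrinkage
#' @return A tibble of class `whole_brain_series`: `species`, `specimen`,
#'   `time_h`, `mean_p1`, `mean_p2`, `mean_p3`, `mean_width`.
#' @export
aggregate_whole_brain <- function(slice_metrics, exclude_regions = "Tel1") {
  check_columns(slice_metrics, c("species", "specimen", "slice", "time_h",
                                 "p1_values", "p2", "p3", "p4_widths",
                                 "regions"), "slice metrics")
  all_slices <- sort(unique(slice_metrics$slice))
  per_slice <- slice_metrics %>%
    mutate(
      slice_p1 = purrr::map_dbl(.data$p1_values, mean),
      slice_width = purrr::map2_dbl(.data$p4_widths, .data$regions, function(w, r) {
        keep <- is.na(r) | !(r %in% exclude_regions)
        if (!any(keep)) NA_real_ else mean(w[keep])
      })
    )
  gaps <- per_slice %>%
    group_by(.data$species, .data$specimen, .data$time_h) %>%
    summarise(missing = paste(setdiff(all_slices, .data$slice), collapse = ","),
              .groups = "drop") %>%
    filter(.data$missing != "")
  if (nrow(gaps) > 0) {
    abort(sprintf("missing slice(s) %s for %s/%s at t=%g h",
                  gaps$missing[1], gaps$species[1], gaps$specimen[1],
                  gaps$time_h[1]),
          class = "dicect_coverage_error")
  }
  out <- per_slice %>%
    group_by(.data$species, .data$specimen, .data$time_h) %>%
    summarise(
      mean_p1 = mean(.data$slice_p1),
      mean_p2 = mean(.data$p2),
      mean_p3 = mean(.data$p3),
      mean_width = mean(.data$slice_width, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    arrange(.data$species, .data$specimen, .data$time_h)
  class(out) <- c("whole_brain_series", class(out))
  out
}

#' Plot a whole-brain parameter series over staining time
#'
#' @param object A `whole_brain_series` from [aggregate_whole_brain()].
#' @param ... Unused.
#' @return A ggplot object faceted by parameter.
#' @exportS3Method ggplot2::autoplot
autoplot.whole_brain_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("mean_p1", "mean_p2", "mean_p3", "mean_width"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value,
                                     colour = .data$specimen)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "staining time (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Summarize shrinkage across specimens and regions
#'
#' Region-wise mean and SD (n-1) of shrinkage percentages across specimens,
#' plus an overall mean and SD over the flat region-by-specimen values (not
#' the mean of region means, which differs when region counts are unequal).
#' A region with a single specimen reports `NA` for its SD.
#'
#' @param results Tibble with columns `region`, `percent` and optionally
#'   `species` (summaries are per species when present) and `specimen`.
#' @return A tibble: (`species`,) `region`, `mean_percent`, `sd_percent`,
#'   `n`; one `Overall` row per species.
#' @export
summarize_shrinkage <- function(results) {
  check_columns(results, c("region", "percent"), "shrinkage results")
  if (!"species" %in% names(results)) results$species <- "all"
  per_species <- function(g) {
    by_region <- g %>%
      group_by(.data$region) %>%
      summarise(mean_percent = mean(.data$percent),
                sd_percent = sd_or_na(.data$percent),
                n = dplyr::n(), .groups = "drop")
    overall <- tibble(region = "Overall",
                      mean_percent = mean(g$percent),
                      sd_percent = sd_or_na(g$percent),
                      n = nrow(g))
    bind_rows(by_region, overall) %>%
      mutate(species = g$species[1], .before = 1)
  }
  results %>%
    group_by(.data$species) %>%
    dplyr::group_split() %>%
    purrr::map_dfr(per_species)
}
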