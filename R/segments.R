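#' Summary statistics of the smoothed profile over an inter-edge interval
#'
#' Mean, median, standard deviation (n-1 denominator) and interquartile range
#' (linear interpolation between order statistics, quantile type 7) of the
#' smoothed intensity at sample positions strictly inside the open interval
#' `(x_left, x_right)`. Open intervals ensure edge samples are not
#' double-counted between adjacent segments.
#'
#' @param sp A [smooth_profile()] result.
#' @param x_left,x_right Interval bounds in mm, within the probe range, with
#'   at least 4 samples strictly inside.
#' @return A one-row tibble: `mean_hu`, `median_hu`, `sd_hu`, `iqr_hu`,
#'   `n_samples`, plus the interval bounds and `width_mm`; attribute
#'   `quantile_type = 7` records the quartile convention.
#' @export
segment_stats <- function(sp, x_left, x_right) {
  check_columns(sp, c("position_mm", "smoothed_hu"), "smoothed profile")
  if (!(x_left < x_right)) {
    abort("x_left must be < x_right", class = "dicect_range_error")
  }
  rng <- range(sp$position_mm)
  if (x_left < rng[1] - 1e-9 || x_right > rng[2] + 1e-9) {
    abort(sprintf("interval (%.4g, %.4g) lies outside the probe range [%.4g, %.4g]",
                  x_left, x_right, rng[1], rng[2]),
          class = "dicect_range_error")
  }
  inside <- sp$position_mm > x_left & sp$position_mm < x_right
  v <- sp$smoothed_hu[inside]
  if (length(v) < 4) {
    abort(sprintf(
      "interval (%.4g, %.4g) contains only %d interior sample(s); at least 4 required",
      x_left, x_right, length(v)), class = "dicect_degenerate_interval_error")
  }
  out <- tibble(
    x_left_mm = x_left,
    x_right_mm = x_right,
    width_mm = x_right - x_left,
    mean_hu = mean(v),
    median_hu = median(v),
    sd_hu = sd(v),
    iqr_hu = unname(quantile(v, 0.75, type = 7) - quantile(v, 0.25, type = 7)),
    n_samples = length(v)
  )
  attr(out, "quantile_type") <- 7L
  out
}

#' Extract the per-segment parameter record for one profile
#'
#' The core per-profile procedure: smooth the intensity profile with a cubic
#' smoothing spline, detect significant derivative peaks, select the expected
#' edge pairs about the probe midpoint (with optional override positions),
#' and compute segment statistics of the smoothed profile between each pair
#' of consecutive edges. `2k` selected edges delimit `2k - 1` segments, each
#' labelled background / brain tissue / excluded nerve from the slice
#' configuration.
#'
#' @param profile Data frame with `position_mm` and `intensity_hu` columns
#'   for one probe.
#' @param labels Character vector of segment labels, length `2k - 1`, values
#'   in `"background"`, `"brain_tissue"`, `"excluded_nerve"`; the expected
#'   edge count `2k` is inferred from its length.
#' @param regions Optional character vector (same length) of anatomical
#'   region names for brain-tissue segments (`NA` elsewhere), used by the
#'   shrinkage analysis.
#' @param smoothing,min_prominence,prominence_k,min_separation Passed to
#'   [smooth_profile()] and [detect_edge_peaks()].
#' @param override Optional numeric vector of edge positions (mm) passed to
#'   [pair_edges()].
#' @return A list with components `segments` (tibble, one row per segment
#'   with edge positions/strengths and interval statistics), `edges` (the
#'   selected edge tibble) and `smoothed` (the `smoothed_profile`).
#' @export
extract_profile <- function(profile, labels, regions = NULL,
                            smoothing = "gcv", min_prominence = "auto",
                            prominence_k = 3, min_separation = 5,
                            override = NULL) {
  bad <- setdiff(labels, c("background", "brain_tissue", "excluded_nerve"))
  if (length(bad) > 0) {
    abort(sprintf("unknown segment label(s): %s", paste(bad, collapse = ", ")),
          class = "dicect_validation_error")
  }
  n_edges <- length(labels) + 1L
  if (n_edges %% 2L != 0L) {
    abort("`labels` must have odd length (2k edges delimit 2k - 1 segments)",
          class = "dicect_validation_error")
  }
  if (is.null(regions)) regions <- rep(NA_character_, length(labels))
  if (length(regions) != length(labels)) {
    abort("`regions` must have the same length as `labels`",
          class = "dicect_validation_error")
  }
  sp <- smooth_profile(profile, smoothing = smoothing)
  cand <- detect_edge_peaks(sp, min_prominence = min_prominence,
                            prominence_k = prominence_k,
                            min_separation = min_separation)
  midpoint <- (min(sp$position_mm) + max(sp$position_mm)) / 2
  edges <- pair_edges(cand, expected_pairs = n_edges / 2,
                      midpoint_mm = midpoint, override = override)
  segments <- purrr::map_dfr(seq_len(n_edges - 1L), function(i) {
    st <- segment_stats(sp, edges$position_mm[i], edges$position_mm[i + 1])
    tibble(
      segment_index = i,
      segment_label = labels[i],
      region = regions[i],
      x_left_mm = st$x_left_mm,
      x_right_mm = st$x_right_mm,
      edge_strength_left = edges$strength[i],
      edge_strength_right = edges$strength[i + 1],
      mean_hu = st$mean_hu,
      median_hu = st$median_hu,
      sd_hu = st$sd_hu,
      iqr_hu = st$iqr_hu,
      width_mm = st$width_mm,
      n_samples = st$n_samples
    )
  })
  list(segments = segments, edges = edges, smoothed = sp)
}
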