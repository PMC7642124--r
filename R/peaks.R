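# Significant-peak detection on the first derivative of a smoothed profile,
# and selection of edge pairs about the probe midpoint.

# Local maxima of a numeric vector with topographic prominence.
# Returns a data frame (index, height, prominence). A peak's prominence is
# its height minus the higher of the two lowest points separating it from
# higher terrain on either side (the boundary acting as higher terrain when
# none exists). Plateaus are represented by their first sample.
find_peaks <- function(v) {
  n <- length(v)
  if (n < 3) return(data.frame(index = integer(), height = double(),
                               prominence = double()))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(idx) == 0) return(data.frame(index = integer(), height = double(),
                                          prominence = double()))
  prom <- vapply(idx, function(i) {
    h <- v[i]
    j <- i
    left_min <- h
    while (j > 1 && v[j] <= h) {
      j <- j - 1
      if (v[j] < left_min) left_min <- v[j]
    }
    j <- i
    right_min <- h
    while (j < n && v[j] <= h) {
      j <- j + 1
      if (v[j] < right_min) right_min <- v[j]
    }
    h - max(left_min, right_min)
  }, 0)
  data.frame(index = idx, height = v[idx], prominence = prom)
}

# Greedy enforcement of a minimum index separation: keep peaks in decreasing
# prominence order, dropping any within `min_sep` samples of one already kept.
enforce_separation <- function(pk, min_sep) {
  if (nrow(pk) < 2 || min_sep <= 0) return(pk)
  ord <- order(-pk$prominence, pk$index)
  keep <- logical(nrow(pk))
  kept_idx <- integer(0)
  for (i in ord) {
    if (all(abs(pk$index[i] - kept_idx) >= min_sep)) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, pk$index[i])
    }
  }
  pk[keep, , drop = FALSE]
}

#' Detect tissue-edge candidates as significant derivative peaks
#'
#' Locates the significant positive (rising edge) and negative (falling edge)
#' peaks of the first derivative of a smoothed profile. The positions of
#' these peaks are the candidate tissue-edge positions; the absolute peak
#' height is the edge strength. "Significant" is operationalized as
#' topographic prominence of at least `min_prominence`; by default the
#' threshold adapts to the profile as 3 robust standard deviations
#' (1.4826 x median absolute deviation) of the derivative.
#'
#' @param sp A [smooth_profile()] result.
#' @param min_prominence `"auto"` (default) or a fixed threshold in HU/mm.
#'   The auto threshold is
#'   `max(prominence_k * 1.4826 * mad(derivative), rel_floor * max(|derivative|))`:
#'   the robust-sigma term adapts to the profile's noise, while the relative
#'   floor keeps numerically tiny ripples insignificant on noise-free
#'   profiles, where the robust sigma collapses towards zero.
#' @param prominence_k Multiplier on the robust sigma for the auto threshold.
#' @param rel_floor Fraction of the maximum absolute derivative used as the
#'   auto threshold's lower bound.
#' @param min_separation Minimum number of samples between retained peaks of
#'   the same sign; lower-prominence peaks closer than this are dropped.
#' @return A tibble of candidates sorted by position: `sample_index`,
#'   `position_mm`, `signed_height` (derivative value at the peak, HU/mm),
#'   `sign` (`"rising"`/`"falling"`), `prominence`. Empty when the derivative
#'   has no significant structure (e.g. a flat profile).
#' @export
detect_edge_peaks <- function(sp, min_prominence = "auto", prominence_k = 3,
                              min_separation = 5, rel_floor = 0.01) {
  check_columns(sp, c("position_mm", "derivative_hu_mm"), "smoothed profile")
  d <- sp$derivative_hu_mm
  if (identical(min_prominence, "auto")) {
    min_prominence <- max(prominence_k * mad(d), rel_floor * max(abs(d)))
  }
  out <- list()
  for (s in c("rising", "falling")) {
    # prominence is measured on the polarity's half-wave (negatives clipped
    # to zero): a small wiggle beside a large opposite-sign peak must not
    # inherit prominence from the deep valley between them, so a peak's
    # prominence is bounded by its own height above zero
    v <- pmax(if (s == "rising") d else -d, 0)
    pk <- find_peaks(v)
    pk <- pk[pk$height >= min_prominence & pk$prominence >= min_prominence, ,
             drop = FALSE]
    pk <- enforce_separation(pk, min_separation)
    if (nrow(pk) > 0) {
      out[[s]] <- tibble(
        sample_index = pk$index,
        position_mm = sp$position_mm[pk$index],
        signed_height = d[pk$index],
        sign = s,
        prominence = pk$prominence
      )
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(sample_index = integer(), position_mm = double(),
                  signed_height = double(), sign = character(),
                  prominence = double()))
  }
  arrange(res, .data$position_mm)
}

# Lexicographic comparison of score triples (higher is better).
score_better <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + 1e-12) return(TRUE)
    if (a[i] < b[i] - 1e-12) return(FALSE)
  }
  FALSE
}

#' Select paired tissue edges about the probe midpoint
#'
#' From detected edge candidates, selects `expected_pairs` pairs of edges
#' (2 x `expected_pairs` edges in total) delimiting the stained structures on
#' the probe. Automatic selection maximizes total prominence over ordered
#' subsequences whose first edge is rising at or left of the midpoint and
#' whose last edge is falling at or right of it, so the selected span always
#' brackets the midpoint; ties are broken in favour of candidates nearer the
#' midpoint, then leftmost. The signs of interior edges are unconstrained
#' because the contrast between a stained tissue and the surrounding brain
#' case reverses over staining time.
#'
#' When the automatic choice does not coincide with the desired tissue edges
#' (e.g. a trough inside an understained tissue produces spurious interior
#' peaks), supply `override` positions: each is snapped to the nearest
#' candidate within `snap_window` samples and the snapped set is used
#' verbatim.
#'
#' @param candidates Tibble from [detect_edge_peaks()].
#' @param expected_pairs Number of edge pairs to select (>= 1).
#' @param midpoint_mm Midpoint of the line probe in mm.
#' @param override Optional numeric vector of edge positions (mm), length
#'   `2 * expected_pairs`, replacing automatic selection.
#' @param snap_window Snap radius for override positions, in samples.
#' @return A tibble of `2 * expected_pairs` edges sorted by position:
#'   `edge_index`, `sample_index`, `position_mm`, `signed_height`, `sign`,
#'   `strength` (absolute height), `prominence`; attribute `pairing_source`
#'   is `"automatic"` or `"override"`.
#' @export
pair_edges <- function(candidates, expected_pairs, midpoint_mm,
                       override = NULL, snap_window = 10) {
  if (!is.numeric(expected_pairs) || expected_pairs < 1) {
    abort("`expected_pairs` must be >= 1", class = "dicect_validation_error")
  }
  k2 <- as.integer(2 * expected_pairs)

  if (!is.null(override)) {
    if (length(override) != k2) {
      abort(sprintf("override supplies %d positions; %d expected",
                    length(override), k2), class = "dicect_pairing_error")
    }
    chosen <- integer(0)
    for (pos in sort(override)) {
      free <- setdiff(seq_len(nrow(candidates)), chosen)
      if (length(free) == 0) {
        abort("override has more positions than available candidates",
              class = "dicect_pairing_error")
      }
      d_samp <- abs(candidates$position_mm[free] - pos) /
        position_spacing(candidates, pos)
      j <- free[which.min(d_samp)]
      if (min(d_samp) > snap_window) {
        abort(sprintf(
          "no edge candidate within %d samples of override position %.4g mm",
          snap_window, pos), class = "dicect_pairing_error")
      }
      chosen <- c(chosen, j)
    }
    return(build_edge_set(candidates[sort(chosen), ], "override"))
  }

  if (nrow(candidates) < k2) {
    abort(sprintf(
      "found %d edge candidate(s) at [%s] mm; %d needed for %g pair(s)",
      nrow(candidates),
      paste(format(candidates$position_mm, digits = 4), collapse = ", "),
      k2, expected_pairs), class = "dicect_pairing_error")
  }

  cand <- arrange(candidates, .data$position_mm)
  n <- nrow(cand)
  dist_mid <- abs(cand$position_mm - midpoint_mm)
  # dp[[j]][[i]]: best (sum prominence, -sum dist to midpoint, -sum position)
  # over subsequences of length j ending at candidate i, with the first edge
  # rising and <= midpoint. back[[j]][i] stores the predecessor.
  neg_inf <- c(-Inf, -Inf, -Inf)
  dp <- lapply(seq_len(k2), function(j) lapply(seq_len(n), function(i) neg_inf))
  back <- lapply(seq_len(k2), function(j) integer(n))
  for (i in seq_len(n)) {
    if (cand$sign[i] == "rising" && cand$position_mm[i] <= midpoint_mm) {
      dp[[1]][[i]] <- c(cand$prominence[i], -dist_mid[i], -cand$position_mm[i])
    }
  }
  if (k2 >= 2) {
    for (j in 2:k2) {
      for (i in j:n) {
        for (p in (j - 1):(i - 1)) {
          prev <- dp[[j - 1]][[p]]
          if (!is.finite(prev[1])) next
          candidate_score <- prev + c(cand$prominence[i], -dist_mid[i],
                                      -cand$position_mm[i])
          if (score_better(candidate_score, dp[[j]][[i]])) {
            dp[[j]][[i]] <- candidate_score
            back[[j]][i] <- p
          }
        }
      }
    }
  }
  best <- neg_inf
  best_i <- 0L
  for (i in seq_len(n)) {
    if (cand$sign[i] != "falling" || cand$position_mm[i] < midpoint_mm) next
    if (score_better(dp[[k2]][[i]], best)) {
      best <- dp[[k2]][[i]]
      best_i <- i
    }
  }
  if (best_i == 0L) {
    abort(sprintf(
      "no admissible selection of %g edge pair(s) bracketing the midpoint (%.4g mm) among %d candidates",
      expected_pairs, midpoint_mm, n), class = "dicect_pairing_error")
  }
  sel <- integer(k2)
  i <- best_i
  for (j in k2:1) {
    sel[j] <- i
    i <- back[[j]][i]
  }
  build_edge_set(cand[sel, ], "automatic")
}

# Approximate sample spacing near a position, from candidate sample indices.
position_spacing <- function(candidates, pos) {
  if (nrow(candidates) >= 2) {
    dp <- diff(candidates$position_mm) / diff(candidates$sample_index)
    sp <- stats::median(dp[is.finite(dp) & dp > 0])
    if (is.finite(sp) && sp > 0) return(sp)
  }
  1
}

build_edge_set <- function(edges, source) {
  edges <- arrange(edges, .data$position_mm) %>%
    mutate(edge_index = dplyr::row_number(),
           strength = abs(.data$signed_height)) %>%
    select(all_of(c("edge_index", "sample_index", "position_mm",
                    "signed_height", "sign", "strength", "prominence")))
  attr(edges, "pairing_source") <- source
  edges
}
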