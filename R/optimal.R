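# Optimal-staining-time selection at slice and whole-brain level.

new_decision <- function(level, keys, chosen_time_h, candidate_times_h,
                         onset_time_h, rationale, flag, detail = list()) {
  structure(
    list(level = level, keys = keys, chosen_time_h = chosen_time_h,
         candidate_times_h = candidate_times_h, onset_time_h = onset_time_h,
         rationale = rationale, flag = flag, detail = detail),
    class = "optimal_time_decision"
  )
}

#' Optimal staining time for a single slice
#'
#' Two-step rule. Step 1 selects the candidate time points at which a clear
#' edge response exists across the line profile: every brain-tissue edge
#' must have strength P1 at or above a threshold. The study's visual
#' assessment is operationalized as an automatic threshold of 10 times the
#' median P1 at the first (unstained) time point, with a configurable floor;
#' the threshold actually used is recorded in the decision. Step 2 chooses,
#' among candidates, the time with minimum P3 (best intra-tissue
#' homogeneity); candidates whose P3 lies within a relative tolerance of the
#' minimum are treated as tied and the tie is broken by the largest P2
#' (inter-tissue contrast).
#'
#' @param series Tibble with one row per staining time for one slice:
#'   columns `time_h`, `p2`, `p3` and either a `p1_values` list column or a
#'   `p1_min` column (with `p1_values` also used for the auto threshold's
#'   median; `p1_min` is used for both when values are absent). At least two
#'   time points.
#' @param p1_threshold `"auto"` or a fixed threshold in HU/mm.
#' @param p1_floor Lower bound on the automatic threshold.
#' @param auto_multiplier Multiplier on the first-time-point median P1.
#' @param tie_tolerance Relative tolerance within which P3 values count as
#'   tied.
#' @return An `optimal_time_decision`. When no time passes step 1 the
#'   decision has `chosen_time_h = NA` and flag `"understained"` (this is a
#'   result, not an error).
#' @export
slice_optimal_time <- function(series, p1_threshold = "auto", p1_floor = 0,
                               auto_multiplier = 10, tie_tolerance = 0.05) {
  check_columns(series, c("time_h", "p2", "p3"), "slice series")
  if (!("p1_values" %in% names(series)) && !("p1_min" %in% names(series))) {
    abort("series needs a `p1_values` list column or a `p1_min` column",
          class = "dicect_validation_error")
  }
  if (nrow(series) < 2) {
    abort("at least 2 time points are required",
          class = "dicect_validation_error")
  }
  series <- arrange(series, .data$time_h)
  has_values <- "p1_values" %in% names(series)
  p1_min <- if (has_values) {
    purrr::map_dbl(series$p1_values, min)
  } else {
    series$p1_min
  }
  if (identical(p1_threshold, "auto")) {
    first_p1 <- if (has_values) series$p1_values[[1]] else series$p1_min[1]
    p1_threshold <- max(p1_floor, auto_multiplier * median(first_p1))
  }
  passes <- p1_min >= p1_threshold
  rationale <- tibble(
    time_h = series$time_h, p1_min = p1_min, passes_p1 = passes,
    p3 = series$p3, p2 = series$p2
  )
  keys <- as.list(series[1, intersect(c("species", "specimen", "slice"),
                                      names(series)), drop = FALSE])
  if (!any(passes)) {
    return(new_decision("slice", keys, NA_real_, numeric(0), NA_real_,
                        rationale, "understained",
                        list(p1_threshold = p1_threshold)))
  }
  cand <- rationale[passes, ]
  p3_min <- min(cand$p3)
  tied <- cand$p3 <= p3_min * (1 + tie_tolerance)
  finalists <- cand[tied, ]
  chosen <- finalists$time_h[order(-finalists$p2, -finalists$time_h)][1]
  new_decision("slice", keys, chosen, cand$time_h, NA_real_, rationale,
               if (sum(tied) > 1) "p3_tie_broken_by_p2" else "ok",
               list(p1_threshold = p1_threshold,
                    tie_tolerance = tie_tolerance))
}

#' Optimal staining time for the whole brain
#'
#' Works on the pooled per-time means of P1-P3 across all slices of one
#' specimen. The onset of stain uptake is the earliest time at which mean P2
#' reaches `onset_fraction` of its series maximum (P2 is approximately zero
#' before uptake). Restricted to times at or after onset, the rule looks for
#' the time that simultaneously maximizes mean P1, maximizes mean P2 and
#' minimizes mean P3. When the three criteria agree the choice is unambiguous;
#' when they disagree, each criterion's optimum is recorded and the decision
#' is taken by majority vote, remaining ties resolved in favour of the latest
#' time, with the disagreement flagged in the result.
#'
#' @param series Tibble with columns `time_h`, `mean_p1`, `mean_p2`,
#'   `mean_p3` for one specimen (e.g. one specimen's rows of
#'   [aggregate_whole_brain()]). At least three time points.
#' @param onset_fraction Fraction of the peak mean P2 defining onset,
#'   in (0, 1).
#' @return An `optimal_time_decision` with `onset_time_h` set. A series whose
#'   mean P2 never becomes positive yields `chosen_time_h = NA` and flag
#'   `"unstained"`.
#' @export
whole_brain_optimal_time <- function(series, onset_fraction = 0.1) {
  check_columns(series, c("time_h", "mean_p1", "mean_p2", "mean_p3"),
                "whole-brain series")
  if (nrow(series) < 3) {
    abort("at least 3 time points are required",
          class = "dicect_validation_error")
  }
  if (!(onset_fraction > 0 && onset_fraction < 1)) {
    abort("onset_fraction must lie in (0, 1)", class = "dicect_validation_error")
  }
  series <- arrange(as_tibble(series), .data$time_h)
  keys <- as.list(series[1, intersect(c("species", "specimen"), names(series)),
                         drop = FALSE])
  rationale <- series[c("time_h", "mean_p1", "mean_p2", "mean_p3")]
  p2_max <- max(series$mean_p2)
  if (p2_max <= 0) {
    return(new_decision("whole_brain", keys, NA_real_, numeric(0), NA_real_,
                        rationale, "unstained"))
  }
  onset <- min(series$time_h[series$mean_p2 >= onset_fraction * p2_max])
  post <- series[series$time_h >= onset, ]
  latest_of <- function(times) max(times)
  t_p1 <- latest_of(post$time_h[post$mean_p1 == max(post$mean_p1)])
  t_p2 <- latest_of(post$time_h[post$mean_p2 == max(post$mean_p2)])
  t_p3 <- latest_of(post$time_h[post$mean_p3 == min(post$mean_p3)])
  votes <- c(p1 = t_p1, p2 = t_p2, p3 = t_p3)
  tab <- table(votes)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  chosen <- max(winners)
  agree <- length(unique(votes)) == 1
  new_decision("whole_brain", keys, chosen, post$time_h, onset, rationale,
               if (agree) "unambiguous" else "criteria_disagree",
               list(criterion_optima = votes,
                    onset_fraction = onset_fraction))
}

#' @export
print.optimal_time_decision <- function(x, ...) {
  key_str <- paste(unlist(x$keys), collapse = "/")
  cat(sprintf("<optimal_time_decision> level: %s%s\n", x$level,
              if (nzchar(key_str)) paste0(" (", key_str, ")") else ""))
  if (is.na(x$chosen_time_h)) {
    cat(sprintf("  no optimum: flagged '%s'\n", x$flag))
  } else {
    cat(sprintf("  chosen time: %g h (flag: %s)\n", x$chosen_time_h, x$flag))
    cat(sprintf("  candidates: %s h\n",
                paste(x$candidate_times_h, collapse = ", ")))
  }
  if (!is.na(x$onset_time_h)) {
    cat(sprintf("  uptake onset: %g h\n", x$onset_time_h))
  }
  invisible(x)
}

#' Per-time criterion trace of an optimal-time decision
#'
#' @param x An `optimal_time_decision`.
#' @param ... Unused.
#' @return The rationale tibble, one row per staining time.
#' @exportS3Method generics::tidy
tidy.optimal_time_decision <- function(x, ...) {
  out <- x$rationale
  for (nm in names(x$keys)) out[[nm]] <- x$keys[[nm]]
  out
}

#' One-row summary of an optimal-time decision
#'
#' @inheritParams tidy.optimal_time_decision
#' @return A one-row tibble: keys, level, chosen and onset times, number of
#'   candidate times, and the decision flag.
#' @exportS3Method generics::glance
glance.optimal_time_decision <- function(x, ...) {
  dplyr::bind_cols(
    as_tibble(x$keys),
    tibble(level = x$level, chosen_time_h = x$chosen_time_h,
           onset_time_h = x$onset_time_h,
           n_candidates = length(x$candidate_times_h), flag = x$flag)
  )
}

#' Plot the criterion traces behind an optimal-time decision
#'
#' @param object An `optimal_time_decision`.
#' @param ... Unused.
#' @return A ggplot object; the chosen time is marked with a vertical line.
#' @exportS3Method ggplot2::autoplot
autoplot.optimal_time_decision <- function(object, ...) {
  long <- tidyr::pivot_longer(object$rationale,
                              -dplyr::any_of(c("time_h", "passes_p1")),
                              names_to = "criterion", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$criterion), scales = "free_y") +
    ggplot2::labs(x = "staining time (h)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$chosen_time_h)) {
    p <- p + ggplot2::geom_vline(xintercept = object$chosen_time_h,
                                 linetype = "dashed", colour = "red3")
  }
  p
}
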