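# Synthetic stain-ingress generator: line-profile time series with the
# statistical structure the analysis assumes (two-sided diffusive ingress
# into brain compartments bounded by a stained brain case, saturating
# shrinkage, noise), with full ground truth.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_stream_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic stained-slice phantom
#'
#' Describes the geometry and staining kinetics of one simulated orthoslice
#' crossed by a line probe. The brain case is modelled as a band spanning
#' `case_bounds_mm` whose intensity saturates over time; inside it sit one or
#' more stained tissue segments (brain tissue, optionally an excluded nerve)
#' into which stain ingresses diffusively from both edges. Tissue shrinkage
#' moves each segment's edges towards its centre following
#' `s(t) = s_max * (1 - exp(-t / shrink_tau_h))`, so the true width sequence
#' is `w0 * (1 - s(t))`.
#'
#' The interior concentration profile is the two-front diffusion form
#' `c(x, t) = c_max * supply(t) * min(1, erfc(dL / (2 sqrt(D t))) +
#' erfc(dR / (2 sqrt(D t))))` with `dL`, `dR` the distances to the current
#' (shrunken) edges and `supply(t) = 1 - exp(-t / supply_tau_h)` the gradual
#' build-up of stain around the tissue. This is the simplest model producing
#' the observed concave (understained) to flat to convex (overstained)
#' interior progression; it is not claimed to be the physical staining
#' kinetics. An optional overstain term adds intensity near the edges at a
#' fixed rate after `overstain_start_h`.
#'
#' @param probe_length_mm Length of the line probe (x = 0 at the left end).
#' @param n_samples Number of evenly spaced samples along the probe.
#' @param brain_segments Data frame with columns `left`, `right` (initial
#'   edge positions, mm), `region` (anatomical label or `NA`) and `label`
#'   (`"brain_tissue"` or `"excluded_nerve"`); segments must be disjoint,
#'   ordered, and inside `case_bounds_mm`.
#' @param case_bounds_mm Outer boundaries of the brain-case band, mm.
#' @param baseline_hu Radiodensity outside the case, HU.
#' @param case_base_hu Brain-case intensity above baseline before staining.
#' @param case_gain_hu,case_tau_h Saturating increment and time scale of
#'   brain-case staining.
#' @param c_max_hu Interior plateau intensity above baseline.
#' @param diffusivity_mm2_h Stain front diffusivity D.
#' @param supply_tau_h Time scale of the stain supply build-up.
#' @param s_max,shrink_tau_h Shrinkage plateau (fraction, < 1) and time scale.
#' @param overstain_rate_hu_h,overstain_start_h,overstain_scale_mm Overstain
#'   intensity rate near the edges, its start time, and its decay length.
#' @param psf_sd_mm SD of the Gaussian point-spread blur applied to the
#'   noiseless signal, emulating the finite edge width left by tomographic
#'   reconstruction and upstream denoising; edges remain centred on the true
#'   boundaries.
#' @param noise_sd_hu SD of additive Gaussian noise.
#' @param time_grid_h Staining time grid, hours.
#' @param seed Base seed for the per-profile noise streams.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(probe_length_mm = 10, n_samples = 500,
                         brain_segments = data.frame(
                           left = 2.5, right = 7.5, region = NA_character_,
                           label = "brain_tissue"),
                         case_bounds_mm = c(1.5, 8.5),
                         baseline_hu = 0, case_base_hu = 200,
                         case_gain_hu = 7000, case_tau_h = 40,
                         c_max_hu = 12000, diffusivity_mm2_h = 0.025,
                         supply_tau_h = 50,
                         s_max = 0.14, shrink_tau_h = 60,
                         overstain_rate_hu_h = 0, overstain_start_h = Inf,
                         overstain_scale_mm = 0.3,
                         psf_sd_mm = 0.05,
                         noise_sd_hu = 50,
                         time_grid_h = seq(0, 240, by = 48), seed = 1L) {
  seg <- as.data.frame(brain_segments)
  check_columns(seg, c("left", "right"), "brain_segments")
  if (!"region" %in% names(seg)) seg$region <- NA_character_
  if (!"label" %in% names(seg)) seg$label <- "brain_tissue"
  if (n_samples < 16) {
    abort("n_samples must be at least 16", class = "dicect_validation_error")
  }
  if (!(s_max >= 0 && s_max < 1)) {
    abort("s_max must lie in [0, 1)", class = "dicect_validation_error")
  }
  if (diffusivity_mm2_h <= 0) {
    abort("diffusivity must be positive", class = "dicect_validation_error")
  }
  if (any(seg$left >= seg$right) ||
      any(seg$left < case_bounds_mm[1]) || any(seg$right > case_bounds_mm[2]) ||
      case_bounds_mm[1] <= 0 || case_bounds_mm[2] >= probe_length_mm) {
    abort("segments must be inside the case band, which must be inside the probe",
          class = "dicect_validation_error")
  }
  if (nrow(seg) > 1 && any(seg$left[-1] <= seg$right[-nrow(seg)])) {
    abort("brain segments must be disjoint and ordered",
          class = "dicect_validation_error")
  }
  structure(list(
    probe_length_mm = probe_length_mm, n_samples = as.integer(n_samples),
    brain_segments = seg, case_bounds_mm = case_bounds_mm,
    baseline_hu = baseline_hu, case_base_hu = case_base_hu,
    case_gain_hu = case_gain_hu, case_tau_h = case_tau_h,
    c_max_hu = c_max_hu, diffusivity_mm2_h = diffusivity_mm2_h,
    supply_tau_h = supply_tau_h, s_max = s_max, shrink_tau_h = shrink_tau_h,
    overstain_rate_hu_h = overstain_rate_hu_h,
    overstain_start_h = overstain_start_h,
    overstain_scale_mm = overstain_scale_mm, psf_sd_mm = psf_sd_mm,
    noise_sd_hu = noise_sd_hu, time_grid_h = time_grid_h, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Symmetric Gaussian blur with edge replication; kernel normalized so flat
# regions are preserved exactly.
gaussian_blur <- function(y, sd_samples) {
  if (sd_samples <= 0) return(y)
  r <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(-r:r, sd = sd_samples)
  k <- k / sum(k)
  ypad <- c(rep(y[1], r), y, rep(y[length(y)], r))
  out <- stats::filter(ypad, k, sides = 2)
  as.numeric(out[(r + 1):(r + length(y))])
}

# Shrinkage fraction at time t.
shrink_fraction <- function(spec, time_h) {
  spec$s_max * (1 - exp(-time_h / spec$shrink_tau_h))
}

# Current (shrunken) edges of each stained segment at time t.
true_edges_at <- function(spec, time_h) {
  s <- shrink_fraction(spec, time_h)
  seg <- spec$brain_segments
  m <- (seg$left + seg$right) / 2
  w <- (seg$right - seg$left) * (1 - s)
  data.frame(left = m - w / 2, right = m + w / 2, width = w,
             region = seg$region, label = seg$label)
}

#' Generate one synthetic line profile with ground truth
#'
#' Evaluates the phantom's noiseless intensity at the probe's sample
#' positions at one staining time, adds independent Gaussian noise from a
#' stream keyed by `(seed, species, specimen, slice, time)` — so any subset
#' of a study regenerates identically — and returns both the profile and the
#' per-segment ground truth (true edge positions after shrinkage, width, and
#' interior mean / IQR of the noiseless signal).
#'
#' @param spec A [phantom_spec()].
#' @param time_h Staining time, hours (>= 0).
#' @param species,specimen,slice Key labels stamped on the output.
#' @param seed Base seed; defaults to the spec's.
#' @return A list with `profile` (tibble in the standard profiles layout) and
#'   `truth` (tibble, one row per stained segment).
#' @export
generate_profile <- function(spec, time_h, species = "demo", specimen = "S1",
                             slice = 1L, seed = spec$seed) {
  if (!inherits(spec, "phantom_spec")) {
    abort("`spec` must be a phantom_spec", class = "dicect_validation_error")
  }
  if (!is.finite(time_h) || time_h < 0) {
    abort("time_h must be a finite non-negative number",
          class = "dicect_domain_error")
  }
  x <- seq(0, spec$probe_length_mm, length.out = spec$n_samples)
  y <- rep(spec$baseline_hu, spec$n_samples)
  edges <- true_edges_at(spec, time_h)

  case_t <- spec$case_base_hu +
    spec$case_gain_hu * (1 - exp(-time_h / spec$case_tau_h))
  in_case <- x >= spec$case_bounds_mm[1] & x <= spec$case_bounds_mm[2]
  in_tissue <- rep(FALSE, length(x))
  for (i in seq_len(nrow(edges))) {
    in_tissue <- in_tissue | (x > edges$left[i] & x < edges$right[i])
  }
  y[in_case & !in_tissue] <- spec$baseline_hu + case_t

  supply <- 1 - exp(-time_h / spec$supply_tau_h)
  if (time_h > 0) {
    denom <- 2 * sqrt(spec$diffusivity_mm2_h * time_h)
    for (i in seq_len(nrow(edges))) {
      inside <- x > edges$left[i] & x < edges$right[i]
      if (!any(inside)) next
      dl <- x[inside] - edges$left[i]
      dr <- edges$right[i] - x[inside]
      conc <- pmin(1, erfc(dl / denom) + erfc(dr / denom))
      val <- spec$c_max_hu * supply * conc
      if (spec$overstain_rate_hu_h > 0 && time_h > spec$overstain_start_h) {
        val <- val + spec$overstain_rate_hu_h * (time_h - spec$overstain_start_h) *
          (exp(-dl / spec$overstain_scale_mm) + exp(-dr / spec$overstain_scale_mm))
      }
      y[inside] <- spec$baseline_hu + val
    }
  }

  spacing <- spec$probe_length_mm / (spec$n_samples - 1)
  y <- gaussian_blur(y, spec$psf_sd_mm / spacing)

  truth <- purrr::map_dfr(seq_len(nrow(edges)), function(i) {
    inside <- x > edges$left[i] & x < edges$right[i]
    v <- y[inside]
    tibble(
      species = species, specimen = specimen, slice = as.integer(slice),
      time_h = time_h, segment = i, region = edges$region[i],
      label = edges$label[i],
      true_left_mm = edges$left[i], true_right_mm = edges$right[i],
      true_width_mm = edges$width[i],
      true_mean_hu = mean(v),
      true_iqr_hu = unname(quantile(v, 0.75, type = 7) -
                             quantile(v, 0.25, type = 7))
    )
  })

  if (spec$noise_sd_hu > 0) {
    stream <- derive_seed(seed, species, specimen, slice, time_h)
    y <- y + with_stream_seed(stream,
                              rnorm(length(y), sd = spec$noise_sd_hu))
  }
  profile <- tibble(
    species = species, specimen = specimen, slice = as.integer(slice),
    time_h = time_h, index = seq_along(x), position_mm = x, intensity_hu = y
  )
  list(profile = profile, truth = truth)
}

#' Slice geometries emulating the study's sampling design
#'
#' Four phantom slices sharing kinetics: slice 1 crosses three stained
#' segments (two olfactory bulbs flanking an anterior telencephalon sliver,
#' region `"Tel1"`, which the shrinkage analysis excludes), slices 2 and 3
#' cross one tissue (telencephalon, cerebellum), and slice 4 crosses the
#' medulla plus a small separately stained nerve labelled `excluded_nerve`.
#'
#' @param ... Overrides passed to every [phantom_spec()] (e.g. `noise_sd_hu`,
#'   `time_grid_h`, `s_max`).
#' @return A named list of four `phantom_spec` objects.
#' @export
demo_slice_specs <- function(...) {
  list(
    `1` = phantom_spec(brain_segments = data.frame(
      left = c(2.0, 4.2, 6.6), right = c(3.4, 5.8, 8.0),
      region = c("OBs", "Tel1", "OBs"),
      label = "brain_tissue"), case_bounds_mm = c(1.2, 8.8), ...),
    `2` = phantom_spec(brain_segments = data.frame(
      left = 2.5, right = 7.5, region = "Tel", label = "brain_tissue"), ...),
    `3` = phantom_spec(brain_segments = data.frame(
      left = 2.7, right = 7.3, region = "Cer", label = "brain_tissue"), ...),
    `4` = phantom_spec(brain_segments = data.frame(
      left = c(2.2, 7.6), right = c(6.4, 8.3),
      region = c("Med", NA), label = c("brain_tissue", "excluded_nerve")),
      case_bounds_mm = c(1.4, 8.9), ...)
  )
}

# Segment labels (and regions) for the 2k - 1 inter-edge intervals of a
# phantom slice: background bands interleaved with the stained segments.
spec_segment_labels <- function(spec) {
  seg <- spec$brain_segments
  labels <- "background"
  regions <- NA_character_
  for (i in seq_len(nrow(seg))) {
    labels <- c(labels, seg$label[i], "background")
    regions <- c(regions, seg$region[i], NA_character_)
  }
  list(labels = labels, regions = regions)
}

#' Generate a full synthetic staining study
#'
#' Full factorial (specimen x slice x time) study from a set of per-slice
#' phantom specs, mirroring the repeated-measures design of a staining
#' optimization experiment. All slices must share one time grid.
#'
#' @param slice_specs Named list of [phantom_spec()] objects, one per slice
#'   index; defaults to [demo_slice_specs()].
#' @param species Species label.
#' @param specimens Character vector of specimen labels.
#' @param seed Base seed for all noise streams.
#' @return A list: `profiles` (validated long tibble of all profiles),
#'   `truth` (ground-truth tibble), `config` (per-slice segment labels and
#'   regions, in the layout [run_pipeline()] expects).
#' @export
generate_study <- function(slice_specs = demo_slice_specs(), species = "demo",
                           specimens = c("S1", "S2"), seed = 1L) {
  grids <- unique(lapply(slice_specs, function(s) s$time_grid_h))
  if (length(grids) != 1) {
    abort("all slice specs must share the same time grid",
          class = "dicect_validation_error")
  }
  time_grid <- grids[[1]]
  out <- list()
  truth <- list()
  for (sp in specimens) {
    for (sl in names(slice_specs)) {
      for (t in time_grid) {
        g <- generate_profile(slice_specs[[sl]], t, species = species,
                              specimen = sp, slice = as.integer(sl),
                              seed = seed)
        out[[length(out) + 1]] <- g$profile
        truth[[length(truth) + 1]] <- g$truth
      }
    }
  }
  config <- lapply(slice_specs, spec_segment_labels)
  list(profiles = validate_profiles(bind_rows(out)),
       truth = bind_rows(truth),
       config = list(slices = config))
}
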