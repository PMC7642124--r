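test_that("before staining the profile is baseline except the case bands", {
  spec <- phantom_spec(noise_sd_hu = 0, baseline_hu = 10, case_base_hu = 300)
  g <- generate_profile(spec, 0)
  p <- g$profile
  away <- p$position_mm < 1.2 | p$position_mm > 8.8 |
    (p$position_mm > 2.8 & p$position_mm < 7.2)
  expect_equal(p$intensity_hu[away][1:5], rep(10, 5), tolerance = 1e-9)
  expect_equal(min(p$intensity_hu), 10, tolerance = 1e-9)
  in_band <- p$position_mm > 1.8 & p$position_mm < 2.2
  expect_lt(max(abs(p$intensity_hu[in_band] - 310)), 1e-3)
  expect_equal(g$truth$true_width_mm, 5)
})

test_that("at long times the interior saturates to the plateau", {
  spec <- phantom_spec(noise_sd_hu = 0)
  g <- generate_profile(spec, 2000)
  p <- g$profile
  w <- g$truth$true_width_mm
  centre <- (g$truth$true_left_mm + g$truth$true_right_mm) / 2
  mid50 <- p$position_mm > centre - w / 4 & p$position_mm < centre + w / 4
  plateau <- spec$baseline_hu + spec$c_max_hu
  expect_lt(max(abs(p$intensity_hu[mid50] - plateau)) / plateau, 0.01)
})

test_that("interior concentration follows the two-front erfc sum", {
  spec <- phantom_spec(noise_sd_hu = 0, psf_sd_mm = 0, s_max = 0)
  t <- 96
  g <- generate_profile(spec, t)
  p <- g$profile
  # independent oracle for the complementary error function
  supply <- 1 - exp(-t / spec$supply_tau_h)
  denom <- 2 * sqrt(spec$diffusivity_mm2_h * t)
  inside <- p$position_mm > 2.51 & p$position_mm < 7.49
  x <- p$position_mm[inside]
  expected <- spec$c_max_hu * supply *
    pmin(1, pracma::erfc((x - 2.5) / denom) + pracma::erfc((7.5 - x) / denom))
  expect_equal(p$intensity_hu[inside], expected, tolerance = 1e-9)
})

test_that("profiles regenerate bitwise-identically from their keyed stream", {
  spec <- phantom_spec(noise_sd_hu = 80)
  a <- generate_profile(spec, 48, specimen = "S1", slice = 2L, seed = 5)
  b <- generate_profile(spec, 48, specimen = "S1", slice = 2L, seed = 5)
  expect_identical(a$profile$intensity_hu, b$profile$intensity_hu)
  c <- generate_profile(spec, 48, specimen = "S2", slice = 2L, seed = 5)
  expect_false(identical(a$profile$intensity_hu, c$profile$intensity_hu))
  # the stream does not disturb the session RNG
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_profile(spec, 48)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("true widths shrink monotonically and invert exactly", {
  spec <- phantom_spec(noise_sd_hu = 0, s_max = 0.2, shrink_tau_h = 40)
  times <- seq(0, 240, 24)
  widths <- vapply(times, function(t) {
    generate_profile(spec, t)$truth$true_width_mm
  }, 0)
  expect_true(all(diff(widths) <= 0))
  s_t <- 0.2 * (1 - exp(-times / 40))
  expect_equal(widths, 5 * (1 - s_t), tolerance = 1e-12)
  expect_equal(shrinkage_percent(widths[1], widths), 100 * s_t,
               tolerance = 1e-9)
})

test_that("expected P2 is non-decreasing over time before overstaining", {
  spec <- phantom_spec(noise_sd_hu = 0)
  means <- vapply(seq(0, 240, 48), function(t) {
    g <- generate_profile(spec, t)
    p <- g$profile
    inside <- p$position_mm > g$truth$true_left_mm &
      p$position_mm < g$truth$true_right_mm
    mean(p$intensity_hu[inside])
  }, 0)
  expect_true(all(diff(means) > -1e-9))
})

test_that("a full study has the factorial layout and a usable config", {
  st <- demo_study()
  expect_equal(nrow(dplyr::distinct(st$profiles, specimen, slice, time_h)),
               2 * 4 * 6)
  expect_equal(nrow(st$profiles), 2 * 4 * 6 * 500)
  expect_named(st$config$slices, c("1", "2", "3", "4"))
  expect_equal(st$config$slices[["1"]]$labels[c(2, 4, 6)],
               rep("brain_tissue", 3))
  specs <- demo_slice_specs(time_grid_h = c(0, 24))
  specs[["2"]] <- phantom_spec(time_grid_h = c(0, 48))
  expect_error(generate_study(specs), class = "dicect_validation_error")
})

test_that("noiseless generation plus peak analysis recovers the true fronts", {
  # cross-module oracle: detected paired edges lie within one sample spacing
  # of the generator's ground truth, at every time of the demo grid
  specs <- demo_slice_specs(noise_sd_hu = 0)
  for (sl in names(specs)) {
    spec <- specs[[sl]]
    spacing <- spec$probe_length_mm / (spec$n_samples - 1)
    for (t in spec$time_grid_h) {
      g <- generate_profile(spec, t, slice = as.integer(sl))
      ex <- extract_profile(g$profile,
                            labels = dicect:::spec_segment_labels(spec)$labels)
      found <- sort(ex$edges$position_mm)
      truth <- phantom_true_edges(spec, g$truth)
      expect_lt(max(abs(found - truth)), spacing,
                label = sprintf("slice %s, t=%g: max edge error", sl, t))
    }
  }
})
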