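seg_row <- function(label, mean_hu, n = 100, left = 0, right = 1,
                    strength = 10, iqr = 0, region = NA_character_) {
  tibble::tibble(segment_label = label, region = region, x_left_mm = left,
                 x_right_mm = right, edge_strength_left = strength,
                 edge_strength_right = strength, mean_hu = mean_hu,
                 median_hu = mean_hu, sd_hu = 0, iqr_hu = iqr,
                 width_mm = right - left, n_samples = n)
}

test_that("P2 pools background samples across both flanking intervals", {
  segs <- dplyr::bind_rows(
    seg_row("background", 4, left = 0, right = 1),
    seg_row("brain_tissue", 10, left = 1, right = 2),
    seg_row("background", 6, left = 2, right = 3)
  )
  m <- compute_slice_metrics(segs)
  expect_equal(m$p2, 5) # 10 - pooled mean of {4 x100, 6 x100}
  # unequal background sample counts shift the pooled mean, not the mean of
  # means
  segs2 <- segs
  segs2$n_samples[1] <- 300
  m2 <- compute_slice_metrics(segs2)
  expect_equal(m2$p2, 10 - (300 * 4 + 100 * 6) / 400)
})

test_that("an unstained flat profile gives zero contrast and homogeneity", {
  x <- seq(0, 10, length.out = 200)
  sp <- smooth_profile(make_profile(x, rep(100, 200)))
  segs <- dplyr::bind_rows(
    seg_row("background", 100, left = 1, right = 3),
    seg_row("brain_tissue", 100, left = 3, right = 7),
    seg_row("background", 100, left = 7, right = 9)
  )
  m <- compute_slice_metrics(segs, smoothed = sp)
  expect_equal(m$p2, 0)
  expect_equal(m$p3, 0)
})

test_that("a three-tissue slice yields six P1 values and three widths", {
  spec <- demo_slice_specs(noise_sd_hu = 0)[["1"]]
  g <- generate_profile(spec, 96, slice = 1L)
  lab <- dicect:::spec_segment_labels(spec)
  ex <- extract_profile(g$profile, labels = lab$labels, regions = lab$regions)
  m <- compute_slice_metrics(ex$segments, smoothed = ex$smoothed)
  expect_length(m$p1_values[[1]], 6)
  expect_length(m$p4_widths[[1]], 3)
  expect_equal(m$regions[[1]], c("OBs", "Tel1", "OBs"))
})

test_that("excluded nerve segments are omitted from P2 and P3", {
  x <- seq(0, 10, length.out = 300)
  sp <- smooth_profile(make_profile(x, rep(100, 300)))
  base <- dplyr::bind_rows(
    seg_row("background", 4, left = 1, right = 2),
    seg_row("brain_tissue", 10, left = 2, right = 5),
    seg_row("background", 6, left = 5, right = 6)
  )
  with_nerve <- dplyr::bind_rows(
    base, seg_row("excluded_nerve", 50, left = 6, right = 7, iqr = 30))
  expect_equal(compute_slice_metrics(with_nerve)$p2,
               compute_slice_metrics(base)$p2)
  expect_equal(compute_slice_metrics(with_nerve)$p3,
               compute_slice_metrics(base)$p3)
  # nerve widths are not brain-tissue widths either
  expect_length(compute_slice_metrics(with_nerve)$p4_widths[[1]], 1)
})

test_that("shrinkage percentage follows the width-loss formula", {
  expect_equal(shrinkage_percent(5.46, 4.78), 100 * (5.46 - 4.78) / 5.46)
  expect_equal(shrinkage_percent(5.46, 4.78), 12.4542, tolerance = 1e-4)
  expect_equal(shrinkage_percent(3.3, 3.3), 0)
  expect_equal(shrinkage_percent(2.0, 2.2), -10) # swelling keeps its sign
  expect_equal(shrinkage_percent(4, 4 * (1 - 0.2)), 20) # exact on w*(1-s)
  expect_error(shrinkage_percent(0, 1), class = "dicect_domain_error")
})

test_that("region shrinkage recovers a programmed fast-saturating shrinkage", {
  spec <- phantom_spec(noise_sd_hu = 0, s_max = 0.15, shrink_tau_h = 10)
  st <- generate_study(list(`3` = spec), specimens = "Z1", seed = 1)
  run <- run_pipeline(st$profiles, st$config)
  expect_equal(nrow(run$failures), 0)
  shr <- compute_region_shrinkage(run$slice_metrics)
  expect_equal(shr$region, "Cer")
  expect_lt(abs(shr$percent - 15), 1)
})

test_that("whole-brain aggregation is a two-stage mean, not a pooled mean", {
  sm <- tibble::tibble(
    species = "sp", specimen = "s", slice = 1:4, time_h = 0,
    p1_values = list(rep(6, 6), c(2, 2), c(2, 2), c(2, 2)),
    p2 = c(1, 2, 3, 4), p3 = c(1, 1, 1, 1),
    p4_widths = list(c(2, 4), 3, 3, 3),
    regions = list(c("OBs", "Tel1"), "Tel", "Cer", "Med")
  )
  wb <- aggregate_whole_brain(sm)
  expect_equal(wb$mean_p1, 3) # per-slice means 6, 2, 2, 2
  expect_equal(wb$mean_p2, 2.5)
  # slice-1 width uses only the non-excluded segment (Tel1 dropped)
  expect_equal(wb$mean_width, mean(c(2, 3, 3, 3)))

  # a slice missing at one time point (but present at another) is a gap
  sm2 <- dplyr::mutate(sm, time_h = 48)
  sm_gap <- dplyr::bind_rows(sm, sm2[-2, ])
  expect_error(aggregate_whole_brain(sm_gap), "missing slice",
               class = "dicect_coverage_error")
})

test_that("metrics respond correctly to intensity offset and scale", {
  spec <- phantom_spec(noise_sd_hu = 30)
  g <- generate_profile(spec, 144)$profile
  lab <- c("background", "brain_tissue", "background")
  metr <- function(prof) {
    ex <- extract_profile(prof, labels = lab)
    compute_slice_metrics(ex$segments, smoothed = ex$smoothed)
  }
  m0 <- metr(g)
  m_off <- metr(dplyr::mutate(g, intensity_hu = intensity_hu + 500))
  expect_equal(m_off$p1_values[[1]], m0$p1_values[[1]], tolerance = 1e-6)
  expect_equal(m_off$p2, m0$p2, tolerance = 1e-6)
  expect_equal(m_off$p3, m0$p3, tolerance = 1e-6)
  expect_equal(m_off$p4_widths[[1]], m0$p4_widths[[1]])

  cc <- 2.5
  m_sc <- metr(dplyr::mutate(g, intensity_hu = intensity_hu * cc))
  expect_equal(m_sc$p1_values[[1]], cc * m0$p1_values[[1]], tolerance = 1e-6)
  expect_equal(m_sc$p2, cc * m0$p2, tolerance = 1e-6)
  expect_equal(m_sc$p3, cc * m0$p3, tolerance = 1e-6)
  expect_equal(m_sc$p4_widths[[1]], m0$p4_widths[[1]])
})

test_that("shrinkage summaries use the flat region-by-specimen mean", {
  tel <- tibble::tibble(region = "Tel", specimen = c("a", "b", "c"),
                        percent = c(11.04, 11.89, 14.63))
  s <- summarize_shrinkage(tel)
  expect_equal(s$mean_percent[s$region == "Tel"], 12.52, tolerance = 1e-3)

  uneven <- tibble::tibble(region = c("A", "A", "B"),
                           specimen = c("a", "b", "a"),
                           percent = c(10, 20, 30))
  s2 <- summarize_shrinkage(uneven)
  expect_equal(s2$mean_percent[s2$region == "Overall"], 20) # not 22.5

  single <- tibble::tibble(region = "A", specimen = "a", percent = 5)
  s3 <- summarize_shrinkage(single)
  expect_true(is.na(s3$sd_percent[s3$region == "A"]))
})

test_that("P2 vanishes when brain and background share a distribution", {
  x <- seq(0, 10, length.out = 400)
  set.seed(9)
  sp <- smooth_profile(make_profile(x, rnorm(400, 500, 20)))
  segs <- dplyr::bind_rows(
    seg_row("background", mean(sp$smoothed_hu), n = 100, left = 1, right = 3),
    seg_row("brain_tissue", mean(sp$smoothed_hu), n = 200, left = 3, right = 7),
    seg_row("background", mean(sp$smoothed_hu), n = 100, left = 7, right = 9)
  )
  m <- compute_slice_metrics(segs, smoothed = sp)
  expect_equal(m$p2, 0, tolerance = 1e-9)
})
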