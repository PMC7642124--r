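test_that("a flat derivative yields no edge candidates", {
  sp <- smooth_profile(make_profile(seq(0, 5, length.out = 50), rep(3, 50)))
  cand <- detect_edge_peaks(sp)
  expect_equal(nrow(cand), 0)
})

test_that("a single noiseless step yields one rising candidate at its centre", {
  x <- seq(0, 10, length.out = 500)
  prof <- make_profile(x, 1000 * pnorm(x, 5, 0.1))
  cand <- detect_edge_peaks(smooth_profile(prof))
  rising <- cand[cand$sign == "rising", ]
  expect_equal(nrow(rising), 1)
  # the generating step's derivative maximum is exactly at 5 mm
  expect_lt(abs(rising$position_mm - 5), (10 / 499) / 2 + 1e-9)
  expect_gt(rising$signed_height, 0)
})

test_that("a noiseless two-edge tissue yields rising then falling candidates at the fronts", {
  prof <- box_profile(n = 500, left = 3, right = 7)
  cand <- detect_edge_peaks(smooth_profile(prof))
  expect_equal(cand$sign, c("rising", "falling"))
  expect_lt(max(abs(cand$position_mm - c(3, 7))), (10 / 499) / 2 + 1e-9)
})

test_that("peak prominence matches a brute-force oracle on half-wave signals", {
  # oracle: walk out to the nearest higher point on each side; the peak's
  # prominence is its height minus the higher of the two interval minima
  oracle_prom <- function(v, i) {
    n <- length(v)
    left <- which(v[seq_len(i - 1)] > v[i])
    lmin <- min(v[(if (length(left)) max(left) else 1):i])
    right <- which(v[(i + 1):n] > v[i])
    rmin <- min(v[i:(if (length(right)) i + min(right) else n)])
    v[i] - max(lmin, rmin)
  }
  set.seed(42)
  for (rep in 1:25) {
    v <- pmax(0, round(cumsum(rnorm(60)), 2))
    pk <- dicect:::find_peaks(v)
    for (j in seq_len(nrow(pk))) {
      expect_equal(pk$prominence[j], oracle_prom(v, pk$index[j]))
    }
  }
})

test_that("pairing selects a symmetric pair about the midpoint", {
  cand <- tibble::tibble(
    sample_index = c(100, 400), position_mm = c(2, 8),
    signed_height = c(100, -100), sign = c("rising", "falling"),
    prominence = c(100, 100)
  )
  es <- pair_edges(cand, expected_pairs = 1, midpoint_mm = 5)
  expect_equal(es$position_mm, c(2, 8))
  expect_equal(es$strength, c(100, 100))
  expect_equal(attr(es, "pairing_source"), "automatic")
})

test_that("an understained central trough can be overridden", {
  # interior trough adds a spurious falling/rising pair between the edges
  cand <- tibble::tibble(
    sample_index = c(100, 220, 280, 400), position_mm = c(2, 4.5, 5.5, 8),
    signed_height = c(100, -40, 40, -100),
    sign = c("rising", "falling", "rising", "falling"),
    prominence = c(100, 40, 40, 100)
  )
  auto <- pair_edges(cand, 1, 5)
  expect_equal(auto$position_mm, c(2, 8)) # outer pair wins on prominence
  over <- pair_edges(cand, 1, 5, override = c(2, 8))
  expect_equal(over$position_mm, c(2, 8))
  expect_equal(attr(over, "pairing_source"), "override")
  expect_error(pair_edges(cand, 1, 5, override = c(2, 3.1)),
               class = "dicect_pairing_error")
})

test_that("pairing fails loudly when candidates are insufficient", {
  cand <- tibble::tibble(sample_index = 100, position_mm = 2,
                         signed_height = 100, sign = "rising",
                         prominence = 100)
  expect_error(pair_edges(cand, 1, 5), "1 edge candidate",
               class = "dicect_pairing_error")
})

test_that("edge detection is mirror symmetric and scale equivariant", {
  spec <- phantom_spec(noise_sd_hu = 50)
  for (t in c(48, 144, 240)) {
    g <- generate_profile(spec, t)$profile
    L <- max(g$position_mm)
    e1 <- pair_edges(detect_edge_peaks(smooth_profile(g)), 2, L / 2)

    mirrored <- dplyr::arrange(
      dplyr::mutate(g, position_mm = L - position_mm), position_mm)
    e2 <- pair_edges(detect_edge_peaks(smooth_profile(mirrored)), 2, L / 2)
    expect_equal(rev(L - e2$position_mm), e1$position_mm, tolerance = 1e-8)
    expect_equal(rev(e2$strength), e1$strength, tolerance = 1e-8)
    swap <- c(rising = "falling", falling = "rising")
    expect_equal(unname(swap[rev(e2$sign)]), e1$sign)

    scaled <- dplyr::mutate(g, intensity_hu = intensity_hu * 2.5)
    e3 <- pair_edges(detect_edge_peaks(smooth_profile(scaled)), 2, L / 2)
    expect_equal(e3$position_mm, e1$position_mm)
    expect_equal(e3$strength, 2.5 * e1$strength, tolerance = 1e-8)
  }
})
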