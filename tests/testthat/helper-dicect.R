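# Shared fixtures, built in code. Expensive objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The demo synthetic study (2 specimens x 4 slices x 6 times).
demo_study <- function(noise_sd_hu = 50, seed = 7) {
  cached(sprintf("study_%g_%d", noise_sd_hu, seed),
         generate_study(demo_slice_specs(noise_sd_hu = noise_sd_hu),
                        seed = seed))
}

demo_run <- function(noise_sd_hu = 50, seed = 7) {
  cached(sprintf("run_%g_%d", noise_sd_hu, seed), {
    st <- demo_study(noise_sd_hu = noise_sd_hu, seed = seed)
    run_pipeline(st$profiles, st$config)
  })
}

# A bare profile tibble from position/intensity vectors.
make_profile <- function(x, y) {
  tibble::tibble(position_mm = x, intensity_hu = y)
}

# Smooth box profile: rises at `left`, falls at `right` (Gaussian-CDF
# transitions), amplitude A over baseline 0.
box_profile <- function(n = 400, length_mm = 10, left = 3, right = 7,
                        A = 1000, edge_sd = 0.08) {
  x <- seq(0, length_mm, length.out = n)
  y <- A * (pnorm(x, left, edge_sd) - pnorm(x, right, edge_sd))
  make_profile(x, y)
}

# True edge positions of a phantom slice at a time (case bounds + segment
# fronts), sorted.
phantom_true_edges <- function(spec, truth_slice) {
  sort(c(spec$case_bounds_mm, truth_slice$true_left_mm,
         truth_slice$true_right_mm))
}

expect_tibble_equal <- function(a, b, tolerance = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
}
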