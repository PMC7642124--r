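slice_series <- function(times, p1_min, p2, p3) {
  tibble::tibble(species = "sp", specimen = "s", slice = 1L, time_h = times,
                 p1_min = p1_min, p2 = p2, p3 = p3)
}

test_that("slice rule: only time passing the edge-strength step wins", {
  s <- slice_series(c(0, 48, 96), p1_min = c(1, 2, 100),
                    p2 = c(0, 5, 10), p3 = c(0, 50, 40))
  d <- slice_optimal_time(s, p1_threshold = 50)
  expect_equal(d$chosen_time_h, 96)
  expect_equal(d$candidate_times_h, 96)
})

test_that("slice rule: minimum P3 with P2 breaking near-ties", {
  base <- slice_series(c(48, 96, 144), p1_min = c(100, 100, 100),
                       p2 = c(10, 30, 20), p3 = c(900, 400, 410))
  d <- slice_optimal_time(base, p1_threshold = 50)
  # 400 vs 410 within 5%: tie broken by larger P2 at 96 h
  expect_equal(d$chosen_time_h, 96)
  expect_equal(d$flag, "p3_tie_broken_by_p2")

  flipped <- base
  flipped$p2 <- c(10, 20, 30)
  expect_equal(slice_optimal_time(flipped, p1_threshold = 50)$chosen_time_h,
               144)

  clear <- base
  clear$p3 <- c(900, 400, 800) # no tie: P3 decides alone
  expect_equal(slice_optimal_time(clear, p1_threshold = 50)$chosen_time_h, 96)
})

test_that("slice rule flags an understained series instead of erroring", {
  s <- slice_series(c(0, 48), p1_min = c(1, 2), p2 = c(0, 1), p3 = c(0, 1))
  d <- slice_optimal_time(s, p1_threshold = 50)
  expect_true(is.na(d$chosen_time_h))
  expect_equal(d$flag, "understained")
  expect_length(d$candidate_times_h, 0)
})

test_that("a chosen slice time always passes its own step-1 predicate", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    s <- slice_series(seq(0, by = 24, length.out = n),
                      p1_min = c(runif(1, 0, 2), runif(n - 1, 0, 400)),
                      p2 = runif(n, -100, 3000), p3 = runif(n, 10, 2000))
    d <- slice_optimal_time(s)
    r <- tidy(d)
    if (!is.na(d$chosen_time_h)) {
      expect_true(r$passes_p1[r$time_h == d$chosen_time_h])
      expect_true(all(d$candidate_times_h %in% r$time_h[r$passes_p1]))
    } else {
      expect_false(any(r$passes_p1))
    }
  }
})

test_that("slice decisions are invariant to uniform intensity rescaling", {
  s <- slice_series(c(0, 24, 48, 72), p1_min = c(0.5, 20, 80, 60),
                    p2 = c(0, 10, 40, 40), p3 = c(1, 100, 60, 80))
  s$p1_values <- lapply(s$p1_min, function(v) c(v, v * 1.5))
  d1 <- slice_optimal_time(s)
  cc <- 7.3
  s2 <- dplyr::mutate(s, p1_min = p1_min * cc, p2 = p2 * cc, p3 = p3 * cc,
                      p1_values = lapply(p1_values, `*`, cc))
  d2 <- slice_optimal_time(s2)
  expect_equal(d2$chosen_time_h, d1$chosen_time_h)
  expect_equal(d2$candidate_times_h, d1$candidate_times_h)
})

wb_series <- function(times, p1, p2, p3) {
  tibble::tibble(species = "sp", specimen = "s", time_h = times,
                 mean_p1 = p1, mean_p2 = p2, mean_p3 = p3)
}

test_that("whole-brain rule: concordant criteria give the last time point", {
  s <- wb_series(seq(0, 240, 48),
                 p1 = c(1, 2, 100, 300, 500, 600),
                 p2 = c(-10, 0, 500, 2000, 4000, 4500),
                 p3 = c(5, 40, 2000, 900, 300, 100))
  d <- whole_brain_optimal_time(s)
  expect_equal(d$chosen_time_h, 240)
  expect_equal(d$flag, "unambiguous")
  expect_equal(d$onset_time_h, 96)
  expect_lte(d$onset_time_h, d$chosen_time_h)
})

test_that("whole-brain rule flags a flat series as unstained", {
  s <- wb_series(c(0, 24, 48), p1 = c(1, 1, 1), p2 = c(0, 0, 0),
                 p3 = c(1, 1, 1))
  d <- whole_brain_optimal_time(s)
  expect_true(is.na(d$chosen_time_h))
  expect_equal(d$flag, "unstained")
})

test_that("a shared argoptimum is returned for any reasonable onset fraction", {
  s <- wb_series(seq(0, 120, 24),
                 p1 = c(1, 5, 50, 80, 120, 90),
                 p2 = c(0, 2, 300, 800, 1200, 1000),
                 p3 = c(2, 30, 700, 400, 90, 150))
  for (f in c(0.05, 0.1, 0.25, 0.4, 0.5)) {
    d <- whole_brain_optimal_time(s, onset_fraction = f)
    expect_equal(d$chosen_time_h, 96)
    expect_equal(d$flag, "unambiguous")
  }
})

test_that("disagreeing criteria are resolved by majority with the tie to the latest", {
  s <- wb_series(seq(0, 96, 24),
                 p1 = c(1, 10, 50, 100, 80),  # argmax 72
                 p2 = c(0, 5, 100, 400, 500), # argmax 96
                 p3 = c(1, 20, 300, 100, 30)) # argmin 96
  d <- whole_brain_optimal_time(s)
  expect_equal(d$chosen_time_h, 96) # majority p2, p3
  expect_equal(d$flag, "criteria_disagree")

  s2 <- wb_series(seq(0, 96, 24),
                  p1 = c(1, 10, 100, 60, 80),  # argmax 48
                  p2 = c(0, 5, 100, 500, 400), # argmax 72
                  p3 = c(1, 20, 300, 100, 30)) # argmin 96
  d2 <- whole_brain_optimal_time(s2)
  expect_equal(d2$chosen_time_h, 96) # three-way tie resolved to latest
})

test_that("decision accessors expose the rationale and summary", {
  s <- wb_series(seq(0, 96, 24), p1 = c(1, 2, 3, 4, 5),
                 p2 = c(0, 1, 10, 50, 100), p3 = c(1, 50, 30, 20, 10))
  d <- whole_brain_optimal_time(s)
  td <- tidy(d)
  expect_equal(nrow(td), 5)
  expect_true(all(c("time_h", "mean_p1", "mean_p2", "mean_p3") %in% names(td)))
  gl <- glance(d)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$level, "whole_brain")
  expect_equal(gl$chosen_time_h, d$chosen_time_h)
})
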