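test_that("local maxima follow the strict-interior definition", {
  expect_equal(find_local_maxima(c(0, 1, 0, 5, 0)), c(2L, 4L))
  expect_equal(find_local_maxima(rep(5, 5)), integer(0))
  # plateau flanked by lower values counts once, at its leftmost index
  expect_equal(find_local_maxima(c(0, 3, 3, 3, 1, 4, 0)), c(2L, 6L))
  # plateau running into the edge is not a maximum
  expect_equal(find_local_maxima(c(0, 2, 2)), integer(0))
  expect_error(find_local_maxima(c(1, 2)), "at least 3")
})

test_that("maxima, bounds and prominence agree with brute force on random traces", {
  for (seed in 1:100) {
    y <- random_trace(60, seed)
    mx <- find_local_maxima(y)
    expect_identical(mx, oracle_local_maxima(y))
    for (i in mx) {
      expect_equal(prominence_of(y, i), oracle_prominence(y, i))
      expect_identical(integration_bounds(y, i), oracle_bounds(y, i))
    }
  }
})

test_that("prominence matches hand-worked and reference values", {
  expect_equal(prominence_of(c(0, 10, 0), 2), 10)
  # the valley at 2 separates the small peak from the higher one
  expect_equal(prominence_of(c(0, 6, 2, 10, 0), 2), 4)
  # global maximum with descending edges: prominence = height - min(trace)
  y <- c(0, 6, 2, 10, 0)
  expect_equal(prominence_of(y, 4), 10 - min(y))
  # frozen reference-implementation values on a fixed random walk
  for (j in seq_along(frozen_prom_peaks))
    expect_equal(prominence_of(frozen_prom_trace, frozen_prom_peaks[j]),
                 frozen_prominences[j], tolerance = 1e-12)
  expect_error(prominence_of(c(0, 1, 2), 2), "not a local maximum")
})

test_that("integration bounds bracket the peak at flanking minima", {
  expect_identical(integration_bounds(c(0, 1, 0, 3, 0, 2, 0), 4), c(3L, 5L))
  # no left minimum: fall back to the signal start
  expect_identical(integration_bounds(c(0, 1, 2, 5, 4), 4), c(1L, 5L))
  for (seed in 1:25) {
    y <- random_trace(50, seed)
    for (i in find_local_maxima(y)) {
      b <- integration_bounds(y, i)
      expect_true(b[1] < i && i < b[2])
    }
  }
})

test_that("peak areas are exact trapezoids", {
  ch <- chromatogram(0:7, c(0, 2, 0, 0, 0, 0, 0, 0))
  expect_equal(peak_area(ch, 1, 3), 2)
  ch2 <- chromatogram(seq(0, 1, length.out = 11), rep(100, 11))
  expect_equal(peak_area(ch2, 1, 11), 100)
  # independent summation oracle on random traces
  for (seed in 1:20) {
    y <- abs(random_trace(40, seed))
    ch3 <- chromatogram(seq(0, 3.9, by = 0.1), y)
    expect_equal(peak_area(ch3, 5, 35), oracle_area(ch3$rt, y, 5, 35),
                 tolerance = 1e-12)
  }
  expect_error(peak_area(ch, 3, 1), "reversed")
})

test_that("the significance filter uses the configured basis", {
  rt <- seq(0, 10, by = 0.01)
  y <- 9999 * exp(-(rt - 5)^2 / (2 * 0.1^2))
  expect_equal(nrow(detect_peaks(chromatogram(rt, y))), 0)
  y2 <- 20000 * exp(-(rt - 5)^2 / (2 * 0.05^2))
  tab <- detect_peaks(chromatogram(rt, y2))
  expect_equal(nrow(tab), 1)
  expect_gt(tab$ratio, 0)
  expect_equal(tab$rt, 5, tolerance = 0.011)
  # on a raised baseline prominence stays put while height shifts
  y3 <- y2 + 5000
  tab3 <- detect_peaks(chromatogram(rt, y3))
  expect_equal(tab3$prominence, tab$prominence, tolerance = 1e-9)
  expect_equal(tab3$height, tab$height + 5000, tolerance = 1e-9)
  # height basis counts the baseline
  tab4 <- detect_peaks(chromatogram(rt, y),
                       peak_params(intensity_basis = "height"))
  expect_equal(nrow(tab4), 0)  # 9999 < 10000 either way
  tab5 <- detect_peaks(chromatogram(rt, y + 5000),
                       peak_params(intensity_basis = "height"))
  expect_equal(nrow(tab5), 1)  # raised above the filter by the baseline
})

test_that("raising the filter never adds peaks and shifting rt only moves them", {
  ch <- generate_cohort(mini_scenario())$chromatograms[[1]]
  sweep_counts <- vapply(c(1000, 5000, 10000, 20000, 50000), function(thr)
    nrow(detect_peaks(ch, peak_params(min_intensity = thr))), integer(1))
  expect_true(all(diff(sweep_counts) <= 0))

  base <- detect_peaks(ch)
  shifted <- chromatogram(ch$rt + 7, ch$intensity, ch$sample_id)
  tab <- detect_peaks(shifted)
  expect_equal(tab$rt, base$rt + 7)
  expect_equal(tab$height, base$height)
  expect_equal(tab$prominence, base$prominence)
  expect_equal(tab$width, base$width, tolerance = 1e-9)
})

test_that("confirmation keeps broad peaks and rejects impulse spikes", {
  rt <- seq(0, 10, by = 0.01)
  gauss <- chromatogram(rt, 30000 * exp(-(rt - 5)^2 / (2 * 0.05^2)))
  tab <- confirm_peaks(detect_peaks(gauss), gauss)
  expect_true(all(tab$confirmed))

  y <- numeric(length(rt)); y[501] <- 30000
  spike <- chromatogram(rt, y)
  tab2 <- detect_peaks(spike, peak_params(confirm_levels = 2L))
  expect_equal(nrow(tab2), 1)
  tab2 <- confirm_peaks(tab2, spike, peak_params(confirm_levels = 2L))
  expect_false(any(tab2$confirmed))

  empty <- detect_peaks(chromatogram(rt, rep(1, length(rt))))
  expect_equal(nrow(confirm_peaks(empty, gauss)), 0)
})

test_that("shrinking the confirmation tolerance never confirms more peaks", {
  cohort <- generate_cohort(mini_scenario())
  ch <- cohort$chromatograms[[4]]
  tab <- detect_peaks(ch)
  confirmed <- vapply(c(0.2, 0.1, 0.05, 0.02), function(tol)
    sum(confirm_peaks(tab, ch, peak_params(confirm_rt_tol = tol))$confirmed),
    integer(1))
  expect_true(all(diff(confirmed) <= 0))
})

test_that("peak density histograms conserve counts", {
  t1 <- detect_peaks(chromatogram(seq(0, 10, 0.01),
    20000 * exp(-(seq(0, 10, 0.01) - 3)^2 / (2 * 0.05^2)) +
    30000 * exp(-(seq(0, 10, 0.01) - 7)^2 / (2 * 0.05^2))))
  h1 <- peak_density(list(t1), 1)
  expect_equal(h1$count, 2L)
  h10 <- peak_density(list(t1, t1), 10, rt_range = c(0, 10))
  expect_equal(sum(h10$count), 4L)
  expect_error(peak_density(list(), 5), "no peak tables")
})
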