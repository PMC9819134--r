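test_that("built-in scenario has the study's cohort structure", {
  sc <- default_scenario()
  expect_equal(sc$n_samples, 37)
  expect_equal(vapply(sc$class_templates, function(t) t$size, integer(1)),
               c(10L, 8L, 11L, 8L))
  uniq <- lapply(sc$class_templates, function(t)
    vapply(t$unique_peaks, function(p) p$compound_name, character(1)))
  expect_equal(anyDuplicated(unlist(uniq)), 0L)
  expect_true(all(vapply(uniq, length, integer(1)) == 6L))
  # heights straddle the 10,000 significance filter
  shared_h <- vapply(sc$class_templates[[1]]$shared_peaks,
                     function(p) p$height_mean, double(1))
  expect_true(any(shared_h < 10000) && any(shared_h > 10000))
  expect_true(all(vapply(unlist(lapply(sc$class_templates, `[[`, "unique_peaks"),
                                recursive = FALSE),
                         function(p) p$height_mean, double(1)) > 25000))
})

test_that("degenerate generator settings produce closed-form traces", {
  tpl <- class_template(0L, 1L, list(), list())
  sc <- cohort_scenario(list(tpl), 0, 2, 10, baseline_level = 100,
                        baseline_drift_slope = 0, noise_sd = 0, seed = 1L)
  ch <- generate_chromatogram(tpl, sc, "s", 1)$chromatogram
  expect_true(all(ch$intensity == 100))

  tpl2 <- class_template(0L, 1L,
                         list(peak_spec("x", 10, 20000, 0, 0, 0.05)), list())
  sc2 <- cohort_scenario(list(tpl2), 0, 20, 50, baseline_level = 100,
                         noise_sd = 0, seed = 1L)
  ch2 <- generate_chromatogram(tpl2, sc2, "s", 1)$chromatogram
  i <- which.max(ch2$intensity)
  expect_equal(ch2$rt[i], ch2$rt[which.min(abs(ch2$rt - 10))])
  expect_lt(abs(ch2$intensity[i] - 20100) / 20100, 0.01)
})

test_that("identical seeds reproduce traces and cohorts bitwise", {
  sc <- mini_scenario()
  tpl <- sc$class_templates[[2]]
  a <- generate_chromatogram(tpl, sc, "s", 42)
  b <- generate_chromatogram(tpl, sc, "s", 42)
  expect_identical(a$chromatogram$intensity, b$chromatogram$intensity)
  expect_identical(a$compounds, b$compounds)

  c1 <- generate_cohort(sc)
  c2 <- generate_cohort(sc)
  expect_identical(c1$compounds, c2$compounds)
  expect_identical(lapply(c1$chromatograms, `[[`, "intensity"),
                   lapply(c2$chromatograms, `[[`, "intensity"))
})

test_that("cohorts conserve class sizes and labels", {
  cohort <- generate_cohort(mini_scenario())
  expect_length(cohort$chromatograms, 9)
  expect_equal(as.integer(table(cohort$labels)), c(3L, 3L, 3L))
  # every placed peak is recorded per sample
  expect_setequal(unique(cohort$compounds$sample_id),
                  names(cohort$chromatograms))

  empty <- cohort_scenario(list(class_template(0L, 1L, list(), list())),
                           0, 1, 10, seed = 3L)
  out <- generate_cohort(empty)
  expect_length(out$chromatograms, 1)
  expect_equal(nrow(out$compounds), 0)
})

test_that("templates foreign to the scenario are rejected", {
  sc <- mini_scenario()
  alien <- class_template(9L, 2L, list(), list(peak_spec("z", 1, 5000)))
  expect_error(generate_chromatogram(alien, sc, "s", 1), "not part")
})

test_that("noiseless cohorts give identical peak counts within a class", {
  sc0 <- mini_scenario(noise_sd = 0)
  cohort <- generate_cohort(sc0)
  counts <- vapply(cohort$chromatograms,
                   function(ch) nrow(detect_peaks(ch)), integer(1))
  for (cl in unique(cohort$labels))
    expect_length(unique(counts[cohort$labels == cl]), 1)
})

test_that("scenario JSON serialization round-trips", {
  sc <- default_scenario()
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back, sc)
})

test_that("invalid scenarios are rejected", {
  shared <- list(peak_spec("a", 1, 20000))
  dup <- list(
    class_template(0L, 2L, shared, list(peak_spec("u", 2, 30000))),
    class_template(1L, 2L, shared, list(peak_spec("u", 3, 30000))))
  expect_error(cohort_scenario(dup, 0, 5, 10), "disjoint")
  expect_error(cohort_scenario(list(class_template(0L, 1L, shared, list())),
                               5, 0, 10), "rt_end")
  expect_error(peak_spec("a", 1, -5), "height_mean")
})
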