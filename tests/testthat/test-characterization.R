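test_that("compound sets union member samples per cluster", {
  tab <- data.frame(sample_id = c("s1", "s1", "s2", "s2"),
                    compound_name = c("x", "y", "y", "z"),
                    rt = c(1, 2, 2, 3))
  labs <- c(s1 = 0L, s2 = 1L)
  sets <- cluster_compound_sets(tab, labs)
  expect_equal(sets, list(`0` = c("x", "y"), `1` = c("y", "z")))

  empty <- tab[0, ]
  expect_equal(cluster_compound_sets(empty, labs),
               list(`0` = character(0), `1` = character(0)))
  expect_error(cluster_compound_sets(tab, c(s1 = 0L)), "no cluster label")

  # minimum support: a compound seen in one sample only can be excluded
  tab2 <- rbind(tab, data.frame(sample_id = "s3", compound_name = "y", rt = 2))
  labs2 <- c(labs, s3 = 0L)
  expect_equal(cluster_compound_sets(tab2, labs2, min_support = 2)[["0"]], "y")
})

test_that("unique compounds exclude substances recurring across clusters", {
  expect_equal(unique_compounds(list(`0` = c("x", "y"), `1` = c("y", "z"))),
               list(`0` = "x", `1` = "z"))
  same <- list(a = c("p", "q"), b = c("p", "q"))
  expect_equal(unique_compounds(same), list(a = character(0), b = character(0)))
  expect_error(unique_compounds(list(a = "x")), "at least 2")
})

test_that("unique compound lists are disjoint and idempotent", {
  for (seed in 1:20) {
    sets <- with_seed_test(seed, lapply(1:4, function(i)
      sample(letters, sample(3:10, 1))))
    names(sets) <- as.character(0:3)
    u <- unique_compounds(sets)
    all_u <- unlist(u)
    expect_equal(anyDuplicated(all_u), 0L)
    expect_equal(unique_compounds(u), u)
  }
})

test_that("the published cluster compound lists are already unique", {
  sets <- published_cluster_compounds()
  expect_length(sets, 4)
  expect_true("Chloroform" %in% sets[["4"]])
  expect_false("Chloroform" %in% unlist(sets[c("1", "2", "3")]))
  expect_equal(anyDuplicated(unlist(sets)), 0L)
  expect_equal(unname(unique_compounds(sets)),
               unname(lapply(sets, sort)))
})

test_that("covariate summaries report clinical-style statistics", {
  tab <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s1", "s2", "s3", "s4"),
    covariate = c(rep("age", 4), rep("sex", 4)),
    value = c("1", "2", "3", "10", "F", "F", "M", "F"))
  labs <- c(s1 = 0L, s2 = 0L, s3 = 0L, s4 = 1L)
  out <- summarize_covariates(tab, labs)

  age0 <- out$numeric[out$numeric$cluster == 0 & out$numeric$covariate == "age", ]
  expect_equal(age0$n, 3L)
  expect_equal(age0$mean, 2)
  expect_equal(age0$sd, 1)
  expect_equal(age0$median, 2)
  expect_equal(c(age0$min, age0$max), c(1, 3))

  # single-member cluster: SD undefined, reported NA
  age1 <- out$numeric[out$numeric$cluster == 1 & out$numeric$covariate == "age", ]
  expect_equal(age1$n, 1L)
  expect_true(is.na(age1$sd))

  sex0 <- out$categorical[out$categorical$cluster == 0, ]
  expect_equal(sex0$count[sex0$level == "F"], 2L)
  expect_equal(sex0$count[sex0$level == "M"], 1L)

  # per-cluster n sums to cohort n for complete covariates
  expect_equal(sum(out$numeric$n[out$numeric$covariate == "age"]), 4L)
})
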