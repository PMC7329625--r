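test_that("spherical equivalent follows sphere + cyl/2 and is linear", {
  expect_equal(spherical_equivalent(-2, -1), -2.5)
  expect_equal(spherical_equivalent(0, 0), 0)
  expect_equal(spherical_equivalent(1.5, 0.5), 1.75)
  expect_true(is.na(spherical_equivalent(NA, -1)))
  # linearity
  a <- c(-1, 2); b <- c(0.5, -0.25); c_ <- c(-2, 1); d <- c(0, 0.5)
  expect_equal(spherical_equivalent(a + b, c_ + d),
               spherical_equivalent(a, c_) + spherical_equivalent(b, d))
})

test_that("mean refractive error averages eyes with single-eye fallback", {
  expect_equal(mean_refractive_error(-1, -3), -2)
  expect_equal(mean_refractive_error(-1, NA), -1)
  expect_equal(mean_refractive_error(NA, -3), -3)
  expect_true(is.na(mean_refractive_error(NA, NA)))
  expect_equal(mean_refractive_error(c(-1, NA), c(-3, 2)), c(-2, 2))
})

test_that("polygenic scores equal the brute-force weighted sum", {
  panel <- list(weights = c(-0.1, 0.2), dosages = matrix(c(1, 2), 2, 1))
  expect_equal(unname(compute_prs(panel)), 0.3)
  zero <- list(weights = c(0, 0), dosages = matrix(c(1, 2), 2, 1))
  expect_equal(unname(compute_prs(zero)), 0)

  big <- simulate_genotypes(5, 20, seed = 13)
  expect_equal(unname(compute_prs(big)),
               prs_bruteforce(unname(big$weights), big$dosages))
  # invariance to variant ordering
  perm <- sample(20)
  shuffled <- big
  shuffled$dosages <- big$dosages[perm, ]
  shuffled$weights <- big$weights[perm]
  expect_equal(compute_prs(shuffled), compute_prs(big))
  # weight/variant mismatch
  bad <- big; bad$weights <- bad$weights[-1]
  expect_error(compute_prs(bad), "match")
})

test_that("missing dosages are mean-imputed unless disabled", {
  panel <- simulate_genotypes(10, 4, seed = 14)
  panel$dosages[2, 3] <- NA
  s <- compute_prs(panel)
  manual <- panel$dosages
  manual[2, 3] <- mean(panel$dosages[2, ], na.rm = TRUE)
  expect_equal(unname(s), prs_bruteforce(unname(panel$weights), manual))
  expect_error(compute_prs(panel, impute_missing = FALSE), "missing")
})

test_that("PRS binarisation centres scores and codes below-mean as 1", {
  expect_equal(binarize_prs(c(1, 2, 3)), c(1L, 0L, 0L))   # 0 at the mean
  expect_equal(binarize_prs(c(5, 5, 5)), c(0L, 0L, 0L))
  # shift invariance
  s <- rnorm(50)
  expect_equal(binarize_prs(s), binarize_prs(s + 100))
  # symmetric scores split about half/half
  sym <- with_sym <- c(rnorm(500), -rnorm(500))
  expect_lt(abs(mean(binarize_prs(sym)) - 0.5), 3 * sqrt(0.25 / 1000))
  expect_error(binarize_prs(c(NA, NA, 1)), "non-missing")
})

test_that("questionnaire coding rules reproduce the cohort conventions", {
  rules <- builtin_coding_rules()
  expect_setequal(names(rules),
                  c("alspac_time_outdoors", "alspac_time_reading",
                    "genr_time_outdoors", "genr_time_reading"))
  # ALSPAC outdoors: 3+ hours = high outdoors = lower risk (0)
  expect_equal(apply_coding("3_or_more_hours", rules$alspac_time_outdoors), 0L)
  expect_equal(apply_coding("1_to_2_hours", rules$alspac_time_outdoors), 1L)
  # ALSPAC reading: < 1 hour = low reading = lower risk (0)
  expect_equal(apply_coding("less_than_1_hour", rules$alspac_time_reading), 0L)
  expect_equal(apply_coding("3_or_more_hours", rules$alspac_time_reading), 1L)
  # Generation R outdoors: under 7 h/week = low outdoors = higher risk (1)
  expect_equal(apply_coding("less_than_7_hours_per_week",
                            rules$genr_time_outdoors), 1L)
  expect_equal(apply_coding("7_hours_per_week", rules$genr_time_outdoors), 1L)
  expect_equal(apply_coding("more_than_7_hours_per_week",
                            rules$genr_time_outdoors), 0L)
  # Generation R reading: 5-10 h/week upward = high reading = risk 1
  expect_equal(apply_coding("5_to_10_hours_per_week",
                            rules$genr_time_reading), 1L)
  expect_equal(apply_coding("never", rules$genr_time_reading), 0L)
  # undeclared category -> missing with warning; outputs stay in {0,1,NA}
  expect_warning(out <- apply_coding(c("never", "whenever"),
                                     rules$genr_time_reading),
                 "undeclared")
  expect_equal(out, c(0L, NA))
  for (r in rules) {
    coded <- apply_coding(names(r$mapping), r)
    expect_true(all(coded %in% c(0L, 1L)))
  }
})

test_that("parental myopia classification follows the both-eyes rule", {
  expect_equal(classify_parent_myopia_alspac("cant_see_distance",
                                             "cant_see_much"), "myopic")
  expect_equal(classify_parent_myopia_alspac("always_very_good",
                                             "cant_see_close_up"),
               "nonmyopic")
  # mixed combination -> missing
  expect_true(is.na(classify_parent_myopia_alspac("always_very_good",
                                                  "cant_see_distance")))
  expect_true(is.na(classify_parent_myopia_alspac("gibberish",
                                                  "cant_see_much")))
})

test_that("parental myopia combines with at-least-one rule", {
  expect_equal(combine_parental_myopia("myopic", "nonmyopic"), 1L)
  expect_equal(combine_parental_myopia("nonmyopic", "nonmyopic"), 0L)
  expect_true(is.na(combine_parental_myopia("nonmyopic", NA)))
  # a missing parent cannot mask a myopic one
  expect_equal(combine_parental_myopia(NA, "myopic"), 1L)
})
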