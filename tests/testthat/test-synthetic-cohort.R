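test_that("genotype simulation respects Hardy-Weinberg dosage moments", {
  expect_error(simulate_genotypes(0, 10, seed = 1), "positive")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0, 0.6), seed = 1),
               "maf_range")

  panel <- simulate_genotypes(1000, 146, maf_range = c(0.05, 0.5), seed = 1)
  expect_equal(dim(panel$dosages), c(146, 1000))
  expect_true(all(panel$dosages %in% 0:2))

  one <- simulate_genotypes(10000, 1, maf_range = c(0.3, 0.3), seed = 2)
  se <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(one$dosages) - 0.6), 3 * se)

  again <- simulate_genotypes(1000, 146, maf_range = c(0.05, 0.5), seed = 1)
  expect_identical(panel$dosages, again$dosages)
})

test_that("null cohort shows no exposure-phenotype association", {
  cfg <- sim_config(5000, age_groups = 10,
                    factors = list(factor_spec("f", 0.4, 0, 0)),
                    mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 3)
  tab <- simulate_cohort(cfg)
  expect_lt(abs(cor(tab$f, tab$refractive_error)), 3 / sqrt(nrow(tab)))
})

test_that("location and scale shifts are recovered empirically", {
  cfg <- sim_config(20000, age_groups = 7,
                    factors = list(factor_spec("f", 0.5, -0.125, 0)),
                    mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 4)
  tab <- simulate_cohort(cfg)
  d <- mean(tab$refractive_error[tab$f == 1]) -
    mean(tab$refractive_error[tab$f == 0])
  expect_lt(abs(d + 0.125), 3 * sqrt(2 / 10000))

  cfg2 <- sim_config(20000, age_groups = 7,
                     factors = list(factor_spec("f", 0.5, 0, log(2))),
                     mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 5)
  t2 <- simulate_cohort(cfg2)
  ratio <- sd(t2$refractive_error[t2$f == 1]) /
    sd(t2$refractive_error[t2$f == 0])
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("true_quantile_effect matches its closed form", {
  cfg <- sim_config(100, age_groups = 7,
                    factors = list(factor_spec("f", 0.5, -0.125, log(2))),
                    mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 6)
  # pure shift: constant in tau
  cfg0 <- sim_config(100, age_groups = 7,
                     factors = list(factor_spec("f", 0.5, -0.125, 0)),
                     mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 6)
  for (tau in c(0.05, 0.3, 0.5, 0.9))
    expect_equal(true_quantile_effect(cfg0, "f", tau), -0.125)
  # location-scale: beta + (e^gamma - 1) qnorm(tau)
  expect_equal(true_quantile_effect(cfg, "f", 0.05),
               -0.125 + qnorm(0.05), tolerance = 1e-10)
  expect_equal(round(true_quantile_effect(cfg, "f", 0.05), 4), -1.7699)
  expect_equal(true_quantile_effect(cfg, "f", 0.5), -0.125)
  expect_error(true_quantile_effect(cfg, "nope", 0.5), "unknown factor")
  cfg_corr <- sim_config(100, age_groups = 7,
                         factors = list(factor_spec("f", 0.5, -0.1, 0),
                                        factor_spec("g", 0.5, 0.1, 0)),
                         factor_corr = 0.4, error_shape = "normal", seed = 7)
  expect_error(true_quantile_effect(cfg_corr, "f", 0.5), "closed form")
})

test_that("true quantile effects agree with empirical group quantiles", {
  cfg <- sim_config(200000, age_groups = 7,
                    factors = list(factor_spec("f", 0.5, -0.125, log(2))),
                    mu0 = 0, sigma0 = 1, error_shape = "skew-normal",
                    alpha = -4, seed = 8)
  tab <- simulate_cohort(cfg)
  for (tau in c(0.05, 0.25, 0.5, 0.75)) {
    emp <- quantile(tab$refractive_error[tab$f == 1], tau, names = FALSE) -
      quantile(tab$refractive_error[tab$f == 0], tau, names = FALSE)
    expect_lt(abs(emp - true_quantile_effect(cfg, "f", tau)), 0.02)
  }
})

test_that("age scaling grows effects linearly from the youngest age", {
  cfg <- sim_config(100, age_groups = c(7, 10, 12, 15),
                    factors = list(factor_spec("f", 0.5, -0.1, 0)),
                    age_slope = c(f = 0.2), error_shape = "normal", seed = 9)
  expect_equal(true_quantile_effect(cfg, "f", 0.5, age = 7), -0.1)
  expect_equal(true_quantile_effect(cfg, "f", 0.5, age = 12), -0.1 * 2)
  expect_equal(true_quantile_effect(cfg, "f", 0.5, age = 15), -0.1 * 2.6)
})

test_that("tail amplification: |effect| decreases from tau 0.05 to 0.50", {
  cfg <- sim_config(20000, age_groups = 7,
                    factors = list(factor_spec("f", 0.5, -0.125, log(2))),
                    mu0 = 0, sigma0 = 1, error_shape = "normal", seed = 10)
  tab <- simulate_cohort(cfg)
  taus <- seq(0.05, 0.5, by = 0.05)
  eff <- vapply(taus, function(t)
    group_quantile_oracle(tab$refractive_error, tab$f, t), numeric(1))
  # allow small Monte Carlo wiggle but require a clear overall decrease
  expect_true(all(diff(abs(eff)) < 0.05))
  expect_gt(abs(eff[1]), abs(eff[length(eff)]) + 1)
})

test_that("cohort simulation is bit-reproducible given the seed", {
  cfg <- sim_config(500, age_groups = c(7, 10),
                    factors = list(factor_spec("f", 0.3, -0.2, 0.1)),
                    missing_rates = c(f = 0.2), seed = 11)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("missingness injection hits target rates under MCAR and MAR", {
  tab <- toy_cohort(10000, seed = 12)
  tab <- tab[tab$age_group == 7, ]
  expect_identical(inject_missingness(tab, c(expo = 0), seed = 1), tab)
  expect_error(inject_missingness(tab, c(expo = 1), seed = 1), "rates")

  mc <- inject_missingness(tab, c(expo = 0.3), mechanism = "MCAR", seed = 2)
  expect_lt(abs(mean(is.na(mc$expo)) - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(tab)))
  # observed values unchanged
  keep <- !is.na(mc$expo)
  expect_identical(mc$expo[keep], tab$expo[keep])

  mar <- inject_missingness(tab, rates = list(expo = c(`0` = 0.1, `1` = 0.5)),
                            mechanism = "MAR", condition_on = "sex", seed = 3)
  for (lv in 0:1) {
    sub <- mar$expo[tab$sex == lv]
    target <- c(0.1, 0.5)[lv + 1]
    expect_lt(abs(mean(is.na(sub)) - target),
              3 * sqrt(target * (1 - target) / length(sub)))
  }
  expect_error(inject_missingness(tab, c(nope = 0.1), seed = 1), "absent")
})
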