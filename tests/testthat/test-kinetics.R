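test_that("noiseless synthetic data are recovered to high precision", {
  for (k in c(0.01, 0.05, 0.25)) {
    series <- generate_synthetic_kinetics(k, f_max = 0.7, f0 = 0.05,
                                          noise_sd = 0, replicates = 1)
    fit <- fit_cleavage(series)
    expect_equal(fit$k_obs, k, tolerance = 1e-6)
    expect_equal(fit$f_max, 0.7, tolerance = 1e-6)
    expect_equal(fit$f0, 0.05, tolerance = 1e-6)
    expect_lt(fit$mse, 1e-12)
  }
})

test_that("replicates are pooled and noise inflates the mse", {
  clean <- fit_cleavage(generate_synthetic_kinetics(0.02, noise_sd = 0))
  noisy <- fit_cleavage(generate_synthetic_kinetics(0.02, noise_sd = 0.05,
                                                    seed = 2))
  expect_equal(clean$n_points, 27) # 3 replicates x 9 times
  expect_gt(noisy$mse, clean$mse)
  expect_equal(noisy$k_obs, 0.02, tolerance = 0.5) # order of magnitude
})

test_that("degenerate inputs raise explicit errors", {
  ok <- generate_synthetic_kinetics(0.02, noise_sd = 0, replicates = 1)
  bad <- ok
  bad$fraction_cleaved[1] <- 1.5
  expect_error(fit_cleavage(bad), "outside")
  bad <- ok
  bad$time_min[1] <- -1
  expect_error(fit_cleavage(bad), "negative")
  expect_error(fit_cleavage(ok[c(1, 1, 1), ]), "strictly increasing")
  expect_error(fit_cleavage(dplyr::mutate(ok, fraction_cleaved = 0.5)),
               "constant")
  two <- tibble::tibble(time_min = c(0, 5), fraction_cleaved = c(0, 0.4))
  expect_error(fit_cleavage(two), "3 distinct")
  expect_error(fit_cleavage(ok[, "time_min", drop = FALSE]), "columns")
})

test_that("tidy and glance expose the broom-style record", {
  fit <- fit_cleavage(generate_synthetic_kinetics(0.05, seed = 3))
  td <- tidy(fit)
  expect_equal(td$term, c("k_obs", "f_max", "f0"))
  expect_true(all(c("estimate", "std_error", "statistic",
                    "conf_low", "conf_high") %in% names(td)))
  expect_true(all(td$conf_low < td$estimate & td$estimate < td$conf_high))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, fit$n_points)
  expect_equal(gl$df_residual, fit$n_points - 3L)
  expect_true(gl$converged)
  expect_output(print(fit), "K_obs")
})

test_that("the confidence band brackets the fitted curve symmetrically", {
  fit <- fit_cleavage(generate_synthetic_kinetics(0.05, seed = 3))
  b <- fit$band
  expect_true(all(b$lower <= b$fit & b$fit <= b$upper))
  expect_equal(b$upper - b$fit, b$fit - b$lower, tolerance = 1e-12)
  expect_equal(sort(b$time_min), b$time_min)
})

test_that("pearson handles exact and degenerate cases", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearson(1:3, 1:4), "length")
  expect_error(pearson(1:2, 1:2), "3 observations")
  expect_error(pearson(c(1, 1, 1), 1:3), "zero variance")
})

test_that("correlation_table flags degeneracies and is permutation invariant", {
  rates <- tibble::tibble(id = c("a", "b", "c", "d"),
                          k_obs = c(0.01, 0.02, 0.05, 0.2))
  measures <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    good = c(4, 3, 2, 1),
    flat = c(1, 1, 1, 1),
    holey = c(1, NA, 3, 4),
    label = c("w", "x", "y", "z")
  )
  tab <- correlation_table(rates, measures)
  expect_setequal(tab$measure, c("good", "flat", "holey"))
  expect_true(is.na(tab$r[tab$measure == "flat"]))
  expect_equal(tab$note[tab$measure == "flat"], "zero variance")
  expect_true(is.na(tab$r[tab$measure == "holey"]))
  expect_equal(tab$note[tab$measure == "holey"], "missing values")
  expect_lt(tab$r[tab$measure == "good"], 0)
  # row order of inputs does not matter
  tab2 <- correlation_table(rates[c(3, 1, 4, 2), ], measures[c(2, 4, 1, 3), ])
  expect_equal(tab, tab2)
  expect_error(correlation_table(rates[1:3, ], measures), "ids do not match")
})

test_that("bundled candidate rates correlate negatively with ensemble measures", {
  kin <- hh_kinetics()
  tab <- correlation_table(kin[, c("id", "k_obs")],
                           kin[, c("id", "pos_ent", "ens_def")])
  expect_true(all(tab$r < 0))
})
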