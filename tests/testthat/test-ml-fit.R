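test_that("ML fit recovers generating parameters from a large cell", {
  set.seed(101)
  e <- simulate_mixture_errors(500, p_mem = 0.8, kappa = 8)
  fit <- fit_mixture2_ml(e)
  expect_lt(abs(fit$p_mem - 0.8), 0.06)
  expect_lt(abs(fit$kappa - 8) / 8, 0.25)
  expect_equal(fit$deviance, -2 * fit$loglik)
  expect_equal(fit$bic, fit$deviance + 2 * log(500))
})

test_that("fitted likelihood dominates a dense grid search", {
  set.seed(102)
  for (i in 1:10) {
    e <- simulate_mixture_errors(90, p_mem = runif(1), kappa = runif(1, 1, 40))
    fit <- fit_mixture2_ml(e)
    expect_gte(fit$loglik, wmreport:::grid_loglik_mixture2(e) - 0.01)
  }
})

test_that("uniform data cannot be fitted much better than the uniform model", {
  set.seed(103)
  for (i in 1:5) {
    e <- runif(90, -180, 180)
    fit <- fit_mixture2_ml(e)
    expect_lte(fit$loglik, loglik_uniform(90) + 2)
  }
})

test_that("BIC comparison applies the correct penalties and boundary limit", {
  set.seed(104)
  e <- runif(90, -180, 180)
  cls <- compare_to_uniform(fit_mixture2_ml(e))
  # uniform model has no free parameters: BIC equals the closed-form deviance
  expect_equal(cls$bic_uniform, 2 * 90 * log(2 * pi))
  expect_equal(cls$bic_uniform, 330.818, tolerance = 1e-3)
  # flexibility can only raise the mixture deviance penalty-adjusted score
  # up to the 2 log(n) penalty at the p_mem -> 0 boundary
  expect_lte(cls$bic_difference, 2 * log(90) + 1e-8)
  expect_gte(cls$bic_difference, 2 * log(90) - 4)
  expect_identical(cls$uniform_preferred, cls$bic_difference > 0)
})

test_that("cells below the trial minimum are degenerate, not fitted", {
  expect_error(fit_mixture2_ml(c(1, 2, 3)), "degenerate")
})

test_that("classification counts tabulate per design cell", {
  cls <- tibble::tibble(
    experiment = "e1",
    participant = rep(1:4, 2),
    set_size = 6L,
    output_position = rep(c(5L, 6L), each = 4),
    uniform_preferred = c(FALSE, FALSE, TRUE, FALSE,
                          TRUE, TRUE, FALSE, TRUE)
  )
  tab <- classification_table(cls)
  expect_equal(tab$count[tab$output_position == 5], 1)
  expect_equal(tab$count[tab$output_position == 6], 3)
  expect_equal(tab$n_participants, c(4L, 4L))
})

test_that("classification is invariant to rotation and participant relabeling", {
  set.seed(105)
  tmpl <- experiment_template("t", 4, 30, 6)
  trials <- simulate_experiment(tmpl, sim_config(pm_mean = 0.5), seed = 9)
  fits <- compare_to_uniform(fit_cells_ml(trials, set_sizes = 4))

  rotated <- dplyr::mutate(trials,
                           target_deg = wrap_angle(target_deg + 73),
                           response_deg = wrap_angle(response_deg + 73))
  fits_rot <- compare_to_uniform(fit_cells_ml(rotated, set_sizes = 4))
  expect_equal(fits$bic, fits_rot$bic)
  expect_equal(fits$uniform_preferred, fits_rot$uniform_preferred)

  relabeled <- dplyr::mutate(trials, participant = 7L - participant)
  tab <- classification_table(
    compare_to_uniform(fit_cells_ml(relabeled, set_sizes = 4))
  )
  expect_equal(tab$count,
               classification_table(fits)$count)
})

test_that("cohorts with planted guessers are counted at the planted rate", {
  # 6 of 12 participants respond uniformly at every trial; the rest have
  # strong memory. At n = 60 trials the split should be recovered closely.
  set.seed(106)
  rows <- purrr::map_dfr(1:12, function(j) {
    e <- if (j <= 6) runif(60, -180, 180) else
      simulate_mixture_errors(60, 0.7, 10)
    tibble::tibble(
      experiment = "t", participant = j, session = 1L,
      trial = 1:60, set_size = 6L, location = 0L,
      target_deg = 0, response_deg = wrap_angle(e),
      output_position = 6L, guess_flag = 0L
    )
  })
  tab <- classification_table(
    compare_to_uniform(fit_cells_ml(rows, set_sizes = 6))
  )
  expect_true(abs(tab$count - 6) <= 2)
})
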