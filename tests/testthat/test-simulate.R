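test_that("array features are uniform integers on the wheel, with replacement", {
  set.seed(71)
  expect_true(draw_array(1) %in% 0:359)
  d <- draw_array(1e5)
  tab <- tabulate(d + 1, 360)
  z <- (tab - 1e5 / 360) / sqrt(1e5 * (1 / 360) * (359 / 360))
  # per-degree counts stay within a Bonferroni-sized band across 360 bins
  expect_lt(max(abs(z)), 5)
  expect_gt(chisq.test(tab)$p.value, 0.001)
  # replacement: duplicates at set size 6 occur (over many draws)
  dup <- replicate(200, anyDuplicated(draw_array(6)) > 0)
  expect_true(any(dup))
})

test_that("templates match their experimental designs", {
  t4 <- template_experiment(4)
  expect_equal(t4$set_sizes, 6L)
  expect_equal(t4$trials_per_set_size, 500L)
  expect_equal(t4$n_participants, 24L)
  expect_equal(t4$n_sessions, 4L)
  t1 <- template_experiment(1)
  expect_equal(t1$set_sizes, c(1L, 2L, 3L, 4L, 6L))
  expect_equal(t1$trials_per_set_size, 90L)
  expect_error(experiment_template("x", 3, 91, 10, n_sessions = 2),
               "divisible")
})

test_that("simulated experiments are reproducible and schema-valid", {
  tmpl <- experiment_template("t", c(2, 4), 30, 5, n_sessions = 3)
  a <- simulate_experiment(tmpl, sim_config(), seed = 72)
  b <- simulate_experiment(tmpl, sim_config(), seed = 72)
  expect_equal(a, b, ignore_attr = TRUE)
  expect_silent(validate_trials(a))

  # identical seeds give byte-identical CSV files
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_trials(a, f1)
  write_trials(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  # conservation: every trial contributes exactly set_size response rows
  per_trial <- dplyr::count(a, participant, session, set_size, trial)
  expect_equal(per_trial$n, per_trial$set_size)
  # output positions are permutations (validate_trials checked it too)
  expect_true(all(a$output_position >= 1 & a$output_position <= a$set_size))

  # exp-4 template dimensions
  t4 <- simulate_experiment(template_experiment(4),
                            sim_config(), seed = 73)
  expect_equal(nrow(t4), 24 * 500 * 6)
  expect_equal(unique(t4$set_size), 6L)
})

test_that("a pure-guessing cohort produces uniform errors", {
  # a single chi-square at alpha = .01 has a 1% false-alarm rate by design,
  # so require a majority of independent cohorts to pass
  ps <- purrr::map_dbl(c(74, 174, 274), function(s) {
    tmpl <- experiment_template("g", 1, 10000, 1)
    trials <- simulate_experiment(tmpl, sim_config(p_mix = 0), seed = s)
    err <- angular_error(trials$response_deg, trials$target_deg)
    chisq.test(table(cut(err, seq(-180, 180, length.out = 37))))$p.value
  })
  expect_gte(sum(ps > 0.01), 2)
})

test_that("strength ordering makes error grow with output position", {
  tmpl <- experiment_template("s", 6, 1700, 1)
  cfg <- sim_config(p_mix = 1, pm_mean = 0.5, pm_concentration = 50,
                    kappa_mean = 16, kappa_shape = 50, swap_prob = 0,
                    order_strategy = "strength_ordered")
  trials <- simulate_experiment(tmpl, cfg, seed = 75)
  mae <- trials |>
    dplyr::mutate(ae = abs(angular_error(response_deg, target_deg))) |>
    dplyr::group_by(output_position) |>
    dplyr::summarise(mae = mean(ae), .groups = "drop") |>
    dplyr::arrange(output_position)
  expect_true(all(diff(mae$mae) > 0))
})

test_that("spatial scan decouples output position from memory", {
  tmpl <- experiment_template("p", 4, 2500, 1)
  cfg <- sim_config(p_mix = 1, pm_mean = 0.5, pm_concentration = 50,
                    kappa_mean = 12, swap_prob = 0,
                    order_strategy = "spatial_scan",
                    guess_report_rule = "threshold_on_z")
  trials <- simulate_experiment(tmpl, cfg, seed = 76)
  # under threshold_on_z the flag marks the latent guesses exactly, so the
  # per-position guess rate traces P(z = 0 | position); under spatial scan
  # it must be flat
  rate <- trials |>
    dplyr::group_by(output_position) |>
    dplyr::summarise(guess = mean(guess_flag), .groups = "drop")
  expect_lt(diff(range(rate$guess)), 0.06)
  # and output position is just the location scan order
  expect_equal(trials$output_position, trials$location + 1L)
})

test_that("guess flags behave as their reporting rule prescribes", {
  tmpl <- experiment_template("f", 3, 4000, 1)
  thr <- simulate_experiment(
    tmpl, sim_config(pm_mean = 0.5, guess_report_rule = "threshold_on_z"),
    seed = 77
  )
  err_flag <- angular_error(thr$response_deg[thr$guess_flag == 1],
                            thr$target_deg[thr$guess_flag == 1])
  expect_lt(resultant_length(err_flag), 0.05)

  sdt <- simulate_experiment(
    tmpl, sim_config(pm_mean = 0.5, guess_report_rule = "sdt_criterion"),
    seed = 78
  )
  e1 <- angular_error(sdt$response_deg[sdt$guess_flag == 1],
                      sdt$target_deg[sdt$guess_flag == 1])
  e0 <- angular_error(sdt$response_deg[sdt$guess_flag == 0],
                      sdt$target_deg[sdt$guess_flag == 0])
  # flagged responses are near-uniform; unflagged keep a guessing tail
  expect_lt(resultant_length(e1), 0.15)
  expect_gt(resultant_length(e0), 0.3)
  expect_gt(mean(abs(e0) > 120), 0.01)
})

test_that("a high-memory cohort is recovered as such at set size 1", {
  cfg <- sim_config(p_mix = 1, pm_mean = 0.97, pm_concentration = 300,
                    kappa_mean = 16, kappa_shape = 50)
  tmpl <- experiment_template("hm", 1, 90, 24)
  trials <- simulate_experiment(tmpl, cfg, seed = 79)
  fits <- fit_cells_ml(trials, set_sizes = 1)
  expect_gte(sum(fits$p_mem > 0.9), 22)
})
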