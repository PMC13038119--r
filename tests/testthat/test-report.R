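test_that("error histograms tile the signed range and conserve counts", {
  trials <- simulate_experiment(experiment_template("h", c(2, 4), 40, 4),
                                sim_config(), seed = 91)
  h <- error_histograms(trials, bins = 30)
  # bins tile [-180, 180) exactly
  per_cell <- split(h, interaction(h$set_size, h$output_position,
                                   drop = TRUE))
  for (cell in per_cell) {
    cell <- cell[order(cell$bin_low), ]
    expect_equal(cell$bin_low[1], -180)
    expect_equal(cell$bin_high[nrow(cell)], 180)
    expect_equal(cell$bin_low[-1], cell$bin_high[-nrow(cell)])
  }
  expect_equal(sum(h$count), nrow(trials))

  # sharply concentrated errors put the modal bin at zero
  conc <- simulate_experiment(
    experiment_template("c", 1, 3000, 1),
    sim_config(pm_mean = 0.97, pm_concentration = 80, kappa_mean = 32,
               kappa_shape = 300),
    seed = 92
  )
  # odd bin count puts zero strictly inside the central bin
  hc <- error_histograms(conc, bins = 31)
  top <- hc[which.max(hc$count), ]
  expect_true(top$bin_low < 0 && top$bin_high > 0)

  # uniform data flatten out as n grows
  unif <- simulate_experiment(experiment_template("u", 1, 12000, 1),
                              sim_config(p_mix = 0), seed = 93)
  hu <- error_histograms(unif, bins = 30)
  expect_lt(max(hu$count) / min(hu$count), 1.5)
})

test_that("metacognition split summarizes flagged and unflagged errors", {
  trials <- simulate_experiment(
    experiment_template("m", 6, 1700, 1),
    sim_config(pm_mean = 0.5, guess_report_rule = "threshold_on_z"),
    seed = 94
  )
  ms <- metacognition_split(trials)
  expect_setequal(ms$guess_flag, c(0, 1))
  r1 <- ms$resultant_length[ms$guess_flag == 1]
  r0 <- ms$resultant_length[ms$guess_flag == 0]
  expect_lt(r1, 0.05)
  expect_gt(r0, r1)
  expect_equal(sum(ms$n), nrow(trials))

  # flags all zero: a single row, no guessing panel
  all0 <- dplyr::mutate(trials, guess_flag = 0L)
  ms0 <- metacognition_split(all0)
  expect_equal(nrow(ms0), 1)
  expect_equal(ms0$guess_flag, 0)
})

test_that("the pipeline runs end to end, deterministically, with per-cell logging", {
  trials <- simulate_experiment(
    experiment_template("p", c(2, 4), 40, 8),
    sim_config(pm_mean = 0.55), seed = 95
  )
  rep1 <- suppressWarnings(run_pipeline(
    trials, ml_set_sizes = 4,
    hier_cells = data.frame(set_size = 4, output_position = 4),
    hdmm_cell = c(4, 4),
    chains = 2, warmup = 100, iter = 200, seed = 96
  ))
  expect_s3_class(rep1, "wm_report")
  expect_false(is.null(rep1$classification))
  expect_false(is.null(rep1$hier_summaries))
  expect_false(is.null(rep1$hdmm))
  expect_true(all(c("stage", "cell", "status") %in% names(rep1$log)))
  # HDMM diagnosis joined with the BIC differences from the same cell
  expect_true(all(c("p_guessing_population", "bic_difference") %in%
                    names(rep1$hdmm_diagnosis)))

  rep2 <- suppressWarnings(run_pipeline(
    trials, ml_set_sizes = 4,
    hier_cells = data.frame(set_size = 4, output_position = 4),
    hdmm_cell = c(4, 4),
    chains = 2, warmup = 100, iter = 200, seed = 96
  ))
  expect_equal(rep1$classification, rep2$classification)
  expect_equal(rep1$hier_summaries, rep2$hier_summaries)
  expect_equal(rep1$hdmm_diagnosis, rep2$hdmm_diagnosis)

  # a failing stage is logged, not fatal: request a cell that lacks data
  rep3 <- suppressWarnings(run_pipeline(
    trials, ml_set_sizes = 4,
    hier_cells = data.frame(set_size = 6, output_position = 6),
    hdmm_cell = NULL, chains = 2, warmup = 50, iter = 100, seed = 97
  ))
  expect_true(any(rep3$log$stage == "hier" & rep3$log$status != "ok"))
  expect_false(is.null(rep3$classification))
})

test_that("report regeneration from its own written table is idempotent", {
  trials <- simulate_experiment(experiment_template("r", 4, 25, 5),
                                sim_config(), seed = 98)
  path <- tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  r1 <- run_pipeline(trials, ml_set_sizes = 4, hier_cells = NULL,
                     hdmm_cell = NULL, seed = 99)
  r2 <- run_pipeline(back, ml_set_sizes = 4, hier_cells = NULL,
                     hdmm_cell = NULL, seed = 99)
  expect_equal(r1$classification, r2$classification)
  expect_equal(r1$histograms$count, r2$histograms$count)
})

test_that("plot builders return ggplot objects", {
  trials <- simulate_experiment(experiment_template("g", 2, 20, 3),
                                sim_config(), seed = 100)
  expect_s3_class(plot_error_histograms(trials), "ggplot")
})
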