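# Short-chain settings keep these fits fast; the fuller recovery study runs
# in the acceptance suite.
short <- list(chains = 2, warmup = 250, iter = 500)

test_that("hierarchical fit recovers population parameters and keeps the simplex identity", {
  cell <- simulate_hier_cell(n_participants = 24, n_trials = 90,
                             set_size = 6, pm_mean = 0.6, q_mean = 0.25,
                             kappa_mean = 8, seed = 31)
  truth <- attr(cell, "truth")
  fit <- suppressWarnings(
    fit_hier3(cell, chains = short$chains, warmup = short$warmup,
              iter = short$iter, seed = 32)
  )
  summ <- summarize_population(fit)
  expect_lt(abs(summ$mode[summ$parameter == "p_mem"] - truth$p_mem), 0.08)

  # elementwise identity on every draw, population and participant level
  pop <- fit$population
  expect_equal(pop$p_mem + pop$p_nontarget + pop$p_uniform,
               rep(1, nrow(pop)))
  expect_true(all(pop$p_mem >= 0 & pop$p_mem <= 1))
  expect_true(all(fit$participants$kappa >= 0))
  pu_j <- 1 - fit$participants$p_mem - fit$participants$p_nontarget
  expect_true(all(pu_j >= 0 & pu_j <= 1))

  # p_uniform is summarized from its own draws; modes are not linear, so
  # the three modes need not sum to 1, but each mode must lie in its HDI
  expect_true(all(summ$mode >= summ$hdi_low & summ$mode <= summ$hdi_high))
})

test_that("participant estimates shrink toward the population mean", {
  cell <- simulate_hier_cell(n_participants = 16, n_trials = 40,
                             set_size = 4, seed = 33)
  fit <- suppressWarnings(
    fit_hier3(cell, chains = short$chains, warmup = short$warmup,
              iter = short$iter, seed = 34)
  )
  part <- fit$participants |>
    dplyr::group_by(participant) |>
    dplyr::summarise(p_mem = mean(p_mem), .groups = "drop")
  ml <- cell |>
    dplyr::group_by(participant) |>
    dplyr::summarise(
      p_hat = fit_mixture2_ml(angular_error(response_deg, target_deg))$p_mem,
      .groups = "drop"
    )
  center <- mean(fit$population$p_mem)
  # hierarchical estimates sit closer to the population mean than the
  # per-participant ML estimates do
  expect_lt(mean(abs(part$p_mem - center)), mean(abs(ml$p_hat - center)))
})

test_that("degenerate inputs are rejected", {
  cell <- toy_cell(n_participants = 1, n_trials = 30)
  expect_error(
    fit_hier3(cell, chains = 1, warmup = 10, iter = 10),
    "participants"
  )
})

test_that("with the likelihood withheld the posterior reproduces the prior", {
  cell <- toy_cell(n_participants = 2, n_trials = 2)
  fit <- fit_hier3(cell, chains = 2, warmup = 200, iter = 20000, seed = 35,
                   prior_only = TRUE)
  # population mean of p_mem has a uniform prior
  ks <- suppressWarnings(ks.test(fit$population$p_mem, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  # population mean of kappa has a gamma(5, 0.2) prior
  ks2 <- suppressWarnings(
    ks.test(fit$population$kappa_mean, "pgamma", 5, 0.2)
  )
  expect_lt(unname(ks2$statistic), 0.1)
})

test_that("posterior mode of p_mem tracks the generating population mean", {
  modes <- purrr::map_dbl(c(0.25, 0.5, 0.75), function(mu) {
    cell <- simulate_hier_cell(n_participants = 12, n_trials = 50,
                               set_size = 3, pm_mean = mu, seed = 36)
    fit <- suppressWarnings(
      fit_hier3(cell, chains = 2, warmup = 200, iter = 400, seed = 37)
    )
    posterior_mode(fit$population$p_mem)
  })
  expect_true(all(diff(modes) > 0))
})

test_that("set size 1 cells drop the nontarget component structurally", {
  cell <- simulate_hier_cell(n_participants = 8, n_trials = 40,
                             set_size = 1, pm_mean = 0.7, seed = 38)
  fit <- suppressWarnings(
    fit_hier3(cell, chains = 2, warmup = 150, iter = 300, seed = 39)
  )
  expect_true(all(fit$population$p_nontarget == 0))
  expect_equal(fit$population$p_uniform, 1 - fit$population$p_mem)
})

test_that("tidiers and draw export have the documented shapes", {
  cell <- simulate_hier_cell(n_participants = 6, n_trials = 30,
                             set_size = 2, seed = 40)
  fit <- suppressWarnings(
    fit_hier3(cell, chains = 2, warmup = 100, iter = 200, seed = 41)
  )
  td <- tidy(fit)
  expect_named(td, c("parameter", "mode", "hdi_low", "hdi_high", "mass"))
  gl <- glance(fit)
  expect_equal(gl$draws, 400)
  long <- posterior_draws(fit, "population")
  expect_named(long, c("chain", "iter", "parameter", "value"))
  expect_s3_class(autoplot(fit), "ggplot")
})
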