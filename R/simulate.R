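# Generative simulator of free-order whole-report continuous-reproduction
# experiments. Produces trial tables with the statistical structure the
# analysis stages assume: participant-level heterogeneity (a latent
# consistent-guesser indicator, beta-distributed memory probabilities,
# gamma-distributed precisions), trial-level memory/guess indicators, swap
# (binding) errors, a self-chosen report order, and a self-reported guess
# flag.

#' Experiment template
#'
#' Describes the design of a whole-report experiment: set sizes, trials per
#' set size, participants, and sessions. Ready-made templates follow the
#' designs the package targets: `template_experiment(1:3)` use set sizes
#' 1, 2, 3, 4 and 6 with 90 trials per set size over 3 sessions (N = 23, 24
#' and 23 participants respectively); `template_experiment(4)` uses set size
#' 6 only with 500 trials over 4 sessions (N = 24); `template_adam()` is a
#' brief-simultaneous-presentation style design with set sizes 2 and 6
#' (N = 22). Presentation details (exposure duration, sequential vs
#' simultaneous, articulatory suppression) are metadata only: they have no
#' generative effect.
#'
#' @param name Template label, stored in the `experiment` column.
#' @param set_sizes Integer vector of set sizes (each >= 1).
#' @param trials_per_set_size Trials per set size (divisible by
#'   `n_sessions`).
#' @param n_participants,n_sessions Design counts.
#' @param presentation Free-text metadata describing the presentation mode.
#' @return An object of class `wm_template`.
#' @export
experiment_template <- function(name, set_sizes, trials_per_set_size,
                                n_participants, n_sessions = 1,
                                presentation = "simultaneous") {
  set_sizes <- as.integer(set_sizes)
  stopifnot(length(set_sizes) >= 1, all(set_sizes >= 1),
            trials_per_set_size >= 1, n_participants >= 1, n_sessions >= 1)
  if (trials_per_set_size %% n_sessions != 0) {
    stop("trials_per_set_size must be divisible by n_sessions", call. = FALSE)
  }
  structure(
    list(name = name, set_sizes = set_sizes,
         trials_per_set_size = as.integer(trials_per_set_size),
         n_participants = as.integer(n_participants),
         n_sessions = as.integer(n_sessions),
         presentation = presentation),
    class = "wm_template"
  )
}

#' @rdname experiment_template
#' @param which Which of the four target experiments (1-4).
#' @export
template_experiment <- function(which) {
  stopifnot(which %in% 1:4)
  switch(which,
    experiment_template("exp1", c(1, 2, 3, 4, 6), 90, 23, 3,
                        "sequential 500 ms/item"),
    experiment_template("exp2", c(1, 2, 3, 4, 6), 90, 24, 3,
                        "simultaneous 250 ms x set size"),
    experiment_template("exp3", c(1, 2, 3, 4, 6), 90, 23, 3,
                        "simultaneous 150 ms"),
    experiment_template("exp4", 6, 500, 24, 4, "simultaneous 150 ms")
  )
}

#' @rdname experiment_template
#' @export
template_adam <- function() {
  experiment_template("adam_style", c(2, 6), 120, 22, 1, "simultaneous 150 ms")
}

#' Generative configuration for the simulator
#'
#' Population-level parameters and behavioral strategy settings of the
#' simulator. Participant `j` draws a consistent-guesser indicator
#' `x_j ~ Bernoulli(p_mix)` (`x_j = 0` means every response is a uniform
#' guess), a memory probability `Pm_j ~ beta` with mean `pm_mean` and
#' concentration `pm_concentration`, and a precision
#' `kappa_j ~ gamma` with mean `kappa_mean` and shape `kappa_shape`. On each
#' trial, item `i` is remembered with probability `Pm_j` (`z_ij = 1`); a
#' remembered item is reported with von Mises noise of precision `kappa_j`
#' around the target, except that with probability `swap_prob(set size)` the
#' response centers on a randomly chosen nontarget instead (a binding
#' error); a non-remembered item is reported uniformly at random.
#'
#' Report order: under `"strength_ordered"` items are reported in descending
#' order of a latent strength (`z_ij * kappa_j` plus Gaussian noise with SD
#' `order_noise_sd`, so the ordering is a strong preference rather than
#' deterministic); `"spatial_scan"` reports in location order regardless of
#' memory; `"mixed"` picks between the two per trial with probability
#' `mixed_weight` for strength ordering.
#'
#' Guess flag: `"threshold_on_z"` flags exactly the uniform responses
#' (`z_ij * x_j = 0`); `"sdt_criterion"` places a criterion `sdt_criterion`
#' on a noisy confidence signal (strength plus Gaussian noise with SD
#' `sdt_noise_sd`), yielding conservative flags with heavy-tailed unflagged
#' responses.
#'
#' @param p_mix Probability a participant belongs to the mixture-model
#'   (non-guessing) population.
#' @param pm_mean,pm_concentration Beta population of `Pm_j` (mean and
#'   concentration; `A = mean * conc`, `B = (1 - mean) * conc`).
#' @param kappa_mean,kappa_shape Gamma population of `kappa_j` (mean and
#'   shape; rate is `shape / mean`).
#' @param swap_prob Named function or single number: probability that a
#'   remembered item's response centers on a nontarget, per set size. The
#'   default is 0 at set size 1 (no nontargets) and 0.1 otherwise.
#' @param order_strategy One of `"strength_ordered"`, `"spatial_scan"`,
#'   `"mixed"`.
#' @param mixed_weight Probability of strength ordering under `"mixed"`.
#' @param order_noise_sd SD of the Gaussian noise added to latent strength
#'   before ordering.
#' @param guess_report_rule One of `"threshold_on_z"`, `"sdt_criterion"`.
#' @param sdt_criterion,sdt_noise_sd Criterion and confidence-noise SD of the
#'   signal-detection flagging rule.
#' @return An object of class `wm_sim_config`.
#' @export
sim_config <- function(p_mix = 1,
                       pm_mean = 0.6, pm_concentration = 8,
                       kappa_mean = 8, kappa_shape = 4,
                       swap_prob = function(set_size)
                         ifelse(set_size > 1, 0.1, 0),
                       order_strategy = c("strength_ordered", "spatial_scan",
                                          "mixed"),
                       mixed_weight = 0.5,
                       order_noise_sd = 2,
                       guess_report_rule = c("threshold_on_z",
                                             "sdt_criterion"),
                       sdt_criterion = 2, sdt_noise_sd = 2) {
  order_strategy <- match.arg(order_strategy)
  guess_report_rule <- match.arg(guess_report_rule)
  if (is.numeric(swap_prob)) {
    s <- swap_prob
    swap_prob <- function(set_size) ifelse(set_size > 1, s, 0)
  }
  stopifnot(p_mix >= 0, p_mix <= 1, pm_mean > 0, pm_mean < 1,
            pm_concentration > 0, kappa_mean > 0, kappa_shape > 0,
            mixed_weight >= 0, mixed_weight <= 1, order_noise_sd >= 0,
            sdt_noise_sd >= 0)
  structure(
    list(p_mix = p_mix, pm_mean = pm_mean,
         pm_concentration = pm_concentration, kappa_mean = kappa_mean,
         kappa_shape = kappa_shape, swap_prob = swap_prob,
         order_strategy = order_strategy, mixed_weight = mixed_weight,
         order_noise_sd = order_noise_sd,
         guess_report_rule = guess_report_rule,
         sdt_criterion = sdt_criterion, sdt_noise_sd = sdt_noise_sd),
    class = "wm_sim_config"
  )
}

#' Draw a memory array
#'
#' Item features are drawn uniformly, with replacement, from the 360 integer
#' positions of the response wheel, so duplicated colors are legal.
#'
#' @param set_size Number of items (>= 1).
#' @return Integer degrees in `{0, ..., 359}`.
#' @export
draw_array <- function(set_size) {
  stopifnot(set_size >= 1)
  sample(0:359, set_size, replace = TRUE)
}

# von Mises sampler (Best & Fisher rejection method), mean 0, radians
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(stats::runif(k) - 0.5) * acos(f[ok])
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  out
}

# simulate all responses of one participant in one set-size block;
# returns a tibble of response rows (see TrialRecord schema)
simulate_participant_block <- function(participant, x_j, pm_j, kappa_j,
                                       set_size, n_trials, n_sessions,
                                       config) {
  n_items <- n_trials * set_size
  trial_of <- rep(seq_len(n_trials), each = set_size)
  location <- rep(seq_len(set_size) - 1L, times = n_trials)
  target <- as.numeric(draw_array(n_items))

  z <- if (x_j == 1) stats::rbinom(n_items, 1, pm_j) else rep(0L, n_items)
  sp <- config$swap_prob(set_size)
  swap <- if (set_size > 1 && sp > 0) {
    as.integer(z == 1 & stats::runif(n_items) < sp)
  } else {
    rep(0L, n_items)
  }

  # response centers: target, a random nontarget (swap), or none (uniform)
  center <- target
  if (any(swap == 1)) {
    for (i in which(swap == 1)) {
      others <- which(trial_of == trial_of[i] & seq_len(n_items) != i)
      center[i] <- target[sample(others, 1)]
    }
  }
  response <- numeric(n_items)
  mem <- z == 1
  if (any(mem)) {
    noise <- rvonmises(sum(mem), kappa_j) / DEG2RAD
    response[mem] <- wrap_angle(center[mem] + noise)
  }
  if (any(!mem)) {
    response[!mem] <- stats::runif(sum(!mem), 0, 360)
  }

  strength <- z * kappa_j + stats::rnorm(n_items, 0, config$order_noise_sd)
  op <- integer(n_items)
  strat <- config$order_strategy
  use_strength <- switch(strat,
    strength_ordered = rep(TRUE, n_trials),
    spatial_scan = rep(FALSE, n_trials),
    mixed = stats::runif(n_trials) < config$mixed_weight
  )
  for (t in seq_len(n_trials)) {
    idx <- which(trial_of == t)
    if (use_strength[t]) {
      op[idx][order(strength[idx], decreasing = TRUE)] <- seq_len(set_size)
    } else {
      op[idx][order(location[idx])] <- seq_len(set_size)
    }
  }

  guess_flag <- if (config$guess_report_rule == "threshold_on_z") {
    as.integer(z == 0)
  } else {
    conf <- z * kappa_j + stats::rnorm(n_items, 0, config$sdt_noise_sd)
    as.integer(conf < config$sdt_criterion)
  }

  per_session <- n_trials / n_sessions
  tibble::tibble(
    participant = participant,
    session = ((trial_of - 1L) %/% per_session) + 1L,
    trial = trial_of,
    set_size = set_size,
    location = location,
    target_deg = target,
    response_deg = response,
    output_position = op,
    guess_flag = guess_flag
  )
}

#' Simulate a whole-report experiment
#'
#' Generates a full trial table for an [experiment_template()] under a
#' [sim_config()]. Deterministic given `seed`: identical configuration and
#' seed produce an identical table. Trials of different set sizes are
#' numbered independently within participant (the `trial` counter restarts
#' per set-size block, which keeps `(participant, session, trial, set_size)`
#' unique).
#'
#' @param template An [experiment_template()].
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return A trial table (tibble) with one row per response event and an
#'   attribute `"participants"` holding the latent participant parameters
#'   (`x_j`, `pm_j`, `kappa_j`).
#' @export
simulate_experiment <- function(template, config = sim_config(),
                                seed = 1) {
  stopifnot(inherits(template, "wm_template"),
            inherits(config, "wm_sim_config"))
  set.seed(seed)
  a_pm <- config$pm_mean * config$pm_concentration
  b_pm <- (1 - config$pm_mean) * config$pm_concentration
  rate_k <- config$kappa_shape / config$kappa_mean

  pp <- tibble::tibble(
    participant = seq_len(template$n_participants),
    x_j = stats::rbinom(template$n_participants, 1, config$p_mix),
    pm_j = stats::rbeta(template$n_participants, a_pm, b_pm),
    kappa_j = stats::rgamma(template$n_participants, config$kappa_shape,
                            rate_k)
  )

  rows <- purrr::map(seq_len(template$n_participants), function(j) {
    purrr::map(template$set_sizes, function(ss) {
      simulate_participant_block(j, pp$x_j[j], pp$pm_j[j], pp$kappa_j[j],
                                 ss, template$trials_per_set_size,
                                 template$n_sessions, config)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  out <- dplyr::bind_cols(tibble::tibble(experiment = template$name),
                          rows) |>
    dplyr::arrange(.data$participant, .data$set_size, .data$trial,
                   .data$output_position)
  attr(out, "participants") <- pp
  out
}

#' Simulate signed errors from a fixed-parameter mixture
#'
#' Draws `n` signed errors from the two- or three-parameter mixture with
#' fixed weights: von Mises around 0 with probability `p_mem`, around a
#' random nontarget offset with probability `p_nontarget` (offsets drawn
#' uniformly, as for random array colors), uniform otherwise. Used for
#' operating-characteristic and recovery studies of the ML fits.
#'
#' @param n Number of errors.
#' @param p_mem,p_nontarget,kappa Mixture parameters.
#' @return Signed errors in degrees on `[-180, 180)`.
#' @export
simulate_mixture_errors <- function(n, p_mem, kappa, p_nontarget = 0) {
  check_mixture_params(p_mem, p_nontarget, kappa)
  comp <- sample(1:3, n, replace = TRUE,
                 prob = c(p_mem, p_nontarget, 1 - p_mem - p_nontarget))
  err <- stats::runif(n, -180, 180)
  mem <- comp == 1
  if (any(mem)) err[mem] <- rvonmises(sum(mem), kappa) / DEG2RAD
  nt <- comp == 2
  if (any(nt)) {
    offs <- stats::runif(sum(nt), 0, 360)
    err[nt] <- wrap_error(offs + rvonmises(sum(nt), kappa) / DEG2RAD)
  }
  wrap_error(err)
}

#' Simulate one condition cell from the hierarchical mixture model
#'
#' Generates the data of a single (set size x output position) cell directly
#' from the hierarchical three-parameter model: per participant,
#' `Pm_j ~ beta(pm_mean * pm_concentration, ...)`, a conditional swap
#' proportion `q_j ~ beta(q_mean * q_concentration, ...)` (so the swap
#' probability is `(1 - Pm_j) * q_j`... see Details), and
#' `kappa_j ~ gamma(kappa_shape, kappa_shape / kappa_mean)`; per trial a
#' target and `m` nontargets are drawn uniformly and the response comes from
#' the target component, a nontarget component, or the uniform.
#'
#' @details The cell-level generative simplex is parameterized as
#' `P(mem) = Pm_j`, `P(nontarget) = (1 - Pm_j) * q_j`, matching the
#' hierarchical fit in [fit_hier3()]. The implied population mean of
#' `P(nontarget)` is `(1 - pm_mean) * q_mean` (independence of the two
#' betas).
#'
#' @param n_participants,n_trials Cell dimensions.
#' @param set_size Array size; `set_size - 1` nontargets per trial.
#' @param pm_mean,pm_concentration,q_mean,q_concentration,kappa_mean,kappa_shape
#'   Population parameters.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `participant`, `trial`, `target_deg`,
#'   `response_deg`, `nontargets_deg` (list-column) and attribute `"truth"`
#'   with the population means.
#' @export
simulate_hier_cell <- function(n_participants = 24, n_trials = 90,
                               set_size = 6,
                               pm_mean = 0.6, pm_concentration = 8,
                               q_mean = 0.25, q_concentration = 8,
                               kappa_mean = 8, kappa_shape = 4,
                               seed = 1) {
  set.seed(seed)
  J <- n_participants
  pm_j <- stats::rbeta(J, pm_mean * pm_concentration,
                       (1 - pm_mean) * pm_concentration)
  q_j <- if (set_size > 1) {
    stats::rbeta(J, q_mean * q_concentration,
                 (1 - q_mean) * q_concentration)
  } else {
    rep(0, J)
  }
  kappa_j <- stats::rgamma(J, kappa_shape, kappa_shape / kappa_mean)
  m <- set_size - 1L

  rows <- purrr::map(seq_len(J), function(j) {
    target <- stats::runif(n_trials, 0, 360)
    nts <- purrr::map(seq_len(n_trials),
                      ~ if (m > 0) stats::runif(m, 0, 360) else numeric(0))
    p_nt <- (1 - pm_j[j]) * q_j[j]
    comp <- sample(1:3, n_trials, replace = TRUE,
                   prob = c(pm_j[j], p_nt, (1 - pm_j[j]) * (1 - q_j[j])))
    center <- target
    if (m > 0) {
      sw <- which(comp == 2)
      for (i in sw) center[i] <- nts[[i]][sample.int(m, 1)]
    }
    resp <- stats::runif(n_trials, 0, 360)
    vm <- comp != 3
    if (any(vm)) {
      resp[vm] <- wrap_angle(center[vm] +
                               rvonmises(sum(vm), kappa_j[j]) / DEG2RAD)
    }
    tibble::tibble(participant = j, trial = seq_len(n_trials),
                   target_deg = target, response_deg = resp,
                   nontargets_deg = nts)
  }) |> dplyr::bind_rows()

  attr(rows, "truth") <- list(
    p_mem = pm_mean,
    p_nontarget = if (set_size > 1) (1 - pm_mean) * q_mean else 0,
    kappa = kappa_mean,
    pm_j = pm_j, q_j = q_j, kappa_j = kappa_j
  )
  rows
}

#' Simulate one condition cell from the double-mixture generative model
#'
#' Generates a single-cell data set from the participant-level double
#' mixture: `x_j ~ Bernoulli(p_mix)` decides whether participant `j` responds
#' from the two-parameter mixture (`x_j = 1`, with `Pm_j ~ beta` and
#' `kappa_j ~ gamma`) or guesses uniformly on every trial (`x_j = 0`).
#'
#' @param n_participants,n_trials Cell dimensions.
#' @param p_mix Probability of membership in the mixture-model population.
#' @param pm_mean,pm_concentration,kappa_mean,kappa_shape Population
#'   parameters of the mixture-model population.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `participant`, `trial`, `target_deg`,
#'   `response_deg` and attribute `"truth"` (including the realized `x_j`).
#' @export
simulate_hdmm_cell <- function(n_participants = 24, n_trials = 125,
                               p_mix = 1,
                               pm_mean = 0.4, pm_concentration = 8,
                               kappa_mean = 10, kappa_shape = 4,
                               seed = 1) {
  set.seed(seed)
  J <- n_participants
  x_j <- stats::rbinom(J, 1, p_mix)
  pm_j <- stats::rbeta(J, pm_mean * pm_concentration,
                       (1 - pm_mean) * pm_concentration)
  kappa_j <- stats::rgamma(J, kappa_shape, kappa_shape / kappa_mean)

  rows <- purrr::map(seq_len(J), function(j) {
    target <- stats::runif(n_trials, 0, 360)
    z <- if (x_j[j] == 1) stats::rbinom(n_trials, 1, pm_j[j]) else 0L
    resp <- stats::runif(n_trials, 0, 360)
    mem <- z == 1
    if (any(mem)) {
      resp[mem] <- wrap_angle(target[mem] +
                                rvonmises(sum(mem), kappa_j[j]) / DEG2RAD)
    }
    tibble::tibble(participant = j, trial = seq_len(n_trials),
                   target_deg = target, response_deg = resp)
  }) |> dplyr::bind_rows()

  attr(rows, "truth") <- list(p_mix = p_mix, x_j = x_j, pm_j = pm_j,
                              kappa_j = kappa_j)
  rows
}
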