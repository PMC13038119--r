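# Hierarchical double-mixture model (HDMM) for a single design cell.
#
# The response of participant j on trial i is modeled as
#   response_ij ~ VM(target_ij, x_j * z_ij * kappa_j)
# where the von Mises with precision 0 is the circular uniform, so the
# response is memory-based if and only if both binary indicators are 1:
#   x_j  ~ Bernoulli(P_mix)    participant from the mixture-model population
#   z_ij ~ Bernoulli(Pm_j)     trial-level memory indicator
#   Pm_j ~ beta(A_Pm, B_Pm)    population of memory probabilities
#   kappa_j ~ gamma(S_k, R_k)  population of precisions
# Priors: P_mix ~ uniform[0, 1]; the beta population is reparameterized by
# mean ~ beta(1, 1) and concentration ~ gamma(1, 0.1); the gamma population
# by its mean ~ gamma(5, 0.2) and shape ~ gamma(1, 0.1).
#
# x_j is updated with its trial indicators z collapsed out (the marginal
# likelihood of participant j's data under x_j = 1 is a product of
# two-component mixture densities), which avoids the sticking that a naive
# joint (x, z) update suffers when Pm_j is small; z_ij is then sampled
# conditionally for participants with x_j = 1. P_mix has a conjugate beta
# update under its uniform prior.

#' HDMM log likelihood for fixed latent states
#'
#' Evaluates the double-mixture likelihood at a full latent configuration:
#' each trial contributes a von Mises density with effective precision
#' `x_j * z_ij * kappa_j`, which is the uniform density `1 / (2 * pi)`
#' whenever either indicator is 0.
#'
#' @param cell_data A cell tibble with columns `participant`, `target_deg`,
#'   `response_deg`.
#' @param x_j Named or participant-ordered binary vector (one per
#'   participant).
#' @param z_ij Binary vector, one per row of `cell_data`.
#' @param kappa_j Nonnegative precision per participant.
#' @return The log likelihood (scalar, radian scale).
#' @export
hdmm_loglik <- function(cell_data, x_j, z_ij, kappa_j) {
  stopifnot(is.data.frame(cell_data),
            all(c("participant", "target_deg", "response_deg") %in%
                  names(cell_data)))
  participants <- sort(unique(cell_data$participant))
  J <- length(participants)
  if (length(x_j) != J || length(kappa_j) != J) {
    stop("x_j and kappa_j must have one entry per participant",
         call. = FALSE)
  }
  if (length(z_ij) != nrow(cell_data)) {
    stop("z_ij must have one entry per trial", call. = FALSE)
  }
  if (!all(x_j %in% c(0, 1)) || !all(z_ij %in% c(0, 1))) {
    stop("x_j and z_ij must be binary", call. = FALSE)
  }
  if (any(kappa_j < 0)) stop("kappa_j must be >= 0", call. = FALSE)
  pid <- match(cell_data$participant, participants)
  err <- angular_error(cell_data$response_deg,
                       cell_data$target_deg) * DEG2RAD
  k_eff <- x_j[pid] * z_ij * kappa_j[pid]
  sum(k_eff * cos(err) - log(2 * pi) - log_bessel_i0(k_eff))
}

#' Fit the hierarchical double-mixture model to one design cell
#'
#' Runs the collapsed Metropolis-within-Gibbs sampler on a single cell
#' (typically the last output position of the largest set size, where
#' consistent guessing is most diagnostic). Yields posterior draws of
#' `P_mix`, the per-participant membership indicators `x_j`, memory
#' probabilities `Pm_j` and precisions `kappa_j`, and the population
#' parameters.
#'
#' @param data A trial table or prepared cell (columns `participant`,
#'   `target_deg`, `response_deg`).
#' @param set_size,output_position Optional cell selectors.
#' @param chains,warmup,iter MCMC layout.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param priors A [hier_priors()] block.
#' @param min_participants Minimum cohort size (default 4).
#' @param prior_only If `TRUE`, ignore the likelihood (prior check).
#' @return An object of class `wm_hdmm_fit` with `population` draws
#'   (`p_mix`, `pm_mean`, `pm_concentration`, `kappa_mean`, `kappa_shape`),
#'   `participants` draws (`x`, `p_mem`, `kappa`), diagnostics, and a
#'   convergence flag.
#' @export
fit_hdmm <- function(data, set_size = NULL, output_position = NULL,
                     chains = 3, warmup = 2000, iter = 5000, seed = 1,
                     priors = hier_priors(), min_participants = 4,
                     prior_only = FALSE) {
  cell <- prepare_cell(data, set_size, output_position,
                       need_nontargets = FALSE)
  participants <- sort(unique(cell$participant))
  J <- length(participants)
  if (J < min_participants) {
    stop("HDMM needs at least ", min_participants, " participants",
         call. = FALSE)
  }
  pid <- match(cell$participant, participants)
  n <- nrow(cell)
  n_j <- tabulate(pid, J)
  if (!prior_only && any(n_j < 20)) {
    message(sum(n_j < 20), " participant(s) with fewer than 20 trials; ",
            "membership indicators may be weakly identified")
  }
  err <- angular_error(cell$response_deg, cell$target_deg) * DEG2RAD
  cos_err <- cos(err)
  pr <- priors

  pop_names <- c("p_mix", "pm_mean", "pm_concentration", "kappa_mean",
                 "kappa_shape")
  keep_pop <- vector("list", chains)
  keep_x <- vector("list", chains)
  keep_pm <- vector("list", chains)
  keep_kap <- vector("list", chains)

  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1)
    p_mix <- stats::runif(1, 0.3, 0.7)
    mu_pm <- stats::runif(1, 0.3, 0.7)
    c_pm <- 4
    m_k <- stats::runif(1, 5, 15)
    s_k <- 2
    x_j <- rep(1L, J)
    pm_j <- rep(mu_pm, J)
    kappa_j <- rep(m_k, J)

    total <- warmup + iter
    pop_mat <- matrix(NA_real_, iter, length(pop_names))
    x_mat <- matrix(NA_integer_, iter, J)
    pm_mat <- matrix(NA_real_, iter, J)
    kap_mat <- matrix(NA_real_, iter, J)

    psd <- c(mu_pm = 0.15, c_pm = 0.3, m_k = 0.15, s_k = 0.3)
    acc_ct <- try_ct <- psd * 0

    for (it in seq_len(total)) {
      if (!prior_only) {
        # -- collapsed update of x_j (z integrated out) --
        vm_dens <- exp(kappa_j[pid] * cos_err +
                         neg_log_norm_vm(kappa_j)[pid])
        mix_dens <- pm_j[pid] * vm_dens + (1 - pm_j[pid]) / (2 * pi)
        l1 <- as.vector(tapply(log(mix_dens), pid, sum))
        l0 <- -n_j * log(2 * pi)
        lo <- log(p_mix) + l1 - (log1p(-p_mix) + l0)
        p_x1 <- if (p_mix <= 0) rep(0, J) else if (p_mix >= 1) rep(1, J)
                else stats::plogis(lo)
        x_j <- stats::rbinom(J, 1, p_x1)

        # -- z_ij for mixture-population participants --
        in_mix <- x_j[pid] == 1
        z <- integer(n)
        if (any(in_mix)) {
          p1 <- pm_j[pid] * vm_dens
          p0 <- (1 - pm_j[pid]) / (2 * pi)
          z[in_mix] <- stats::rbinom(sum(in_mix), 1,
                                     (p1 / (p1 + p0))[in_mix])
        }
        n_mem <- tabulate(pid[z == 1 & in_mix], J)
        n_guess <- ifelse(x_j == 1, n_j - n_mem, 0L)
        vm_s <- as.vector(tapply(cos_err * (z == 1 & in_mix), pid, sum))
        vm_s[is.na(vm_s)] <- 0
        vm_n <- n_mem
      } else {
        x_j <- stats::rbinom(J, 1, p_mix)
        n_mem <- n_guess <- rep(0L, J)
        vm_n <- rep(0L, J)
        vm_s <- rep(0, J)
      }

      # -- conjugate updates: P_mix (uniform prior) and Pm_j --
      p_mix <- stats::rbeta(1, 1 + sum(x_j), 1 + J - sum(x_j))
      a_pm <- mu_pm * c_pm
      b_pm <- (1 - mu_pm) * c_pm
      pm_j <- stats::rbeta(J, a_pm + n_mem, b_pm + n_guess)
      pm_j <- pmin(pmax(pm_j, 1e-9), 1 - 1e-9)

      # -- kappa_j --
      none <- vm_n == 0
      if (any(none)) {
        kappa_j[none] <- pmax(stats::rgamma(sum(none), s_k, s_k / m_k), 1e-8)
      }
      upd <- which(!none)
      if (length(upd) > 0) {
        k0 <- kappa_j[upd]
        k1 <- k0 * exp(stats::rnorm(length(upd), 0, 0.25))
        ll0 <- k0 * vm_s[upd] + vm_n[upd] * neg_log_norm_vm(k0)
        ll1 <- k1 * vm_s[upd] + vm_n[upd] * neg_log_norm_vm(k1)
        lp0 <- stats::dgamma(k0, s_k, s_k / m_k, log = TRUE) + log(k0)
        lp1 <- stats::dgamma(k1, s_k, s_k / m_k, log = TRUE) + log(k1)
        acc <- log(stats::runif(length(upd))) < (ll1 + lp1 - ll0 - lp0)
        kappa_j[upd[acc]] <- k1[acc]
      }

      # -- hyperparameters --
      bll <- function(mu, cc) {
        sum(stats::dbeta(pm_j, mu * cc, (1 - mu) * cc, log = TRUE))
      }
      mh <- function(name, lr) {
        try_ct[name] <<- try_ct[name] + 1
        ok <- !is.na(lr) && log(stats::runif(1)) < lr
        if (ok) acc_ct[name] <<- acc_ct[name] + 1
        ok
      }
      mu1 <- rw_logit(mu_pm, psd["mu_pm"])
      lr <- bll(mu1, c_pm) - bll(mu_pm, c_pm) +
        log_jac_logit(mu1) - log_jac_logit(mu_pm)
      if (mh("mu_pm", lr)) mu_pm <- mu1
      c1 <- c_pm * exp(stats::rnorm(1, 0, psd["c_pm"]))
      lr <- bll(mu_pm, c1) - bll(mu_pm, c_pm) +
        stats::dgamma(c1, pr$conc_shape, pr$conc_rate, log = TRUE) -
        stats::dgamma(c_pm, pr$conc_shape, pr$conc_rate, log = TRUE) +
        log(c1) - log(c_pm)
      if (mh("c_pm", lr)) c_pm <- c1

      gll <- function(mk, sk) {
        sum(stats::dgamma(kappa_j, sk, sk / mk, log = TRUE))
      }
      m1 <- m_k * exp(stats::rnorm(1, 0, psd["m_k"]))
      lr <- gll(m1, s_k) - gll(m_k, s_k) +
        stats::dgamma(m1, pr$kappa_mean_shape, pr$kappa_mean_rate,
                      log = TRUE) -
        stats::dgamma(m_k, pr$kappa_mean_shape, pr$kappa_mean_rate,
                      log = TRUE) +
        log(m1) - log(m_k)
      if (mh("m_k", lr)) m_k <- m1
      s1 <- s_k * exp(stats::rnorm(1, 0, psd["s_k"]))
      lr <- gll(m_k, s1) - gll(m_k, s_k) +
        stats::dgamma(s1, pr$conc_shape, pr$conc_rate, log = TRUE) -
        stats::dgamma(s_k, pr$conc_shape, pr$conc_rate, log = TRUE) +
        log(s1) - log(s_k)
      if (mh("s_k", lr)) s_k <- s1

      if (it <= warmup && it %% 50 == 0) {
        psd <- tune_scales(psd, acc_ct, try_ct)
        acc_ct[] <- 0
        try_ct[] <- 0
      }

      if (it > warmup) {
        kp <- it - warmup
        pop_mat[kp, ] <- c(p_mix, mu_pm, c_pm, m_k, s_k)
        x_mat[kp, ] <- x_j
        pm_mat[kp, ] <- pm_j
        kap_mat[kp, ] <- kappa_j
      }
    }
    colnames(pop_mat) <- pop_names
    keep_pop[[ch]] <- pop_mat
    keep_x[[ch]] <- x_mat
    keep_pm[[ch]] <- pm_mat
    keep_kap[[ch]] <- kap_mat
  }

  diag_names <- c("p_mix", "pm_mean", "kappa_mean")
  diagnostics <- purrr::map_dfr(diag_names, function(p) {
    mat <- sapply(keep_pop, function(x) x[, p])
    tibble::tibble(parameter = p, rhat = split_rhat(as.matrix(mat)),
                   ess = ess_basic(as.matrix(mat)))
  })
  converged <- all(is.na(diagnostics$rhat) | diagnostics$rhat <= 1.05) &&
    all(diagnostics$ess >= 400)

  population <- purrr::imap_dfr(keep_pop, function(mat, ch) {
    dplyr::bind_cols(tibble::tibble(chain = ch, iter = seq_len(nrow(mat))),
                     tibble::as_tibble(mat))
  })
  n_iter <- iter
  part_long <- purrr::map_dfr(seq_len(chains), function(ch) {
    tibble::tibble(
      chain = ch,
      iter = rep(seq_len(n_iter), J),
      participant = rep(participants, each = n_iter),
      x = as.integer(keep_x[[ch]]),
      p_mem = as.vector(keep_pm[[ch]]),
      kappa = as.vector(keep_kap[[ch]])
    )
  })

  out <- list(population = population, participants = part_long,
              diagnostics = diagnostics, converged = converged,
              chains = chains, iter = iter, warmup = warmup,
              n_participants = J, n_obs = n, prior_only = prior_only,
              seed = seed)
  class(out) <- c("wm_hdmm_fit", "wm_hier_fit")
  if (!converged && !prior_only) {
    warning("HDMM fit flagged as non-converged (max split-Rhat = ",
            round(max(diagnostics$rhat, na.rm = TRUE), 3),
            ", min ESS = ", round(min(diagnostics$ess)), ")",
            call. = FALSE)
  }
  out
}

#' Per-participant guessing diagnosis from an HDMM posterior
#'
#' For each participant, the proportion of posterior draws with `x_j = 0`
#' estimates the posterior probability that the participant belongs to the
#' consistent-guessing population.
#'
#' @param fit A `wm_hdmm_fit`.
#' @return A tibble: `participant`, `p_guessing_population`.
#' @export
guessing_diagnosis <- function(fit) {
  stopifnot(inherits(fit, "wm_hdmm_fit"))
  fit$participants |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(p_guessing_population = mean(.data$x == 0),
                     .groups = "drop")
}

#' @export
print.wm_hdmm_fit <- function(x, ...) {
  cat("Hierarchical double-mixture model fit\n")
  cat("  participants:", x$n_participants, " observations:", x$n_obs, "\n")
  cat("  chains:", x$chains, " kept draws/chain:", x$iter, "\n")
  cat("  converged:", x$converged, "\n")
  pm <- x$population$p_mix
  ci <- hdi(pm, 0.95)
  cat(sprintf("  P_mix: mode %.3f, 95%% HDI [%.3f, %.3f]\n",
              posterior_mode(pm), ci$low, ci$high))
  invisible(x)
}

#' Tidy summaries of an HDMM fit
#'
#' `tidy()` summarizes the population-level posteriors (mode and 95% HDI)
#' of `p_mix`, `pm_mean` and `kappa_mean`; `glance()` gives a one-row fit
#' overview including the posterior mode of `P_mix`.
#'
#' @param x A `wm_hdmm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wm_hdmm_fit <- function(x, ...) {
  purrr::map_dfr(c("p_mix", "pm_mean", "kappa_mean"), function(p) {
    d <- x$population[[p]]
    ci <- hdi(d, 0.95)
    tibble::tibble(parameter = p, mode = posterior_mode(d),
                   hdi_low = ci$low, hdi_high = ci$high, mass = 0.95)
  })
}

#' @rdname tidy.wm_hdmm_fit
#' @export
glance.wm_hdmm_fit <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants, n_obs = x$n_obs,
    chains = x$chains, draws = x$chains * x$iter,
    p_mix_mode = posterior_mode(x$population$p_mix),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess),
    converged = x$converged
  )
}

#' Posterior plot for an HDMM fit
#'
#' Shows the posterior density of `P_mix` with its 95% HDI, and the
#' per-participant posterior guessing probabilities.
#'
#' @param object A `wm_hdmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wm_hdmm_fit <- function(object, ...) {
  diag <- guessing_diagnosis(object) |>
    dplyr::mutate(participant = factor(.data$participant))
  ggplot2::ggplot(diag,
                  ggplot2::aes(x = .data$participant,
                               y = .data$p_guessing_population)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(
      x = "participant",
      y = "posterior P(consistent-guessing population)",
      title = sprintf("P_mix posterior mode: %.2f",
                      posterior_mode(object$population$p_mix))
    ) +
    ggplot2::ylim(0, 1)
}
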