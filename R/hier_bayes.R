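# Hierarchical Bayesian three-parameter mixture model for one design cell.
#
# Model, per participant j and trial i of the cell:
#   c_ij ~ categorical(Pm_j, Pnt_j, Pu_j)          latent response component
#   response | c = target     ~ VM(target_i, kappa_j)
#   response | c = nontarget  ~ VM(nontarget_ik, kappa_j), k uniform over m
#   response | c = uniform    ~ uniform on the circle
# with the participant simplex parameterized as Pm_j and a conditional swap
# share q_j: Pnt_j = (1 - Pm_j) * q_j, Pu_j = (1 - Pm_j) * (1 - q_j).
# Population distributions: Pm_j ~ beta(mu_pm * c_pm, (1 - mu_pm) * c_pm),
# q_j ~ beta(mu_q * c_q, ...), kappa_j ~ gamma(shape = s_k, rate = s_k / m_k).
# Hyperpriors: mu_pm, mu_q ~ beta(1, 1); c_pm, c_q ~ gamma(1, 0.1);
# m_k (population mean precision) ~ gamma(5, 0.2); s_k ~ gamma(1, 0.1).
#
# Sampling is Metropolis-within-Gibbs: the trial indicators and the beta
# parameters are Gibbs steps (Gumbel-max categorical draw; conjugate beta);
# kappa_j uses a log-scale random walk driven by the sufficient statistics
# (sum of cosines of the deviations assigned to a von Mises component);
# hyperparameters use logit-/log-scale random walks.

#' Prior configuration for the hierarchical fits
#'
#' All priors live in one configurable block. Defaults: population means of
#' the probability parameters are uniform (`beta(1, 1)`), their beta
#' concentrations are `gamma(1, 0.1)` (weak, mean 10), the population mean
#' of the precision is `gamma(5, 0.2)` (mean 25, assigning low mass to
#' near-guessing precisions), and the gamma shape of the precision
#' population is `gamma(1, 0.1)`.
#'
#' @param kappa_mean_shape,kappa_mean_rate Gamma prior on the population
#'   mean of `kappa`.
#' @param conc_shape,conc_rate Gamma prior on beta concentrations and on the
#'   gamma shape of the `kappa` population.
#' @return A list of prior constants.
#' @export
hier_priors <- function(kappa_mean_shape = 5, kappa_mean_rate = 0.2,
                        conc_shape = 1, conc_rate = 0.1) {
  list(kappa_mean_shape = kappa_mean_shape, kappa_mean_rate = kappa_mean_rate,
       conc_shape = conc_shape, conc_rate = conc_rate)
}

# ---- shared sampler utilities ----------------------------------------------

# split-Rhat over a draws matrix (iterations x chains)
split_rhat <- function(mat) {
  n <- nrow(mat)
  if (n < 4) {
    return(NA_real_)
  }
  half <- floor(n / 2)
  sub <- cbind(mat[1:half, , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w < 1e-300) {
    return(1)
  }
  sqrt(((half - 1) / half * w + b / half) / w)
}

# crude effective sample size: initial positive sequence of autocorrelations
ess_basic <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  if (stats::var(as.vector(mat)) < 1e-300) {
    return(n * m)
  }
  rho_sum <- 0
  for (ch in seq_len(m)) {
    x <- mat[, ch]
    if (stats::var(x) < 1e-300) next
    ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    neg <- which(ac < 0)
    if (length(neg) > 0) ac <- ac[seq_len(neg[1] - 1)]
    rho_sum <- rho_sum + sum(ac)
  }
  (n * m) / (1 + 2 * rho_sum / m)
}

rw_logit <- function(x, sd) stats::plogis(stats::qlogis(x) +
                                            stats::rnorm(1, 0, sd))
log_jac_logit <- function(x) log(x) + log1p(-x)

# warm-up proposal-scale adaptation toward ~44% acceptance (frozen after
# warm-up, so the kept draws come from a fixed transition kernel)
tune_scales <- function(psd, acc, try, lo = 0.02, hi = 5) {
  rate <- ifelse(try > 0, acc / try, 0.44)
  pmin(pmax(psd * exp(rate - 0.44), lo), hi)
}

# log density of the von Mises normalization term, vectorized over kappa
neg_log_norm_vm <- function(kappa) -log(2 * pi) - log_bessel_i0(kappa)

# extract one design cell (set size x output position) from a trial table,
# or accept data already in cell format
prepare_cell <- function(data, set_size = NULL, output_position = NULL,
                         need_nontargets = TRUE) {
  stopifnot(is.data.frame(data))
  if (!is.null(set_size)) {
    data <- dplyr::filter(data, .data$set_size == !!set_size)
  }
  if (need_nontargets && !"nontargets_deg" %in% names(data) &&
      !is.null(set_size) && set_size > 1) {
    data <- with_nontargets(data)
  }
  if (!is.null(output_position)) {
    data <- dplyr::filter(data, .data$output_position == !!output_position)
  }
  stopifnot(all(c("participant", "target_deg", "response_deg") %in%
                  names(data)))
  data
}

# ---- the sampler -----------------------------------------------------------

#' Fit the hierarchical three-parameter mixture to one design cell
#'
#' Runs the Metropolis-within-Gibbs sampler described in the package
#' vignette on one (set size x output position) cell, yielding posterior
#' draws of the population-level means of `P(mem)`, `P(nontarget)`, the
#' derived `P(uniform) = 1 - P(mem) - P(nontarget)` (computed elementwise on
#' every draw), and the population mean and shape of `kappa`, together with
#' per-participant draws. For cells without nontargets (set size 1) the
#' nontarget component is structurally absent and `P(nontarget)` is 0.
#'
#' @param data A trial table, or a prepared cell with columns `participant`,
#'   `target_deg`, `response_deg` and (for set sizes > 1) a list-column
#'   `nontargets_deg`.
#' @param set_size,output_position Optional cell selectors applied to
#'   `data`.
#' @param chains,warmup,iter MCMC layout: `chains` chains of `warmup`
#'   discarded plus `iter` kept draws each.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param priors A [hier_priors()] block.
#' @param prior_only If `TRUE`, ignore the likelihood and sample from the
#'   prior (prior-predictive check).
#' @return An object of class `wm_hier_fit` with elements `population`
#'   (tibble of draws: `chain`, `iter`, one column per population
#'   parameter), `participants` (tibble of per-participant draws),
#'   `diagnostics` (split-Rhat and effective sample size per population
#'   parameter), and `converged` (all Rhat <= 1.05 and ESS >= 400).
#' @export
fit_hier3 <- function(data, set_size = NULL, output_position = NULL,
                      chains = 3, warmup = 2000, iter = 5000, seed = 1,
                      priors = hier_priors(), prior_only = FALSE) {
  cell <- prepare_cell(data, set_size, output_position)
  participants <- sort(unique(cell$participant))
  J <- length(participants)
  if (J < 2) {
    stop("hierarchical fit needs at least 2 participants", call. = FALSE)
  }
  pid <- match(cell$participant, participants)
  n <- nrow(cell)
  err <- angular_error(cell$response_deg, cell$target_deg) * DEG2RAD

  has_nt <- "nontargets_deg" %in% names(cell) &&
    any(lengths(cell$nontargets_deg) > 0)
  if (has_nt) {
    m_i <- lengths(cell$nontargets_deg)
    m_max <- max(m_i)
    nt_dev <- matrix(NA_real_, n, m_max)
    for (i in seq_len(n)) {
      nt <- cell$nontargets_deg[[i]]
      if (length(nt) > 0) {
        nt_dev[i, seq_along(nt)] <-
          angular_error(cell$response_deg[i], nt) * DEG2RAD
      }
    }
    cos_nt <- cos(nt_dev)
  } else {
    m_i <- rep(0L, n)
    m_max <- 0L
  }
  cos_err <- cos(err)
  n_j <- tabulate(pid, J)

  pr <- priors
  pop_names <- c("p_mem", "p_nontarget", "p_uniform", "kappa_mean",
                 "kappa_shape", "pm_concentration")
  keep_pop <- vector("list", chains)
  keep_pm <- vector("list", chains)
  keep_pnt <- vector("list", chains)
  keep_kappa <- vector("list", chains)

  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1)
    # state
    mu_pm <- stats::runif(1, 0.3, 0.7)
    c_pm <- 4
    mu_q <- 0.3
    c_q <- 4
    m_k <- stats::runif(1, 5, 15)
    s_k <- 2
    pm_j <- rep(mu_pm, J)
    q_j <- rep(mu_q, J)
    kappa_j <- rep(m_k, J)

    total <- warmup + iter
    pop_mat <- matrix(NA_real_, iter, length(pop_names))
    pm_mat <- matrix(NA_real_, iter, J)
    pnt_mat <- matrix(NA_real_, iter, J)
    kap_mat <- matrix(NA_real_, iter, J)

    psd <- c(mu_pm = 0.15, c_pm = 0.3, mu_q = 0.15, c_q = 0.3,
             m_k = 0.15, s_k = 0.3)
    acc_ct <- try_ct <- psd * 0

    for (it in seq_len(total)) {
      if (!prior_only) {
        # -- latent component indicators (Gumbel-max categorical) --
        lk <- kappa_j[pid]
        lnorm <- neg_log_norm_vm(kappa_j)[pid]
        lw_t <- log(pm_j[pid]) + lk * cos_err + lnorm
        lw_u <- log1p(-pm_j[pid]) +
          (if (has_nt) log1p(-q_j[pid]) else 0) - log(2 * pi)
        if (has_nt) {
          lw_nt <- log1p(-pm_j[pid]) + log(q_j[pid]) - log(m_i) +
            lk * cos_nt + lnorm
          lw <- cbind(lw_t, lw_u, lw_nt)
        } else {
          lw <- cbind(lw_t, lw_u)
        }
        g <- -log(-log(matrix(stats::runif(length(lw)), nrow = n)))
        g[is.na(lw)] <- -Inf
        lw[is.na(lw)] <- -Inf
        comp <- max.col(lw + g, ties.method = "first")
        is_t <- comp == 1
        is_u <- comp == 2
        is_nt <- comp > 2

        n_mem <- tabulate(pid[is_t], J)
        n_nt <- tabulate(pid[is_nt], J)
        n_uni <- tabulate(pid[is_u], J)
        # sufficient statistics for kappa: cosines of assigned deviations
        dev_cos <- numeric(n)
        dev_cos[is_t] <- cos_err[is_t]
        if (any(is_nt)) {
          idx <- which(is_nt)
          dev_cos[idx] <- cos_nt[cbind(idx, comp[idx] - 2L)]
        }
        vm_n <- n_mem + n_nt
        vm_s <- as.vector(tapply(dev_cos * (is_t | is_nt), pid, sum))
        vm_s[is.na(vm_s)] <- 0
      } else {
        n_mem <- n_nt <- n_uni <- rep(0L, J)
        vm_n <- rep(0L, J)
        vm_s <- rep(0, J)
      }

      # -- participant-level conjugate updates --
      a_pm <- mu_pm * c_pm
      b_pm <- (1 - mu_pm) * c_pm
      pm_j <- stats::rbeta(J, a_pm + n_mem, b_pm + n_nt + n_uni)
      pm_j <- pmin(pmax(pm_j, 1e-9), 1 - 1e-9)
      if (has_nt) {
        a_q <- mu_q * c_q
        b_q <- (1 - mu_q) * c_q
        q_j <- stats::rbeta(J, a_q + n_nt, b_q + n_uni)
        q_j <- pmin(pmax(q_j, 1e-9), 1 - 1e-9)
      }

      # -- kappa_j: direct gamma draw when unconstrained, else log-RW MH --
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

      # -- hyperparameter random walks --
      bll <- function(mu, cc, x) {
        sum(stats::dbeta(x, mu * cc, (1 - mu) * cc, log = TRUE))
      }
      mh <- function(name, lr) {
        try_ct[name] <<- try_ct[name] + 1
        ok <- !is.na(lr) && log(stats::runif(1)) < lr
        if (ok) acc_ct[name] <<- acc_ct[name] + 1
        ok
      }
      mu1 <- rw_logit(mu_pm, psd["mu_pm"])
      lr <- bll(mu1, c_pm, pm_j) - bll(mu_pm, c_pm, pm_j) +
        log_jac_logit(mu1) - log_jac_logit(mu_pm)
      if (mh("mu_pm", lr)) mu_pm <- mu1
      c1 <- c_pm * exp(stats::rnorm(1, 0, psd["c_pm"]))
      lr <- bll(mu_pm, c1, pm_j) - bll(mu_pm, c_pm, pm_j) +
        stats::dgamma(c1, pr$conc_shape, pr$conc_rate, log = TRUE) -
        stats::dgamma(c_pm, pr$conc_shape, pr$conc_rate, log = TRUE) +
        log(c1) - log(c_pm)
      if (mh("c_pm", lr)) c_pm <- c1

      if (has_nt) {
        mu1 <- rw_logit(mu_q, psd["mu_q"])
        lr <- bll(mu1, c_q, q_j) - bll(mu_q, c_q, q_j) +
          log_jac_logit(mu1) - log_jac_logit(mu_q)
        if (mh("mu_q", lr)) mu_q <- mu1
        c1 <- c_q * exp(stats::rnorm(1, 0, psd["c_q"]))
        lr <- bll(mu_q, c1, q_j) - bll(mu_q, c_q, q_j) +
          stats::dgamma(c1, pr$conc_shape, pr$conc_rate, log = TRUE) -
          stats::dgamma(c_q, pr$conc_shape, pr$conc_rate, log = TRUE) +
          log(c1) - log(c_q)
        if (mh("c_q", lr)) c_q <- c1
      }

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
        mu_nt <- if (has_nt) (1 - mu_pm) * mu_q else 0
        pop_mat[kp, ] <- c(mu_pm, mu_nt, 1 - mu_pm - mu_nt, m_k, s_k, c_pm)
        pm_mat[kp, ] <- pm_j
        pnt_mat[kp, ] <- if (has_nt) (1 - pm_j) * q_j else 0
        kap_mat[kp, ] <- kappa_j
      }
    }
    colnames(pop_mat) <- pop_names
    keep_pop[[ch]] <- pop_mat
    keep_pm[[ch]] <- pm_mat
    keep_pnt[[ch]] <- pnt_mat
    keep_kappa[[ch]] <- kap_mat
  }

  diag_names <- c("p_mem", "p_nontarget", "kappa_mean")
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
      p_mem = as.vector(keep_pm[[ch]]),
      p_nontarget = as.vector(keep_pnt[[ch]]),
      kappa = as.vector(keep_kappa[[ch]])
    )
  })

  out <- list(population = population, participants = part_long,
              diagnostics = diagnostics, converged = converged,
              chains = chains, iter = iter, warmup = warmup,
              n_participants = J, n_obs = n, has_nontargets = has_nt,
              prior_only = prior_only, seed = seed)
  class(out) <- "wm_hier_fit"
  if (!converged && !prior_only) {
    warning("hierarchical fit flagged as non-converged ",
            "(max split-Rhat = ",
            round(max(diagnostics$rhat, na.rm = TRUE), 3),
            ", min ESS = ", round(min(diagnostics$ess)), ")",
            call. = FALSE)
  }
  out
}

#' Posterior mode and highest-density interval of population parameters
#'
#' Summarizes the population-level draws of a [fit_hier3()] result with the
#' posterior mode (kernel density argmax) and the 95% highest-density
#' interval, pooling draws across chains. `P(uniform)` is summarized from
#' its own derived draws, not from `1 - mode - mode` (modes are not linear).
#'
#' @param fit A `wm_hier_fit`.
#' @param parameters Which population parameters to summarize.
#' @param mass HDI mass (default 0.95).
#' @return A tibble: `parameter`, `mode`, `hdi_low`, `hdi_high`, `mass`.
#' @export
summarize_population <- function(fit,
                                 parameters = c("p_mem", "p_nontarget",
                                                "p_uniform", "kappa_mean"),
                                 mass = 0.95) {
  stopifnot(inherits(fit, "wm_hier_fit"))
  purrr::map_dfr(parameters, function(p) {
    x <- fit$population[[p]]
    ci <- hdi(x, mass)
    tibble::tibble(parameter = p, mode = posterior_mode(x),
                   hdi_low = ci$low, hdi_high = ci$high, mass = mass)
  })
}

#' @export
print.wm_hier_fit <- function(x, ...) {
  cat("Hierarchical three-parameter mixture fit\n")
  cat("  participants:", x$n_participants, " observations:", x$n_obs, "\n")
  cat("  chains:", x$chains, " kept draws/chain:", x$iter, "\n")
  cat("  converged:", x$converged, "\n")
  print(summarize_population(x))
  invisible(x)
}

#' Tidy posterior summaries of a hierarchical fit
#'
#' `tidy()` returns the population-level posterior modes and 95% HDIs;
#' `glance()` returns a one-row fit overview (dimensions, diagnostics).
#'
#' @param x A `wm_hier_fit`.
#' @param ... Passed to [summarize_population()].
#' @return A tibble.
#' @export
tidy.wm_hier_fit <- function(x, ...) {
  summarize_population(x, ...)
}

#' @rdname tidy.wm_hier_fit
#' @export
glance.wm_hier_fit <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants, n_obs = x$n_obs,
    chains = x$chains, draws = x$chains * x$iter,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess),
    converged = x$converged
  )
}

#' Export posterior draws in long format
#'
#' @param fit A `wm_hier_fit` or `wm_hdmm_fit`.
#' @param level `"population"` or `"participant"`.
#' @return A long tibble: `chain`, `iter`, (`participant`,) `parameter`,
#'   `value`.
#' @export
posterior_draws <- function(fit, level = c("population", "participant")) {
  level <- match.arg(level)
  stopifnot(inherits(fit, "wm_hier_fit") || inherits(fit, "wm_hdmm_fit"))
  src <- if (level == "population") fit$population else fit$participants
  keys <- intersect(c("chain", "iter", "participant"), names(src))
  tidyr::pivot_longer(src, -dplyr::all_of(keys),
                      names_to = "parameter", values_to = "value")
}

#' Population posterior plot for a hierarchical fit
#'
#' Density plots of the population-level posterior draws with the posterior
#' mode and 95% HDI marked.
#'
#' @param object A `wm_hier_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wm_hier_fit <- function(object, ...) {
  draws <- posterior_draws(object, "population") |>
    dplyr::filter(.data$parameter %in%
                    c("p_mem", "p_nontarget", "p_uniform", "kappa_mean"))
  summ <- summarize_population(object)
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(data = summ,
                        ggplot2::aes(xintercept = .data$mode),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "population parameter value", y = "posterior density")
}
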