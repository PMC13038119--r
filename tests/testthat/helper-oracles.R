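# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# modified Bessel function I0 by direct series evaluation
series_i0 <- function(x, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# exhaustive O(n^2) search for the narrowest window of ceiling(mass * n)
# consecutive order statistics; ties resolved to the lowest starting index
brute_hdi <- function(samples, mass = 0.95) {
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) {
    return(c(x[1], x[n]))
  }
  best <- c(Inf, NA, NA)
  for (i in 1:(n - k + 1)) {
    w <- x[i + k - 1] - x[i]
    if (w < best[1]) best <- c(w, x[i], x[i + k - 1])
  }
  best[2:3]
}

# brute-force Gaussian-kernel density argmax on a 512-point grid with the
# same rule-of-thumb bandwidth convention
brute_mode <- function(samples) {
  bw <- stats::bw.nrd0(samples)
  grid <- seq(min(samples), max(samples), length.out = 512)
  dens <- vapply(grid,
                 function(g) mean(stats::dnorm((g - samples) / bw)) / bw,
                 numeric(1))
  grid[which.max(dens)]
}

# per-observation two-parameter mixture density, summed by hand
brute_loglik_mixture2 <- function(errors_deg, p_mem, kappa) {
  tot <- 0
  for (e in errors_deg) {
    th <- e * pi / 180
    vm <- exp(kappa * cos(th)) / (2 * pi * besselI(kappa, 0))
    tot <- tot + log(p_mem * vm + (1 - p_mem) / (2 * pi))
  }
  tot
}

# per-observation three-parameter mixture density (equal split over
# nontargets), summed by hand
brute_loglik_mixture3 <- function(resp, targ, nts, p_mem, p_nt, kappa) {
  vm <- function(delta_deg) {
    d <- ((delta_deg + 180) %% 360 - 180) * pi / 180
    exp(kappa * cos(d)) / (2 * pi * besselI(kappa, 0))
  }
  tot <- 0
  for (i in seq_along(resp)) {
    dens <- p_mem * vm(resp[i] - targ[i]) +
      (1 - p_mem - p_nt) / (2 * pi)
    if (p_nt > 0) {
      dens <- dens + p_nt * mean(vapply(nts[[i]],
                                        function(x) vm(resp[i] - x),
                                        numeric(1)))
    }
    tot <- tot + log(dens)
  }
  tot
}

# tiny cell tibble in the format the Bayesian fitters accept
toy_cell <- function(n_participants = 2, n_trials = 5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    participant = rep(seq_len(n_participants), each = n_trials),
    trial = rep(seq_len(n_trials), n_participants),
    target_deg = stats::runif(n_participants * n_trials, 0, 360),
    response_deg = stats::runif(n_participants * n_trials, 0, 360)
  )
}
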