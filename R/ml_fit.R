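# Per-participant, per-cell maximum-likelihood fits of the two-parameter
# mixture model and BIC comparison against the pure-guessing uniform model.
#
# Each cell (participant x set size x output position) is fitted twice, once
# with Nelder-Mead (on logit/log-transformed parameters, which makes the
# simplex search respect the box constraints) and once with L-BFGS-B on the
# natural bounded scale; the fit with the smaller deviance is kept. Both
# optimizers are multi-started from a small grid of plausible values.

ML_STARTS <- expand.grid(p_mem = c(0.2, 0.5, 0.8), kappa = c(2, 8, 32))

#' Maximum-likelihood fit of the two-parameter mixture to one cell
#'
#' Fits `p_mem` and `kappa` to a vector of signed errors by maximum
#' likelihood, running both a Nelder-Mead search (transformed scale) and
#' L-BFGS-B (bounded natural scale) from a multi-start grid, and keeping the
#' fit with the smaller deviance. Also reports the BIC
#' (`deviance + 2 * log(n)`, two free parameters).
#'
#' @param errors_deg Signed errors in degrees on `[-180, 180)`.
#' @param min_n Minimum number of trials required; smaller cells error.
#' @param kappa_max Upper bound for `kappa` (default 500, beyond the
#'   resolution of a 360-step response wheel; unbounded `kappa` overflows the
#'   Bessel normalization).
#' @return A one-row tibble: `p_mem`, `kappa`, `loglik`, `deviance`, `bic`,
#'   `optimizer` (label of the winning algorithm), `n`.
#' @export
fit_mixture2_ml <- function(errors_deg, min_n = 5, kappa_max = 500) {
  n <- length(errors_deg)
  if (n < min_n) {
    stop("degenerate cell: ", n, " trials (minimum ", min_n, ")",
         call. = FALSE)
  }
  e <- wrap_error(errors_deg) * DEG2RAD
  ce <- cos(e)

  negll_nat <- function(par) {
    # clamp: L-BFGS-B probes a finite-difference step beyond its box
    p <- min(max(par[1], 0), 1)
    k <- min(max(par[2], 0), kappa_max)
    dens <- p * exp(k * ce - log(2 * pi) - log_bessel_i0(k)) +
      (1 - p) / (2 * pi)
    -sum(log(pmax(dens, 1e-300)))
  }
  negll_trans <- function(par) {
    p <- stats::plogis(par[1])
    k <- exp(par[2])
    if (k > kappa_max) {
      return(1e10)
    }
    negll_nat(c(p, k))
  }

  best <- NULL
  for (s in seq_len(nrow(ML_STARTS))) {
    p0 <- ML_STARTS$p_mem[s]
    k0 <- ML_STARTS$kappa[s]

    nm <- tryCatch(
      stats::optim(c(stats::qlogis(p0), log(k0)), negll_trans,
                   method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(nm)) {
      cand <- list(p_mem = stats::plogis(nm$par[1]),
                   kappa = min(exp(nm$par[2]), kappa_max),
                   value = nm$value, optimizer = "nelder-mead")
      if (is.null(best) || cand$value < best$value) best <- cand
    }

    lb <- tryCatch(
      stats::optim(c(p0, k0), negll_nat, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(1, kappa_max),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(lb)) {
      cand <- list(p_mem = lb$par[1], kappa = lb$par[2],
                   value = lb$value, optimizer = "l-bfgs-b")
      if (is.null(best) || cand$value < best$value) best <- cand
    }
  }
  if (is.null(best)) {
    stop("fit failure: both optimizers failed on all starts (n = ", n, ")",
         call. = FALSE)
  }
  ll <- -best$value
  tibble::tibble(
    p_mem = best$p_mem, kappa = best$kappa,
    loglik = ll, deviance = -2 * ll, bic = -2 * ll + 2 * log(n),
    optimizer = best$optimizer, n = n
  )
}

#' Fit the two-parameter mixture to every participant-level cell
#'
#' Computes signed errors from a trial table and fits [fit_mixture2_ml()] to
#' each `(experiment, participant, set_size, output_position)` cell of the
#' requested set sizes. Cells with fewer than `min_n` trials are dropped with
#' a message (reported as absent, not as zero-information).
#'
#' @param trials A trial table (see [read_trials()]).
#' @param set_sizes Set sizes to fit (default 4 and 6, where guessing-like
#'   cells are diagnostic).
#' @param min_n Minimum trials per cell.
#' @param kappa_max Upper bound for `kappa`.
#' @return A tibble with one row per fitted cell: grouping keys plus the
#'   columns of [fit_mixture2_ml()].
#' @export
fit_cells_ml <- function(trials, set_sizes = c(4, 6), min_n = 5,
                         kappa_max = 500) {
  stopifnot(is.data.frame(trials))
  keys <- intersect(c("experiment", "participant", "set_size",
                      "output_position"), names(trials))
  cells <- trials |>
    dplyr::filter(.data$set_size %in% set_sizes) |>
    dplyr::mutate(error_deg = angular_error(.data$response_deg,
                                            .data$target_deg)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(errors = list(.data$error_deg), .groups = "drop")
  small <- lengths(cells$errors) < min_n
  if (any(small)) {
    message(sum(small), " cell(s) with fewer than ", min_n,
            " trials excluded")
    cells <- cells[!small, ]
  }
  fits <- purrr::map(cells$errors,
                     ~ fit_mixture2_ml(.x, min_n = min_n,
                                       kappa_max = kappa_max))
  dplyr::bind_cols(cells[keys], dplyr::bind_rows(fits))
}

#' Compare fitted cells with the uniform guessing model
#'
#' For each fitted cell, computes the BIC of the pure-guessing uniform model
#' (`2 * n * log(2 * pi)`, no free parameters) and the BIC difference
#' `BIC_mixture - BIC_uniform`. A positive difference favors the uniform
#' model, in which case the cell is classified as a consistent
#' zero-information state (`uniform_preferred = TRUE`).
#'
#' @param fits Output of [fit_cells_ml()] (or a one-row
#'   [fit_mixture2_ml()] result).
#' @return `fits` with added columns `bic_uniform`, `bic_difference`,
#'   `uniform_preferred`.
#' @export
compare_to_uniform <- function(fits) {
  stopifnot(is.data.frame(fits), all(c("bic", "n") %in% names(fits)))
  fits |>
    dplyr::mutate(
      bic_uniform = 2 * .data$n * log(2 * pi),
      bic_difference = .data$bic - .data$bic_uniform,
      uniform_preferred = .data$bic_difference > 0
    )
}

#' Count zero-information classifications per design cell
#'
#' Tabulates, for each `(experiment, set_size, output_position)` design cell,
#' how many participants were classified as consistent guessers by the BIC
#' comparison, alongside the number of participants fitted in that cell.
#' Cells absent from the fits are absent from the table.
#'
#' @param classifications Output of [compare_to_uniform()].
#' @return A tibble with columns (`experiment`,) `set_size`,
#'   `output_position`, `count`, `n_participants`.
#' @export
classification_table <- function(classifications) {
  stopifnot(is.data.frame(classifications),
            "uniform_preferred" %in% names(classifications))
  keys <- intersect(c("experiment", "set_size", "output_position"),
                    names(classifications))
  classifications |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(count = sum(.data$uniform_preferred),
                     n_participants = dplyr::n(), .groups = "drop")
}

# Grid-search reference used by tests and diagnostics: best log likelihood of
# the two-parameter mixture over an explicit (p_mem, kappa) grid.
grid_loglik_mixture2 <- function(errors_deg,
                                 p_grid = seq(0, 1, length.out = 50),
                                 kappa_grid = c(0, exp(seq(log(0.1), log(100),
                                                           length.out = 49)))) {
  e <- wrap_error(errors_deg) * DEG2RAD
  ce <- cos(e)
  best <- -Inf
  for (k in kappa_grid) {
    vm <- exp(k * ce - log(2 * pi) - log_bessel_i0(k))
    for (p in p_grid) {
      ll <- sum(log(p * vm + (1 - p) / (2 * pi)))
      if (ll > best) best <- ll
    }
  }
  best
}
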