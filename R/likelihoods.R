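# Measurement-model likelihoods for continuous-reproduction responses:
# uniform (pure guessing), two-parameter mixture (target + uniform), and
# three-parameter mixture (target + nontargets + uniform). All densities are
# per radian; inputs are degrees and converted at the boundary.

check_mixture_params <- function(p_mem, p_nontarget, kappa) {
  if (!is.numeric(p_mem) || length(p_mem) != 1 || !is.finite(p_mem) ||
      p_mem < 0 || p_mem > 1) {
    stop("p_mem must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(p_nontarget) || length(p_nontarget) != 1 ||
      !is.finite(p_nontarget) || p_nontarget < 0 || p_nontarget > 1) {
    stop("p_nontarget must be a single value in [0, 1]", call. = FALSE)
  }
  if (p_mem + p_nontarget > 1 + 1e-12) {
    stop("p_mem + p_nontarget must not exceed 1", call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) ||
      kappa < 0) {
    stop("kappa must be a single finite value >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Log likelihood of the uniform (pure-guessing) model
#'
#' Under 100% random guessing every response is uniform on the circle, so the
#' log likelihood is `-n * log(2 * pi)` on the radian scale, independent of
#' the data values. Its deviance is `-2` times this, and because the model
#' has no free parameters its BIC equals its deviance.
#'
#' @param n Number of responses (a positive integer).
#' @return The log likelihood (scalar).
#' @export
loglik_uniform <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  -n * log(2 * pi)
}

#' Log likelihood of the two-parameter mixture model
#'
#' Each signed error is modeled as a mixture of a von Mises distribution
#' centered on the target (weight `p_mem`, concentration `kappa`) and a
#' circular uniform (weight `1 - p_mem`).
#'
#' @param errors_deg Signed errors in degrees on `[-180, 180)`.
#' @param p_mem Proportion of memory-based responses, in `[0, 1]`.
#' @param kappa Von Mises concentration, `kappa >= 0`.
#' @return The log likelihood (scalar, radian scale).
#' @export
loglik_mixture2 <- function(errors_deg, p_mem, kappa) {
  check_mixture_params(p_mem, 0, kappa)
  if (length(errors_deg) < 1) {
    stop("at least one error is required", call. = FALSE)
  }
  e <- errors_deg * DEG2RAD
  dens <- p_mem * dvonmises(e, 0, kappa) + (1 - p_mem) / (2 * pi)
  sum(log(dens))
}

#' Log likelihood of the three-parameter mixture model
#'
#' Extends the two-parameter mixture with swap responses: a set of von Mises
#' components centered on the other array items' features (binding errors),
#' sharing the concentration `kappa` of the target component. The nontarget
#' weight `p_nontarget` is divided equally across the `m` nontargets of each
#' observation, so the total swap mass is `p_nontarget` regardless of `m`.
#' The residual weight `1 - p_mem - p_nontarget` is uniform (guessing).
#'
#' @param observations A data frame with columns `response_deg`, `target_deg`
#'   and a list-column `nontargets_deg` holding the other array items'
#'   features in degrees (possibly empty). See [with_nontargets()].
#' @param p_mem,p_nontarget Mixture weights in `[0, 1]` with
#'   `p_mem + p_nontarget <= 1`.
#' @param kappa Shared von Mises concentration, `kappa >= 0`.
#' @return The log likelihood (scalar, radian scale).
#' @export
loglik_mixture3 <- function(observations, p_mem, p_nontarget, kappa) {
  check_mixture_params(p_mem, p_nontarget, kappa)
  stopifnot(is.data.frame(observations))
  need <- c("response_deg", "target_deg", "nontargets_deg")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(observations)
  if (n < 1) stop("at least one observation is required", call. = FALSE)
  m <- lengths(observations$nontargets_deg)
  if (p_nontarget > 0 && any(m == 0)) {
    stop("p_nontarget > 0 requires at least one nontarget per observation",
         call. = FALSE)
  }
  err <- angular_error(observations$response_deg,
                       observations$target_deg) * DEG2RAD
  dens <- p_mem * dvonmises(err, 0, kappa) +
    (1 - p_mem - p_nontarget) / (2 * pi)
  if (p_nontarget > 0) {
    nt_dens <- purrr::map2_dbl(
      observations$response_deg, observations$nontargets_deg,
      function(resp, nt) {
        mean(dvonmises(angular_error(resp, nt) * DEG2RAD, 0, kappa))
      }
    )
    dens <- dens + p_nontarget * nt_dens
  }
  sum(log(dens))
}

#' Attach nontarget features to a trial table
#'
#' For every response row, collects the true features of the *other* items in
#' the same trial into a list-column `nontargets_deg`, as required by the
#' three-parameter mixture and the hierarchical fits. Trials are identified
#' by `(experiment, participant, session, trial)` (whichever of these columns
#' are present).
#'
#' @param trials A trial table (see [read_trials()] for the schema).
#' @return `trials` with an added list-column `nontargets_deg`.
#' @export
with_nontargets <- function(trials) {
  stopifnot(is.data.frame(trials), "target_deg" %in% names(trials))
  keys <- intersect(c("experiment", "participant", "session", "set_size",
                      "trial"), names(trials))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(
      nontargets_deg = purrr::map(dplyr::row_number(),
                                  ~ .data$target_deg[-.x])
    ) |>
    dplyr::ungroup()
}
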