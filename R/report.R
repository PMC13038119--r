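# Report-level analyses: binned error distributions per design cell, the
# guess-flag (meta-cognition) split, and the orchestrating pipeline that
# runs every analysis stage on a trial table.

#' Binned error distributions per design cell
#'
#' Computes signed-error histograms for every
#' `(experiment, set_size, output_position)` cell, with symmetric bin edges
#' tiling `[-180, 180)` exactly. Cells without responses are absent from the
#' result.
#'
#' @param trials A trial table.
#' @param bins Number of bins (default 30).
#' @return A tibble: grouping keys, `bin_low`, `bin_high`, `bin_mid`,
#'   `count`.
#' @export
error_histograms <- function(trials, bins = 30) {
  stopifnot(is.data.frame(trials), bins >= 2)
  edges <- seq(-180, 180, length.out = bins + 1)
  keys <- intersect(c("experiment", "set_size", "output_position"),
                    names(trials))
  trials |>
    dplyr::mutate(error_deg = angular_error(.data$response_deg,
                                            .data$target_deg)) |>
    dplyr::mutate(bin = cut(.data$error_deg, breaks = edges,
                            right = FALSE, include.lowest = FALSE,
                            labels = FALSE)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$bin) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(keys)),
      bin = seq_len(bins), fill = list(count = 0L)
    ) |>
    dplyr::mutate(bin_low = edges[.data$bin],
                  bin_high = edges[.data$bin + 1],
                  bin_mid = (.data$bin_low + .data$bin_high) / 2) |>
    dplyr::select(dplyr::all_of(keys), "bin_low", "bin_high", "bin_mid",
                  "count")
}

#' Error distributions split by self-reported guessing
#'
#' Summarizes signed errors separately for self-reported memory-based
#' responses (`guess_flag = 0`) and self-reported guesses
#' (`guess_flag = 1`), per experiment and set size: trial counts, circular
#' resultant length (near 0 for a uniform distribution, 1 for a point mass)
#' and mean absolute error. Cells in which only one flag value occurs yield
#' a single row.
#'
#' @param trials A trial table with a `guess_flag` column.
#' @return A tibble: grouping keys, `guess_flag`, `n`, `resultant_length`,
#'   `mean_abs_error`.
#' @export
metacognition_split <- function(trials) {
  stopifnot(is.data.frame(trials), "guess_flag" %in% names(trials))
  keys <- intersect(c("experiment", "set_size"), names(trials))
  trials |>
    dplyr::mutate(error_deg = angular_error(.data$response_deg,
                                            .data$target_deg)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$guess_flag) |>
    dplyr::summarise(
      n = dplyr::n(),
      resultant_length = resultant_length(.data$error_deg),
      mean_abs_error = mean(abs(.data$error_deg)),
      .groups = "drop"
    )
}

#' Run the full analysis pipeline on a trial table
#'
#' Orchestrates the analysis stages in sequence: per-cell error histograms,
#' per-participant ML fits with BIC classification against the uniform
#' model, optional hierarchical population fits for selected cells, an
#' optional HDMM fit for the most diagnostic cell (by default the last
#' output position of the largest set size), and the guess-flag split.
#' Stage failures are caught per cell and recorded in the log without
#' aborting the remaining cells. Deterministic given `seed`.
#'
#' @param trials A trial table.
#' @param ml_set_sizes Set sizes for the participant-level ML stage.
#' @param hier_cells A data frame with columns `set_size`,
#'   `output_position` naming the cells for the hierarchical fit, or `NULL`
#'   to skip the stage.
#' @param hdmm_cell Length-2 vector `c(set_size, output_position)` for the
#'   HDMM stage, `"auto"` for the last output position of the largest set
#'   size, or `NULL` to skip.
#' @param chains,warmup,iter MCMC layout for the Bayesian stages.
#' @param bins Histogram bins.
#' @param seed Integer seed for the Bayesian stages.
#' @return An object of class `wm_report`: a list with elements
#'   `histograms`, `ml_fits`, `classification`, `hier_summaries`,
#'   `hdmm` (fit or `NULL`), `hdmm_diagnosis`, `metacognition`, `log`.
#' @export
run_pipeline <- function(trials, ml_set_sizes = c(4, 6),
                         hier_cells = NULL, hdmm_cell = "auto",
                         chains = 3, warmup = 2000, iter = 5000,
                         bins = 30, seed = 1) {
  validate_trials(trials)
  log_rows <- list()
  note <- function(stage, cell, status) {
    log_rows[[length(log_rows) + 1]] <<-
      tibble::tibble(stage = stage, cell = cell, status = status)
  }

  histograms <- error_histograms(trials, bins = bins)
  note("histograms", "all", "ok")

  ml_fits <- NULL
  classification <- NULL
  avail <- intersect(ml_set_sizes, unique(trials$set_size))
  if (length(avail) > 0) {
    ml_fits <- tryCatch(
      compare_to_uniform(fit_cells_ml(trials, set_sizes = avail)),
      error = function(e) {
        note("ml_fit", paste(avail, collapse = ","),
             conditionMessage(e))
        NULL
      }
    )
    if (!is.null(ml_fits)) {
      classification <- classification_table(ml_fits)
      note("ml_fit", paste("set sizes", paste(avail, collapse = ",")), "ok")
    }
  } else {
    note("ml_fit", "none", "no requested set sizes present")
  }

  hier_summaries <- NULL
  if (!is.null(hier_cells)) {
    hier_summaries <- purrr::pmap_dfr(
      hier_cells[c("set_size", "output_position")],
      function(set_size, output_position) {
        cell_id <- paste0("SS", set_size, "/OP", output_position)
        res <- tryCatch(
          {
            fit <- fit_hier3(trials, set_size = set_size,
                             output_position = output_position,
                             chains = chains, warmup = warmup, iter = iter,
                             seed = seed)
            note("hier", cell_id,
                 if (fit$converged) "ok" else "non-converged")
            dplyr::bind_cols(
              tibble::tibble(set_size = set_size,
                             output_position = output_position),
              summarize_population(fit)
            )
          },
          error = function(e) {
            note("hier", cell_id, conditionMessage(e))
            NULL
          }
        )
        res
      }
    )
  }

  hdmm_fit <- NULL
  hdmm_diag <- NULL
  if (!is.null(hdmm_cell)) {
    if (identical(hdmm_cell, "auto")) {
      ss <- max(trials$set_size)
      hdmm_cell <- c(ss, max(trials$output_position[trials$set_size == ss]))
    }
    cell_id <- paste0("SS", hdmm_cell[1], "/OP", hdmm_cell[2])
    hdmm_fit <- tryCatch(
      {
        fit <- fit_hdmm(trials, set_size = hdmm_cell[1],
                        output_position = hdmm_cell[2],
                        chains = chains, warmup = warmup, iter = iter,
                        seed = seed)
        note("hdmm", cell_id, if (fit$converged) "ok" else "non-converged")
        fit
      },
      error = function(e) {
        note("hdmm", cell_id, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(hdmm_fit)) {
      hdmm_diag <- guessing_diagnosis(hdmm_fit)
      if (!is.null(ml_fits)) {
        bic <- ml_fits |>
          dplyr::filter(.data$set_size == hdmm_cell[1],
                        .data$output_position == hdmm_cell[2]) |>
          dplyr::select("participant", "bic_difference")
        hdmm_diag <- dplyr::left_join(hdmm_diag, bic, by = "participant")
      }
    }
  }

  metacog <- metacognition_split(trials)
  note("metacognition", "all", "ok")

  structure(
    list(histograms = histograms, ml_fits = ml_fits,
         classification = classification,
         hier_summaries = hier_summaries,
         hdmm = hdmm_fit, hdmm_diagnosis = hdmm_diag,
         metacognition = metacog,
         log = dplyr::bind_rows(log_rows)),
    class = "wm_report"
  )
}

#' @export
print.wm_report <- function(x, ...) {
  cat("Whole-report analysis report\n")
  cat("  stages run:\n")
  print(x$log)
  if (!is.null(x$classification)) {
    cat("  zero-information classification counts:\n")
    print(x$classification)
  }
  invisible(x)
}

#' Plot per-cell error distributions
#'
#' Faceted histograms of signed errors by set size and output position, the
#' standard display for whole-report data.
#'
#' @param trials A trial table (or the output of [error_histograms()]).
#' @param bins Number of bins when `trials` is a raw table.
#' @return A ggplot object.
#' @export
plot_error_histograms <- function(trials, bins = 30) {
  h <- if ("bin_mid" %in% names(trials)) trials else
    error_histograms(trials, bins = bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(range(h$bin_low)) / max(1, bins)) +
    ggplot2::facet_grid(set_size ~ output_position,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "signed error (degrees)", y = "responses")
}
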