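# Trial-table I/O. The on-disk dialect is a plain CSV (UTF-8, comma
# separated) with one response event per row and columns: experiment,
# participant, session, trial, set_size, location, target_deg, response_deg,
# output_position, guess_flag. Angles are degrees on [0, 360); output
# positions form a permutation of 1..set_size within each trial.

TRIAL_COLUMNS <- c("experiment", "participant", "session", "trial",
                   "set_size", "location", "target_deg", "response_deg",
                   "output_position", "guess_flag")

#' Validate a trial table
#'
#' Checks the schema contract of the trial-table format: required columns,
#' angles in `[0, 360)`, binary guess flags, and output positions forming a
#' permutation of `1..set_size` within every trial. Violations are reported
#' with offending row numbers or trial identifiers.
#'
#' @param trials A data frame.
#' @return `trials`, invisibly, if valid; otherwise an error.
#' @export
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("target_deg", "response_deg")) {
    bad <- which(!is.finite(trials[[col]]) | trials[[col]] < 0 |
                   trials[[col]] >= 360)
    if (length(bad) > 0) {
      stop(col, " out of [0, 360) in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
    }
  }
  bad <- which(!trials$guess_flag %in% c(0, 1))
  if (length(bad) > 0) {
    stop("guess_flag must be 0 or 1; offending row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  perm_ok <- trials |>
    dplyr::group_by(.data$experiment, .data$participant, .data$session,
                    .data$trial, .data$set_size) |>
    dplyr::summarise(
      ok = dplyr::n() == .data$set_size[1] &&
        setequal(.data$output_position, seq_len(.data$set_size[1])),
      .groups = "drop"
    )
  if (any(!perm_ok$ok)) {
    bad_trials <- perm_ok |>
      dplyr::filter(!.data$ok) |>
      utils::head(5)
    stop("output positions are not a permutation of 1..set_size in ",
         sum(!perm_ok$ok), " trial(s), e.g. participant ",
         bad_trials$participant[1], ", session ", bad_trials$session[1],
         ", trial ", bad_trials$trial[1], call. = FALSE)
  }
  invisible(trials)
}

#' Read and write trial tables
#'
#' `read_trials()` reads and schema-validates a trial-table CSV;
#' `write_trials()` writes one. The round trip is lossless for the schema
#' columns.
#'
#' @param path File path.
#' @param trials A valid trial table.
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      experiment = readr::col_character(),
      participant = readr::col_integer(),
      session = readr::col_integer(),
      trial = readr::col_integer(),
      set_size = readr::col_integer(),
      location = readr::col_integer(),
      target_deg = readr::col_double(),
      response_deg = readr::col_double(),
      output_position = readr::col_integer(),
      guess_flag = readr::col_integer()
    )
  )
  validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials[TRIAL_COLUMNS], path)
  invisible(path)
}

#' Import a trial table with foreign column names
#'
#' Thin adapter for externally deposited data sets whose columns differ only
#' in naming: `mapping` gives the foreign name for each schema column (e.g.
#' `c(target_deg = "TargetColor")`). Unmapped schema columns must already be
#' present under their own names.
#'
#' @param path CSV file path.
#' @param mapping Named character vector, `schema_name = foreign_name`.
#' @return A validated trial table.
#' @export
import_trials <- function(path, mapping = character()) {
  raw <- readr::read_csv(path, col_types = readr::cols())
  for (nm in names(mapping)) {
    if (!mapping[[nm]] %in% names(raw)) {
      stop("mapped column '", mapping[[nm]], "' not found", call. = FALSE)
    }
    raw[[nm]] <- raw[[mapping[[nm]]]]
  }
  trials <- dplyr::select(raw, dplyr::all_of(TRIAL_COLUMNS))
  trials$participant <- as.integer(trials$participant)
  trials$session <- as.integer(trials$session)
  trials$trial <- as.integer(trials$trial)
  trials$set_size <- as.integer(trials$set_size)
  trials$location <- as.integer(trials$location)
  trials$output_position <- as.integer(trials$output_position)
  trials$guess_flag <- as.integer(trials$guess_flag)
  validate_trials(trials)
  tibble::as_tibble(trials)
}
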