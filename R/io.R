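#' Write trials to CSV
#'
#' One row per trial with the documented column set; a comment header line
#' records the configuration hash so outputs are traceable to the settings
#' that produced them.
#'
#' @param trials a trial tibble (schedule or completed).
#' @param path output file.
#' @param config_hash optional 8-hex-digit stamp (see [config_hash()]).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  }
  df <- as.data.frame(trials)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read trials from CSV
#'
#' Accepts the format written by [write_trials()]; also serves as the
#' loader for externally collected data in the same layout (columns:
#' `subject_id`, `experiment`, `block`, `trial_index`, `cue_type`,
#' `cue_symbol`, `soa_ms`, `target_present`, `target_side`,
#' `target_colour_deg`, `wheel_rotation_deg`, `response_colour_deg`,
#' `rt_ms`, `outcome`; `block == 0` marks practice).
#'
#' @param path CSV file, optionally with `#` comment headers.
#' @return tibble of trials.
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(
    path, comment = "#", na = c("", "NA"), show_col_types = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      experiment = readr::col_character(),
      block = readr::col_integer(),
      trial_index = readr::col_integer(),
      cue_type = readr::col_character(),
      cue_symbol = readr::col_character(),
      soa_ms = readr::col_integer(),
      target_present = readr::col_logical(),
      target_side = readr::col_character(),
      target_colour_deg = readr::col_double(),
      wheel_rotation_deg = readr::col_double(),
      response_colour_deg = readr::col_double(),
      rt_ms = readr::col_double(),
      outcome = readr::col_character()
    )
  )
  out
}

#' Hash a configuration for output stamping
#' @param config any list; hashed via its deparsed form.
#' @return 8 hex digits.
#' @export
config_hash <- function(config) {
  fnv1a32(paste(deparse(config), collapse = "\n"))
}

#' Round-trip raw wheel clicks
#'
#' Responses are stored as colour angles; a raw click position on a rotated
#' wheel is `click = colour + rotation (mod 360)`.  These helpers convert
#' between the two representations.
#'
#' @param colour_deg,click_deg,rotation_deg angles in degrees.
#' @return angle in \[0, 360).
#' @export
colour_to_click <- function(colour_deg, rotation_deg) {
  (colour_deg + rotation_deg) %% 360
}

#' @rdname colour_to_click
#' @export
click_to_colour <- function(click_deg, rotation_deg) {
  (click_deg - rotation_deg) %% 360
}
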