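#' Build one counterbalanced block of trials
#'
#' Constructs the complete factorial design for a single 60-trial block of
#' either experiment and returns it in a seeded random order.
#'
#' The endogenous design (`"E1"`) crosses 6 cue slots (4 valid + 1 invalid +
#' 1 neutral) with 2 target locations and 5 repetitions of which one is a
#' catch trial, giving 60 trials per block with 20% catch trials and 80%
#' validity among spatial-cue target trials.  The exogenous design (`"E2"`)
#' crosses 3 cue locations (left, right, neutral) with 2 target locations,
#' 2 SOAs (100 ms, 800 ms) and 4 target + 1 catch repetitions, again 60
#' trials.  Catch trials inherit the cue and SOA of their factorial cell but
#' present no target (`target_side = "none"`, no target colour).
#'
#' Target colours are drawn uniformly on \[0, 360) degrees per target trial,
#' and every trial gets an independent uniform wheel rotation.
#'
#' @param experiment `"E1"` (central symbolic cues, 800 ms SOA) or `"E2"`
#'   (peripheral flashes, 100/800 ms SOA).
#' @param seed integer seed controlling trial order, colours and rotations.
#' @param counterbalance_arm for E1 only: `"2_right"` (cue "2" indicates the
#'   right box, "5" the left) or `"2_left"` (the mirror mapping).
#' @param block integer block number stored on each trial (0 denotes
#'   practice).
#' @return A tibble of class `trial_schedule`, one row per trial, with design
#'   fields populated and response fields (`response_colour_deg`, `rt_ms`,
#'   `outcome`) set to `NA`.
#' @examples
#' blk <- build_block("E1", seed = 1)
#' nrow(blk)            # 60
#' table(blk$cue_type)  # valid 40, invalid 10, neutral 10
#' @export
build_block <- function(experiment, seed,
                        counterbalance_arm = c("2_right", "2_left"),
                        block = 1L) {
  experiment <- match.arg(experiment, c("E1", "E2"))
  counterbalance_arm <- match.arg(counterbalance_arm)

  if (experiment == "E1") {
    cells <- expand.grid(
      cue_slot = 1:6,                       # 1-4 valid, 5 invalid, 6 neutral
      cell_side = c("left", "right"),
      rep = 1:5,                            # rep 5 is the catch trial
      stringsAsFactors = FALSE
    )
    cue_type <- ifelse(cells$cue_slot <= 4, "valid",
                       ifelse(cells$cue_slot == 5, "invalid", "neutral"))
    # side the cue points at (for neutral cues there is none)
    cue_side <- ifelse(cue_type == "valid", cells$cell_side,
                       ifelse(cue_type == "invalid",
                              other_side(cells$cell_side), NA))
    cue_symbol <- ifelse(cue_type == "neutral", "H",
                         e1_symbol(cue_side, counterbalance_arm))
    soa <- rep(800L, nrow(cells))
  } else {
    cells <- expand.grid(
      cue_loc = c("left", "right", "neutral"),
      cell_side = c("left", "right"),
      soa = c(100L, 800L),
      rep = 1:5,
      stringsAsFactors = FALSE
    )
    cue_type <- ifelse(cells$cue_loc == "neutral", "neutral",
                       ifelse(cells$cue_loc == cells$cell_side,
                              "valid", "invalid"))
    cue_symbol <- paste0(cells$cue_loc, "-flash")
    soa <- cells$soa
  }

  is_catch <- cells$rep == 5L
  n <- nrow(cells)

  seeds <- child_seeds(seed, 2L)
  ord <- withr::with_seed(seeds[1], sample.int(n))

  sched <- tibble::tibble(
    experiment = experiment,
    block = as.integer(block),
    cue_type = cue_type,
    cue_symbol = cue_symbol,
    soa_ms = as.integer(soa),
    target_present = !is_catch,
    target_side = ifelse(is_catch, "none", cells$cell_side),
    target_colour_deg = NA_real_,
    wheel_rotation_deg = NA_real_,
    response_colour_deg = NA_real_,
    rt_ms = NA_real_,
    outcome = NA_character_
  )[ord, ]
  sched$trial_index <- seq_len(n)
  withr::with_seed(seeds[2], {
    sched$target_colour_deg[sched$target_present] <-
      stats::runif(sum(sched$target_present), 0, 360)
    sched$wheel_rotation_deg <- stats::runif(n, 0, 360)
  })
  new_trial_schedule(sched, counterbalance_arm)
}

other_side <- function(x) c(left = "right", right = "left")[x]

e1_symbol <- function(cue_side, arm) {
  # which digit points where depends on the counterbalance arm
  map <- if (arm == "2_right") c(right = "2", left = "5") else c(right = "5", left = "2")
  unname(map[cue_side])
}

new_trial_schedule <- function(df, counterbalance_arm = NA_character_) {
  df <- df[, c("experiment", "block", "trial_index", "cue_type", "cue_symbol",
               "soa_ms", "target_present", "target_side", "target_colour_deg",
               "wheel_rotation_deg", "response_colour_deg", "rt_ms", "outcome")]
  attr(df, "counterbalance_arm") <- counterbalance_arm
  class(df) <- c("trial_schedule", setdiff(class(df), "trial_schedule"))
  df
}

#' Build a full session of trials
#'
#' Assembles `n_blocks` independent test blocks (each built with
#' [build_block()]) and, optionally, a 30-trial practice block (block 0)
#' sampled without replacement from one additional full block.
#'
#' @inheritParams build_block
#' @param n_blocks number of 60-trial test blocks (7 in the endogenous
#'   experiment, 8 in the exogenous one).
#' @param practice if `TRUE`, prepend a practice block of 30 trials.
#' @return A `trial_schedule` tibble; practice trials carry `block == 0`.
#' @examples
#' sess <- build_session("E1", n_blocks = 7, practice = TRUE, seed = 42)
#' sum(sess$block > 0)   # 420 test trials
#' sum(sess$block == 0)  # 30 practice trials
#' @export
build_session <- function(experiment, n_blocks, practice = TRUE, seed = 1L,
                          counterbalance_arm = c("2_right", "2_left")) {
  stopifnot(n_blocks >= 1)
  counterbalance_arm <- match.arg(counterbalance_arm)
  seeds <- child_seeds(seed, n_blocks + 2L)

  blocks <- lapply(seq_len(n_blocks), function(b) {
    build_block(experiment, seed = seeds[b],
                counterbalance_arm = counterbalance_arm, block = b)
  })
  out <- dplyr::bind_rows(blocks)

  if (isTRUE(practice)) {
    full <- build_block(experiment, seed = seeds[n_blocks + 1L],
                        counterbalance_arm = counterbalance_arm, block = 0L)
    keep <- withr::with_seed(seeds[n_blocks + 2L], sample.int(nrow(full), 30L))
    out <- dplyr::bind_rows(full[sort(keep), ], out)
  }
  out$trial_index <- seq_len(nrow(out))
  new_trial_schedule(out, counterbalance_arm)
}

#' Tabulate a schedule by design cell
#'
#' Counts trials by cue type, target presence and SOA, with the catch-trial
#' fraction and (for spatial cues) the realised cue validity.
#'
#' @param schedule a `trial_schedule` or a tibble of trials.
#' @return A list with elements `counts` (tibble of cell counts),
#'   `catch_fraction`, and `spatial_validity` (proportion of spatial-cue
#'   target trials that are validly cued).
#' @export
design_tabulate <- function(schedule) {
  stopifnot(nrow(schedule) > 0)
  counts <- schedule |>
    dplyr::count(.data$cue_type, .data$target_present, .data$soa_ms,
                 name = "n") |>
    dplyr::arrange(.data$cue_type, .data$target_present, .data$soa_ms)
  spatial_target <- schedule$target_present & schedule$cue_type != "neutral"
  list(
    counts = counts,
    catch_fraction = mean(!schedule$target_present),
    spatial_validity = mean(schedule$cue_type[spatial_target] == "valid")
  )
}
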