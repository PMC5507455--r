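# File formats, pipeline orchestration, CLI.

TRAJ_COLS <- c("frame", "t", "head_x", "head_y", "mid_x", "mid_y",
               "tail_x", "tail_y", "cm_x", "cm_y")

#' Read a trajectory CSV
#'
#' One row per frame with columns `frame, t, head_x, head_y, mid_x,
#' mid_y, tail_x, tail_y, cm_x, cm_y` (header required, coordinates in
#' pixels). Image-coordinate input (y pointing down) is converted to the
#' Cartesian arena frame when `y_down = TRUE`.
#'
#' @param path CSV file.
#' @param frame_rate frames per second (default 60).
#' @param px_per_mm pixels per millimetre (default 11.94).
#' @param y_down TRUE when the input y axis points down (image
#'   coordinates).
#' @param max_gap_frames longest tolerated run of missing coordinates.
#' @return a [trajectory()].
#' @export
read_trajectory_csv <- function(path, frame_rate = 60, px_per_mm = 11.94,
                                y_down = FALSE, max_gap_frames = 3) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(TRAJ_COLS, "t"), names(df))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- setdiff(names(df), "frame")
  for (col in c("frame", intersect(num, TRAJ_COLS))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                   !is.na(df[[col]]))[1]
      stop(path, ": non-numeric value in column ", col,
           if (!is.na(bad)) paste0(" at row ", bad) else "")
    }
  }
  if (anyNA(df$frame) || any(diff(df$frame) <= 0)) {
    bad <- which(c(FALSE, diff(df$frame) <= 0) | is.na(df$frame))[1]
    stop(path, ": frame index not strictly increasing at row ", bad)
  }
  coord_cols <- setdiff(TRAJ_COLS, c("frame", "t"))
  for (col in coord_cols) {
    x <- df[[col]]
    if (anyNA(x) || any(!is.finite(x[!is.na(x)]))) {
      x[!is.finite(x)] <- NA
      r <- rle(is.na(x))
      if (any(r$values & r$lengths > max_gap_frames) ||
          is.na(x[1]) || is.na(x[length(x)])) {
        run <- which(r$values & r$lengths > max_gap_frames)[1]
        row <- if (is.na(run)) which(is.na(x))[1] else
          cumsum(r$lengths)[run] - r$lengths[run] + 1L
        stop(path, ": missing coordinates in ", col,
             " beyond the ", max_gap_frames, "-frame gap tolerance, row ",
             row)
      }
      df[[col]] <- x
    }
  }
  if (y_down) {
    for (col in grep("_y$", coord_cols, value = TRUE)) {
      df[[col]] <- -df[[col]]
    }
  }
  trajectory(df, frame_rate = frame_rate, px_per_mm = px_per_mm)
}

#' @rdname read_trajectory_csv
#' @param traj a [trajectory()] to write.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "larva_trajectory"))
  utils::write.csv(traj$frames[TRAJ_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Write a fixture to disk
#'
#' Writes one trajectory CSV per trial, the arena JSON, ground-truth
#' label CSVs (frame columns 0-based) and a fixture manifest.
#'
#' @param fixture a [make_fixture()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "larva_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(fixture$trials)) {
    write_trajectory_csv(fixture$trials[[id]],
                         file.path(dir, paste0("trial_", id, ".csv")))
  }
  write_arena_json(fixture$arena, file.path(dir, "arena.json"))
  to0 <- function(df, cols) {
    for (col in intersect(cols, names(df))) df[[col]] <- df[[col]] - 1L
    df
  }
  utils::write.csv(to0(fixture$truth$stops, c("start", "end")),
                   file.path(dir, "truth_stops.csv"), row.names = FALSE)
  utils::write.csv(to0(fixture$truth$casts, c("start", "peak", "end")),
                   file.path(dir, "truth_casts.csv"), row.names = FALSE)
  utils::write.csv(to0(fixture$truth$turns, "turn_peak"),
                   file.path(dir, "truth_turns.csv"), row.names = FALSE)
  utils::write.csv(fixture$truth$trials,
                   file.path(dir, "truth_trials.csv"), row.names = FALSE)
  jsonlite::write_json(list(fixture = fixture$name, seed = fixture$seed,
                            noise_sd = fixture$noise_sd,
                            frame_rate = fixture$frame_rate,
                            px_per_mm = fixture$px_per_mm,
                            n_trials = length(fixture$trials)),
                       file.path(dir, "fixture.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes kinematics, stop/cast segmentation, turn classification and
#' summary statistics over a set of trials, optionally writing the event
#' CSVs, summary JSON and run manifest. Output is a pure function of the
#' inputs and configuration. A failing trial is reported as a warning
#' (and recorded in the manifest); remaining trials are still processed.
#'
#' @param trials named list of [trajectory()] objects, or a directory
#'   containing `trial_*.csv` files.
#' @param arena a [light_spot()], or path to an arena JSON.
#' @param config a [cast_config()].
#' @param out_dir if non-NULL, write `events.csv`, `turns.csv`,
#'   `summary.json` and `manifest.json` there.
#' @param frame_rate,px_per_mm,y_down calibration used when `trials` is a
#'   directory of CSVs.
#' @return list with `stops`, `casts` (events), `turns`, `trials`
#'   (per-trial escape flags), `summary` (a [summarize_turns()] report)
#'   and `manifest`.
#' @export
run_pipeline <- function(trials, arena, config = cast_config(),
                         out_dir = NULL, frame_rate = 60,
                         px_per_mm = 11.94, y_down = FALSE) {
  inputs <- "in-memory trajectories"
  if (is.character(trials)) {
    dir <- trials
    paths <- sort(list.files(dir, pattern = "^trial_.*\\.csv$",
                             full.names = TRUE))
    inputs <- paths
    trials <- lapply(paths, read_trajectory_csv, frame_rate = frame_rate,
                     px_per_mm = px_per_mm, y_down = y_down,
                     max_gap_frames = config$max_gap_frames)
    names(trials) <- sub("^trial_(.*)\\.csv$", "\\1", basename(paths))
  }
  if (is.character(arena)) arena <- read_arena_json(arena)
  if (is.null(names(trials)) && length(trials) > 0) {
    names(trials) <- sprintf("t%02d", seq_along(trials))
  }

  stops <- list(); casts <- list(); turns <- list()
  escaped <- rep(NA, length(trials))
  warnings <- character()
  for (i in seq_along(trials)) {
    id <- names(trials)[i]
    res <- tryCatch(
      classify_trial(trials[[i]], arena, config, trial_id = id),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0("trial ", id, " failed: ", conditionMessage(res))
      warnings <- c(warnings, msg)
      warning(msg, call. = FALSE)
      next
    }
    stops[[i]] <- res$stops
    casts[[i]] <- res$casts
    turns[[i]] <- res$turns
    escaped[i] <- res$escaped
  }
  bind <- function(l) do.call(rbind, l[!vapply(l, is.null, logical(1))])
  stops <- bind(stops); casts <- bind(casts); turns <- bind(turns)
  if (is.null(stops)) stops <- data.frame(trial_id = character(),
                                          stop_id = integer(),
                                          start = integer(), end = integer())
  if (is.null(casts)) casts <- data.frame(trial_id = character(),
                                          stop_id = integer(),
                                          turn_id = integer(),
                                          ordinal = integer(),
                                          success = logical(),
                                          acceptance = character(),
                                          amplitude = numeric())
  if (is.null(turns)) turns <- data.frame(trial_id = character(),
                                          turn_id = integer(),
                                          stop_id = integer(),
                                          kind = character(),
                                          n_casts = integer(),
                                          light_related = logical(),
                                          success = logical())
  trials_df <- data.frame(trial_id = names(trials), escaped = escaped,
                          stringsAsFactors = FALSE)
  summary <- summarize_turns(turns, casts, trials_df)
  manifest <- list(
    package = "larvacast",
    version = as.character(utils::packageVersion("larvacast")),
    config = unclass(config),
    inputs = inputs,
    n_trials = length(trials),
    event_counts = list(stops = nrow(stops), casts = nrow(casts),
                        turns = nrow(turns),
                        light_related_turns =
                          sum(turns$light_related %in% TRUE)),
    warnings = warnings
  )
  out <- list(stops = stops, casts = casts, turns = turns,
              trials = trials_df, summary = summary, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    to0 <- function(df, cols) {
      for (col in intersect(cols, names(df))) df[[col]] <- df[[col]] - 1L
      df
    }
    utils::write.csv(to0(casts, c("start", "peak", "end")),
                     file.path(out_dir, "events.csv"), row.names = FALSE)
    utils::write.csv(to0(turns, c("stop_start", "turn_peak")),
                     file.path(out_dir, "turns.csv"), row.names = FALSE)
    jsonlite::write_json(summary_to_list(summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows", pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

cli_usage <- function() {
  cat("usage: larvacast <command> [options]\n",
      "commands:\n",
      "  analyze   --in DIR --arena FILE [--config FILE] --out DIR\n",
      "  simulate  --fixture NAME --seed INT [--noise SD] --out DIR\n",
      "  summarize --in DIR --out DIR\n",
      "  version\n", sep = "")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(args)) stop("flag ", a, " needs a value")
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `analyze` (run the pipeline over a directory of
#' trajectory CSVs), `simulate` (write a named fixture), `summarize`
#' (recompute the summary report from previously written event CSVs),
#' `version`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 on success, 2 on usage errors).
#' @export
larva_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { cli_usage(); return(2L) }
  cmd <- args[1]
  res <- tryCatch({
    flags <- parse_flags(args[-1])
    need <- function(nm) {
      if (is.null(flags[[nm]])) stop("missing required flag --", nm)
      flags[[nm]]
    }
    switch(cmd,
      version = {
        cat(as.character(utils::packageVersion("larvacast")), sep = "\n")
        0L
      },
      analyze = {
        config <- if (!is.null(flags$config)) read_config_json(flags$config)
                  else cast_config()
        run_pipeline(need("in"), need("arena"), config,
                     out_dir = need("out"))
        0L
      },
      simulate = {
        fix <- make_fixture(need("fixture"),
                            seed = as.integer(need("seed")),
                            noise_sd = if (is.null(flags$noise)) 0
                                       else as.numeric(flags$noise))
        write_fixture(fix, need("out"))
        0L
      },
      summarize = {
        indir <- need("in")
        casts <- utils::read.csv(file.path(indir, "events.csv"),
                                 stringsAsFactors = FALSE)
        turns <- utils::read.csv(file.path(indir, "turns.csv"),
                                 stringsAsFactors = FALSE)
        esc <- vapply(split(turns, turns$trial_id),
                      score_trial_escape, logical(1))
        trials <- data.frame(trial_id = names(esc), escaped = unname(esc),
                             stringsAsFactors = FALSE)
        summary <- summarize_turns(turns, casts, trials)
        dir.create(need("out"), showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(summary_to_list(summary),
                             file.path(need("out"), "summary.json"),
                             auto_unbox = TRUE, digits = NA, na = "null",
                             dataframe = "rows", pretty = TRUE)
        0L
      },
      { cli_usage(); 2L }
    )
  }, error = function(e) {
    message("larvacast: ", conditionMessage(e))
    1L
  })
  res
}
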