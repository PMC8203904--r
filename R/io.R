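# File formats: ratings CSV, RGPD JSON, gaze/event JSONL, session-config
# YAML, trajectory and score CSV exports, and an adapter for real
# eye-tracker fixation exports.

#' Read and write gesture-rating CSV files
#'
#' Columns: `rater_id`, `gesture_id`, `rating` (1-7), `total_time_s`,
#' `trap_correct`.
#'
#' @param path File path.
#' @return `read_ratings()` returns the validated record data frame.
#' @export
read_ratings <- function(path) {
  validate_rating_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ratings
#' @param records Rating record data frame.
#' @export
write_ratings <- function(records, path) {
  utils::write.csv(validate_rating_records(records), path, row.names = FALSE)
  invisible(path)
}

#' Write an RGPD (with its gesture models) to JSON
#'
#' Serializes the valence grid, the per-gesture perception models (p(v),
#' valence A, ambiguity H, rating count) and the p(g | m) likelihood
#' table. Values are stored as decimal strings with 12 significant
#' digits, so write -> read -> write reproduces the file byte-exactly.
#'
#' @param rgpd An [rgpd_database()].
#' @param path Output path.
#' @param models Optional list of the retained [gesture_model()]s.
#' @export
write_rgpd <- function(rgpd, path, models = NULL) {
  s12 <- function(x) signif(x, 12)
  # derive the valence grid from the rounded levels so that a
  # write -> read -> write cycle reproduces the same decimal strings
  payload <- list(
    valence_grid = s12(relationship_to_valence(s12(rgpd$levels))),
    relationship_levels = s12(rgpd$levels),
    gesture_ids = rgpd$gesture_ids,
    likelihood = apply(unname(rgpd$likelihood), 1, s12, simplify = FALSE)
  )
  if (!is.null(models)) {
    payload$gestures <- lapply(models, function(m) {
      list(gesture_id = m$gesture_id, p_v = s12(m$p_v),
           valence = s12(m$valence), ambiguity = s12(m$ambiguity),
           n_ratings = m$n_ratings)
    })
    names(payload$gestures) <- NULL
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rgpd
#' @return `read_rgpd()` returns a list with `rgpd` and (if stored)
#'   `models`.
#' @export
read_rgpd <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  ids <- as.integer(num(raw$gesture_ids))
  lik <- do.call(rbind, lapply(raw$likelihood, num))
  db <- rgpd_database(lik, num(raw$relationship_levels), ids)
  models <- NULL
  if (!is.null(raw$gestures)) {
    models <- lapply(raw$gestures, function(g) {
      structure(list(gesture_id = as.integer(g$gesture_id),
                     p_v = num(g$p_v),
                     valence = as.numeric(g$valence),
                     ambiguity = as.numeric(g$ambiguity),
                     n_ratings = as.integer(g$n_ratings)),
                class = "gesture_model")
    })
    names(models) <- vapply(models, function(m) as.character(m$gesture_id),
                            character(1))
  }
  list(rgpd = db, models = models)
}

#' Read and write newline-delimited JSON logs
#'
#' One JSON object per line; used for frame-level gaze logs (`t`, `round`,
#' `turn`, `x`, `f`) and gesture-event streams.
#'
#' @param df Data frame to write.
#' @param path File path.
#' @export
write_jsonl <- function(df, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  jsonlite::stream_in(con, verbose = FALSE)
}

#' Read a session configuration from YAML
#'
#' Keys mirror [session_config()]; per-round matrices are given as
#' 9-value off-diagonal vectors in the [relationship_matrix()] cell order.
#'
#' @param path YAML file path.
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("n_rounds", "turns_per_round", "human_turn_slots",
                          "initial_main", "frame_rate", "gesture_window_s",
                          "human_turn_delay_s"))]
  if (!is.null(raw$matrices)) {
    args$matrices <- lapply(raw$matrices, function(v) {
      relationship_matrix(as.numeric(v))
    })
  }
  do.call(session_config, args)
}

#' @rdname read_session_config
#' @param config A [session_config()].
#' @export
write_session_config <- function(config, path) {
  payload <- list(
    n_rounds = config$n_rounds,
    turns_per_round = config$turns_per_round,
    human_turn_slots = config$human_turn_slots,
    initial_main = config$initial_main,
    frame_rate = config$frame_rate,
    gesture_window_s = config$gesture_window_s,
    human_turn_delay_s = config$human_turn_delay_s,
    matrices = lapply(config$matrices, function(m) {
      as.numeric(m[cbind(.cell_rows, .cell_cols)])
    })
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Export a belief trajectory as CSV
#'
#' One row per tracked update: `round`, `t`, then the 12 expectation-matrix
#' cells row-major (`m11..m34`; the diagonal cells are identically 0).
#'
#' @param traj A `belief_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  cells <- expand.grid(k = 1:4, j = 1:3)[, 2:1]
  header <- paste0("m", cells$j, cells$k)
  rows <- t(vapply(traj$matrices, function(m) as.numeric(t(m)),
                   numeric(12)))
  colnames(rows) <- header
  out <- cbind(traj$meta[, c("round", "t")], as.data.frame(rows))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export per-round scores as CSV
#'
#' One row per participant and round: behavioral error, learning score,
#' the four answers (0 = "I don't know") and their correctness.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param rgpd The gesture database.
#' @param path Output path.
#' @return Invisibly, the exported data frame.
#' @export
write_scores_csv <- function(cohort, rgpd, path) {
  rows <- list()
  for (i in seq_along(cohort$sessions)) {
    sc <- score_session(cohort$sessions[[i]], rgpd)
    pid <- cohort$participants$participant_id[i]
    for (s in seq_along(sc$BE)) {
      key <- paste0("round", s)
      ans <- sc$answers[[key]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, round = s, BE = unname(sc$BE[s]),
        L = if (key %in% names(sc$answers)) unname(sc$L[paste0("L", s)]) else NA_integer_,
        a1 = if (is.null(ans)) NA else ans$belief[1],
        a2 = if (is.null(ans)) NA else ans$belief[2],
        a3 = if (is.null(ans)) NA else ans$belief[3],
        a4 = if (is.null(ans)) NA else ans$belief[4],
        correct1 = if (is.null(ans)) NA else ans$truth[1] != 0 & ans$belief[1] == ans$truth[1],
        correct2 = if (is.null(ans)) NA else ans$truth[2] != 0 & ans$belief[2] == ans$truth[2],
        correct3 = if (is.null(ans)) NA else ans$truth[3] != 0 & ans$belief[3] == ans$truth[3],
        correct4 = if (is.null(ans)) NA else ans$truth[4] != 0 & ans$belief[4] == ans$truth[4])
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Convert a real fixation export to the gaze-log format
#'
#' Maps an eye-tracker surface export (`time`, `surface`, `on_surface`) to
#' the frame-level gaze format: `x` is the robot whose surface was fixated
#' (NA off-surface), and the informative flag is filled in against the
#' event stream with [flag_informative()].
#'
#' @param df Data frame with columns `time`, `surface`, `on_surface`.
#' @param surface_map Named integer vector mapping surface ids to robots.
#' @param rounds Optional vector assigning each sample a round (and
#'   `turns` a turn); defaults to NA.
#' @param turns See `rounds`.
#' @return Gaze data frame (`t`, `round`, `turn`, `x`, `f = NA`).
#' @export
convert_fixation_export <- function(df, surface_map, rounds = NA_integer_,
                                    turns = NA_integer_) {
  x <- unname(surface_map[as.character(df$surface)])
  x[!df$on_surface] <- NA_integer_
  data.frame(t = df$time, round = rounds, turn = turns,
             x = as.integer(x), f = NA)
}

#' @rdname convert_fixation_export
#' @param gaze Gaze data frame with columns `t`, `round`, `x`.
#' @param events Gesture-event stream.
#' @return The gaze frame with `f` set: `TRUE` where the gazed robot is
#'   performing an informative gesture at that instant.
#' @export
flag_informative <- function(gaze, events) {
  info <- events[events$informative, , drop = FALSE]
  gaze$f <- vapply(seq_len(nrow(gaze)), function(i) {
    !is.na(gaze$x[i]) && any(info$round == gaze$round[i] &
                               info$actor == gaze$x[i] &
                               info$t_start <= gaze$t[i] &
                               gaze$t[i] < info$t_end)
  }, logical(1))
  gaze
}
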