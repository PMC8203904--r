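# Belief over the relationship matrix: one discrete distribution per
# off-diagonal cell, all on the RGPD's relationship-level grid.

belief_cells <- function() {
  data.frame(j = .cell_rows, k = .cell_cols)
}

.belief_colnames <- paste0("m", .cell_rows, .cell_cols)

cell_index <- function(j, k) {
  i <- which(.cell_rows == j & .cell_cols == k)
  if (length(i) != 1) {
    stop(sprintf("(%d,%d) is not a relationship-matrix cell", j, k),
         call. = FALSE)
  }
  i
}

#' Initialize a uniform belief over the relationship matrix
#'
#' One discrete probability distribution per off-diagonal matrix cell
#' (robot -> robot and robot -> participant), each starting uniform over
#' the relationship levels.
#'
#' @param levels Ascending relationship levels (typically `rgpd$levels`).
#' @return Object of class `belief`: fields `levels`, `p` (levels x 9 cells,
#'   columns in row-major off-diagonal order), `t` (updates so far).
#' @export
init_belief <- function(levels) {
  if (length(levels) == 0) {
    stop("empty relationship grid", call. = FALSE)
  }
  k <- length(levels)
  p <- matrix(1 / k, k, 9, dimnames = list(NULL, .belief_colnames))
  structure(list(levels = as.numeric(levels), p = p, t = 0L),
            class = "belief")
}

#' @export
print.belief <- function(x, ...) {
  cat(sprintf("<belief>  %d levels x 9 cells, %d update(s)\n",
              length(x$levels), x$t))
  print(round(expectation_matrix(x), 3))
  invisible(x)
}

#' Bayes update of one belief cell from an observed gesture
#'
#' Multiplies the cell's prior by the gesture likelihood \eqn{p(g \mid v)}
#' from the RGPD and renormalizes: \eqn{p_{jk}(v \mid g) \propto
#' p_{jk}(v)\,p(g \mid v)}. All other cells are untouched.
#'
#' @param belief A [init_belief()] object.
#' @param j,k Cell coordinates (actor row, target column).
#' @param gesture_id Observed gesture.
#' @param rgpd The [rgpd_database()] the gesture was drawn from.
#' @return The updated belief (update counter incremented).
#' @export
update_belief <- function(belief, j, k, gesture_id, rgpd) {
  idx <- cell_index(j, k)
  lik <- rgpd_gesture_likelihood(rgpd, gesture_id)
  if (length(lik) != length(belief$levels)) {
    stop("RGPD grid does not match belief grid", call. = FALSE)
  }
  post <- belief$p[, idx] * lik
  z <- sum(post)
  if (z <= 0) {
    stop(sprintf("impossible observation: gesture %d has zero likelihood under belief cell (%d,%d)",
                 gesture_id, j, k), call. = FALSE)
  }
  belief$p[, idx] <- post / z
  belief$t <- belief$t + 1L
  belief
}

#' Expectation matrix of a belief
#'
#' The per-cell expected relationship value \eqn{\tilde M_{jk} =
#' \sum_v v\, p_{jk}(v)}, with the diagonal identically zero.
#'
#' @param belief A belief object.
#' @return A 3x4 [relationship_matrix()].
#' @export
expectation_matrix <- function(belief) {
  m <- .rm_template
  m[.cell_linear] <- as.numeric(crossprod(belief$p, belief$levels))
  m
}

# Shannon entropy in bits, 0 log 0 := 0.
shannon_entropy <- function(p) {
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

# Expected reduction in Shannon entropy of cell (j,k) from observing one
# gesture drawn under the belief's predictive distribution. Uses the
# identity E_g[H(post_g)] = H(joint p(g,v)) - H(marginal p(g)).
expected_info_gain <- function(belief, j, k, rgpd) {
  idx <- cell_index(j, k)
  prior <- belief$p[, idx]
  joint <- rgpd$likelihood * rep(prior, each = nrow(rgpd$likelihood))
  pg <- rowSums(joint)
  eh <- shannon_entropy(as.numeric(joint)) - shannon_entropy(pg)
  shannon_entropy(prior) - eh
}

#' Belief trajectory from a gaze log and gesture events
#'
#' Replays a round-segmented gaze log against the gesture-event stream:
#' an informative gesture counts as observed when the accumulated gaze on
#' its actor during its window exceeds half the window, each observation
#' triggers one Bayes update of the corresponding cell, and the belief
#' resets to uniform at every round boundary (each round uses a fresh
#' relationship matrix). The expectation matrix is recorded after every
#' update.
#'
#' Before replaying, the log is audited: every `f = TRUE` sample must fall
#' inside an informative gesture window of the robot it gazes at.
#'
#' @param gaze Frame-level gaze log: data frame with columns `t`, `round`,
#'   `turn`, `x` (gazed robot 1-3 or `NA`), `f` (informative flag).
#' @param events Gesture events: data frame with columns `round`, `turn`,
#'   `actor`, `target`, `gesture_id`, `t_start`, `t_end`, `informative`.
#' @param rgpd The [rgpd_database()] used in the session.
#' @param frame_rate Gaze sampling rate in Hz (default 30).
#' @return Object of class `belief_trajectory`: `meta` (data frame with
#'   `round`, `turn`, `t` update index, `actor`, `target`, `gesture_id`),
#'   `matrices` (list of expectation matrices, one per update) and
#'   `round_beliefs` (end-of-round belief per round).
#' @export
belief_trajectory <- function(gaze, events, rgpd, frame_rate = 30) {
  audit_gaze_flags(gaze, events)
  rounds <- sort(unique(events$round))
  meta <- list()
  mats <- list()
  round_beliefs <- list()
  for (s in rounds) {
    belief <- init_belief(rgpd$levels)
    ev <- events[events$round == s & events$informative, , drop = FALSE]
    ev <- ev[order(ev$t_start, ev$actor), , drop = FALSE]
    gz <- gaze[gaze$round == s, , drop = FALSE]
    t_idx <- 0L
    for (i in seq_len(nrow(ev))) {
      window <- ev$t_end[i] - ev$t_start[i]
      n_on <- sum(!is.na(gz$x) & gz$x == ev$actor[i] &
                    gz$t >= ev$t_start[i] & gz$t < ev$t_end[i])
      if (n_on / frame_rate > window / 2) {
        belief <- update_belief(belief, ev$actor[i], ev$target[i],
                                ev$gesture_id[i], rgpd)
        t_idx <- t_idx + 1L
        meta[[length(meta) + 1L]] <-
          data.frame(round = s, turn = ev$turn[i], t = t_idx,
                     actor = ev$actor[i], target = ev$target[i],
                     gesture_id = ev$gesture_id[i])
        mats[[length(mats) + 1L]] <- expectation_matrix(belief)
      }
    }
    round_beliefs[[as.character(s)]] <- belief
  }
  new_belief_trajectory(meta, mats, round_beliefs)
}

new_belief_trajectory <- function(meta, mats, round_beliefs) {
  meta_df <- if (length(meta)) {
    do.call(rbind, meta)
  } else {
    data.frame(round = integer(), turn = integer(), t = integer(),
               actor = integer(), target = integer(), gesture_id = integer())
  }
  structure(list(meta = meta_df, matrices = mats,
                 round_beliefs = round_beliefs),
            class = "belief_trajectory")
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat(sprintf("<belief_trajectory>  %d update(s) over %d round(s)\n",
              nrow(x$meta), length(x$round_beliefs)))
  invisible(x)
}

# Every f = TRUE sample must lie inside an informative window of its robot.
audit_gaze_flags <- function(gaze, events) {
  flagged <- which(gaze$f)
  if (length(flagged) == 0) {
    return(invisible(TRUE))
  }
  info <- events[events$informative, , drop = FALSE]
  for (i in flagged) {
    ok <- any(info$round == gaze$round[i] &
                info$actor == gaze$x[i] &
                info$t_start <= gaze$t[i] &
                gaze$t[i] < info$t_end)
    if (is.na(ok) || !ok) {
      stop(sprintf("inconsistent gaze log: sample %d (t = %.3f, round %d) is flagged informative but no informative gesture of robot %s covers it",
                   i, gaze$t[i], gaze$round[i], as.character(gaze$x[i])),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Oracle belief from the full event stream
#'
#' Updates a fresh belief with *every* informative gesture of each round,
#' bypassing gaze scarcity — the fully informed observer used as an upper
#' reference for the learning score.
#'
#' @inheritParams belief_trajectory
#' @return A `belief_trajectory` object.
#' @export
belief_from_events <- function(events, rgpd) {
  rounds <- sort(unique(events$round))
  meta <- list()
  mats <- list()
  round_beliefs <- list()
  for (s in rounds) {
    belief <- init_belief(rgpd$levels)
    ev <- events[events$round == s & events$informative, , drop = FALSE]
    ev <- ev[order(ev$t_start, ev$actor), , drop = FALSE]
    t_idx <- 0L
    for (i in seq_len(nrow(ev))) {
      belief <- update_belief(belief, ev$actor[i], ev$target[i],
                              ev$gesture_id[i], rgpd)
      t_idx <- t_idx + 1L
      meta[[length(meta) + 1L]] <-
        data.frame(round = s, turn = ev$turn[i], t = t_idx,
                   actor = ev$actor[i], target = ev$target[i],
                   gesture_id = ev$gesture_id[i])
      mats[[length(mats) + 1L]] <- expectation_matrix(belief)
    }
    round_beliefs[[as.character(s)]] <- belief
  }
  new_belief_trajectory(meta, mats, round_beliefs)
}
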