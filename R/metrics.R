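#' Distance between two relationship matrices
#'
#' The mean absolute cell difference with the fixed denominator 12 (all
#' matrix cells, including the identically-zero diagonal):
#' \eqn{d(M^{(1)}, M^{(2)}) = \sum_{j,k} |M^{(1)}_{jk} - M^{(2)}_{jk}| / 12}.
#'
#' @param m1,m2 3x4 relationship matrices with zero diagonals.
#' @return Non-negative scalar; 0 iff the matrices are equal.
#' @export
matrix_distance <- function(m1, m2) {
  validate_relationship_matrix(m1)
  validate_relationship_matrix(m2)
  sum(abs(m1 - m2)) / 12
}

#' Greedy global-optimal observer trajectory
#'
#' Replays a round's full gesture-event stream (everything that occurred,
#' regardless of what the participant saw) with an agent that at every
#' choice point — each simultaneous window of informative gestures —
#' observes the emitter maximizing the expected entropy reduction of its
#' own belief cell (ties to the lowest robot index). This defines the
#' optimality reference against which behavioral error is measured. The
#' replay is deterministic.
#'
#' @param events Gesture-event data frame (see [simulate_session()]).
#' @param rgpd The session's gesture database.
#' @return A `belief_trajectory` object with one update per choice point.
#' @export
greedy_optimal_trajectory <- function(events, rgpd) {
  info <- events[events$informative, , drop = FALSE]
  info <- info[order(info$round, info$t_start, info$actor), , drop = FALSE]
  n <- nrow(info)
  meta <- list(round = integer(n), turn = integer(n), t = integer(n),
               actor = integer(n), target = integer(n),
               gesture_id = integer(n))
  mats <- vector("list", n)
  nm <- 0L
  round_beliefs <- list()
  for (s in sort(unique(events$round))) {
    belief <- init_belief(rgpd$levels)
    sel <- which(info$round == s)
    t_idx <- 0L
    for (t0 in unique(info$t_start[sel])) {
      grp <- sel[info$t_start[sel] == t0]
      pick <- greedy_info_choice(belief, info$actor[grp],
                                 cbind(info$actor[grp], info$target[grp]),
                                 rgpd)
      i <- grp[match(pick, info$actor[grp])]
      belief <- update_belief(belief, info$actor[i], info$target[i],
                              info$gesture_id[i], rgpd)
      t_idx <- t_idx + 1L
      nm <- nm + 1L
      meta$round[nm] <- s; meta$turn[nm] <- info$turn[i]; meta$t[nm] <- t_idx
      meta$actor[nm] <- info$actor[i]; meta$target[nm] <- info$target[i]
      meta$gesture_id[nm] <- info$gesture_id[i]
      mats[[nm]] <- expectation_matrix(belief)
    }
    round_beliefs[[as.character(s)]] <- belief
  }
  structure(list(meta = as.data.frame(lapply(meta, `[`, seq_len(nm))),
                 matrices = mats[seq_len(nm)],
                 round_beliefs = round_beliefs),
            class = "belief_trajectory")
}

#' Behavioral error of a trajectory against the optimal reference
#'
#' The time-averaged matrix distance between a participant's
#' expectation-matrix trajectory and the greedy global-optimal agent's
#' trajectory over the round's tracked-gaze timeline \eqn{t = 1..T}:
#' \eqn{BE = (1/T) \sum_t d(\tilde M^t, M_{global}^t)}. Lower values mean
#' gaze closer to optimal information gathering; an observer that misses
#' informative gestures keeps a stale expectation and accrues distance at
#' every later point.
#'
#' @param participant_mats,optimal_mats Equal-length lists of expectation
#'   matrices, already aligned in time (see [score_session()] for the
#'   choice-point alignment).
#' @return Non-negative scalar; `NA` on an empty timeline.
#' @export
behavioral_error <- function(participant_mats, optimal_mats) {
  if (length(participant_mats) != length(optimal_mats)) {
    stop("trajectories must be aligned to equal length", call. = FALSE)
  }
  if (length(participant_mats) == 0) {
    return(NA_real_)
  }
  mean(vapply(seq_along(participant_mats), function(t) {
    matrix_distance(participant_mats[[t]], optimal_mats[[t]])
  }, numeric(1)))
}

# Align both trajectories on the round's full choice-point timeline (one
# informative-gesture window per turn, t = 1..T from the first gaze). The
# participant's expectation matrix is a step function of its own updates:
# uniform before the first observation, then the latest update; the
# optimal agent updates at every point. A participant who observes
# nothing is compared as the constant uniform expectation.
align_optimal <- function(participant_traj, optimal_traj, round, levels) {
  om <- optimal_traj$meta
  o_sel <- which(om$round == round)
  o_turns <- om$turn[o_sel]
  pm <- participant_traj$meta
  p_sel <- which(pm$round == round)
  p_turns <- pm$turn[p_sel]
  uniform <- expectation_matrix(init_belief(levels))
  step <- findInterval(o_turns, p_turns)
  p_mats <- lapply(step, function(k) {
    if (k == 0) uniform else participant_traj$matrices[[p_sel[k]]]
  })
  list(participant = p_mats, optimal = optimal_traj$matrices[o_sel])
}

#' Answer the four end-of-round questions from a matrix
#'
#' Q1/Q2: which robot received the most positive / most negative attitude
#' from the other robots (argmax/argmin of [aggregated_attitude()]);
#' Q3/Q4: which robot holds the most positive / most negative attitude
#' toward the participant (argmax/argmin of column 4). Any tie within
#' tolerance yields "I don't know" (coded 0).
#'
#' @param m A relationship matrix (ground truth or a belief expectation).
#' @param tol Tie tolerance.
#' @return Integer vector of length 4; robot index 1-3, or 0 for
#'   "I don't know".
#' @export
answer_questions <- function(m, tol = 1e-9) {
  validate_relationship_matrix(m)
  agg <- aggregated_attitude(m)
  pick <- function(v, dir) {
    target <- if (dir > 0) max(v) else min(v)
    hit <- which(abs(v - target) <= tol)
    if (length(hit) == 1) unname(hit) else 0L
  }
  c(q1 = pick(agg, 1), q2 = pick(agg, -1),
    q3 = pick(m[, 4], 1), q4 = pick(m[, 4], -1))
}

#' Learning score of one round
#'
#' The number of the four questions answered the same as the truth, where
#' the truth answer names a robot; "I don't know" (0) never scores, on
#' either side.
#'
#' @param belief_answers,truth_answers Integer vectors of 4 answers (see
#'   [answer_questions()]).
#' @return Integer 0-4.
#' @export
learning_score <- function(belief_answers, truth_answers) {
  if (length(belief_answers) != 4 || length(truth_answers) != 4) {
    stop("four answers required on each side", call. = FALSE)
  }
  sum(truth_answers != 0L & belief_answers == truth_answers)
}

#' Expected learning score of a random guesser
#'
#' @param include_dont_know If `FALSE` (default), the guesser picks
#'   uniformly among the three robots per question (expected L = 4/3); if
#'   `TRUE`, "I don't know" is a fourth equiprobable option (expected
#'   L = 1).
#' @return Scalar chance level for one round.
#' @export
chance_level <- function(include_dont_know = FALSE) {
  if (include_dont_know) 1 else 4 / 3
}

#' Score a simulated session: per-round BE and L
#'
#' Computes the behavioral error of every round — the distance from the
#' greedy global-optimal replay of the same event stream, averaged over
#' the round's choice points, with the participant's expectation held
#' between its own observations — and, for the five question rounds, the
#' learning score of the end-of-round belief against the round's true
#' matrix.
#'
#' @param session A [simulate_session()] result.
#' @param rgpd The session's gesture database.
#' @param question_rounds Rounds followed by the four questions
#'   (default 1-5; the free last round has none).
#' @return List with `BE` (one value per round), `L` (named by question
#'   round), and `answers` (per question round: belief and truth answers).
#' @export
score_session <- function(session, rgpd,
                          question_rounds = seq_len(min(5, session$config$n_rounds))) {
  opt <- greedy_optimal_trajectory(session$events, rgpd)
  n_rounds <- session$config$n_rounds
  be <- rep(NA_real_, n_rounds)
  for (s in seq_len(n_rounds)) {
    al <- align_optimal(session$trajectory, opt, s, rgpd$levels)
    be[s] <- behavioral_error(al$participant, al$optimal)
  }
  names(be) <- paste0("BE", seq_len(n_rounds))
  l <- integer(0)
  answers <- list()
  for (s in question_rounds) {
    truth <- answer_questions(session$config$matrices[[s]])
    guess <- answer_questions(
      expectation_matrix(session$round_beliefs[[as.character(s)]]))
    l[paste0("L", s)] <- learning_score(guess, truth)
    answers[[paste0("round", s)]] <- list(belief = guess, truth = truth)
  }
  list(BE = be, L = l, answers = answers)
}
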