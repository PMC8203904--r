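#' Session configuration
#'
#' Describes the interaction protocol: six rounds by default, the first a
#' taskless round of 4 turns with the human turn third, rounds 2-5 with 8
#' turns and one or two preselected human-turn slots, and a final
#' open-ended round (8 turns here). Each round uses its own relationship
#' matrix. Robots gesture in windows of `gesture_window_s` seconds; the two
#' responder gestures of a turn overlap in time, so a gazer can observe at
#' most one of them — this scarcity is what makes gaze choice informative.
#'
#' @param n_rounds Number of rounds.
#' @param turns_per_round Integer vector of turns per round.
#' @param human_turn_slots List (one element per round) of turn indices at
#'   which all three robots address the participant.
#' @param matrices List of [relationship_matrix()], one per round; defaults
#'   to the six [study_matrices()].
#' @param initial_main Main robot of each round's first turn (recycled).
#' @param frame_rate Gaze sampling rate, Hz.
#' @param gesture_window_s Length of one gesture window, seconds.
#' @param human_turn_delay_s Pause before the robots address the
#'   participant in a human turn, seconds.
#' @return Object of class `session_config`.
#' @export
session_config <- function(n_rounds = 6,
                           turns_per_round = c(4, 8, 8, 8, 8, 8),
                           human_turn_slots = list(3, 4, c(3, 6), 4, c(3, 6),
                                                   integer(0)),
                           matrices = NULL,
                           initial_main = 1,
                           frame_rate = 30,
                           gesture_window_s = 4,
                           human_turn_delay_s = 5) {
  if (length(turns_per_round) != n_rounds) {
    stop("turns_per_round must have one entry per round", call. = FALSE)
  }
  if (length(human_turn_slots) != n_rounds) {
    stop("human_turn_slots must have one entry per round", call. = FALSE)
  }
  if (is.null(matrices)) {
    matrices <- study_matrices()
    matrices <- matrices[rep_len(seq_along(matrices), n_rounds)]
  }
  if (length(matrices) != n_rounds) {
    stop("need one relationship matrix per round", call. = FALSE)
  }
  lapply(matrices, validate_relationship_matrix)
  if (frame_rate <= 0) {
    stop("frame_rate must be positive", call. = FALSE)
  }
  structure(
    list(n_rounds = as.integer(n_rounds),
         turns_per_round = as.integer(turns_per_round),
         human_turn_slots = lapply(human_turn_slots, as.integer),
         matrices = matrices,
         initial_main = as.integer(rep_len(initial_main, n_rounds)),
         frame_rate = frame_rate,
         gesture_window_s = gesture_window_s,
         human_turn_delay_s = human_turn_delay_s),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config>  %d rounds, turns: %s\n",
              x$n_rounds, paste(x$turns_per_round, collapse = " ")))
  invisible(x)
}

#' Plan the turn schedule of a session
#'
#' Expands a [session_config()] into one row per turn with its type:
#' `initial` (preselected main robot), `human` (all robots address the
#' participant) or `dynamic` (main robot chosen by the participant's gaze
#' in the previous turn).
#'
#' @param config A [session_config()].
#' @return Data frame with columns `round`, `turn`, `type`.
#' @export
plan_session <- function(config) {
  if (config$n_rounds == 0) {
    return(data.frame(round = integer(), turn = integer(),
                      type = character()))
  }
  out <- vector("list", config$n_rounds)
  for (s in seq_len(config$n_rounds)) {
    n_turns <- config$turns_per_round[s]
    slots <- config$human_turn_slots[[s]]
    if (any(slots < 1 | slots > n_turns)) {
      stop(sprintf("round %d: human turn slot out of range 1..%d", s, n_turns),
           call. = FALSE)
    }
    type <- rep("dynamic", n_turns)
    if (n_turns >= 1) {
      type[1] <- "initial"
    }
    type[slots] <- "human"
    out[[s]] <- data.frame(round = s, turn = seq_len(n_turns), type = type)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gaze agent policy
#'
#' A stochastic gaze policy for the informative phase of each turn. With
#' probability `rho` (stickiness) the agent re-fixates its previous gaze
#' target whether or not that robot is currently conveying information — a
#' perseverative fixation that can waste the observation. Otherwise, with
#' probability `beta` it makes the greedy information-seeking choice
#' ([greedy_info_choice()]), and with probability `1 - beta` it watches a
#' uniformly random current emitter. A `schedule` data frame (`round`,
#' `rho`, `beta`) can modulate both parameters per round.
#'
#' @param kind One of `"random"` (`rho = 0, beta = 0`), `"sticky"`,
#'   `"greedy_info"` (`rho = 0, beta = 1`), `"trait_blend"` (use `rho`,
#'   `beta`, `schedule` as given).
#' @param rho,beta Stickiness and information-seeking weights in `[0, 1]`.
#' @param schedule Optional per-round parameter table.
#' @return Object of class `agent_policy`.
#' @export
agent_policy <- function(kind = c("trait_blend", "random", "sticky", "greedy_info"),
                         rho = 0, beta = 0, schedule = NULL) {
  kind <- match.arg(kind)
  if (kind == "random") {
    rho <- 0; beta <- 0
  } else if (kind == "greedy_info") {
    rho <- 0; beta <- 1
  } else if (kind == "sticky") {
    beta <- 0
  }
  if (rho < 0 || rho > 1 || beta < 0 || beta > 1) {
    stop("rho and beta must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(schedule)) {
    stopifnot(all(c("round", "rho", "beta") %in% names(schedule)))
    if (any(schedule$rho < 0 | schedule$rho > 1 |
              schedule$beta < 0 | schedule$beta > 1)) {
      stop("scheduled rho and beta must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(kind = kind, rho = rho, beta = beta, schedule = schedule),
            class = "agent_policy")
}

policy_params <- function(policy, round) {
  if (!is.null(policy$schedule)) {
    i <- match(round, policy$schedule$round)
    if (!is.na(i)) {
      return(list(rho = policy$schedule$rho[i], beta = policy$schedule$beta[i]))
    }
  }
  list(rho = policy$rho, beta = policy$beta)
}

#' Greedy information-seeking gaze choice
#'
#' Among the robots currently performing informative gestures, returns the
#' one whose observation maximizes the expected Shannon-entropy reduction
#' of the corresponding belief cell (expectation over gestures under the
#' belief's predictive distribution). Ties go to the lowest robot index;
#' with no informative emitter the choice is `NA` (look at nothing).
#'
#' @param belief The agent's current [init_belief()] object.
#' @param emitters Integer vector of robots currently emitting informative
#'   gestures.
#' @param cells Two-column matrix, one `(j, k)` belief cell per emitter.
#' @param rgpd The session [rgpd_database()].
#' @return A robot index, or `NA_integer_`.
#' @export
greedy_info_choice <- function(belief, emitters, cells, rgpd) {
  if (length(emitters) == 0) {
    return(NA_integer_)
  }
  o <- order(emitters)
  emitters <- emitters[o]
  cells <- cells[o, , drop = FALSE]
  gains <- vapply(seq_along(emitters), function(i) {
    expected_info_gain(belief, cells[i, 1], cells[i, 2], rgpd)
  }, numeric(1))
  emitters[which.max(gains)]
}

# One informative-phase gaze decision.
choose_gaze <- function(params, belief, emitters, cells, prev_target, rgpd) {
  if (!is.na(prev_target) && stats::runif(1) < params$rho) {
    return(prev_target)
  }
  if (stats::runif(1) < params$beta) {
    return(greedy_info_choice(belief, emitters, cells, rgpd))
  }
  emitters[sample.int(length(emitters), 1)]
}

#' Simulate one gaze-contingent interaction session
#'
#' Runs the full protocol for a single synthetic participant: in every
#' robot turn the main robot gestures expressively toward another robot,
#' then the two other robots simultaneously convey their matrix attitude
#' toward the main robot (gestures drawn from the RGPD at
#' `M[responder, main]`); in a human turn, after a short pause, all three
#' robots convey their attitude toward the participant (`M[robot, 4]`).
#' The agent allocates gaze per gesture window under its policy, observed
#' informative gestures update its belief, and the robot that accumulated
#' the most gaze becomes the next turn's main robot (never the current
#' main; with no eligible gaze, a uniformly random eligible robot).
#'
#' @param config A [session_config()].
#' @param rgpd The gesture database.
#' @param policy An [agent_policy()].
#' @param emit_frames If `TRUE`, also expand the gaze record to
#'   frame-level samples at `config$frame_rate` (see [expand_frames()]).
#' @return Object of class `gaze_session`: `events` (gesture events),
#'   `gaze` (run-length gaze segments), `frames` (frame-level samples or
#'   `NULL`), `trajectory` (the participant's [belief_trajectory()]-shaped
#'   record), `round_beliefs`, `plan`, `config`.
#' @export
simulate_session <- function(config, rgpd, policy, emit_frames = FALSE) {
  plan <- plan_session(config)
  w <- config$gesture_window_s
  n_turns <- nrow(plan)
  # preallocated accumulators (3 events and 2-3 gaze segments per turn)
  ev <- list(round = integer(3 * n_turns), turn = integer(3 * n_turns),
             actor = integer(3 * n_turns), target = integer(3 * n_turns),
             gesture_id = integer(3 * n_turns),
             t_start = numeric(3 * n_turns), t_end = numeric(3 * n_turns),
             informative = logical(3 * n_turns))
  gz <- list(round = integer(3 * n_turns), turn = integer(3 * n_turns),
             t_start = numeric(3 * n_turns), t_end = numeric(3 * n_turns),
             x = rep(NA_integer_, 3 * n_turns), f = logical(3 * n_turns))
  meta <- list(round = integer(n_turns), turn = integer(n_turns),
               t = integer(n_turns), actor = integer(n_turns),
               target = integer(n_turns), gesture_id = integer(n_turns))
  mats <- vector("list", n_turns)
  ne <- 0L; ng <- 0L; nm <- 0L
  add_event <- function(s, z, actor, target, g, t0, t1, info) {
    ne <<- ne + 1L
    ev$round[ne] <<- s; ev$turn[ne] <<- z; ev$actor[ne] <<- actor
    ev$target[ne] <<- target; ev$gesture_id[ne] <<- g
    ev$t_start[ne] <<- t0; ev$t_end[ne] <<- t1; ev$informative[ne] <<- info
  }
  add_gaze <- function(s, z, t0, t1, x, f) {
    ng <<- ng + 1L
    gz$round[ng] <<- s; gz$turn[ng] <<- z; gz$t_start[ng] <<- t0
    gz$t_end[ng] <<- t1; gz$x[ng] <<- x; gz$f[ng] <<- f
  }
  round_beliefs <- list()
  for (s in seq_len(config$n_rounds)) {
    M <- config$matrices[[s]]
    belief <- init_belief(rgpd$levels)
    prev_target <- NA_integer_
    main <- config$initial_main[s]
    t_now <- 0
    t_idx <- 0L
    turns <- plan[plan$round == s, , drop = FALSE]
    params <- policy_params(policy, s)
    for (z in seq_len(nrow(turns))) {
      type <- turns$type[z]
      if (type == "human") {
        # idle pause, robots facing the participant
        add_gaze(s, z, t_now, t_now + config$human_turn_delay_s,
                 NA_integer_, FALSE)
        t_now <- t_now + config$human_turn_delay_s
        emitters <- 1:3
        cells <- cbind(emitters, 4L)
        g_ids <- c(sample_gesture(rgpd, M[1, 4]),
                   sample_gesture(rgpd, M[2, 4]),
                   sample_gesture(rgpd, M[3, 4]))
        for (i in 1:3) {
          add_event(s, z, i, 4L, g_ids[i], t_now, t_now + w, TRUE)
        }
        eligible <- 1:3
      } else {
        expressive_target <- setdiff(1:3, main)[sample.int(2, 1)]
        add_event(s, z, main, expressive_target,
                  sample_gesture(rgpd, M[main, expressive_target]),
                  t_now, t_now + w, FALSE)
        # orienting gaze: the agent watches the expressive main robot
        add_gaze(s, z, t_now, t_now + w, main, FALSE)
        t_now <- t_now + w
        emitters <- setdiff(1:3, main)
        cells <- cbind(emitters, main)
        g_ids <- c(sample_gesture(rgpd, M[emitters[1], main]),
                   sample_gesture(rgpd, M[emitters[2], main]))
        for (i in 1:2) {
          add_event(s, z, emitters[i], main, g_ids[i], t_now, t_now + w, TRUE)
        }
        eligible <- emitters
      }
      gaze_x <- choose_gaze(params, belief, emitters, cells, prev_target, rgpd)
      hit <- !is.na(gaze_x) && gaze_x %in% emitters
      add_gaze(s, z, t_now, t_now + w, gaze_x, hit)
      if (hit) {
        i <- match(gaze_x, emitters)
        belief <- update_belief(belief, cells[i, 1], cells[i, 2], g_ids[i], rgpd)
        t_idx <- t_idx + 1L
        nm <- nm + 1L
        meta$round[nm] <- s; meta$turn[nm] <- z; meta$t[nm] <- t_idx
        meta$actor[nm] <- cells[i, 1]; meta$target[nm] <- cells[i, 2]
        meta$gesture_id[nm] <- g_ids[i]
        mats[[nm]] <- expectation_matrix(belief)
      }
      t_now <- t_now + w
      if (!is.na(gaze_x)) {
        prev_target <- gaze_x
      }
      if (!is.na(gaze_x) && gaze_x %in% eligible) {
        main <- gaze_x
      } else {
        main <- eligible[sample.int(length(eligible), 1)]
      }
    }
    round_beliefs[[as.character(s)]] <- belief
  }
  trim <- function(l, n) as.data.frame(lapply(l, `[`, seq_len(n)))
  events <- trim(ev, ne)
  gaze <- trim(gz, ng)
  traj <- structure(list(meta = trim(meta, nm), matrices = mats[seq_len(nm)],
                         round_beliefs = round_beliefs),
                    class = "belief_trajectory")
  frames <- if (emit_frames) expand_frames(gaze, config$frame_rate) else NULL
  structure(list(events = events, gaze = gaze, frames = frames,
                 trajectory = traj, round_beliefs = round_beliefs,
                 plan = plan, config = config),
            class = "gaze_session")
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("<gaze_session>  %d rounds, %d gesture events, %d observed informative gesture(s)\n",
              x$config$n_rounds, nrow(x$events), nrow(x$trajectory$meta)))
  invisible(x)
}

#' Expand run-length gaze segments to frame-level samples
#'
#' @param gaze Data frame of gaze segments (`round`, `turn`, `t_start`,
#'   `t_end`, `x`, `f`).
#' @param frame_rate Samples per second.
#' @return Data frame with one row per sample: `t`, `round`, `turn`, `x`,
#'   `f`.
#' @export
expand_frames <- function(gaze, frame_rate = 30) {
  n_f <- pmax(0L, as.integer(floor((gaze$t_end - gaze$t_start) * frame_rate + 1e-9)))
  idx <- rep.int(seq_len(nrow(gaze)), n_f)
  off <- sequence(n_f) - 1L
  data.frame(
    t = gaze$t_start[idx] + off / frame_rate,
    round = gaze$round[idx],
    turn = gaze$turn[idx],
    x = gaze$x[idx],
    f = gaze$f[idx]
  )
}

#' Synthetic trait model for cohort generation
#'
#' Latent-trait distributions (matched to the external-measure summary
#' statistics of the study population: curiosity-inventory total 3.4 (0.6)
#' on 1-5, self-report inflexibility 2.5 (0.99) on 1-7, perseverative-error
#' count 6.8 (2.8)) and their designed couplings to the gaze policy:
#' higher perseverative-error counts raise early-round stickiness `rho`,
#' higher self-report inflexibility lowers it, and higher curiosity raises
#' late-round information seeking `beta`. Couplings act on the logit scale
#' per standard deviation of the trait, with independent logit-normal
#' policy noise.
#'
#' @param a_sumpe_rho,a_inflex_rho,a_curiosity_beta Coupling strengths
#'   (logit units per trait SD).
#' @param rho_early,rho_base Baseline stickiness in early (1-2) vs later
#'   rounds.
#' @param beta_base,beta_late Baseline information seeking in rounds 1-4
#'   vs late (5-6) rounds.
#' @param policy_noise_sd SD of the per-round logit noise.
#' @return Object of class `trait_model` (a parameter list).
#' @export
trait_model <- function(a_sumpe_rho = 1.5, a_inflex_rho = -0.75,
                        a_curiosity_beta = 1.5,
                        rho_early = 0.35, rho_base = 0.1,
                        beta_base = 0.5, beta_late = 0.5,
                        policy_noise_sd = 0.3) {
  structure(
    list(curiosity_mean = 3.4, curiosity_sd = 0.6, curiosity_range = c(1, 5),
         inflex_mean = 2.5, inflex_sd = 0.99, inflex_range = c(1, 7),
         sumpe_mean = 6.8, sumpe_sd = 2.8,
         a_sumpe_rho = a_sumpe_rho, a_inflex_rho = a_inflex_rho,
         a_curiosity_beta = a_curiosity_beta,
         rho_early = rho_early, rho_base = rho_base,
         beta_base = beta_base, beta_late = beta_late,
         policy_noise_sd = policy_noise_sd,
         early_rounds = 1:2, late_rounds = 5:6),
    class = "trait_model"
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# Per-participant policy schedule from trait z-scores.
trait_schedule <- function(tm, z_pe, z_inflex, z_cur, n_rounds) {
  rounds <- seq_len(n_rounds)
  eps_rho <- stats::rnorm(n_rounds, 0, tm$policy_noise_sd)
  eps_beta <- stats::rnorm(n_rounds, 0, tm$policy_noise_sd)
  rho0 <- ifelse(rounds %in% tm$early_rounds, tm$rho_early, tm$rho_base)
  drive <- ifelse(rounds %in% tm$early_rounds,
                  tm$a_sumpe_rho * z_pe + tm$a_inflex_rho * z_inflex, 0)
  rho <- stats::plogis(stats::qlogis(rho0) + drive + eps_rho)
  beta0 <- ifelse(rounds %in% tm$late_rounds, tm$beta_late, tm$beta_base)
  gain <- ifelse(rounds %in% tm$late_rounds, tm$a_curiosity_beta * z_cur, 0)
  beta <- stats::plogis(stats::qlogis(beta0) + gain + eps_beta)
  data.frame(round = rounds, rho = rho, beta = beta)
}

#' Simulate a synthetic cohort
#'
#' Draws `n` participants with latent traits from [trait_model()], builds
#' each one a per-round gaze-policy schedule with the designed
#' trait-policy couplings, and runs a full session per participant.
#' Reproducible under `set.seed()`.
#'
#' @param n Number of participants (at least 2).
#' @param tm A [trait_model()].
#' @param config A [session_config()].
#' @param rgpd The gesture database.
#' @param emit_frames Expand gaze segments to 30 Hz frames (memory-heavy
#'   for large cohorts).
#' @return Object of class `cohort`: `participants` (data frame of ids and
#'   trait scores), `sessions` (list of [simulate_session()] results),
#'   `trait_model` (the design metadata).
#' @export
simulate_cohort <- function(n, tm = trait_model(), config = session_config(),
                            rgpd = NULL, emit_frames = FALSE) {
  if (n < 2) {
    stop("need at least 2 participants for downstream correlations",
         call. = FALSE)
  }
  if (is.null(rgpd)) {
    stop("an rgpd is required", call. = FALSE)
  }
  curiosity <- rtrunc_norm(n, tm$curiosity_mean, tm$curiosity_sd,
                           tm$curiosity_range[1], tm$curiosity_range[2])
  inflex <- rtrunc_norm(n, tm$inflex_mean, tm$inflex_sd,
                        tm$inflex_range[1], tm$inflex_range[2])
  sumpe <- pmax(0, round(stats::rnorm(n, tm$sumpe_mean, tm$sumpe_sd)))
  participants <- data.frame(
    participant_id = sprintf("p%03d", seq_len(n)),
    curiosity = curiosity, inflexibility = inflex, sumPE = sumpe
  )
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- trait_schedule(
      tm,
      z_pe = (sumpe[i] - tm$sumpe_mean) / tm$sumpe_sd,
      z_inflex = (inflex[i] - tm$inflex_mean) / tm$inflex_sd,
      z_cur = (curiosity[i] - tm$curiosity_mean) / tm$curiosity_sd,
      n_rounds = config$n_rounds
    )
    policy <- agent_policy("trait_blend", schedule = sched)
    sessions[[i]] <- simulate_session(config, rgpd, policy,
                                      emit_frames = emit_frames)
  }
  structure(list(participants = participants, sessions = sessions,
                 trait_model = tm, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort>  %d participants, %d rounds each\n",
              nrow(x$participants), x$config$n_rounds))
  invisible(x)
}

#' Blink event times
#'
#' Inter-blink intervals are i.i.d. exponential with the given mean; the
#' mean is 3.5 s in normal mode and 2.5 s when the robot's relationship to
#' its interaction subject exceeds 0.5 (increased blinking signals a
#' positive attitude). Cosmetic realism only — blinks carry no matrix
#' information.
#'
#' @param mean_interval_s Mean inter-blink interval, seconds.
#' @param duration_s Length of the simulated span, seconds.
#' @return Increasing vector of event times within `[0, duration_s]`.
#' @export
blink_times <- function(mean_interval_s, duration_s) {
  if (mean_interval_s <= 0) {
    stop("mean_interval_s must be positive", call. = FALSE)
  }
  if (duration_s <= 0) {
    return(numeric(0))
  }
  # draw in batches until the span is covered
  times <- numeric(0)
  t_last <- 0
  while (t_last <= duration_s) {
    gaps <- stats::rexp(max(16, ceiling(duration_s / mean_interval_s)),
                        rate = 1 / mean_interval_s)
    times <- c(times, t_last + cumsum(gaps))
    t_last <- times[length(times)]
  }
  times[times <= duration_s]
}

#' @rdname blink_times
#' @param relationship Attitude of the blinking robot toward its current
#'   interaction subject, in `[0, 1]`.
#' @export
blink_interval_mean <- function(relationship) {
  ifelse(relationship > 0.5, 2.5, 3.5)
}
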