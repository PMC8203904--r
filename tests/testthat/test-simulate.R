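# Protocol simulation: scheduling, gaze-contingent turn dynamics, agent
# policies, synthetic cohorts, blink model.

test_that("the default schedule has 4 turns in round 1 (human third) and 8 in rounds 2-5", {
  plan <- plan_session(session_config())
  expect_equal(sum(plan$round == 1), 4)
  expect_equal(plan$type[plan$round == 1], c("initial", "dynamic", "human", "dynamic"))
  for (s in 2:5) {
    expect_equal(sum(plan$round == s), 8)
  }
  expect_equal(sum(plan$round == 6), 8)
  expect_false(any(plan$type[plan$round == 6] == "human"))
})

test_that("degenerate schedules are handled: zero rounds empty, bad slots error", {
  cfg0 <- session_config(n_rounds = 0, turns_per_round = integer(0),
                         human_turn_slots = list(), matrices = list())
  expect_equal(nrow(plan_session(cfg0)), 0)
  expect_error(
    plan_session(session_config(n_rounds = 1, turns_per_round = 4,
                                human_turn_slots = list(9L),
                                matrices = study_matrices()[1])),
    "out of range")
})

test_that("every informative-flagged frame lies inside an informative window of its robot", {
  db <- fixture_rgpd()
  set.seed(71)
  for (i in 1:3) {
    s <- simulate_session(short_config(), db,
                          agent_policy("trait_blend", rho = 0.4, beta = 0.5),
                          emit_frames = TRUE)
    expect_silent(sociogaze:::audit_gaze_flags(s$frames, s$events))
  }
})

test_that("the gazed robot becomes the next main robot, never the current one", {
  db <- fixture_rgpd()
  set.seed(72)
  s <- simulate_session(session_config(), db, agent_policy("random"))
  ev <- s$events
  gz <- s$gaze
  for (r in unique(ev$round)) {
    expressive <- ev[ev$round == r & !ev$informative, ]
    mains <- expressive$actor[order(expressive$turn)]
    turns <- sort(unique(ev$turn[ev$round == r]))
    plan_r <- s$plan[s$plan$round == r, ]
    for (zi in seq_along(turns)[-length(turns)]) {
      z <- turns[zi]
      nxt <- turns[zi + 1]
      if (plan_r$type[plan_r$turn == nxt] != "dynamic") next
      main_next <- expressive$actor[expressive$turn == nxt]
      # never the current main
      if (plan_r$type[plan_r$turn == z] != "human") {
        main_now <- expressive$actor[expressive$turn == z]
        expect_false(main_next == main_now)
        # if the agent watched an eligible responder, it is the next main
        seg <- gz[gz$round == r & gz$turn == z, ]
        watched <- seg$x[nrow(seg)]
        if (!is.na(watched) && watched != main_now) {
          expect_equal(main_next, watched)
        }
      }
    }
  }
})

test_that("a fully perseverative agent keeps a constant gaze target within rounds", {
  db <- fixture_rgpd()
  set.seed(73)
  s <- simulate_session(session_config(), db, agent_policy("sticky", rho = 1))
  gz <- s$gaze
  # informative-phase segments are the last per (round, turn)
  for (r in unique(gz$round)) {
    seg <- gz[gz$round == r, ]
    picks <- vapply(split(seg, seg$turn), function(d) d$x[nrow(d)], numeric(1))
    picks <- picks[!is.na(picks)]
    expect_lte(length(unique(picks)), 2)  # first free choice, then locked
    expect_equal(length(unique(picks[-1])), 1)
  }
})

test_that("greedy gaze prefers the less resolved cell and breaks ties downward", {
  db <- separating_rgpd()
  b <- init_belief(db$levels)
  b$p[, sociogaze:::cell_index(2, 1)] <- c(0.98, 0.01, 0.01)  # nearly resolved
  pick <- greedy_info_choice(b, emitters = c(2L, 3L),
                             cells = rbind(c(2L, 1L), c(3L, 1L)), db)
  expect_equal(pick, 3L)
  b2 <- init_belief(db$levels)
  expect_equal(greedy_info_choice(b2, c(3L, 2L), rbind(c(3L, 1L), c(2L, 1L)), db), 2L)
  expect_true(is.na(greedy_info_choice(b2, integer(0), matrix(0, 0, 2), db)))
})

test_that("greedy information gain matches a brute-force expected-entropy oracle", {
  db <- toy_rgpd()
  set.seed(74)
  for (i in 1:20) {
    b <- init_belief(db$levels)
    idx <- sociogaze:::cell_index(1, 2)
    b$p[, idx] <- random_prob(3)
    prior <- b$p[, idx]
    h <- function(p) {
      p <- p[p > 0]
      -sum(p * log2(p))
    }
    eh <- 0
    for (g in 1:2) {
      lik <- db$likelihood[g, ]
      pg <- sum(lik * prior)
      if (pg > 0) eh <- eh + pg * h(lik * prior / pg)
    }
    expect_equal(sociogaze:::expected_info_gain(b, 1, 2, db), h(prior) - eh,
                 tolerance = 1e-12)
  }
})

test_that("cohorts are reproducible under a seed and distinct across seeds", {
  db <- fixture_rgpd()
  cfg <- short_config()
  set.seed(81)
  c1 <- simulate_cohort(3, trait_model(), cfg, db)
  set.seed(81)
  c2 <- simulate_cohort(3, trait_model(), cfg, db)
  expect_identical(c1$participants, c2$participants)
  for (i in 1:3) {
    expect_identical(c1$sessions[[i]]$events, c2$sessions[[i]]$events)
    expect_identical(c1$sessions[[i]]$gaze, c2$sessions[[i]]$gaze)
  }
  set.seed(82)
  c3 <- simulate_cohort(3, trait_model(), cfg, db)
  expect_false(identical(c1$sessions[[1]]$gaze, c3$sessions[[1]]$gaze))
  expect_error(simulate_cohort(1, trait_model(), cfg, db), "at least 2")
})

test_that("zero trait couplings leave trait-behavior correlations near zero", {
  db <- fixture_rgpd()
  tm0 <- trait_model(a_sumpe_rho = 0, a_inflex_rho = 0, a_curiosity_beta = 0)
  set.seed(83)
  coh <- simulate_cohort(200, tm0, session_config(), db)
  tab <- score_cohort(coh, db)
  ct <- suppressMessages(trait_correlations(tab))
  key <- ct[(ct$trait == "sumPE" & ct$measure == "BE1") |
              (ct$trait == "curiosity" & ct$measure == "BE5"), ]
  # null correlations stay within 3 standard errors of zero
  expect_true(all(abs(key$r) < 3 / sqrt(200)))
})

test_that("trait schedules respond to traits in the designed directions", {
  tm <- trait_model()
  withr::with_seed(84, {
    hi <- sociogaze:::trait_schedule(tm, z_pe = 2, z_inflex = 0, z_cur = 2, 6)
  })
  withr::with_seed(84, {
    lo <- sociogaze:::trait_schedule(tm, z_pe = -2, z_inflex = 0, z_cur = -2, 6)
  })
  expect_true(all(hi$rho[1:2] > lo$rho[1:2]))
  expect_true(all(hi$beta[5:6] > lo$beta[5:6]))
  expect_equal(hi$rho[3:6], lo$rho[3:6])   # couplings act on early rounds only
  expect_equal(hi$beta[1:4], lo$beta[1:4])
})

test_that("synthetic ratings have the designed structure and controllable valence", {
  set.seed(85)
  recs <- simulate_ratings(n_raters = 50)
  expect_equal(nrow(recs), 50 * 16)
  expect_true(all(recs$rating %in% 1:7))
  models <- gesture_models(recs)
  a <- vapply(models, `[[`, numeric(1), "valence")
  prof <- default_gesture_profiles()
  # clear gestures: model valence tracks the profile ordering
  clear <- prof$gesture_id[prof$spread < 0.5]
  expect_gt(cor(a[as.character(clear)], prof$mean_valence[clear]), 0.95)
  # high-spread gestures are the most ambiguous
  h <- vapply(models, `[[`, numeric(1), "ambiguity")
  expect_gt(min(h[as.character(c(7, 10, 14, 15))]), max(h[as.character(c(4, 6, 13))]))
})

test_that("blink intervals are exponential with the attitude-dependent mean", {
  expect_equal(blink_interval_mean(0.6), 2.5)
  expect_equal(blink_interval_mean(0.5), 3.5)
  expect_equal(blink_interval_mean(0.2), 3.5)
  expect_length(blink_times(3.5, 0), 0)
  expect_error(blink_times(0, 10), "positive")
  set.seed(86)
  tt <- blink_times(3.5, 1e4)
  gaps <- diff(c(0, tt))
  se <- 3.5 / sqrt(length(gaps))           # exponential: sd = mean
  expect_lt(abs(mean(gaps) - 3.5), 3 * se)
  expect_true(all(diff(tt) > 0) && all(tt <= 1e4))
})
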