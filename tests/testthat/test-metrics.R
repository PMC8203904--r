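# Outcome measures: matrix distance, the greedy-optimal reference,
# behavioral error, end-of-round questions and learning scores.

test_that("the matrix distance satisfies the metric axioms", {
  m <- example_relationship_matrix()
  expect_equal(matrix_distance(m, m), 0)
  z <- relationship_matrix(rep(0, 9))
  o <- relationship_matrix(rep(1, 9))
  expect_equal(matrix_distance(z, o), 9 / 12)   # fixed denominator 12
  set.seed(9)
  for (i in 1:1000) {
    a <- random_relationship_matrix()
    b <- random_relationship_matrix()
    c_ <- random_relationship_matrix()
    dab <- matrix_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, matrix_distance(b, a))
    expect_lte(matrix_distance(a, c_), dab + matrix_distance(b, c_) + 1e-12)
  }
  expect_equal(matrix_distance(m, relationship_matrix(rep(0.5, 9))),
               sum(abs(m - relationship_matrix(rep(0.5, 9)))) / 12)
})

test_that("the greedy reference observes forced choices and its own BE is zero", {
  db <- fixture_rgpd()
  # hand-built stream with a single informative emitter per window
  ev <- data.frame(
    round = 1L, turn = 1:3, actor = c(2L, 3L, 1L), target = c(1L, 1L, 2L),
    gesture_id = db$gesture_ids[c(1, 2, 3)],
    t_start = c(4, 12, 20), t_end = c(8, 16, 24), informative = TRUE
  )
  tr <- greedy_optimal_trajectory(ev, db)
  expect_equal(tr$meta$actor, ev$actor)
  expect_equal(tr$meta$t, 1:3)
  expect_length(tr$matrices, 3)

  set.seed(91)
  s <- simulate_session(short_config(), db, agent_policy("greedy_info"))
  expect_equal(unname(score_session(s, db)$BE), rep(0, 2))
  # empty stream: empty trajectory
  expect_equal(nrow(greedy_optimal_trajectory(ev[0, ], db)$meta), 0)
})

test_that("the greedy reference ends closer to the truth than a random gazer on average", {
  db <- fixture_rgpd()
  cfg <- session_config(n_rounds = 1, turns_per_round = 8,
                        human_turn_slots = list(4L),
                        matrices = study_matrices()[2])
  truth <- cfg$matrices[[1]]
  set.seed(92)
  gaps <- replicate(100, {
    s <- simulate_session(cfg, db, agent_policy("random"))
    opt <- greedy_optimal_trajectory(s$events, db)
    d_opt <- matrix_distance(expectation_matrix(opt$round_beliefs[["1"]]), truth)
    d_rnd <- matrix_distance(expectation_matrix(s$round_beliefs[["1"]]), truth)
    d_rnd - d_opt
  })
  expect_gt(mean(gaps), 0)
})

test_that("behavioral error averages aligned distances and validates alignment", {
  db <- fixture_rgpd()
  set.seed(93)
  s <- simulate_session(short_config(1), db, agent_policy("random"))
  opt <- greedy_optimal_trajectory(s$events, db)
  uniform <- expectation_matrix(init_belief(db$levels))
  # constant-uniform participant: BE equals the hand-computed mean
  hand <- mean(vapply(opt$matrices, function(m) sum(abs(uniform - m)) / 12,
                      numeric(1)))
  empty_traj <- sociogaze:::new_belief_trajectory(list(), list(), list())
  al <- sociogaze:::align_optimal(empty_traj, opt, 1, db$levels)
  expect_equal(behavioral_error(al$participant, al$optimal), hand)

  expect_equal(behavioral_error(list(uniform), opt$matrices[1]),
               matrix_distance(uniform, opt$matrices[[1]]))
  expect_error(behavioral_error(opt$matrices[1:2], opt$matrices[1:3]),
               "aligned")
  expect_true(is.na(behavioral_error(list(), list())))
})

test_that("mean behavioral error degrades monotonically as information seeking decays", {
  db <- fixture_rgpd()
  cfg <- short_config()
  betas <- c(1, 0.75, 0.5, 0.25, 0)
  set.seed(94)
  mbe <- vapply(betas, function(b) {
    mean(replicate(40, {
      s <- simulate_session(cfg, db, agent_policy("trait_blend", rho = 0, beta = b))
      mean(score_session(s, db)$BE)
    }))
  }, numeric(1))
  # non-decreasing, allowing one adjacent inversion within noise
  inversions <- sum(diff(mbe) < -0.002)
  expect_lte(inversions, 1)
  expect_gt(mbe[length(betas)], mbe[1])
})

test_that("the four questions read the matrix extremes, with ties as dont-know", {
  m <- example_relationship_matrix()
  expect_equal(answer_questions(m), c(q1 = 1L, q2 = 2L, q3 = 3L, q4 = 2L))
  uniform <- relationship_matrix(rep(0.5, 9))
  expect_equal(unname(answer_questions(uniform)), rep(0L, 4))
})

test_that("learning scores count matches against robot-valued truth only", {
  truth <- c(1L, 2L, 3L, 2L)
  expect_equal(learning_score(truth, truth), 4)
  expect_equal(learning_score(c(0L, 0L, 0L, 0L), truth), 0)
  expect_equal(learning_score(c(1L, 3L, 3L, 1L), truth), 2)
  # dont-know in the truth never scores
  expect_equal(learning_score(c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L)), 0)
  expect_error(learning_score(1:3, truth), "four answers")
  # five perfect rounds reach the session maximum of 20
  expect_equal(sum(rep(learning_score(truth, truth), 5)), 20)
})

test_that("chance level reflects the guessing model", {
  expect_equal(chance_level(), 4 / 3)
  expect_equal(chance_level(include_dont_know = TRUE), 1)
})

test_that("a fully informed observer answers the robot-robot questions near-perfectly", {
  db <- fixture_rgpd()
  cfg <- session_config()
  set.seed(95)
  acc <- replicate(25, {
    s <- simulate_session(cfg, db, agent_policy("random"))
    tr <- belief_from_events(s$events, db)
    out <- vapply(2:5, function(r) {
      g <- answer_questions(expectation_matrix(tr$round_beliefs[[as.character(r)]]))
      tru <- answer_questions(cfg$matrices[[r]])
      c(q12 = sum(tru[1:2] != 0 & g[1:2] == tru[1:2]),
        L = learning_score(g, tru))
    }, numeric(2))
    rowMeans(out)
  })
  expect_gte(mean(acc["q12", ]) / 2, 0.9)   # Q1/Q2 accuracy
  expect_gte(mean(acc["L", ]), 2.5)         # far above the 4/3 chance level
})

test_that("session scores have the documented shape and ranges", {
  db <- fixture_rgpd()
  set.seed(96)
  s <- simulate_session(session_config(), db,
                        agent_policy("trait_blend", rho = 0.2, beta = 0.5))
  sc <- score_session(s, db)
  expect_named(sc$BE, paste0("BE", 1:6))
  expect_named(sc$L, paste0("L", 1:5))
  expect_true(all(sc$BE >= 0))
  expect_true(all(sc$L >= 0 & sc$L <= 4))
  expect_lte(sum(sc$L), 20)
})
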