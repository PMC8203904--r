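# Gesture-perception model: rater filtering, rating distributions,
# valence/ambiguity scores, and the Bayes-inverted gesture database.

test_that("rater filters drop trap failures and sub-180 s completions, preserving order", {
  recs <- data.frame(
    rater_id = c("a", "b", "c", "d", "e"),
    gesture_id = 1L,
    rating = c(4L, 4L, 4L, 4L, 4L),
    total_time_s = c(500, 400, 179, 180, 300),
    trap_correct = c(TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  kept <- filter_raters(recs)
  expect_identical(kept$rater_id, c("a", "d", "e"))
  expect_identical(filter_raters(recs[0, ]), recs[0, ])
})

test_that("rating distributions are normalized histograms over the 7 levels", {
  expect_equal(rating_distribution(rep(7L, 10)), c(0, 0, 0, 0, 0, 0, 1))
  expect_equal(rating_distribution(1:7), rep(1 / 7, 7))
  expect_equal(rating_distribution(c(rep(4L, 5), rep(7L, 5))),
               c(0, 0, 0, 0.5, 0, 0, 0.5))
  expect_error(rating_distribution(integer(0)), "no ratings")
  expect_error(rating_distribution(c(0L, 3L)), "levels")
})

test_that("valence is the expected attitude on [-1, 1]", {
  expect_equal(valence(rep(1 / 7, 7)), 0)
  expect_equal(valence(c(0, 0, 0, 0, 0, 0, 1)), 1)
  expect_equal(valence(c(0.5, 0, 0, 0, 0, 0, 0.5)), 0)
  expect_error(valence(rep(0.2, 7)), "sum")
  set.seed(1)
  for (i in 1:20) {
    p <- random_prob()
    a <- valence(p)
    expect_gte(a, -1)
    expect_lte(a, 1)
  }
})

test_that("ambiguity is normalized entropy with the documented limits", {
  expect_equal(ambiguity(rep(1 / 7, 7)), 1)
  expect_equal(ambiguity(c(0, 0, 1, 0, 0, 0, 0)), 0)
  expect_equal(ambiguity(c(0.5, 0.5, 0, 0, 0, 0, 0)), log2(2) / log2(7))
})

test_that("ambiguity equals an independent entropy oracle over log2(K) on random vectors", {
  set.seed(99)
  for (i in 1:100) {
    p <- random_prob()
    expect_equal(ambiguity(p), oracle_entropy_bits(p) / log2(7),
                 tolerance = 1e-12)
  }
  # maximal iff uniform, minimal iff degenerate
  set.seed(100)
  for (i in 1:25) {
    p <- random_prob()
    h <- ambiguity(p)
    expect_true(h >= 0 && h <= 1)
    if (max(abs(p - 1 / 7)) > 1e-6) expect_lt(h, 1)
  }
})

test_that("gesture models bundle distribution, valence, ambiguity and count", {
  gm <- gesture_model(3L, c(rep(6L, 8), rep(7L, 2)))
  expect_s3_class(gm, "gesture_model")
  expect_equal(gm$n_ratings, 10)
  expect_equal(sum(gm$p_v), 1)
  expect_equal(gm$valence, 0.8 * (2 / 3) + 0.2 * 1)
})

test_that("the default discard set removes gestures 7, 10, 14, 15", {
  models <- fixture_models()
  all16 <- gesture_models(filter_raters(withr::with_seed(1, simulate_ratings())))
  expect_length(all16, 16)
  kept <- discard_ambiguous(all16)
  expect_length(kept, 12)
  expect_false(any(c(7, 10, 14, 15) %in% vapply(kept, `[[`, integer(1), "gesture_id")))
  expect_identical(discard_ambiguous(all16, integer(0)), all16)
  expect_error(build_rgpd(discard_ambiguous(all16, 1:16)), "no gesture models")
})

test_that("the RGPD is a Bayes inversion with normalized columns", {
  db <- fixture_rgpd()
  expect_equal(colSums(db$likelihood), rep(1, 7), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(db$likelihood >= 0))
  expect_equal(db$levels, (valence_grid() + 1) / 2)

  # single retained gesture with mass at every level: p(g | m) = 1 everywhere
  solo <- build_rgpd(list(gesture_model(1L, c(1:7, 4L, 4L))))
  expect_equal(unname(solo$likelihood), matrix(1, 1, 7))

  # mirror-image pair: equal likelihood at the middle level
  a <- gesture_model(1L, c(rep(1L, 3), rep(2L, 4), rep(3L, 2), rep(4L, 3)))
  b <- gesture_model(2L, c(rep(7L, 3), rep(6L, 4), rep(5L, 2), rep(4L, 3)))
  mir <- build_rgpd(list(a, b))
  expect_equal(unname(mir$likelihood[, 4]), c(0.5, 0.5))
})

test_that("a hand-computed three-gesture inversion matches build_rgpd", {
  p1 <- c(0.6, 0.3, 0.1, 0, 0, 0, 0)
  p2 <- c(0.1, 0.2, 0.4, 0.2, 0.1, 0, 0)
  p3 <- c(0, 0, 0.1, 0.2, 0.3, 0.2, 0.2)
  mk <- function(id, p) {
    structure(list(gesture_id = id, p_v = p, valence = valence(p),
                   ambiguity = ambiguity(p), n_ratings = 10L),
              class = "gesture_model")
  }
  db <- build_rgpd(list(mk(1L, p1), mk(2L, p2), mk(3L, p3)))
  for (k in 1:7) {
    tot <- p1[k] + p2[k] + p3[k]
    expect_equal(unname(db$likelihood[, k]), c(p1[k], p2[k], p3[k]) / tot)
  }
})

test_that("an all-zero relationship level makes the inversion fail loudly", {
  p1 <- c(1, 0, 0, 0, 0, 0, 0)
  p2 <- c(0, 1, 0, 0, 0, 0, 0)
  mk <- function(id, p) gesture_model(id, rep(which(p == 1), 5))
  expect_error(build_rgpd(list(mk(1L, p1), mk(2L, p2))), "likelihood undefined")
})

test_that("gesture sampling snaps to the grid, matches p(g|m), and is reproducible", {
  db <- fixture_rgpd()
  expect_error(sample_gesture(db, -0.1), "\\[0, 1\\]")
  expect_error(sample_gesture(db, 1.5), "\\[0, 1\\]")

  solo <- rgpd_database(matrix(1, 1, 3), c(0, 0.5, 1), 7L)
  expect_equal(unique(sample_gesture(solo, 0.3, 50)), 7L)

  set.seed(123)
  draws1 <- sample_gesture(db, 0.8, 100)
  set.seed(123)
  draws2 <- sample_gesture(db, 0.8, 100)
  expect_identical(draws1, draws2)

  # large-sample frequencies match the snapped column within 3 SE
  set.seed(42)
  n <- 1e5
  m <- 0.8                                  # snaps to level 5/6
  k <- which.min(abs(db$levels - m))
  draws <- sample_gesture(db, m, n)
  freq <- tabulate(match(draws, db$gesture_ids), length(db$gesture_ids)) / n
  p <- db$likelihood[, k]
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) <= 3 * se + 1e-12))

  # midpoint ties snap downward
  tie <- rgpd_database(rbind(c(1, 0), c(0, 1)), c(0, 1), 1:2)
  expect_equal(unique(sample_gesture(tie, 0.5, 20)), 1L)
})

test_that("sampled gestures fed back through the Bayes update recover the level", {
  db <- fixture_rgpd()
  set.seed(77)
  for (m in c(0.1, 0.5, 0.9)) {
    lvl <- db$levels[which.min(abs(db$levels - m))]
    b <- init_belief(db$levels)
    for (i in 1:500) {
      b <- update_belief(b, 1, 2, sample_gesture(db, m), db)
    }
    expect_lt(abs(sum(b$levels * b$p[, 1]) - lvl), 0.05)
  }
})
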