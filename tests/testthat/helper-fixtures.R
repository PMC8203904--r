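# Shared fixtures, built in code. Expensive objects are memoized for the
# duration of the test run.

.fx <- new.env(parent = emptyenv())

# Default gesture database: synthetic rating survey -> filter -> models ->
# discard high-ambiguity -> RGPD, under a fixed fixture seed.
fixture_rgpd <- function() {
  if (is.null(.fx$rgpd)) {
    withr::with_seed(20260901, {
      recs <- filter_raters(simulate_ratings())
      models <- discard_ambiguous(gesture_models(recs))
      .fx$models <- models
      .fx$rgpd <- build_rgpd(models)
    })
  }
  .fx$rgpd
}

fixture_models <- function() {
  fixture_rgpd()
  .fx$models
}

# Full enumeration of the default nine-value multiset.
fixture_candidates <- function() {
  if (is.null(.fx$candidates)) {
    .fx$candidates <- enumerate_candidates(default_attitude_values())
  }
  .fx$candidates
}

# Two-gesture, three-level toy database with hand-checkable likelihoods.
toy_rgpd <- function() {
  rgpd_database(
    likelihood = rbind(c(0.5, 0.3, 0.2),
                       c(0.5, 0.7, 0.8)),
    levels = c(0, 0.5, 1),
    gesture_ids = c(101L, 102L)
  )
}

# A sharply level-separating database: each gesture is strongly preferred
# at exactly one of three levels.
separating_rgpd <- function(eps = 0.05) {
  lik <- matrix(eps / 2, 3, 3)
  diag(lik) <- 1 - eps
  rgpd_database(lik, levels = c(0, 0.5, 1), gesture_ids = 1:3)
}

# Random probability vector of length k.
random_prob <- function(k = 7) {
  x <- stats::rexp(k)
  x / sum(x)
}

# Random valid relationship matrix.
random_relationship_matrix <- function() {
  relationship_matrix(stats::runif(9))
}

# Independent Shannon-entropy oracle (natural definition, base 2).
oracle_entropy_bits <- function(p) {
  s <- 0
  for (pi in p) {
    if (pi > 0) s <- s - pi * log(pi) / log(2)
  }
  s
}

# Short session configuration for fast protocol tests.
short_config <- function(n_rounds = 2) {
  session_config(
    n_rounds = n_rounds,
    turns_per_round = rep(4, n_rounds),
    human_turn_slots = rep(list(3L), n_rounds),
    matrices = study_matrices()[seq_len(n_rounds)]
  )
}
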