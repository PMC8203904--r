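#' Default synthetic gesture profiles
#'
#' Target valence (mean of the perceived-attitude distribution, on
#' \eqn{[-1,1]}) and spread (standard deviation of the latent Gaussian that
#' is discretized onto the 7 levels) for the 16 nonverbal gestures. The set
#' spans clearly positive (nodding, leaning), clearly negative (aggressive,
#' shy) and neutral gestures, and includes four high-spread gestures
#' (7, 10, 14, 15) that raters perceive very differently — these are the
#' default discard set downstream.
#'
#' @return Data frame with columns `gesture_id`, `mean_valence`, `spread`.
#' @export
default_gesture_profiles <- function() {
  data.frame(
    gesture_id = 1:16,
    mean_valence = c(0.0, -0.3, 0.3, 0.0, 0.6, 0.8, 0.4, 0.5,
                     -0.5, 0.1, 0.2, -0.6, -0.8, 0.0, -0.2, -0.4),
    spread = c(0.25, 0.30, 0.30, 0.15, 0.25, 0.20, 1.50, 0.30,
               0.30, 1.80, 0.35, 0.30, 0.20, 2.50, 1.80, 0.35)
  )
}

# Discretized-Gaussian rating distribution on the valence grid.
profile_distribution <- function(mean_valence, spread, grid = valence_grid()) {
  w <- exp(-(grid - mean_valence)^2 / (2 * spread^2))
  w / sum(w)
}

#' Simulate a gesture-rating survey
#'
#' Generates per-rater 7-point Likert ratings of every gesture, with rater
#' metadata for the attention filters: a trap-question flag and a total
#' completion time (a small fraction of raters rush below the 180 s floor).
#' Ratings are drawn from a discretized Gaussian on the valence grid with
#' per-gesture mean and spread.
#'
#' @param n_raters Number of raters (default 105, of whom roughly 10% fail
#'   an attention filter).
#' @param profiles Gesture profile table, see [default_gesture_profiles()].
#' @param p_trap_fail Probability a rater answers the trap question wrong.
#' @param p_fast Probability a rater finishes in under 180 s.
#' @param grid Valence grid.
#' @return Data frame of rating records (`rater_id`, `gesture_id`, `rating`,
#'   `total_time_s`, `trap_correct`), one row per rater x gesture.
#' @export
simulate_ratings <- function(n_raters = 105, profiles = default_gesture_profiles(),
                             p_trap_fail = 0.07, p_fast = 0.04,
                             grid = valence_grid()) {
  n_g <- nrow(profiles)
  trap <- stats::runif(n_raters) >= p_trap_fail
  fast <- stats::runif(n_raters) < p_fast
  total_time <- ifelse(fast,
                       stats::runif(n_raters, 60, 179),
                       stats::rlnorm(n_raters, log(600), 0.4) + 180)
  dists <- lapply(seq_len(n_g), function(i) {
    profile_distribution(profiles$mean_valence[i], profiles$spread[i], grid)
  })
  k <- length(grid)
  ratings <- matrix(0L, n_raters, n_g)
  for (i in seq_len(n_g)) {
    ratings[, i] <- sample.int(k, n_raters, replace = TRUE, prob = dists[[i]])
  }
  data.frame(
    rater_id = rep(sprintf("r%03d", seq_len(n_raters)), each = n_g),
    gesture_id = rep(profiles$gesture_id, times = n_raters),
    rating = as.integer(t(ratings)),
    total_time_s = rep(total_time, each = n_g),
    trap_correct = rep(trap, each = n_g)
  )
}
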