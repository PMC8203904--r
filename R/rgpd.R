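#' Filter gesture raters by attention checks
#'
#' Removes raters who failed the trap question or finished the whole rating
#' task in under 180 seconds (the minimum time needed to actually watch all
#' stimulus videos). A total time of exactly 180 s is retained.
#'
#' @param records Data frame of rating records with columns `rater_id`,
#'   `gesture_id`, `rating`, `total_time_s`, `trap_correct`.
#' @return The retained records, in input order.
#' @export
filter_raters <- function(records) {
  records <- validate_rating_records(records)
  keep <- records$trap_correct & records$total_time_s >= 180
  records[keep, , drop = FALSE]
}

validate_rating_records <- function(records) {
  needed <- c("rater_id", "gesture_id", "rating", "total_time_s", "trap_correct")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("rating records missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$rating %in% 1:7)) {
    stop("ratings must be integer levels 1..7", call. = FALSE)
  }
  if (any(records$total_time_s < 0)) {
    stop("total_time_s must be non-negative", call. = FALSE)
  }
  records$trap_correct <- as.logical(records$trap_correct)
  records
}

#' Rating histogram as a probability distribution
#'
#' Tabulates Likert ratings of a single gesture over the levels of the
#' valence grid and normalizes by the number of observations, giving the
#' probability of perceiving each attitude valence given the gesture.
#'
#' @param ratings Integer vector of rating levels in `1:length(grid)`.
#' @param grid Valence grid (default [valence_grid()]).
#' @return Probability vector over the grid levels.
#' @export
rating_distribution <- function(ratings, grid = valence_grid()) {
  if (length(ratings) == 0) {
    stop("no ratings supplied for gesture", call. = FALSE)
  }
  k <- length(grid)
  if (!all(ratings %in% seq_len(k))) {
    stop("ratings must be integer levels 1..", k, call. = FALSE)
  }
  tabulate(ratings, nbins = k) / length(ratings)
}

#' Expected valence of a gesture
#'
#' The expected value \eqn{A = \sum_v v\, p(v)} of the perceived attitude,
#' on the \eqn{[-1, 1]} valence axis.
#'
#' @param p_v Probability vector over the grid levels.
#' @param grid Valence grid (default [valence_grid()]).
#' @return Scalar valence in \eqn{[-1, 1]}.
#' @export
valence <- function(p_v, grid = valence_grid()) {
  if (length(p_v) != length(grid)) {
    stop("p_v and grid lengths differ", call. = FALSE)
  }
  check_prob_vector(p_v, "p_v")
  sum(grid * p_v)
}

#' Ambiguity of a gesture (normalized entropy)
#'
#' The normalized Shannon entropy
#' \eqn{H = \sum_v p(v)\log_2 p(v) / \log_2(1/K)} of the rating
#' distribution over its K levels, with \eqn{0\log 0 := 0}. H = 0 for a
#' unanimously perceived gesture, H = 1 when all levels are equally likely.
#'
#' @param p_v Probability vector.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
ambiguity <- function(p_v) {
  check_prob_vector(p_v, "p_v")
  k <- length(p_v)
  nz <- p_v[p_v > 0]
  sum(nz * log2(nz)) / log2(1 / k)
}

#' Per-gesture perception model
#'
#' Bundles one gesture's rating distribution with its derived valence and
#' ambiguity scores.
#'
#' @param gesture_id Integer gesture identifier.
#' @param ratings Integer rating levels for this gesture.
#' @param grid Valence grid.
#' @return Object of class `gesture_model` with fields `gesture_id`, `p_v`,
#'   `valence`, `ambiguity`, `n_ratings`.
#' @export
gesture_model <- function(gesture_id, ratings, grid = valence_grid()) {
  p_v <- rating_distribution(ratings, grid)
  structure(
    list(
      gesture_id = as.integer(gesture_id),
      p_v = p_v,
      valence = valence(p_v, grid),
      ambiguity = ambiguity(p_v),
      n_ratings = length(ratings)
    ),
    class = "gesture_model"
  )
}

#' @export
print.gesture_model <- function(x, ...) {
  cat(sprintf("<gesture_model %d>  n = %d, valence A = %.3f, ambiguity H = %.3f\n",
              x$gesture_id, x$n_ratings, x$valence, x$ambiguity))
  invisible(x)
}

#' Fit gesture models from filtered rating records
#'
#' @param records Filtered rating records (see [filter_raters()]).
#' @param grid Valence grid.
#' @return Named list of [gesture_model()] objects, ordered by gesture id.
#' @export
gesture_models <- function(records, grid = valence_grid()) {
  records <- validate_rating_records(records)
  ids <- sort(unique(records$gesture_id))
  models <- lapply(ids, function(g) {
    gesture_model(g, records$rating[records$gesture_id == g], grid)
  })
  names(models) <- as.character(ids)
  models
}

#' Drop high-ambiguity gestures
#'
#' Removes the gestures judged too ambiguous to convey attitude reliably.
#' The default discard set is gestures 7, 10, 14 and 15.
#'
#' @param models List of gesture models.
#' @param discard_ids Integer vector of gesture ids to drop.
#' @return The retained models.
#' @export
discard_ambiguous <- function(models, discard_ids = c(7L, 10L, 14L, 15L)) {
  ids <- vapply(models, function(m) m$gesture_id, integer(1))
  models[!(ids %in% discard_ids)]
}

#' Relationship-to-gesture probability database (RGPD)
#'
#' Inverts the per-gesture perception distributions \eqn{p(v \mid g)} into
#' a likelihood \eqn{p(g \mid m)} of each gesture given a relationship
#' (attitude) level, via Bayes' rule with a uniform prior over the retained
#' gestures. The relationship grid is the valence grid mapped to
#' \eqn{[0, 1]} by \eqn{m = (v+1)/2}.
#'
#' @param models List of retained gesture models (all on the same grid).
#' @param grid Valence grid.
#' @return Object of class `rgpd`; see [rgpd_database()].
#' @export
build_rgpd <- function(models, grid = valence_grid()) {
  if (length(models) == 0) {
    stop("no gesture models supplied", call. = FALSE)
  }
  pv <- t(vapply(models, function(m) m$p_v, numeric(length(grid))))
  col_mass <- colSums(pv)
  if (any(col_mass <= 0)) {
    stop("likelihood undefined: no gesture has positive probability at ",
         "relationship level(s) ",
         paste(which(col_mass <= 0), collapse = ", "), call. = FALSE)
  }
  lik <- sweep(pv, 2, col_mass, "/")
  rgpd_database(
    likelihood = lik,
    levels = valence_to_relationship(grid),
    gesture_ids = vapply(models, function(m) m$gesture_id, integer(1))
  )
}

#' Construct an RGPD from an explicit likelihood table
#'
#' Lower-level constructor used by [build_rgpd()] and by tests with toy
#' grids. Each column of `likelihood` is the distribution over gestures at
#' one relationship level and must sum to 1.
#'
#' @param likelihood Numeric matrix, gestures in rows, levels in columns.
#' @param levels Ascending relationship levels in \eqn{[0, 1]}.
#' @param gesture_ids Integer ids, one per row.
#' @return Object of class `rgpd` with fields `gesture_ids`, `levels`,
#'   `likelihood`.
#' @export
rgpd_database <- function(likelihood, levels, gesture_ids = seq_len(nrow(likelihood))) {
  likelihood <- as.matrix(likelihood)
  if (nrow(likelihood) != length(gesture_ids)) {
    stop("one gesture id per likelihood row required", call. = FALSE)
  }
  if (ncol(likelihood) != length(levels)) {
    stop("one relationship level per likelihood column required", call. = FALSE)
  }
  if (is.unsorted(levels, strictly = TRUE) || any(levels < 0) || any(levels > 1)) {
    stop("levels must be strictly increasing within [0, 1]", call. = FALSE)
  }
  for (k in seq_along(levels)) {
    check_prob_vector(likelihood[, k], sprintf("p(g | m = %g)", levels[k]))
  }
  dimnames(likelihood) <- list(as.character(gesture_ids),
                               formatC(levels, format = "g"))
  structure(
    list(
      gesture_ids = as.integer(gesture_ids),
      levels = as.numeric(levels),
      likelihood = likelihood
    ),
    class = "rgpd"
  )
}

#' @export
print.rgpd <- function(x, ...) {
  cat(sprintf("<rgpd>  %d gestures x %d relationship levels\n",
              length(x$gesture_ids), length(x$levels)))
  cat("  levels:", paste(formatC(x$levels, format = "g"), collapse = " "), "\n")
  invisible(x)
}

# Likelihood row for a gesture: p(g | m) across all levels.
rgpd_gesture_likelihood <- function(rgpd, gesture_id) {
  i <- match(gesture_id, rgpd$gesture_ids)
  if (is.na(i)) {
    stop("gesture ", gesture_id, " not in RGPD", call. = FALSE)
  }
  rgpd$likelihood[i, ]
}

#' Sample a gesture expressing a relationship value
#'
#' Snaps `m` to the nearest relationship-grid level (midpoint ties snap
#' downward) and draws a gesture from \eqn{p(g \mid m)}. Reproducible under
#' `set.seed()`.
#'
#' @param rgpd An [rgpd_database()] object.
#' @param m Relationship value in \eqn{[0, 1]}.
#' @param n Number of draws.
#' @return Integer vector of gesture ids.
#' @export
sample_gesture <- function(rgpd, m, n = 1) {
  if (length(m) != 1 || is.na(m) || m < 0 || m > 1) {
    stop("m must be a single value in [0, 1]", call. = FALSE)
  }
  k <- snap_to_grid(rgpd$levels, m)
  ids <- rgpd$gesture_ids
  p <- rgpd$likelihood[, k]
  ids[sample.int(length(ids), n, replace = TRUE, prob = p)]
}
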