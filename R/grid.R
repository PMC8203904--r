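#' The 7-level valence grid
#'
#' The seven Likert response levels mapped affinely onto the valence axis
#' \eqn{[-1, 1]}: level 1 ("very negative") becomes -1, level 4 ("neutral")
#' becomes 0, level 7 ("very positive") becomes +1.
#'
#' @return Numeric vector of 7 strictly increasing values, symmetric about 0.
#' @export
#' @examples
#' valence_grid()
valence_grid <- function() {
  seq(-1, 1, length.out = 7)
}

#' Map valence levels to the relationship axis
#'
#' Relationship (attitude) values live on \eqn{[0, 1]}; the map from the
#' valence axis is the affine endpoint-preserving \eqn{m = (v + 1) / 2}.
#'
#' @param v Numeric vector of valences in \eqn{[-1, 1]}.
#' @return Values on \eqn{[0, 1]}.
#' @export
valence_to_relationship <- function(v) {
  (v + 1) / 2
}

#' @rdname valence_to_relationship
#' @param m Numeric vector of relationship values in \eqn{[0, 1]}.
#' @export
relationship_to_valence <- function(m) {
  2 * m - 1
}

# Snap a value to the nearest element of an ascending grid; exact midpoints
# snap downward (the lower level wins).
snap_to_grid <- function(levels, m) {
  vapply(m, function(x) {
    d <- abs(levels - x)
    which(d == min(d))[1L]
  }, integer(1))
}

# shared normalization tolerance for probability-vector validation
.prob_tol <- 1e-9

check_prob_vector <- function(p, what = "p") {
  if (any(p < 0)) {
    stop(sprintf("'%s' has negative entries", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > .prob_tol) {
    stop(sprintf("'%s' does not sum to 1 (got %.12g)", what, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}
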