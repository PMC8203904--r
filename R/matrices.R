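#' Attitude values used to build the study's relationship matrices
#'
#' The fixed multiset of nine attitude values whose placements into the
#' off-diagonal cells generate every candidate relationship matrix. Using
#' one multiset for all matrices keeps their learning complexity identical.
#'
#' @return Numeric vector of 9 values in \eqn{[0, 1]}.
#' @export
default_attitude_values <- function() {
  c(0.27, 0.61, 0.94, 0.16, 0.94, 0.05, 0.5, 0.72, 0.5)
}

# Off-diagonal cell order used to fill a 3x4 matrix from a 9-vector:
# (1,2),(1,3),(1,4),(2,1),(2,3),(2,4),(3,1),(3,2),(3,4)  [row-major].
.cell_rows <- c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L)
.cell_cols <- c(2L, 3L, 4L, 1L, 3L, 4L, 1L, 2L, 4L)
.cell_linear <- .cell_rows + 3L * (.cell_cols - 1L)

.rm_template <- local({
  m <- matrix(0, 3, 4, dimnames = list(paste0("robot", 1:3),
                                       c(paste0("robot", 1:3), "participant")))
  class(m) <- c("relationship_matrix", class(m))
  m
})

#' Build a relationship matrix from its nine off-diagonal values
#'
#' A relationship matrix is 3x4: rows are the acting robots 1..3, columns
#' are the targets (robots 1..3 and the human participant as column 4).
#' The diagonal is identically zero (robots do not relate to themselves)
#' and entries lie in \eqn{[0, 1]}, 0 = strongly negative attitude,
#' 1 = strongly positive.
#'
#' @param values Numeric vector of 9 attitudes, filling the off-diagonal
#'   cells row by row: (1,2),(1,3),(1,4),(2,1),(2,3),(2,4),(3,1),(3,2),(3,4).
#' @return 3x4 matrix of class `relationship_matrix`.
#' @export
#' @examples
#' relationship_matrix(c(0.50, 0.72, 0.50, 0.61, 0.27, 0.05, 0.94, 0.16, 0.94))
relationship_matrix <- function(values) {
  if (length(values) != 9 || any(values < 0) || any(values > 1)) {
    stop("need exactly 9 attitude values in [0, 1]", call. = FALSE)
  }
  m <- .rm_template
  m[.cell_linear] <- values
  m
}

#' The worked-example relationship matrix
#'
#' One particular placement of the default attitude values, used throughout
#' the documentation: its aggregated attitude is `c(1.55, 0.66, 0.99)` and
#' its binary class `c(1, -1, 0)`.
#'
#' @return A [relationship_matrix()].
#' @export
example_relationship_matrix <- function() {
  relationship_matrix(c(0.50, 0.72, 0.50, 0.61, 0.27, 0.05, 0.94, 0.16, 0.94))
}

validate_relationship_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 4L))) {
    stop("relationship matrix must be 3x4", call. = FALSE)
  }
  if (any(diag(m[, 1:3]) != 0)) {
    stop("relationship matrix must have a zero diagonal", call. = FALSE)
  }
  if (any(m < 0) || any(m > 1)) {
    stop("relationship values must lie in [0, 1]", call. = FALSE)
  }
  invisible(m)
}

# All distinct permutations of a multiset, one per row (lexicographic).
multiset_permutations <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) {
    return(matrix(x, 1, 1))
  }
  ux <- unique(x)
  blocks <- lapply(ux, function(v) {
    rest <- x[-match(v, x)]
    sub <- multiset_permutations(rest)
    cbind(rep(v, nrow(sub)), sub, deparse.level = 0)
  })
  do.call(rbind, blocks)
}

#' Enumerate all candidate relationship matrices
#'
#' Yields every distinct placement of the 9-value multiset into the nine
#' off-diagonal cells (duplicated values produce each distinct matrix once).
#'
#' @param values Multiset of 9 attitude values (default
#'   [default_attitude_values()], giving 9!/(2!2!) = 90720 matrices).
#' @return Object of class `matrix_candidates`: an N x 9 matrix, one row of
#'   off-diagonal values per candidate, in the [relationship_matrix()] cell
#'   order. Use [get_candidate()] to materialize row `i`.
#' @export
enumerate_candidates <- function(values = default_attitude_values()) {
  if (length(values) != 9 || any(values < 0) || any(values > 1)) {
    stop("need exactly 9 attitude values in [0, 1]", call. = FALSE)
  }
  perms <- multiset_permutations(values)
  class(perms) <- c("matrix_candidates", class(perms))
  perms
}

#' @export
print.matrix_candidates <- function(x, ...) {
  cat(sprintf("<matrix_candidates>  %d distinct placements of 9 values\n", nrow(x)))
  invisible(x)
}

#' @rdname enumerate_candidates
#' @param candidates A `matrix_candidates` object.
#' @param i Row index.
#' @export
get_candidate <- function(candidates, i) {
  relationship_matrix(candidates[i, ])
}

#' Reciprocity (symmetry) filter
#'
#' A matrix is realistic when no robot-robot pair disagrees by more than
#' `threshold` about each other: \eqn{|M_{ij} - M_{ji}| \le} `threshold` for
#' all robot pairs. The participant column has no reciprocal and is exempt.
#'
#' @param m A [relationship_matrix()].
#' @param threshold Maximum tolerated reciprocal gap (default 0.25).
#' @return Logical.
#' @export
symmetry_ok <- function(m, threshold = 0.25) {
  validate_relationship_matrix(m)
  all(abs(c(m[1, 2] - m[2, 1], m[1, 3] - m[3, 1], m[2, 3] - m[3, 2])) <= threshold)
}

# Vectorized over candidate rows (cell order: see .cell_rows/.cell_cols).
symmetry_ok_rows <- function(candidates, threshold = 0.25) {
  abs(candidates[, 1] - candidates[, 4]) <= threshold &
    abs(candidates[, 2] - candidates[, 7]) <= threshold &
    abs(candidates[, 5] - candidates[, 8]) <= threshold
}

#' Aggregated attitude received by each robot
#'
#' For each robot, the sum of the attitudes the other two robots hold
#' toward it (column sums of the robot-robot submatrix).
#'
#' @param m A [relationship_matrix()].
#' @return Numeric vector of length 3.
#' @export
#' @examples
#' aggregated_attitude(example_relationship_matrix())  # 1.55 0.66 0.99
aggregated_attitude <- function(m) {
  validate_relationship_matrix(m)
  a <- colSums(m[, 1:3])
  names(a) <- paste0("robot", 1:3)
  a
}

aggregated_attitude_rows <- function(candidates) {
  cbind(candidates[, 4] + candidates[, 7],
        candidates[, 1] + candidates[, 8],
        candidates[, 2] + candidates[, 5])
}

#' Binary relationship class of a matrix
#'
#' The coarse class of a matrix: +1 marks the robot receiving the highest
#' aggregated attitude, -1 the lowest, 0 the middle one. A tie for the
#' extreme positions makes the matrix unclassifiable.
#'
#' @param m A [relationship_matrix()].
#' @return Integer vector in \eqn{\{1, 0, -1\}^3}, or `NULL` if the
#'   maximum or minimum aggregated attitude is tied.
#' @export
#' @examples
#' binary_class(example_relationship_matrix())  # 1 -1 0
binary_class <- function(m) {
  a <- aggregated_attitude(m)
  hi <- which(a == max(a))
  lo <- which(a == min(a))
  if (length(hi) != 1 || length(lo) != 1) {
    return(NULL)
  }
  code <- integer(3)
  code[hi] <- 1L
  code[lo] <- -1L
  code
}

# Class labels for candidate rows; NA for tied extremes. With three
# aggregated values, a unique max and min exist iff all three differ.
binary_class_rows <- function(candidates) {
  a <- aggregated_attitude_rows(candidates)
  tied <- a[, 1] == a[, 2] | a[, 1] == a[, 3] | a[, 2] == a[, 3]
  hi <- max.col(a, ties.method = "first")
  lo <- max.col(-a, ties.method = "first")
  lab <- paste(hi, lo, sep = ">")
  lab[tied] <- NA_character_
  lab
}

class_label <- function(code) {
  paste(which(code == 1L), which(code == -1L), sep = ">")
}

# population standard deviation (describes a fixed 3-vector)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Select the study matrices, one per binary class
#'
#' Groups symmetry-filtered, classifiable candidates by their binary class
#' and, within each class, keeps the matrix with the highest population
#' standard deviation of its aggregated-attitude vector — the matrix whose
#' class structure is most pronounced, hence easiest to learn. Ties keep
#' the first candidate in enumeration order.
#'
#' @param candidates A `matrix_candidates` object (see
#'   [enumerate_candidates()]).
#' @param threshold Reciprocity threshold passed to the symmetry filter.
#' @return Named list of [relationship_matrix()] objects, keyed by class
#'   label `"<argmax>><argmin>"`, in enumeration order of first appearance.
#' @export
select_study_matrices <- function(candidates, threshold = 0.25) {
  keep <- symmetry_ok_rows(candidates, threshold)
  cand <- candidates[keep, , drop = FALSE]
  labels <- binary_class_rows(cand)
  ok <- !is.na(labels)
  cand <- cand[ok, , drop = FALSE]
  labels <- labels[ok]
  if (nrow(cand) == 0) {
    return(list())
  }
  a <- aggregated_attitude_rows(cand)
  spread <- apply(a, 1, sd_pop)
  out <- list()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    best <- idx[which.max(spread[idx])]
    out[[lab]] <- relationship_matrix(cand[best, ])
  }
  out
}

# Memoized default selection (the enumeration is deterministic).
.sg_cache <- new.env(parent = emptyenv())

#' The six default study matrices
#'
#' [select_study_matrices()] applied to the full enumeration of
#' [default_attitude_values()], cached after the first call.
#'
#' @return Named list of six relationship matrices.
#' @export
study_matrices <- function() {
  if (is.null(.sg_cache$study_matrices)) {
    .sg_cache$study_matrices <-
      select_study_matrices(enumerate_candidates(default_attitude_values()))
  }
  .sg_cache$study_matrices
}
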