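#' Construct an annual transition matrix over ordered health states
#'
#' A transition matrix is a square, row-stochastic table of annual
#' transition probabilities: rows are origin states, columns are
#' destination states, and a cohort occupancy row vector is propagated by
#' right-multiplication (`occupancy %*% m`). Absorbing states (typically
#' death) must carry an identity row.
#'
#' @param p A square numeric matrix (or object coercible to one) with
#'   identical row and column names giving the ordered state labels.
#' @param absorbing Character vector of absorbing state labels. If `NULL`,
#'   absorbing states are detected as rows with probability 1 of
#'   self-transition.
#' @param tol Absolute numerical tolerance for the row-stochastic checks.
#'
#' @return A validated `transition_matrix` object (a numeric matrix with an
#'   `absorbing` attribute).
#' @seealso [validate_transition_matrix()], [apply_treatment_effect()],
#'   [run_cohort()]
#' @examples
#' m <- transition_matrix(rbind(
#'   mild  = c(mild = 0.9, death = 0.1),
#'   death = c(mild = 0,   death = 1)
#' ))
#' states(m)
#' absorbing_states(m)
#' @export
transition_matrix <- function(p, absorbing = NULL, tol = 1e-9) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) {
    stop("transition matrix must be square, got ", nrow(p), " x ", ncol(p),
         call. = FALSE)
  }
  if (is.null(rownames(p)) && is.null(colnames(p))) {
    stop("transition matrix needs state labels as dimnames", call. = FALSE)
  }
  if (is.null(rownames(p))) rownames(p) <- colnames(p)
  if (is.null(colnames(p))) colnames(p) <- rownames(p)
  if (!identical(rownames(p), colnames(p))) {
    stop("row and column state labels must match (in the same order)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(p)) > 0) {
    stop("duplicated state labels: ",
         paste(unique(rownames(p)[duplicated(rownames(p))]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(p) < 2) stop("a state space needs at least two states", call. = FALSE)
  storage.mode(p) <- "double"
  if (is.null(absorbing)) {
    self_one <- vapply(seq_len(nrow(p)), function(i) {
      abs(p[i, i] - 1) <= tol && all(abs(p[i, -i]) <= tol)
    }, logical(1))
    absorbing <- rownames(p)[self_one]
  } else {
    absorbing <- as.character(absorbing)
    missing <- setdiff(absorbing, rownames(p))
    if (length(missing) > 0) {
      stop("absorbing labels not in the state space: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  m <- structure(p, absorbing = absorbing,
                 class = c("transition_matrix", "matrix", "array"))
  validate_transition_matrix(m, tol = tol)
}

#' State labels and absorbing states of a transition matrix
#'
#' @param m A [transition_matrix()].
#' @return `states()` returns the ordered character vector of state labels;
#'   `absorbing_states()` the subset marked absorbing.
#' @export
states <- function(m) rownames(m)

#' @rdname states
#' @export
absorbing_states <- function(m) attr(m, "absorbing")

#' Validate a transition matrix
#'
#' Checks that every entry lies in \[0, 1\], that every row sums to 1
#' within `tol`, and that every absorbing state's row is the identity row.
#' Errors name the offending row or entry.
#'
#' @inheritParams transition_matrix
#' @param m A `transition_matrix` (or plain named square matrix with an
#'   `absorbing` attribute).
#' @return The matrix, unchanged, if all invariants hold.
#' @export
validate_transition_matrix <- function(m, tol = 1e-9) {
  p <- unclass(m)
  lab <- rownames(p)
  bad <- which(p < -tol | p > 1 + tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("entry outside [0, 1]: p[%s -> %s] = %.6g",
                 lab[i], lab[j], p[i, j]), call. = FALSE)
  }
  sums <- rowSums(p)
  off <- which(abs(sums - 1) > tol)
  if (length(off) > 0) {
    stop(sprintf("row sum != 1: row '%s' sums to %.10g",
                 lab[off[1]], sums[off[1]]), call. = FALSE)
  }
  for (a in absorbing_states(m)) {
    row <- p[a, ]
    if (abs(row[a] - 1) > tol || any(abs(row[setdiff(lab, a)]) > tol)) {
      stop(sprintf("absorbing state '%s' must have an identity row", a),
           call. = FALSE)
    }
  }
  m
}

#' Read a transition matrix from CSV
#'
#' Expects a header row of state labels and a first column of state labels
#' (same order), as written by [utils::write.csv()] with `row.names = TRUE`
#' or by hand.
#'
#' @param path Path to a CSV file.
#' @inheritParams transition_matrix
#' @return A validated [transition_matrix()].
#' @export
read_transition_matrix <- function(path, absorbing = NULL, tol = 1e-9) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(df[[1]])
  p <- as.matrix(df[, -1, drop = FALSE])
  rownames(p) <- labels
  transition_matrix(p, absorbing = absorbing, tol = tol)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", nrow(x), " states: ",
      paste(states(x), collapse = ", "), "\n", sep = "")
  cat("absorbing: ", paste(absorbing_states(x), collapse = ", "), "\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}
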