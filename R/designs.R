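#' Validate a stepped-wedge allocation matrix
#'
#' An SW-CRT allocation matrix is a C x P binary matrix whose entry (i, j)
#' indicates whether cluster i is in the intervention condition in period j.
#' Rows must be monotone: once a cluster switches to the intervention it
#' cannot switch back to control, so within each row every entry after the
#' first 1 is also 1. All-zero rows (clusters that never switch) are
#' admissible.
#'
#' @param M A matrix (or object coercible to one) with entries in \{0, 1\}.
#' @param C,P Optional expected dimensions; if supplied, a mismatch is an
#'   error.
#' @return The validated matrix, as an integer matrix of class
#'   `"sw_allocation"`.
#' @examples
#' validate_allocation(rbind(c(0, 1, 1), c(0, 0, 1)))
#' @export
validate_allocation <- function(M, C = NULL, P = NULL) {
  M <- as.matrix(M)
  if (!is.null(C) && nrow(M) != C)
    stop("allocation matrix has ", nrow(M), " rows; expected C = ", C)
  if (!is.null(P) && ncol(M) != P)
    stop("allocation matrix has ", ncol(M), " columns; expected P = ", P)
  if (!all(M %in% c(0, 1)))
    stop("allocation matrix entries must all be 0 or 1")
  storage.mode(M) <- "integer"
  # no switch-back: a 1 may never be followed by a 0 within a row
  if (ncol(M) > 1) {
    drop <- M[, -ncol(M), drop = FALSE] > M[, -1, drop = FALSE]
    if (any(drop))
      stop("row ", which(apply(drop, 1, any))[1],
           " switches back from intervention to control")
  }
  dimnames(M) <- NULL
  class(M) <- c("sw_allocation", class(M))
  M
}

#' @export
print.sw_allocation <- function(x, ...) {
  cat("SW-CRT allocation matrix (", nrow(x), " clusters x ", ncol(x),
      " periods)\n", sep = "")
  cat(" ", format_allocation(x), "\n")
  invisible(x)
}

#' Parse and format compact allocation strings
#'
#' Allocation matrices are displayed as comma-separated rows of 0/1
#' characters, e.g. `"01111,00111,00011,00001"` for a four-cluster,
#' five-period design with one cluster switching per period.
#'
#' @param s A single string of comma-separated binary rows.
#' @return `parse_allocation()` returns a validated allocation matrix;
#'   `format_allocation()` its compact string form.
#' @examples
#' parse_allocation("0111,0011,0001")
#' @export
parse_allocation <- function(s) {
  rows <- strsplit(trimws(strsplit(s, ",")[[1]]), "")
  n <- lengths(rows)
  if (length(unique(n)) != 1)
    stop("rows have unequal lengths: ", paste(unique(n), collapse = ", "))
  M <- do.call(rbind, lapply(rows, as.integer))
  validate_allocation(M)
}

#' @rdname parse_allocation
#' @param M An allocation matrix.
#' @export
format_allocation <- function(M) {
  paste(apply(M, 1, paste, collapse = ""), collapse = ",")
}

#' Read or write an allocation matrix as CSV
#'
#' Plain CSV with one row per cluster, one 0/1 column per period, no header.
#'
#' @param path File path.
#' @return `read_allocation()` returns a validated allocation matrix.
#' @export
read_allocation <- function(path) {
  M <- as.matrix(utils::read.csv(path, header = FALSE))
  validate_allocation(M)
}

#' @rdname read_allocation
#' @param M An allocation matrix.
#' @export
write_allocation <- function(M, path) {
  utils::write.table(unclass(M), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Switch times of an allocation matrix
#'
#' The switch time of a cluster is the first period in which it is in the
#' intervention condition, or `NA` if it never switches. Because rows are
#' monotone, the switch times determine the matrix completely.
#'
#' @param M A validated allocation matrix.
#' @return Integer vector of length C; `NA` marks never-switching clusters.
#' @export
switch_times <- function(M) {
  apply(M, 1, function(r) {
    w <- which(r == 1L)
    if (length(w)) w[1] else NA_integer_
  })
}

#' Switch-time histogram of an allocation matrix
#'
#' Counts how many clusters switch in each period (plus a "never" bin).
#' Under the exchangeable-cluster mixed model the histogram is a sufficient
#' summary of the design: every design quantity that does not distinguish
#' cluster identities (information, intervention proportion) depends on the
#' matrix only through it.
#'
#' @param M A validated allocation matrix.
#' @return An integer vector of class `"sw_histogram"` and length P + 1:
#'   element t (t = 1..P) counts clusters switching in period t, element
#'   P + 1 counts clusters that never switch. The counts sum to C.
#' @export
switch_time_histogram <- function(M) {
  P <- ncol(M)
  t <- switch_times(M)
  t[is.na(t)] <- P + 1L
  h <- tabulate(t, nbins = P + 1L)
  new_histogram(h, P)
}

new_histogram <- function(counts, P) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == P + 1L)
  names(counts) <- c(seq_len(P), "never")
  class(counts) <- "sw_histogram"
  counts
}

#' @export
print.sw_histogram <- function(x, ...) {
  cat("Switch-time histogram (", sum(x), " clusters):\n", sep = "")
  print(unclass(x)[x > 0])
  invisible(x)
}

histogram_key <- function(h) paste(unclass(h), collapse = ",")

#' Rebuild a canonical allocation matrix from a switch-time histogram
#'
#' Produces the canonical representative of the exchangeability class: rows
#' ordered by ascending switch time (never-switching clusters last), which
#' is the nonincreasing-intervention-time ordering.
#'
#' @param h An `"sw_histogram"`.
#' @return A validated allocation matrix with `sum(h)` rows.
#' @export
histogram_to_matrix <- function(h) {
  P <- length(h) - 1L
  times <- rep(seq_len(P + 1L), unclass(h))
  M <- matrix_from_times(times, P)
  validate_allocation(M)
}

# switch-time vector (never coded P + 1 or NA) -> plain 0/1 matrix
matrix_from_times <- function(times, P) {
  times[is.na(times)] <- P + 1L
  outer(times, seq_len(P), function(t, j) as.integer(j >= t))
}

#' Proportion of cluster-periods spent in the intervention condition
#'
#' @param M A validated allocation matrix.
#' @return The fraction of entries equal to 1, in [0, 1].
#' @examples
#' intervention_proportion(parse_allocation("01111,00111,00011,00011"))  # 0.55
#' @export
intervention_proportion <- function(M) {
  sum(M) / length(M)
}

#' Canonical row ordering of an allocation matrix
#'
#' Rows are permuted so the proportion of time each cluster spends in the
#' intervention condition is nonincreasing from top to bottom (equivalently,
#' ascending switch time with never-switching clusters last). Used to
#' deduplicate enumerated continuation matrices; never used to relabel
#' realized clusters.
#'
#' @param M A validated allocation matrix.
#' @return The row-sorted allocation matrix.
#' @export
canonical_form <- function(M) {
  P <- ncol(M)
  t <- switch_times(M)
  t[is.na(t)] <- P + 1L
  out <- M[order(t), , drop = FALSE]
  class(out) <- class(M)
  out
}

#' Build a continuation matrix at an interim analysis
#'
#' After period p the columns 1..p of the current matrix `X_p` are frozen and
#' clusters already in the intervention at period p must remain in it. The
#' planned roll-out of the remaining control clusters is replaced by a new
#' multiset of switch times over \{p+1, ..., P, never\}. Control clusters in
#' ascending row order receive the new switch times in nondecreasing order
#' (clusters are exchangeable under the model, so this convention does not
#' affect any design quantity; it fixes a reproducible assignment).
#'
#' @param X_p The current allocation matrix.
#' @param p Interim period, 1 <= p <= P - 1.
#' @param new_switch_times Integer vector (multiset) of switch times for the
#'   control clusters, each in \{p+1, ..., P\} or `NA` for never; its length
#'   must equal the number of clusters with `X_p[i, p] == 0`.
#' @return The continuation allocation matrix.
#' @examples
#' X <- parse_allocation("01111,00111,00011,00001")
#' build_continuation(X, 3, c(4, 4))  # both control clusters switch at period 4
#' @export
build_continuation <- function(X_p, p, new_switch_times) {
  P <- ncol(X_p)
  if (p < 1 || p > P - 1) stop("p must be in [1, P-1]")
  ctrl <- which(X_p[, p] == 0L)
  if (length(new_switch_times) != length(ctrl))
    stop("need ", length(ctrl), " switch times (one per control cluster), got ",
         length(new_switch_times))
  tt <- as.integer(new_switch_times)
  if (any(!is.na(tt) & (tt <= p | tt > P)))
    stop("new switch times must lie in {p+1, ..., P} or be NA (never)")
  tt[is.na(tt)] <- P + 1L
  out <- unclass(X_p)
  out[ctrl, ] <- matrix_from_times(sort(tt), P)
  # frozen columns must be preserved exactly (control clusters have 0 there
  # by construction since all new times exceed p)
  out[, seq_len(p)] <- X_p[, seq_len(p)]
  validate_allocation(out)
}
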