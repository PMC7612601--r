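#' Specify a response-adaptive allocation policy
#'
#' The tunables governing interim selection of the continuation matrix. A
#' continuation X' is scored by
#' \deqn{s(X') = w \frac{I_{P|X'}}{\max I} + (1 - w)\frac{b(X')}{\max b},}
#' where I is end-of-trial information (a power surrogate) and b is the
#' patient-benefit score: the probability that a binomial draw over the
#' modifiable cluster-periods, with success probability
#' \eqn{\Phi[(Z - \eta) / \{\gamma (1 - p/P)\}]}, equals the number of
#' modifiable cluster-periods X' spends in the intervention. Larger `eta`
#' shifts preference toward slowing the roll-out; larger `gamma` pulls the
#' success probability toward 1/2 (a steadier roll-out); the 1 - p/P factor
#' sharpens decisions at later interims, when more evidence is available.
#'
#' @param w Weight in [0, 1] on the information term. The extremes 0 and 1
#'   are permitted but flagged with a warning: they leave ties between
#'   designs with equal I (or equal b) unbroken by the data.
#' @param eta Benefit location parameter (any real).
#' @param gamma Benefit scale parameter (> 0).
#' @param restriction `"none"` or `"must_complete_rollout"` (every cluster
#'   must be in the intervention condition by period P, i.e. "never" is not
#'   an admissible new switch time).
#' @param admissible Optional predicate `function(M)` applied to each
#'   candidate matrix after enumeration; return `FALSE` to exclude it. Each
#'   candidate is materialized for the test, so this is expensive for large
#'   candidate sets.
#' @return An object of class `"sw_policy"`.
#' @export
sw_policy <- function(w = 0.5, eta = 0, gamma = 2.5,
                      restriction = c("none", "must_complete_rollout"),
                      admissible = NULL) {
  restriction <- match.arg(restriction)
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (gamma <= 0) stop("gamma must be positive")
  if (w %in% c(0, 1))
    warning("w = ", w, " leaves ties in the score unbroken by the data; ",
            "values strictly inside (0, 1) are usually preferable")
  structure(list(w = w, eta = eta, gamma = gamma, restriction = restriction,
                 admissible = admissible),
            class = "sw_policy")
}

#' @export
print.sw_policy <- function(x, ...) {
  cat("Adaptation policy: w =", x$w, " eta =", x$eta, " gamma =", x$gamma,
      " restriction =", x$restriction, "\n")
  invisible(x)
}

#' Enumerate admissible continuation matrices at an interim analysis
#'
#' At the analysis after period p, columns 1..p are frozen and clusters
#' already in the intervention stay in it; the continuation is determined by
#' a multiset of new switch times over \{p+1, ..., P, never\} for the n
#' control clusters. One candidate per multiset (row permutations of the
#' same multiset give exchangeable matrices and are not enumerated twice),
#' so the candidate count is the combinations-with-repetition number
#' C(n + K - 1, n) with K = P - p + 1 options (P - p under the
#' `must_complete_rollout` restriction). The no-change continuation is
#' always a member, so the set is never empty.
#'
#' Candidates are kept in compact switch-time form; use
#' [candidate_matrix()] to materialize one, and [combined_scores()] to
#' attach I, b and s.
#'
#' @param X_p Current allocation matrix.
#' @param p Interim period, 1 <= p <= P - 1.
#' @param policy An `sw_policy` (supplies the restriction rule).
#' @return An object of class `"sw_candidates"`: a list with the interim
#'   state and, per candidate, the sorted new-switch-time multiset and the
#'   count S of modifiable cluster-periods spent in the intervention.
#' @examples
#' X <- parse_allocation("01111,00111,00011,00001")
#' enumerate_candidates(X, 3, sw_policy())  # the 6 continuations
#' @export
enumerate_candidates <- function(X_p, p, policy = sw_policy()) {
  X_p <- validate_allocation(X_p)
  P <- ncol(X_p)
  C <- nrow(X_p)
  if (p < 1 || p > P - 1) stop("p must lie in [1, P-1]")
  ctrl <- which(X_p[, p] == 0L)
  n <- length(ctrl)
  # switch times of clusters already in the intervention (frozen part)
  tfroz <- switch_times(X_p)
  tfroz <- tfroz[!is.na(tfroz) & tfroz <= p]
  base_h <- tabulate(tfroz, nbins = P + 1L)
  # option codes: periods p+1..P, then P+1 for "never" unless restricted
  opts <- if (policy$restriction == "must_complete_rollout")
    seq.int(p + 1L, P) else c(seq.int(p + 1L, P), P + 1L)
  K <- length(opts)
  if (n == 0L) {
    times <- matrix(integer(0), 0L, 1L)
  } else {
    # multisets of size n from K options via stars and bars, in ascending
    # lexicographic order of the sorted option-index tuple
    cmb <- utils::combn(n + K - 1L, n)
    idx <- cmb - (seq_len(n) - 1L)
    times <- matrix(opts[idx], nrow = n)
  }
  S <- if (n == 0L) 0L else
    as.integer(colSums(matrix(pmax(P + 1L - times, 0L), nrow = n)))
  out <- structure(list(X_p = X_p, p = p, P = P, C = C,
                        control = ctrl, base_h = base_h,
                        restriction = policy$restriction,
                        times = times, S = S,
                        N = (P - p) * n),
                   class = "sw_candidates")
  if (!is.null(policy$admissible)) {
    keep <- vapply(seq_len(ncol(times)),
                   function(k) isTRUE(policy$admissible(candidate_matrix(out, k))),
                   logical(1))
    if (!any(keep)) stop("admissibility predicate excluded every candidate")
    out$times <- out$times[, keep, drop = FALSE]
    out$S <- out$S[keep]
  }
  out
}

#' @export
print.sw_candidates <- function(x, ...) {
  cat("Continuation candidates after period", x$p, "of", x$P, ":",
      n_candidates(x), "matrices (", length(x$control),
      "control clusters )\n")
  invisible(x)
}

#' @rdname enumerate_candidates
#' @param cands An `sw_candidates` object.
#' @export
n_candidates <- function(cands) ncol(cands$times)

#' @rdname enumerate_candidates
#' @param k Candidate index.
#' @export
candidate_matrix <- function(cands, k) {
  tt <- cands$times[, k]
  tt[tt == cands$P + 1L] <- NA_integer_
  build_continuation(cands$X_p, cands$p, tt)
}

#' @rdname enumerate_candidates
#' @export
candidate_histogram <- function(cands, k) {
  h <- cands$base_h
  tt <- cands$times[, k]
  if (length(tt)) h <- h + tabulate(tt, nbins = cands$P + 1L)
  new_histogram(h, cands$P)
}

# log-pmf of the benefit binomial over S = 0..N at interim statistic Z
benefit_log_pmf <- function(N, Z, p, P, policy) {
  if (p >= P) stop("interim period p must be < P")
  q <- stats::pnorm((Z - policy$eta) / (policy$gamma * (1 - p / P)))
  stats::dbinom(0:N, N, q, log = TRUE)
}

#' Patient-benefit score of a continuation
#'
#' b is the probability that S* = S, where S is the number of modifiable
#' cluster-periods the candidate spends in the intervention, and S* follows
#' a binomial over the N = (P - p)(C - #switched) modifiable cluster-periods
#' with success probability \eqn{\Phi[(Z - \eta) / \{\gamma(1 - p/P)\}]}.
#' As Z grows, the mass moves toward fast roll-outs: in the limit the
#' immediate-full-switch candidate scores 1 and all others 0 (and
#' conversely as Z falls). Computed in log space; with no control clusters
#' (N = 0) the unique candidate has b = 1.
#'
#' @param S Count(s) of modifiable intervention cluster-periods, in 0..N.
#' @param N Number of modifiable cluster-periods.
#' @param Z Interim Wald statistic.
#' @param p,P Interim period and trial horizon.
#' @param policy An `sw_policy`.
#' @return Benefit probabilities, same length as `S`.
#' @export
benefit_score <- function(S, N, Z, p, P, policy = sw_policy()) {
  if (any(S < 0 | S > N)) stop("S must lie in 0..N")
  exp(benefit_log_pmf(N, Z, p, P, policy)[S + 1L])
}

# I_{P|X'} for every candidate, computed once per (p, interim state) and
# cached: at a given interim the candidate set and its information vector
# are shared by all replicates, only Z differs.
candidate_information <- function(cands, design, vc, cache = NULL) {
  key <- paste("CI", cands$p, design$m, design$cohort, vc$sigma2_c,
               vc$sigma2_pi, vc$sigma2_s, vc$sigma2_e,
               paste(cands$base_h, collapse = ","), cands$restriction,
               ncol(cands$times), sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  P <- cands$P
  xp <- cluster_crossprods(P, design, vc, cache = cache)
  A_base <- matrix(0, P + 1L, P + 1L)
  for (t in seq_len(P + 1L)) {
    if (cands$base_h[t] > 0) A_base <- A_base + cands$base_h[t] * xp[[t]]
  }
  nc <- ncol(cands$times)
  I <- numeric(nc)
  for (k in seq_len(nc)) {
    A <- A_base
    tt <- cands$times[, k]
    for (t in tt) A <- A + xp[[t]]
    Ainv <- solve_spd(A)
    I[k] <- 1 / Ainv[P + 1L, P + 1L]
  }
  if (!is.null(cache)) cache[[key]] <- I
  I
}

#' Score all continuation candidates
#'
#' Attaches to each candidate its end-of-trial information I, benefit b and
#' combined score s = w I / max(I) + (1 - w) b / max(b). The benefit ratio
#' is formed in log space (max log-pmf subtracted before exponentiation), so
#' scores remain well-defined when the binomial pmf underflows for extreme
#' Z.
#'
#' @param cands An `sw_candidates` object from [enumerate_candidates()].
#' @param Z Interim Wald statistic.
#' @param design An `sw_design`.
#' @param vc `sw_variance` components.
#' @param policy An `sw_policy`.
#' @param cache Optional [new_info_cache()] store.
#' @return `cands` with numeric vectors `I`, `b`, `s` and scalar `q` (the
#'   binomial success probability) added; class gains `"sw_scored"`.
#' @export
combined_scores <- function(cands, Z, design, vc, policy = sw_policy(),
                            cache = NULL) {
  if (n_candidates(cands) == 0L) stop("empty candidate set")
  I <- candidate_information(cands, design, vc, cache)
  lp <- benefit_log_pmf(cands$N, Z, cands$p, cands$P, policy)
  lb <- lp[cands$S + 1L]
  brat <- exp(lb - max(lb))
  cands$q <- stats::pnorm((Z - policy$eta) /
                            (policy$gamma * (1 - cands$p / cands$P)))
  cands$I <- I
  cands$b <- exp(lb)
  cands$s <- policy$w * I / max(I) + (1 - policy$w) * brat
  cands$Z <- Z
  cands$w <- policy$w
  class(cands) <- unique(c("sw_scored", class(cands)))
  cands
}

#' Select the continuation matrix
#'
#' Returns the s-maximizing candidate. Exact ties (measure-zero in Z, but
#' possible at w = 0 or 1) are broken in favor of larger information, then
#' by the earlier position in the enumeration order.
#'
#' @param scored A scored candidate set from [combined_scores()].
#' @return The selected allocation matrix, with the winning index attached
#'   as attribute `"index"`.
#' @export
select_continuation <- function(scored) {
  if (is.null(scored$s)) stop("candidates have not been scored")
  k <- select_index(scored$s, scored$I)
  M <- candidate_matrix(scored, k)
  attr(M, "index") <- k
  M
}

select_index <- function(s, I) {
  best <- which(s == max(s))
  if (length(best) > 1L) best <- best[I[best] == max(I[best])]
  best[1L]
}

#' Scored candidate table for one interim analysis
#'
#' End-to-end convenience: enumerate the continuations of `X_p` after period
#' p, score them at interim statistic Z, and return a data frame with one
#' row per candidate (compact matrix string, S, I, b, s) plus a logical
#' `selected` column. Reproduces the worked-example table for a four-cluster
#' five-period trial in under a second.
#'
#' @param X_p Current allocation matrix.
#' @param p Interim period.
#' @param Z Interim Wald statistic.
#' @param design An `sw_design`.
#' @param vc `sw_variance` components.
#' @param policy An `sw_policy`.
#' @param cache Optional information cache.
#' @return A data frame of scored candidates.
#' @export
score_candidates <- function(X_p, p, Z, design, vc, policy = sw_policy(),
                             cache = NULL) {
  cands <- enumerate_candidates(X_p, p, policy)
  scored <- combined_scores(cands, Z, design, vc, policy, cache)
  k <- select_index(scored$s, scored$I)
  nc <- n_candidates(scored)
  mats <- vapply(seq_len(nc),
                 function(j) format_allocation(candidate_matrix(scored, j)),
                 character(1))
  data.frame(matrix = mats, S = scored$S, I = scored$I, b = scored$b,
             s = scored$s, selected = seq_len(nc) == k)
}
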