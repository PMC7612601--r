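#' Variance components of the SW-CRT linear mixed model
#'
#' The data-generating and analysis model for a measurement k in cluster i,
#' period j is
#' \deqn{Y_{ijk} = \beta_j + \theta X_{ij} + c_i + \pi_{ij} + s_{ik} +
#'   \epsilon_{ijk},}
#' with independent normal random effects: cluster effect c_i with variance
#' `sigma2_c`, cluster-period effect \eqn{\pi_{ij}} with variance
#' `sigma2_pi`, individual effect s_ik with variance `sigma2_s` (closed
#' cohorts only; identically 0 for cross-sectional sampling, where each
#' period measures new individuals), and residual with variance `sigma2_e`.
#' All components are treated as known throughout: the GLS analysis uses the
#' true covariance, with no REML/ML estimation.
#'
#' @param sigma2_c,sigma2_pi,sigma2_s Nonnegative variances.
#' @param sigma2_e Strictly positive residual variance.
#' @return An object of class `"sw_variance"`.
#' @export
sw_variance <- function(sigma2_c = 0, sigma2_pi = 0, sigma2_s = 0, sigma2_e) {
  if (sigma2_e <= 0) stop("sigma2_e must be strictly positive")
  if (min(sigma2_c, sigma2_pi, sigma2_s) < 0)
    stop("variance components must be nonnegative")
  structure(list(sigma2_c = sigma2_c, sigma2_pi = sigma2_pi,
                 sigma2_s = sigma2_s, sigma2_e = sigma2_e),
            class = "sw_variance")
}

#' @export
print.sw_variance <- function(x, ...) {
  cat("Variance components: sigma2_c =", x$sigma2_c,
      " sigma2_pi =", x$sigma2_pi, " sigma2_s =", x$sigma2_s,
      " sigma2_e =", x$sigma2_e, "\n")
  invisible(x)
}

#' Specify a stepped-wedge trial design
#'
#' Bundles the dimensions of the trial, the sampling scheme, the initially
#' planned allocation matrix, the interim-analysis schedule, and the error
#' rate / effect size targets.
#'
#' @param C Number of clusters (> 1).
#' @param P Number of time periods (> 1).
#' @param m Measurements per cluster-period (> 0).
#' @param cohort `"cross_sectional"` (new individuals each period) or
#'   `"closed_cohort"` (the same m individuals measured every period).
#' @param X_init The initially planned C x P allocation matrix.
#' @param interim_periods Strictly increasing integers in [1, P-1]: the
#'   periods after which interim analyses are performed. May be empty for a
#'   fixed (non-adaptive) design.
#' @param alpha One-sided type-I error rate target in (0, 1).
#' @param beta Type-II error rate target in (0, 1).
#' @param delta Effect size (> 0) at which power 1 - beta is sought.
#' @return An object of class `"sw_design"`.
#' @export
sw_design <- function(C, P, m, cohort = c("cross_sectional", "closed_cohort"),
                      X_init, interim_periods = integer(0),
                      alpha = 0.05, beta = 0.2, delta) {
  cohort <- match.arg(cohort)
  if (C <= 1 || P <= 1 || m < 1) stop("need C > 1, P > 1, m >= 1")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("alpha and beta must lie in (0, 1)")
  if (delta <= 0) stop("delta must be positive")
  X_init <- validate_allocation(X_init, C, P)
  ip <- as.integer(interim_periods)
  if (length(ip) && (any(diff(ip) <= 0) || any(ip < 1) || any(ip > P - 1)))
    stop("interim_periods must be strictly increasing integers in [1, P-1]")
  structure(list(C = C, P = P, m = m, cohort = cohort, X_init = X_init,
                 interim_periods = ip, alpha = alpha, beta = beta,
                 delta = delta),
            class = "sw_design")
}

#' @export
print.sw_design <- function(x, ...) {
  cat("SW-CRT design: C =", x$C, " P =", x$P, " m =", x$m,
      paste0("(", x$cohort, ")"), "\n")
  cat("  X_init:", format_allocation(x$X_init), "\n")
  cat("  interims after periods:",
      if (length(x$interim_periods)) paste(x$interim_periods, collapse = ", ")
      else "none", "\n")
  cat("  alpha =", x$alpha, " beta =", x$beta, " delta =", x$delta, "\n")
  invisible(x)
}

#' Design matrix of the fixed effects
#'
#' One row per observation up to period p: p period-indicator columns
#' followed by the intervention-exposure column. The period effects absorb
#' the intercept, so no separate intercept column is included and the matrix
#' has p + 1 columns. With `collapse = TRUE` (the default computational
#' representation) observations are cluster-period means and there is one
#' row per cluster-period; otherwise m rows per cluster-period.
#'
#' @param X Allocation matrix.
#' @param p Analysis period, 1 <= p <= P.
#' @param m Measurements per cluster-period (used when `collapse = FALSE`).
#' @param collapse Use the cluster-period-mean representation?
#' @return A numeric matrix with p + 1 columns; rows are ordered by cluster,
#'   then period (then measurement).
#' @export
build_design_matrix <- function(X, p, m = 1, collapse = TRUE) {
  P <- ncol(X)
  if (p < 1 || p > P) stop("p must lie in [1, P]")
  m_eff <- if (collapse) 1L else as.integer(m)
  per <- diag(p)
  blocks <- lapply(seq_len(nrow(X)), function(i) {
    Di <- cbind(per, X[i, seq_len(p)])
    Di[rep(seq_len(p), each = m_eff), , drop = FALSE]
  })
  out <- do.call(rbind, blocks)
  dimnames(out) <- NULL
  out
}

#' Within-cluster covariance block
#'
#' Covariance matrix of one cluster's responses through `P_obs` periods
#' under the mixed model. At observation level the block is
#' (P_obs * m) square; at the collapsed (cluster-period mean) level it is
#' P_obs square with
#' \deqn{Cov(\bar Y_{ij}, \bar Y_{ij'}) = \sigma^2_c + [closed]\,
#'   \sigma^2_s/m + [j = j'] (\sigma^2_\pi + \sigma^2_\epsilon / m).}
#' For cross-sectional sampling individuals differ across periods, so the
#' individual variance contributes only within a period (and is 0 by
#' definition of `sw_variance`). The collapse is exact for equal m: GLS
#' estimates, information and Wald statistics agree between the two
#' representations. The full covariance of the trial is block-diagonal over
#' clusters and does not depend on the allocation matrix.
#'
#' @param vc `sw_variance` components.
#' @param cohort `"cross_sectional"` or `"closed_cohort"`.
#' @param P_obs Number of observed periods.
#' @param m Measurements per cluster-period.
#' @param collapse Return the P_obs-square block for cluster-period means?
#' @return A symmetric positive-definite matrix.
#' @export
build_covariance <- function(vc, cohort = c("cross_sectional", "closed_cohort"),
                             P_obs, m, collapse = TRUE) {
  cohort <- match.arg(cohort)
  if (cohort == "cross_sectional" && vc$sigma2_s != 0)
    stop("cross-sectional designs must have sigma2_s = 0")
  J <- matrix(1, P_obs, P_obs)
  if (collapse) {
    shared <- vc$sigma2_c + if (cohort == "closed_cohort") vc$sigma2_s / m else 0
    within <- vc$sigma2_pi +
      (vc$sigma2_e + if (cohort == "cross_sectional") vc$sigma2_s else 0) / m
    return(shared * J + diag(within, P_obs))
  }
  Jm <- matrix(1, m, m)
  V <- vc$sigma2_c * kronecker(J, Jm) +
    vc$sigma2_pi * kronecker(diag(P_obs), Jm) +
    vc$sigma2_e * diag(P_obs * m)
  if (cohort == "closed_cohort") {
    # same individual k measured in every period
    V <- V + vc$sigma2_s * kronecker(J, diag(m))
  } else {
    V <- V + vc$sigma2_s * diag(P_obs * m)
  }
  V
}

# threshold above which the normal-equations matrix is declared singular
.cond_tol <- 1e12

solve_spd <- function(A) {
  if (rcond(A) < 1 / .cond_tol)
    stop("singular GLS system: intervention column is collinear with the ",
         "period effects (condition number exceeds ", .cond_tol, ")")
  chol2inv(chol(A))
}

#' Generalized least squares under known covariance
#'
#' Solves the GLS normal equations
#' \eqn{\hat\theta = (D'\Sigma^{-1}D)^{-1} D'\Sigma^{-1} Y} by Cholesky
#' whitening (no explicit inverse of \eqn{\Sigma}), exploiting the
#' block-diagonal structure over clusters: `Sigma` may be given either as
#' the full covariance or as the single per-cluster block, which is then
#' recycled over the `length(y) / nrow(Sigma)` clusters.
#'
#' The intervention effect is the last coordinate of the coefficient vector;
#' its variance is the corresponding diagonal entry of
#' \eqn{(D'\Sigma^{-1}D)^{-1}}, the Wald statistic is
#' \eqn{Z = \hat\theta / \sqrt{Var(\hat\theta)}} and the information is
#' \eqn{I = 1 / Var(\hat\theta)}.
#'
#' @param D Design matrix (last column = intervention exposure).
#' @param Sigma Covariance: full, or one cluster block.
#' @param y Response vector.
#' @return A list of class `"sw_gls"`: `theta_hat`, `var_theta`, `Z`, `I`,
#'   and `beta_hat` (the period-effect estimates).
#' @export
gls_fit <- function(D, Sigma, y) {
  n <- length(y)
  b <- nrow(Sigma)
  if (n %% b != 0) stop("length(y) is not a multiple of the block size")
  if (nrow(D) != n) stop("nrow(D) must equal length(y)")
  R <- chol(Sigma)
  nblk <- n / b
  Dw <- matrix(0, n, ncol(D))
  yw <- numeric(n)
  for (g in seq_len(nblk)) {
    idx <- (g - 1L) * b + seq_len(b)
    Dw[idx, ] <- backsolve(R, D[idx, , drop = FALSE], transpose = TRUE)
    yw[idx] <- backsolve(R, y[idx], transpose = TRUE)
  }
  A <- crossprod(Dw)
  Ainv <- solve_spd(A)
  coef <- drop(Ainv %*% crossprod(Dw, yw))
  q <- ncol(D)
  var_theta <- Ainv[q, q]
  theta_hat <- coef[q]
  structure(list(theta_hat = theta_hat, var_theta = var_theta,
                 Z = theta_hat / sqrt(var_theta), I = 1 / var_theta,
                 beta_hat = coef[-q]),
            class = "sw_gls")
}

#' @export
print.sw_gls <- function(x, ...) {
  cat("GLS fit: theta_hat =", signif(x$theta_hat, 5),
      " se =", signif(sqrt(x$var_theta), 5),
      " Z =", signif(x$Z, 5), " I =", signif(x$I, 6), "\n")
  invisible(x)
}

# --- information ------------------------------------------------------------

# Per-switch-time single-cluster cross-product matrices D_t' V^{-1} D_t at
# analysis period p. Clusters with switch time > p (including "never") share
# the all-control exposure pattern, stored at slot p + 1. Cached because the
# blocks depend only on (p, m, cohort, vc), never on the data.
cluster_crossprods <- function(p, design, vc, m = design$m, cache = NULL) {
  key <- paste("xp", p, m, design$cohort, vc$sigma2_c, vc$sigma2_pi,
               vc$sigma2_s, vc$sigma2_e, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  V <- build_covariance(vc, design$cohort, p, m, collapse = TRUE)
  Vi <- chol2inv(chol(V))
  per <- diag(p)
  out <- lapply(seq_len(p + 1L), function(t) {
    x <- as.numeric(seq_len(p) >= t)  # t = p + 1 gives the never-exposed row
    D <- cbind(per, x)
    crossprod(D, Vi %*% D)
  })
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# normal-equations matrix A = D' Sigma^{-1} D for a switch-time histogram
info_crossprod <- function(h, p, design, vc, m = design$m, cache = NULL) {
  xp <- cluster_crossprods(p, design, vc, m, cache)
  A <- matrix(0, p + 1L, p + 1L)
  for (t in seq_along(h)) {
    if (h[t] > 0) A <- A + h[t] * xp[[min(t, p + 1L)]]
  }
  A
}

#' Information for the intervention effect
#'
#' The information \eqn{I_{p|X}} is the reciprocal of the GLS variance of
#' the intervention-effect estimator using data through period p under
#' allocation X: \eqn{I = 1 / [(D'\Sigma^{-1}D)^{-1}]_{qq}}. It depends on
#' the design only, never on response data, and is invariant to permuting
#' cluster rows.
#'
#' @param X Allocation matrix.
#' @param p Analysis period.
#' @param design An `sw_design` (supplies m and cohort type).
#' @param vc `sw_variance` components.
#' @param m Measurements per cluster-period (defaults to `design$m`).
#' @return Positive scalar information.
#' @export
information <- function(X, p, design, vc, m = design$m) {
  h <- switch_time_histogram(validate_allocation(X))
  A <- info_crossprod(h, p, design, vc, m)
  Ainv <- solve_spd(A)
  1 / Ainv[p + 1L, p + 1L]
}

#' Create a cache for information computations
#'
#' A mutable store shared across interim analyses, replicates and effect
#' sizes of a simulation: information depends on the design only, so every
#' distinct switch-time histogram is solved once.
#'
#' @return An environment used as a key-value cache.
#' @export
new_info_cache <- function() new.env(parent = emptyenv())

#' Information from a switch-time histogram, with caching
#'
#' Assembles \eqn{D'\Sigma^{-1}D} as the histogram-weighted sum of
#' per-switch-time single-cluster cross-product blocks and extracts the
#' information. Equals [information()] on the expanded matrix to numerical
#' tolerance; results are cached by histogram.
#'
#' @param h An `"sw_histogram"` (counts over switch periods 1..P and never).
#' @param design,vc,m As in [information()].
#' @param p Analysis period (defaults to the trial horizon `design$P`).
#' @param cache Optional cache from [new_info_cache()].
#' @return Positive scalar information.
#' @export
information_from_histogram <- function(h, design, vc, cache = NULL,
                                       p = design$P, m = design$m) {
  if (sum(h) != design$C) stop("histogram total must equal C")
  key <- paste("I", p, m, design$cohort, vc$sigma2_c, vc$sigma2_pi,
               vc$sigma2_s, vc$sigma2_e, histogram_key(h), sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  A <- info_crossprod(h, p, design, vc, m, cache)
  Ainv <- solve_spd(A)
  I <- 1 / Ainv[p + 1L, p + 1L]
  if (!is.null(cache)) cache[[key]] <- I
  I
}

# A^{-1} and per-switch-time GLS weight vectors at period p for a histogram:
# theta_hat = sum_i w[[t_i]] . ybar_i(1:p). Used by the simulation engine.
gls_weights <- function(h, p, design, vc, cache = NULL) {
  key <- paste("W", p, design$m, design$cohort, vc$sigma2_c, vc$sigma2_pi,
               vc$sigma2_s, vc$sigma2_e, histogram_key(h), sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  A <- info_crossprod(h, p, design, vc, cache = cache)
  Ainv <- solve_spd(A)
  V <- build_covariance(vc, design$cohort, p, design$m, collapse = TRUE)
  Vi <- chol2inv(chol(V))
  aq <- Ainv[, p + 1L]
  per <- diag(p)
  w <- lapply(seq_len(p + 1L), function(t) {
    x <- as.numeric(seq_len(p) >= t)
    D <- cbind(per, x)
    drop(Vi %*% (D %*% aq))
  })
  out <- list(weights = w, I = 1 / Ainv[p + 1L, p + 1L])
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Power of the fixed stepped-wedge design
#'
#' Normal-approximation power with known variance components, following the
#' Hussey-Hughes approach: the final Wald statistic is N(theta * sqrt(I_P),
#' 1), rejected when it exceeds the upper-alpha normal quantile, so
#' \deqn{power = \Phi(\theta \sqrt{I_{P|X}} - z_{1-\alpha}).}
#'
#' @param design An `sw_design`; the initially planned matrix is used.
#' @param vc `sw_variance` components.
#' @param m Measurements per cluster-period (defaults to `design$m`).
#' @param theta Effect size (defaults to `design$delta`).
#' @return Power in (0, 1).
#' @export
hh_power <- function(design, vc, m = design$m, theta = design$delta) {
  I <- information(design$X_init, design$P, design, vc, m = m)
  stats::pnorm(theta * sqrt(I) - stats::qnorm(1 - design$alpha))
}

#' Smallest per-cluster-period sample size achieving the target power
#'
#' Increments m from 1 until `hh_power()` at effect `design$delta` reaches
#' `1 - design$beta`. Information is bounded as m grows (the cluster and
#' cluster-period variances do not average away), so the search may be
#' infeasible; this is detected from the limiting covariance and reported
#' as an error.
#'
#' @param design An `sw_design`.
#' @param vc `sw_variance` components.
#' @param max_m Search bound.
#' @return The required integer m.
#' @examples
#' \dontrun{required_m(tds("TDS2")$design, tds("TDS2")$vc)  # 70}
#' @export
required_m <- function(design, vc, max_m = 100000) {
  target <- 1 - design$beta
  for (m in seq_len(max_m)) {
    if (hh_power(design, vc, m = m) >= target) return(m)
  }
  stop("power does not reach ", target, " for any m <= ", max_m,
       "; the design is infeasible for these variance components")
}
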