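#' Specify a simulation scenario
#'
#' Bundles a trial design, variance components, adaptation policy, true
#' intervention effect, replicate count and seed into a validated
#' configuration for the Monte-Carlo engine.
#'
#' @param design An `sw_design`.
#' @param vc An `sw_variance`.
#' @param policy An `sw_policy`.
#' @param theta True intervention effect used to generate responses.
#' @param n_reps Number of replicate trials (>= 1).
#' @param seed Master RNG seed; each replicate uses an independent
#'   L'Ecuyer-CMRG substream derived from it, so results are bit-identical
#'   for a given (seed, config) and invariant to execution order.
#' @param analysis_mode `"collapsed"` (cluster-period means; exact for equal
#'   m and the default) or `"observation_level"` (full individual-level
#'   generation and GLS; retained to validate the collapse on small
#'   problems).
#' @return An object of class `"sw_scenario"`.
#' @export
sw_scenario <- function(design, vc, policy = sw_policy(), theta = design$delta,
                        n_reps = 10000, seed = 1,
                        analysis_mode = c("collapsed", "observation_level")) {
  stopifnot(inherits(design, "sw_design"), inherits(vc, "sw_variance"),
            inherits(policy, "sw_policy"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  analysis_mode <- match.arg(analysis_mode)
  structure(list(design = design, vc = vc, policy = policy, theta = theta,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 analysis_mode = analysis_mode),
            class = "sw_scenario")
}

#' @export
print.sw_scenario <- function(x, ...) {
  cat("SW-CRT simulation scenario (theta =", x$theta, ", n_reps =", x$n_reps,
      ", seed =", x$seed, ")\n")
  print(x$design); print(x$vc); print(x$policy)
  invisible(x)
}

#' Built-in trial design scenarios
#'
#' Three reference scenarios spanning typical SW-CRT configurations:
#'
#' * `TDS1` — cross-sectional, C = 20 clusters, P = 9 periods; three
#'   clusters switch in each of periods 2-5 and two in each of periods 6-9;
#'   `sigma2_c` = 1/9, `sigma2_e` = 1; alpha = 0.05, beta = 0.2,
#'   delta = 0.24, giving m = 7 per cluster-period. Default interim
#'   analyses after periods 3 and 6 (single-interim variants \{3\}, \{4\},
#'   \{5\} are also studied).
#' * `TDS2` — cross-sectional, C = 4, P = 5, one cluster switching per
#'   period 2-5, modelled on a trial of communication-skills training for
#'   doctors; `sigma2_c` = 0.02, `sigma2_e` = 0.51; alpha = 0.05,
#'   beta = 0.1, delta = 0.2, giving m = 70. Default interim after
#'   period 3 (variant \{2, 3, 4\}).
#' * `TDS3` — closed cohort, C = 12, P = 4, four clusters switching per
#'   period 2-4, modelled on a school-based self-esteem programme measured
#'   on the Rosenberg scale; `sigma2_c` = 7.425, `sigma2_pi` = 0.825,
#'   `sigma2_s` = 11.725, `sigma2_e` = 5.025, m = 10; alpha = 0.025,
#'   beta = 0.2, delta = 2. Default interim after period 2 (variant
#'   \{2, 3\}).
#'
#' @param name `"TDS1"`, `"TDS2"` or `"TDS3"`.
#' @param interim_periods Override the default interim schedule.
#' @param policy An `sw_policy` (default w = 1/2, eta = 0, gamma = 2.5).
#' @param theta True effect (defaults to the design's delta).
#' @param n_reps,seed Passed to [sw_scenario()].
#' @return An `sw_scenario`.
#' @examples
#' tds("TDS2")$design
#' @export
tds <- function(name = c("TDS1", "TDS2", "TDS3"), interim_periods = NULL,
                policy = sw_policy(), theta = NULL, n_reps = 10000, seed = 1) {
  name <- match.arg(name)
  spec <- switch(name,
    TDS1 = list(C = 20, P = 9, m = 7, cohort = "cross_sectional",
                switch_counts = c(rep(2:5, each = 3), rep(6:9, each = 2)),
                vc = sw_variance(sigma2_c = 1 / 9, sigma2_e = 1),
                alpha = 0.05, beta = 0.2, delta = 0.24, interims = c(3L, 6L)),
    TDS2 = list(C = 4, P = 5, m = 70, cohort = "cross_sectional",
                switch_counts = 2:5,
                vc = sw_variance(sigma2_c = 0.02, sigma2_e = 0.51),
                alpha = 0.05, beta = 0.1, delta = 0.2, interims = 3L),
    TDS3 = list(C = 12, P = 4, m = 10, cohort = "closed_cohort",
                switch_counts = rep(2:4, each = 4),
                vc = sw_variance(sigma2_c = 7.425, sigma2_pi = 0.825,
                                 sigma2_s = 11.725, sigma2_e = 5.025),
                alpha = 0.025, beta = 0.2, delta = 2, interims = 2L))
  X <- validate_allocation(matrix_from_times(spec$switch_counts, spec$P))
  design <- sw_design(C = spec$C, P = spec$P, m = spec$m, cohort = spec$cohort,
                      X_init = X,
                      interim_periods = if (is.null(interim_periods))
                        spec$interims else interim_periods,
                      alpha = spec$alpha, beta = spec$beta, delta = spec$delta)
  sw_scenario(design, spec$vc, policy,
              theta = if (is.null(theta)) spec$delta else theta,
              n_reps = n_reps, seed = seed)
}

#' Draw the random effects of one replicate trial
#'
#' All random effects for all C clusters and P periods are drawn up front,
#' before any allocation decision: responses then depend on the realized
#' allocation only through the fixed part theta * X_ij, so the adaptive
#' procedure cannot influence the noise it will observe (decisions depend on
#' the data only through the interim Wald statistic).
#'
#' In the default collapsed mode the draw is at cluster-period-mean
#' granularity, which is exact for equal m: the mean of cluster i in period
#' j is c_i + pi_ij + (closed cohorts) s-bar_i + eps-bar_ij, with s-bar_i ~
#' N(0, sigma2_s / m) shared across periods and eps-bar_ij ~ N(0,
#' sigma2_e / m) (cross-sectional sampling redraws the individual/residual
#' aggregate each period). In observation-level mode the full individual
#' arrays are drawn and their means returned alongside.
#'
#' @param config An `sw_scenario`. Uses the current RNG state.
#' @return A list with `noise` (C x P matrix of cluster-period mean noise)
#'   and, in observation-level mode, `noise_obs` (C x P x m array).
#' @export
draw_random_effects <- function(config) {
  d <- config$design
  vc <- config$vc
  C <- d$C; P <- d$P; m <- d$m
  closed <- d$cohort == "closed_cohort"
  ci <- stats::rnorm(C, 0, sqrt(vc$sigma2_c))
  pij <- matrix(stats::rnorm(C * P, 0, sqrt(vc$sigma2_pi)), C, P)
  if (config$analysis_mode == "observation_level") {
    sik <- matrix(stats::rnorm(C * m, 0, sqrt(vc$sigma2_s)), C, m)
    eps <- array(stats::rnorm(C * P * m, 0, sqrt(vc$sigma2_e)), c(C, P, m))
    noise_obs <- array(0, c(C, P, m))
    for (k in seq_len(m)) {
      s_k <- if (closed) sik[, k] else 0  # cross-sectional has sigma2_s = 0
      noise_obs[, , k] <- ci + pij + s_k + eps[, , k]
    }
    noise <- apply(noise_obs, c(1, 2), mean)
    return(list(noise = noise, noise_obs = noise_obs))
  }
  if (closed) {
    sbar <- stats::rnorm(C, 0, sqrt(vc$sigma2_s / m))
    ebar <- matrix(stats::rnorm(C * P, 0, sqrt(vc$sigma2_e / m)), C, P)
    noise <- ci + sbar + pij + ebar
  } else {
    ebar <- matrix(stats::rnorm(C * P, 0,
                                sqrt((vc$sigma2_s + vc$sigma2_e) / m)), C, P)
    noise <- ci + pij + ebar
  }
  list(noise = noise)
}

#' Realize responses for given cluster-periods
#'
#' Deterministic given the random-effects draw and the allocation: the mean
#' response of cluster i in period j is theta * X_ij plus the drawn noise
#' (period effects beta_j are 0 throughout the simulations; with known
#' covariance the distribution of the GLS Wald statistic does not depend on
#' them).
#'
#' @param draw Output of [draw_random_effects()].
#' @param X Allocation matrix.
#' @param periods Integer vector of period indices.
#' @param theta True intervention effect.
#' @return C x length(periods) matrix of cluster-period mean responses.
#' @export
realize_responses <- function(draw, X, periods, theta) {
  if (max(periods) > ncol(X)) stop("requested period beyond the horizon P")
  draw$noise[, periods, drop = FALSE] +
    theta * X[, periods, drop = FALSE]
}

# GLS fit of the intervention effect on data through period p, collapsed
# path: per-cluster weight vectors looked up by the switch-time histogram.
fit_through_period <- function(Ybar, X, p, config, cache) {
  d <- config$design
  if (config$analysis_mode == "observation_level") {
    stop("observation-level fitting requires fit_observations()")
  }
  tt <- switch_times(X)
  tt[is.na(tt)] <- d$P + 1L
  h <- new_histogram(tabulate(tt, nbins = d$P + 1L), d$P)
  gw <- gls_weights(h, p, d, config$vc, cache)
  th <- 0
  for (i in seq_len(d$C)) {
    th <- th + sum(gw$weights[[min(tt[i], p + 1L)]] * Ybar[i, seq_len(p)])
  }
  list(theta_hat = th, I = gw$I, Z = th * sqrt(gw$I))
}

# observation-level GLS through period p (validation path, small problems)
fit_observations <- function(noise_obs, X, p, config, theta) {
  d <- config$design
  y <- numeric(0)
  for (i in seq_len(d$C)) {
    yi <- noise_obs[i, seq_len(p), ] + theta * X[i, seq_len(p)]
    y <- c(y, as.vector(t(yi)))  # period-major, measurement within period
  }
  D <- build_design_matrix(X, p, m = d$m, collapse = FALSE)
  V <- build_covariance(config$vc, d$cohort, p, d$m, collapse = FALSE)
  fit <- gls_fit(D, V, y)
  list(theta_hat = fit$theta_hat, I = fit$I, Z = fit$Z)
}

# enumeration cached by the frozen part of X_p (its switch-time vector
# through p determines the candidate set up to the identity of the control
# rows, which build_continuation fixes)
cached_candidates <- function(X_p, p, policy, cache) {
  if (is.null(cache) || !is.null(policy$admissible))
    return(enumerate_candidates(X_p, p, policy))
  tt <- switch_times(X_p)
  tt[is.na(tt)] <- ncol(X_p) + 1L
  key <- paste("EN", p, policy$restriction, paste(tt, collapse = ","),
               sep = "|")
  if (is.null(cache[[key]])) cache[[key]] <- enumerate_candidates(X_p, p, policy)
  cache[[key]]
}

#' Run one replicate of the response-adaptive trial
#'
#' Periods 1..p1 use the initially planned matrix. At each interim analysis
#' after period p: the Wald statistic Z is computed by GLS on the data so
#' far, the admissible continuations are enumerated and scored, and the
#' s-maximizing continuation becomes the planned matrix for the remaining
#' periods. After period P the final GLS determines rejection of the
#' one-sided null at level alpha.
#'
#' @param config An `sw_scenario`.
#' @param draw A replicate draw from [draw_random_effects()]; if `NULL`, one
#'   is drawn from the current RNG state.
#' @param cache An information cache ([new_info_cache()]), shared across
#'   replicates for speed.
#' @return A list of class `"sw_trial"`: `reject`, `theta_hat`, `Z_final`,
#'   `X_final`, `proportion`, `interim_Z`.
#' @export
run_adaptive_trial <- function(config, draw = NULL, cache = NULL) {
  if (is.null(draw)) draw <- draw_random_effects(config)
  d <- config$design
  X <- d$X_init
  interim_Z <- numeric(length(d$interim_periods))
  Ybar <- realize_responses(draw, X, seq_len(d$P), config$theta)
  for (l in seq_along(d$interim_periods)) {
    p <- d$interim_periods[l]
    f <- if (config$analysis_mode == "observation_level")
      fit_observations(draw$noise_obs, X, p, config, config$theta)
    else fit_through_period(Ybar, X, p, config, cache)
    interim_Z[l] <- f$Z
    cands <- cached_candidates(X, p, config$policy, cache)
    scored <- combined_scores(cands, f$Z, d, config$vc, config$policy, cache)
    X_new <- select_continuation(scored)
    if (!identical(unclass(X_new), unclass(X))) {
      X <- X_new
      # past columns are frozen, so realized responses change only in the
      # not-yet-conducted periods
      Ybar[, (p + 1):d$P] <- realize_responses(draw, X, (p + 1):d$P,
                                               config$theta)
    }
  }
  final <- if (config$analysis_mode == "observation_level")
    fit_observations(draw$noise_obs, X, d$P, config, config$theta)
  else fit_through_period(Ybar, X, d$P, config, cache)
  structure(list(reject = final$Z > stats::qnorm(1 - d$alpha),
                 theta_hat = final$theta_hat, Z_final = final$Z,
                 X_final = X, proportion = intervention_proportion(X),
                 interim_Z = interim_Z),
            class = "sw_trial")
}

#' Run one replicate of the conventional fixed trial
#'
#' No interim adaptation: the initially planned matrix is used throughout
#' and the same final rejection rule is applied.
#'
#' @inheritParams run_adaptive_trial
#' @return An `"sw_trial"` list as in [run_adaptive_trial()].
#' @export
run_fixed_trial <- function(config, draw = NULL, cache = NULL) {
  if (is.null(draw)) draw <- draw_random_effects(config)
  d <- config$design
  X <- d$X_init
  final <- if (config$analysis_mode == "observation_level")
    fit_observations(draw$noise_obs, X, d$P, config, config$theta)
  else fit_through_period(realize_responses(draw, X, seq_len(d$P),
                                            config$theta),
                          X, d$P, config, cache)
  structure(list(reject = final$Z > stats::qnorm(1 - d$alpha),
                 theta_hat = final$theta_hat, Z_final = final$Z,
                 X_final = X, proportion = intervention_proportion(X),
                 interim_Z = numeric(0)),
            class = "sw_trial")
}

#' Simulate replicate trials and estimate operating characteristics
#'
#' Runs `config$n_reps` independent replicates (adaptive by default) under
#' per-replicate L'Ecuyer-CMRG substreams derived from `config$seed`, and
#' summarizes them with [estimate_operating_characteristics()]. The
#' information cache is shared across replicates (and may be passed in to be
#' shared across scenarios or effect sizes: information never depends on
#' theta).
#'
#' @param config An `sw_scenario`.
#' @param adaptive Run the response-adaptive procedure (`TRUE`) or the fixed
#'   design (`FALSE`)?
#' @param cache Optional shared [new_info_cache()].
#' @return An `"sw_oc"` object; the per-replicate results are attached as
#'   the data-frame element `$results`.
#' @examples
#' \donttest{
#' oc <- sw_simulate(tds("TDS2", n_reps = 200), adaptive = TRUE)
#' oc$erp
#' }
#' @export
sw_simulate <- function(config, adaptive = TRUE, cache = new_info_cache()) {
  d <- config$design
  n <- config$n_reps
  reject <- logical(n); theta_hat <- numeric(n); proportion <- numeric(n)
  interim_Z <- matrix(NA_real_, n,
                      if (adaptive) length(d$interim_periods) else 0L)
  X_sum <- matrix(0, d$C, d$P)
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(config$seed)
  s <- get(".Random.seed", globalenv())
  for (r in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    assign(".Random.seed", s, globalenv())
    draw <- draw_random_effects(config)
    res <- if (adaptive) run_adaptive_trial(config, draw, cache)
    else run_fixed_trial(config, draw, cache)
    reject[r] <- res$reject
    theta_hat[r] <- res$theta_hat
    proportion[r] <- res$proportion
    if (ncol(interim_Z)) interim_Z[r, ] <- res$interim_Z
    X_sum <- X_sum + res$X_final
  }
  results <- data.frame(reject = reject, theta_hat = theta_hat,
                        proportion = proportion)
  oc <- estimate_operating_characteristics(results, config$theta,
                                           mean_X = X_sum / n)
  oc$interim_Z <- interim_Z
  oc$config <- config
  oc$adaptive <- adaptive
  oc
}

#' Operating characteristics of a set of replicate trials
#'
#' Summarizes replicate results into the standard metrics: the empirical
#' rejection probability (ERP; at theta = 0 the empirical type-I error rate,
#' at theta = delta the empirical power), the empirical average and standard
#' deviation of the proportion of cluster-periods spent in the intervention
#' condition (EACP, ESDCP), the empirical bias (EB) and root-mean-square
#' error (ERMSE) of the final effect estimate, and the empirical pmf of the
#' realized intervention proportion. Binomial / standard-error-of-the-mean
#' Monte-Carlo standard errors are attached for ERP, EACP and EB.
#'
#' @param results A data frame with columns `reject`, `theta_hat`,
#'   `proportion` (one row per replicate), or a list of `"sw_trial"`
#'   objects.
#' @param theta_true True effect used to generate the replicates.
#' @param mean_X Optional elementwise mean of the final allocation matrices.
#' @return A list of class `"sw_oc"` with elements `erp`, `eacp`, `esdcp`,
#'   `eb`, `ermse`, `prop_pmf`, `mean_X`, `mc_se`, `n_reps`, `results`.
#' @export
estimate_operating_characteristics <- function(results, theta_true,
                                               mean_X = NULL) {
  if (!is.data.frame(results)) {
    results <- data.frame(
      reject = vapply(results, `[[`, logical(1), "reject"),
      theta_hat = vapply(results, `[[`, numeric(1), "theta_hat"),
      proportion = vapply(results, `[[`, numeric(1), "proportion"))
  }
  if (!nrow(results)) stop("no replicate results supplied")
  n <- nrow(results)
  erp <- mean(results$reject)
  eacp <- mean(results$proportion)
  esdcp <- stats::sd(results$proportion)
  if (n == 1) esdcp <- 0
  err <- results$theta_hat - theta_true
  eb <- mean(err)
  ermse <- sqrt(mean(err^2))
  tab <- table(results$proportion) / n
  prop_pmf <- data.frame(proportion = as.numeric(names(tab)),
                         probability = as.numeric(tab))
  mc_se <- list(erp = sqrt(erp * (1 - erp) / n),
                eacp = esdcp / sqrt(n),
                eb = stats::sd(err) / sqrt(n))
  structure(list(erp = erp, eacp = eacp, esdcp = esdcp, eb = eb,
                 ermse = ermse, prop_pmf = prop_pmf, mean_X = mean_X,
                 mc_se = mc_se, theta_true = theta_true, n_reps = n,
                 results = results),
            class = "sw_oc")
}

#' @export
print.sw_oc <- function(x, ...) {
  cat("Operating characteristics over", x$n_reps, "replicates (theta =",
      x$theta_true, "):\n")
  cat(sprintf("  ERP   %.4f (MC SE %.4f)\n", x$erp, x$mc_se$erp))
  cat(sprintf("  EACP  %.2f%% (MC SE %.2f pp)\n", 100 * x$eacp,
              100 * x$mc_se$eacp))
  cat(sprintf("  ESDCP %.2f pp\n", 100 * x$esdcp))
  cat(sprintf("  EB    %+.5f (MC SE %.5f)\n", x$eb, x$mc_se$eb))
  cat(sprintf("  ERMSE %.5f\n", x$ermse))
  invisible(x)
}
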