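test_that("design matrix has the documented layout", {
  X <- validate_allocation(rbind(c(0L, 1L)))
  D <- build_design_matrix(X, 2)
  expect_equal(D, rbind(c(1, 0, 0), c(0, 1, 1)))
  # column count is always p + 1; exposure count matches the matrix
  M6 <- tds2_continuations()$M6
  D6 <- build_design_matrix(M6, 5)
  expect_equal(ncol(D6), 6)
  expect_equal(sum(D6[, 6]), 11)  # M6 has 11 intervention cluster-periods
})

test_that("covariance blocks follow the mixed-model formulas", {
  vc <- sw_variance(sigma2_e = 0.8)
  expect_equal(build_covariance(vc, "cross_sectional", 3, 4),
               diag(0.2, 3))
  vc2 <- sw_variance(sigma2_c = 0.02, sigma2_e = 0.51)
  expect_equal(build_covariance(vc2, "cross_sectional", 5, 70),
               0.02 * matrix(1, 5, 5) + diag(0.51 / 70, 5))
  # closed cohort: the individual effect persists across periods
  vc3 <- sw_variance(sigma2_c = 1, sigma2_pi = 0.5, sigma2_s = 2,
                     sigma2_e = 0.9)
  V <- build_covariance(vc3, "closed_cohort", 4, 10)
  expect_equal(V[1, 2], 1 + 2 / 10)
  expect_equal(V[1, 1], 1 + 2 / 10 + 0.5 + 0.9 / 10)
  expect_error(build_covariance(vc3, "cross_sectional", 4, 10), "sigma2_s")
  # observation level, cross-sectional: no cross-period individual term
  Vo <- build_covariance(vc2, "cross_sectional", 2, 3, collapse = FALSE)
  expect_equal(dim(Vo), c(6, 6))
  expect_equal(Vo[1, 4], 0.02)          # different periods
  expect_equal(Vo[1, 2], 0.02)          # same period, different individual
  expect_equal(Vo[1, 1], 0.02 + 0.51)
})

test_that("GLS with identity covariance coincides with ordinary least squares", {
  set.seed(11)
  X <- rand_allocation(4, 5)
  D <- build_design_matrix(X, 5)
  y <- rnorm(nrow(D))
  fit <- gls_fit(D, diag(5), y)
  ols <- lm.fit(D, y)
  expect_equal(fit$theta_hat, unname(ols$coefficients[6]), tolerance = 1e-10)
  expect_equal(fit$beta_hat, unname(ols$coefficients[1:5]), tolerance = 1e-10)
})

test_that("GLS recovers a noise-free signal and the closed-form information", {
  X <- validate_allocation(rbind(c(0L, 1L), c(0L, 0L)))
  D <- build_design_matrix(X, 2)
  theta0 <- 0.7
  y <- drop(D %*% c(0.1, -0.2, theta0))
  fit <- gls_fit(D, diag(2), y)
  expect_equal(fit$theta_hat, theta0, tolerance = 1e-10)
  # two clusters, two periods, unit variance: hand-computed information 0.5
  expect_equal(fit$I, 0.5, tolerance = 1e-12)
  expect_equal(fit$Z, fit$theta_hat / sqrt(fit$var_theta))
})

test_that("a collinear intervention column raises a singularity error", {
  # every cluster switches at the same period: exposure = period indicator
  X <- validate_allocation(rbind(c(0L, 1L, 1L), c(0L, 1L, 1L)))
  d <- small_design(X, m = 5)
  vc <- sw_variance(sigma2_c = 0.1, sigma2_e = 1)
  expect_error(information(X, 3, d, vc), "singular")
})

test_that("worked-example information values are reproduced", {
  d <- tds("TDS2")$design
  vc <- tds("TDS2")$vc
  ref <- tds2_reference()
  Ms <- tds2_continuations()
  for (k in 1:6) {
    expect_lt(abs(information(Ms[[k]], 5, d, vc) - ref$I[k]), 0.05)
  }
})

test_that("information is permutation-invariant and nondecreasing in p", {
  d <- tds("TDS2")$design
  vc <- tds("TDS2")$vc
  set.seed(3)
  for (M in tds2_continuations()) {
    perm <- validate_allocation(M[sample(nrow(M)), , drop = FALSE])
    expect_equal(information(perm, 5, d, vc), information(M, 5, d, vc),
                 tolerance = 1e-12)
    Ip <- vapply(3:5, function(p) information(M, p, d, vc), numeric(1))
    expect_true(all(diff(Ip) > -1e-10))
  }
})

test_that("histogram-assembled information equals the brute-force oracle", {
  set.seed(19)
  cache <- new_info_cache()
  for (r in 1:30) {
    closed <- runif(1) < 0.5
    X <- rand_allocation(5, 4)
    m <- sample(2:6, 1)
    d <- small_design(X, m, cohort = if (closed) "closed_cohort"
                      else "cross_sectional")
    vc <- rand_variance(closed)
    h <- switch_time_histogram(X)
    Ih <- information_from_histogram(h, d, vc, cache)
    Id <- information_bruteforce(X, 4, d, vc)
    expect_equal(Ih, Id, tolerance = 1e-10)
    # cache hit is bit-identical
    expect_identical(information_from_histogram(h, d, vc, cache), Ih)
  }
})

test_that("collapsed and observation-level GLS agree on theta, Z and I", {
  set.seed(23)
  for (r in 1:10) {
    closed <- r %% 2 == 0
    X <- rand_allocation(4, 4)
    m <- sample(2:5, 1)
    cohort <- if (closed) "closed_cohort" else "cross_sectional"
    vc <- rand_variance(closed)
    p <- sample(2:4, 1)
    tt <- switch_times(X)
    eff <- pmin(replace(tt, is.na(tt), 99L), p + 1L)
    if (length(unique(eff)) < 2 || all(eff > p)) {
      # keep the truncated design nonsingular
      X <- validate_allocation(matrix_from_times_test(c(2L, rep(p + 1L, 3)), 4))
    }
    y <- rnorm(nrow(X) * p * m)
    D_obs <- build_design_matrix(X, p, m, collapse = FALSE)
    V_obs <- build_covariance(vc, cohort, p, m, collapse = FALSE)
    fit_obs <- gls_fit(D_obs, V_obs, y)
    ybar <- colMeans(matrix(y, nrow = m))  # means within cluster-period
    D_col <- build_design_matrix(X, p)
    V_col <- build_covariance(vc, cohort, p, m)
    fit_col <- gls_fit(D_col, V_col, ybar)
    expect_equal(fit_col$theta_hat, fit_obs$theta_hat, tolerance = 1e-8)
    expect_equal(fit_col$Z, fit_obs$Z, tolerance = 1e-8)
    expect_equal(fit_col$I, fit_obs$I, tolerance = 1e-8)
  }
})

test_that("power is alpha at the null and increases with m and theta", {
  sc <- tds("TDS2")
  expect_equal(hh_power(sc$design, sc$vc, theta = 0), 0.05, tolerance = 1e-12)
  pw_m <- vapply(c(10, 30, 70, 120), function(m)
    hh_power(sc$design, sc$vc, m = m), numeric(1))
  expect_true(all(diff(pw_m) > 0))
  pw_t <- vapply(c(0.05, 0.1, 0.2, 0.3), function(th)
    hh_power(sc$design, sc$vc, theta = th), numeric(1))
  expect_true(all(diff(pw_t) > 0))
  expect_gte(hh_power(sc$design, sc$vc, m = 70, theta = 0.2), 0.90)
})

test_that("required_m is the smallest m meeting the power target", {
  for (name in c("TDS1", "TDS2")) {
    sc <- tds(name)
    m <- required_m(sc$design, sc$vc)
    expect_gte(hh_power(sc$design, sc$vc, m = m), 1 - sc$design$beta)
    expect_lt(hh_power(sc$design, sc$vc, m = m - 1), 1 - sc$design$beta)
  }
})
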