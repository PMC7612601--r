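test_that("policy validation flags extreme weights and bad parameters", {
  expect_error(sw_policy(w = 1.2), "w must lie")
  expect_error(sw_policy(gamma = 0), "gamma")
  expect_warning(sw_policy(w = 1), "ties")
  expect_warning(sw_policy(w = 0), "ties")
})

test_that("enumeration yields the illustration's six continuations", {
  cands <- enumerate_candidates(tds2_X(), 3, sw_policy())
  expect_equal(n_candidates(cands), 6)
  got <- sort(vapply(1:6, function(k)
    format_allocation(candidate_matrix(cands, k)), character(1)))
  want <- sort(unname(vapply(tds2_continuations(), format_allocation,
                             character(1))))
  expect_equal(got, want)
  expect_equal(sort(cands$S), c(0L, 1L, 2L, 2L, 3L, 4L))
  expect_equal(cands$N, 4L)
})

test_that("the four-cluster illustration has 6 unrestricted and 3 restricted continuations", {
  X2 <- parse_allocation("1111,0111,0011,0001")
  expect_equal(n_candidates(enumerate_candidates(X2, 2, sw_policy())), 6)
  pol <- sw_policy(restriction = "must_complete_rollout")
  cands <- enumerate_candidates(X2, 2, pol)
  expect_equal(n_candidates(cands), 3)
  # under the restriction every candidate completes the roll-out
  for (k in 1:3)
    expect_true(all(candidate_matrix(cands, k)[, 4] == 1))
})

test_that("candidate counts match the combinations-with-repetition formula", {
  # large case: 14 control clusters, 7 switch-time options
  t1 <- tds("TDS1")
  cands <- enumerate_candidates(t1$design$X_init, 3, sw_policy())
  expect_equal(n_candidates(cands), choose(20, 14))
  expect_equal(n_candidates(cands), 38760)
  # small cases: formula against explicit enumeration of all assignments
  set.seed(31)
  for (r in 1:10) {
    P <- sample(3:6, 1)
    X <- rand_allocation(5, P)
    p <- sample(seq_len(P - 1), 1)
    n <- sum(X[, p] == 0)
    K <- P - p + 1
    cands <- enumerate_candidates(X, p, sw_policy())
    expect_equal(n_candidates(cands), choose(n + K - 1, n))
    if (n > 0) {
      # oracle: all K^n labelled assignments, deduplicated as multisets
      grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
      multi <- unique(apply(t(apply(grid, 1, sort)), 1, paste, collapse = "-"))
      expect_equal(n_candidates(cands), length(multi))
    }
  }
})

test_that("an admissibility hook prunes candidates", {
  pol <- sw_policy(admissible = function(M) intervention_proportion(M) <= 0.5)
  cands <- enumerate_candidates(tds2_X(), 3, pol)
  # proportions run 0.35..0.55 over the six candidates; 0.55 is pruned
  expect_equal(n_candidates(cands), 5)
  for (k in seq_len(5))
    expect_lte(intervention_proportion(candidate_matrix(cands, k)), 0.5)
  pol_none <- sw_policy(admissible = function(M) FALSE)
  expect_error(enumerate_candidates(tds2_X(), 3, pol_none), "excluded every")
})

test_that("benefit scores reproduce the worked example and binomial structure", {
  pol <- sw_policy(eta = 0, gamma = 2.5)
  ref <- tds2_reference()
  b <- benefit_score(ref$S, 4, Z = 1, p = 3, P = 5, pol)
  expect_equal(b, dbinom(ref$S, 4, pnorm(1)), tolerance = 1e-12)
  expect_lt(max(abs(b - ref$b)), 5e-4)  # printed to three decimals
  expect_equal(b[3], b[4])  # equal S implies equal b
  # the pmf over S = 0..N sums to one for any Z
  for (Z in c(-3, 0, 1.7)) {
    expect_equal(sum(benefit_score(0:8, 8, Z, p = 2, P = 6, pol)), 1,
                 tolerance = 1e-12)
  }
  expect_error(benefit_score(5, 4, 1, 3, 5, pol), "0..N")
})

test_that("combined scores and selection reproduce the worked example", {
  sc <- tds("TDS2")
  cands <- enumerate_candidates(tds2_X(), 3, sc$policy)
  scored <- combined_scores(cands, Z = 1, sc$design, sc$vc, sc$policy)
  ref <- tds2_reference()
  key <- vapply(seq_len(6), function(k)
    format_allocation(candidate_matrix(scored, k)), character(1))
  ord <- match(vapply(tds2_continuations(), format_allocation, character(1)),
               key)
  expect_lt(max(abs(scored$I[ord] - ref$I)), 0.05)
  expect_lt(max(abs(scored$b[ord] - ref$b)), 5e-4)
  expect_lt(max(abs(scored$s[ord] - ref$s)), 1e-3)
  sel <- select_continuation(scored)
  expect_equal(format_allocation(sel),
               format_allocation(tds2_continuations()$M6))
  expect_equal(intervention_proportion(sel), 0.55)
  # scores lie in [0, 1]; some candidate attains first term w, another 1 - w
  expect_true(all(scored$s >= 0 & scored$s <= 1))
  imax <- which.max(scored$I)
  expect_equal(scored$s[imax] -
                 (1 - sc$policy$w) * scored$b[imax] / max(scored$b),
               sc$policy$w, tolerance = 1e-12)
})

test_that("a singleton candidate set scores 1 regardless of w", {
  # restriction + one control cluster and one remaining option
  X <- parse_allocation("0111,0011,0011,0001")
  pol <- sw_policy(w = 0.3, restriction = "must_complete_rollout")
  cands <- enumerate_candidates(X, 3, pol)
  expect_equal(n_candidates(cands), 1)
  sc <- tds("TDS2")
  d <- small_design(X, m = 10)
  scored <- combined_scores(cands, Z = 0.4, d, sc$vc, pol)
  expect_equal(scored$s, 1)
})

test_that("extreme interim statistics select the frozen or full-switch design", {
  sc <- tds("TDS2")
  cands <- enumerate_candidates(tds2_X(), 3, sc$policy)
  full <- format_allocation(build_continuation(tds2_X(), 3, c(4, 4)))
  froz <- format_allocation(build_continuation(tds2_X(), 3, c(NA, NA)))
  sel_hi <- select_continuation(
    combined_scores(cands, Z = 20, sc$design, sc$vc, sc$policy))
  sel_lo <- select_continuation(
    combined_scores(cands, Z = -20, sc$design, sc$vc, sc$policy))
  expect_equal(format_allocation(sel_hi), full)
  expect_equal(format_allocation(sel_lo), froz)
})

test_that("selected intervention exposure is nondecreasing in Z", {
  sc <- tds("TDS2")
  cands <- enumerate_candidates(tds2_X(), 3, sc$policy)
  S_sel <- vapply(seq(-5, 5, by = 0.25), function(Z) {
    scored <- combined_scores(cands, Z, sc$design, sc$vc, sc$policy)
    scored$S[raswcrt:::select_index(scored$s, scored$I)]
  }, integer(1))
  expect_true(all(diff(S_sel) >= 0))
})

test_that("a near-unit information weight always selects the I-maximizing design", {
  sc <- tds("TDS2")
  pol <- sw_policy(w = 999 / 1000)
  cands <- enumerate_candidates(tds2_X(), 3, pol)
  for (Z in seq(-5, 5, by = 1)) {
    scored <- combined_scores(cands, Z, sc$design, sc$vc, pol)
    expect_equal(scored$I[raswcrt:::select_index(scored$s, scored$I)],
                 max(scored$I))
  }
})

test_that("selected continuations respect the admissibility constraints", {
  set.seed(47)
  sc <- tds("TDS2")
  for (r in 1:10) {
    X <- rand_allocation(4, 5)
    tt <- switch_times(X)
    eff <- pmin(replace(tt, is.na(tt), 99L), 4L)
    if (length(unique(eff)) < 2 || all(eff > 3)) next
    cands <- enumerate_candidates(X, 3, sc$policy)
    scored <- combined_scores(cands, rnorm(1), sc$design, sc$vc, sc$policy)
    sel <- select_continuation(scored)
    expect_identical(sel[, 1:3], X[, 1:3])
    switched <- which(X[, 3] == 1)
    expect_true(all(sel[switched, 4:5] == 1))
  }
})
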