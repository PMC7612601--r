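# Shared fixtures and independent oracles for the test suite.

# the four-cluster, five-period illustration and its six continuations
tds2_X <- function() parse_allocation("01111,00111,00011,00001")

tds2_continuations <- function() {
  list(M1 = parse_allocation("01111,00111,00000,00000"),
       M2 = parse_allocation("01111,00111,00001,00000"),
       M3 = parse_allocation("01111,00111,00001,00001"),
       M4 = parse_allocation("01111,00111,00011,00000"),
       M5 = parse_allocation("01111,00111,00011,00001"),
       M6 = parse_allocation("01111,00111,00011,00011"))
}

# printed reference values for the illustration (Z = 1, eta = 0, gamma = 2.5,
# w = 0.5, interim after period 3)
tds2_reference <- function() {
  data.frame(name = paste0("M", 1:6),
             S = c(0L, 1L, 2L, 2L, 3L, 4L),
             I = c(188.5, 224.5, 204.7, 222.2, 215.2, 169.8),
             b = c(0.001, 0.013, 0.107, 0.107, 0.378, 0.501),
             s = c(0.420, 0.513, 0.563, 0.601, 0.856, 0.878))
}

# random monotone allocation with a nonsingular design (at least two
# distinct exposure patterns, at least one exposed cluster-period)
rand_allocation <- function(C, P) {
  repeat {
    tt <- sample(2:(P + 1), C, replace = TRUE)
    if (length(unique(tt)) >= 2 && any(tt <= P)) break
  }
  validate_allocation(matrix_from_times_test(tt, P))
}

new_histogram_for_test <- function(counts, P) {
  raswcrt:::new_histogram(counts, P)
}

matrix_from_times_test <- function(tt, P) {
  outer(tt, seq_len(P), function(t, j) as.integer(j >= t))
}

rand_variance <- function(closed = FALSE) {
  sw_variance(sigma2_c = runif(1, 0, 0.5), sigma2_pi = runif(1, 0, 0.3),
              sigma2_s = if (closed) runif(1, 0, 0.5) else 0,
              sigma2_e = runif(1, 0.2, 1.5))
}

# brute-force information: observation-level design and covariance, dense
# solve; independent of the collapsed/histogram production path
information_bruteforce <- function(X, p, design, vc, m = design$m) {
  D <- build_design_matrix(X, p, m = m, collapse = FALSE)
  V1 <- build_covariance(vc, design$cohort, p, m, collapse = FALSE)
  Sig <- kronecker(diag(nrow(X)), V1)
  A <- t(D) %*% solve(Sig) %*% D
  1 / solve(A)[p + 1, p + 1]
}

small_design <- function(X, m, cohort = "cross_sectional",
                         alpha = 0.05, beta = 0.2, delta = 0.2) {
  sw_design(C = nrow(X), P = ncol(X), m = m, cohort = cohort, X_init = X,
            alpha = alpha, beta = beta, delta = delta)
}
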