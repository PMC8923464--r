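# Fisher/CRLB machinery against closed forms and independent oracles.

test_that("constant-rate Fisher information equals the closed form T/r", {
  # one fiber, r(t) = theta spikes/s, T = 0.1 s, theta = 100 -> I = 1e-3
  dt <- 1e-4
  nt <- 1001  # times 0..0.1
  rate_fn <- function(theta) fake_response(matrix(theta, 1, nt), dt = dt)
  ps <- param_spec("r", "sp/s", step = 0.1)
  I <- fisher_matrix(rate_fn, ps, 100)
  expect_equal(I[1, 1], 0.1 / 100, tolerance = 1e-12)
  # fibers-per-CF multiplier scales information linearly
  rate_fn_k <- function(theta) fake_response(matrix(theta, 1, nt), dt = dt,
                                             k = 72)
  expect_equal(fisher_matrix(rate_fn_k, ps, 100)[1, 1], 72 * 0.1 / 100)
})

test_that("Fisher matrix matches an analytic-derivative oracle to 1%", {
  # r(t) = R0 (1 + m cos(2 pi F t)); information about F
  dt <- 2e-5
  t <- seq(0, 0.1, by = dt)
  R0 <- 120; m <- 0.6
  rate_fn <- function(theta) fake_response(
    matrix(R0 * (1 + m * cos(2 * pi * theta * t)), 1), dt = dt)
  ps <- param_spec("F", "Hz", step = 0.05)
  I_fd <- fisher_matrix(rate_fn, ps, 700)[1, 1]
  # oracle: analytic dr/dF = -R0 m 2 pi t sin(2 pi F t), high-res quadrature
  r <- R0 * (1 + m * cos(2 * pi * 700 * t))
  dr <- -R0 * m * 2 * pi * t * sin(2 * pi * 700 * t)
  w <- c(diff(t) / 2, 0) + c(0, diff(t) / 2)
  I_an <- sum(w * dr^2 / r)
  expect_equal(I_fd, I_an, tolerance = 0.01)
})

test_that("parameters the rate ignores contribute zero rows and columns", {
  dt <- 1e-4
  t <- seq(0, 0.1, by = dt)
  rate_fn <- function(theta) fake_response(
    matrix(100 + theta[1] * cos(2 * pi * 50 * t), 1), dt = dt)
  ps <- param_spec(c("amp", "dummy"), step = c(0.1, 0.1),
                   prior_sd = c(Inf, Inf))
  I <- fisher_matrix(rate_fn, ps, c(20, 5))
  expect_gt(I[1, 1], 0)
  expect_equal(I[1, 2], 0)
  expect_equal(I[2, 2], 0)
  # a phase-like parameter that a constant-rate stub cannot see
  const_fn <- function(theta) fake_response(matrix(100, 1, 201))
  I0 <- fisher_matrix(const_fn, ps, c(20, 5))
  expect_equal(max(abs(I0)), 0)
})

test_that("CRLB inversion matches two-parameter algebra and a brute-force inverse", {
  # n = 2, zero cross-term: reduces to the scalar bound
  EI <- matrix(c(4, 0, 0, 9), 2)
  A <- diag(c(0, 1 / 0.5^2))
  expect_equal(crlb_variance(EI, A, 1), 1 / 4)
  # n = 2 with cross-sensitivity: explicit two-parameter expression
  EI2 <- matrix(c(4, 1.5, 1.5, 9), 2)
  nu2 <- 0.25
  v <- crlb_variance(EI2, diag(c(0, 1 / nu2)), 1)
  expect_equal(1 / v, EI2[1, 1] - EI2[1, 2]^2 / (EI2[2, 2] + 1 / nu2))
  # random SPD 3x3 + diagonal prior vs independent adjugate inversion
  set.seed(31)
  for (rep in 1:5) {
    B <- matrix(rnorm(9), 3)
    EI3 <- B %*% t(B) + diag(3) * 0.1
    A3 <- diag(runif(3, 0, 2)); A3[1, 1] <- 0
    M <- EI3 + A3
    adj <- function(M) { # cofactor expansion, independent of solve()
      co <- matrix(0, 3, 3)
      for (i in 1:3) for (j in 1:3) {
        co[i, j] <- (-1)^(i + j) * det(M[-i, -j, drop = FALSE])
      }
      t(co) / det(M)
    }
    expect_equal(crlb_variance(EI3, A3, 1), adj(M)[1, 1], tolerance = 1e-10)
  }
  expect_error(crlb_variance(matrix(0, 2, 2), diag(0, 2), 1), "singular")
})

test_that("nuisance roving is a penalty that vanishes as the prior tightens", {
  EI <- matrix(c(4, 1.2, 1.2, 3), 2)
  v_fixed <- 1 / EI[1, 1]
  # adding a roved parameter with cross-sensitivity never helps
  for (nu in c(0.1, 1, 10, 1000)) {
    v <- crlb_variance(EI, diag(c(0, 1 / nu^2)), 1)
    expect_gte(v, v_fixed - 1e-12)
  }
  # prior limit: nu^2 -> 0 recovers the fixed-parameter bound
  expect_equal(crlb_variance(EI, diag(c(0, 1e12)), 1), v_fixed,
               tolerance = 1e-6)
})

test_that("thresholds are square roots of the variance bound", {
  expect_equal(threshold_from_variance(4)$jnd, 2)
  expect_equal(threshold_from_variance(0.25)$jnd, 0.5)
  expect_equal(threshold_from_variance(2.8^2, baseline = 280)$jnd_rel_pct, 1)
  expect_error(threshold_from_variance(-1), "positive")
  expect_error(threshold_from_variance(0), "positive")
})

test_that("the rate-place transform averages over time and loses information", {
  const <- fake_response(matrix(80, 2, 101))
  expect_equal(rate_place_transform(const)$rates, const$rates)
  mod <- fake_response(matrix(100 * (1 + 0.5 * sin(seq(0, 20 * pi,
                                                       length.out = 2001))),
                              1), dt = 5e-5)
  rp <- rate_place_transform(mod)
  expect_equal(unique(round(as.vector(rp$rates), 6)),
               round(anpitch:::trapz(mod$times, mod$rates[1, ]) /
                       diff(range(mod$times)), 6))
  # data-processing inequality over randomized responses
  set.seed(77)
  dt <- 1e-4
  t <- seq(0, 0.1, by = dt)
  for (rep in 1:8) {
    a <- runif(1, 5, 50); ph <- runif(1, 0, 2 * pi); f <- runif(1, 30, 300)
    rate_fn <- function(theta) fake_response(
      matrix(100 + theta * 0.3 + a * sin(2 * pi * f * t + ph) *
               sqrt(theta / 50), 1), dt = dt)
    ps <- param_spec("x", step = 0.05)
    I_all <- fisher_matrix(rate_fn, ps, 50)[1, 1]
    I_rp <- fisher_matrix(rate_place_fn(rate_fn), ps, 50)[1, 1]
    expect_lte(I_rp, I_all + 1e-9)
  }
})

test_that("the Fisher expectation over roves converges to the analytic mean", {
  # constant rate r = theta2 (roved); I_22 = T / theta2, so the expectation
  # over theta2 ~ U(mu - h, mu + h) is T log((mu+h)/(mu-h)) / (2h)
  dt <- 1e-4
  nt <- 1001
  rate_fn <- function(theta) fake_response(matrix(theta[2], 1, nt), dt = dt)
  mu <- 100; h <- 40
  ps <- param_spec(c("tgt", "r"), step = c(1, 0.1),
                   prior_sd = c(Inf, 20), rove_half = c(0, h))
  EI <- expected_fisher(rate_fn, ps, c(1, mu), n_draws = 256, seed = 5)
  analytic <- 0.1 * log((mu + h) / (mu - h)) / (2 * h)
  expect_equal(EI[2, 2], analytic, tolerance = 0.02)
  # no roved parameters: expectation equals the single-point matrix
  ps_fix <- param_spec(c("tgt", "r"), step = c(1, 0.1))
  expect_equal(expected_fisher(rate_fn, ps_fix, c(1, mu), n_draws = 7)[2, 2],
               fisher_matrix(rate_fn, ps_fix, c(1, mu))[2, 2])
  # seeded: reproducible
  expect_equal(unclass(expected_fisher(rate_fn, ps, c(1, mu), 4, seed = 9)),
               unclass(expected_fisher(rate_fn, ps, c(1, mu), 4, seed = 9)))
})

test_that("the ML oracle is unbiased at zero increment and saturates", {
  dt <- 1e-4
  t <- seq(0, 0.1, by = dt)
  rate_fn <- function(theta) fake_response(
    matrix(100 * (1 + 0.8 * cos(2 * pi * theta * t)), 1, byrow = TRUE),
    dt = dt, k = 20)
  pc0 <- oracle_ml_discrimination(rate_fn, 200, 0, n_trials = 500, seed = 2)
  expect_lt(abs(pc0 - 0.5), 0.06)
  pc_big <- oracle_ml_discrimination(rate_fn, 200, 8, n_trials = 300,
                                     seed = 3)
  expect_gt(pc_big, 0.95)
  expect_error(oracle_ml_discrimination(rate_fn, 200, 1, n_trials = 0), ">=")
})
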