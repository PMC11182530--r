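test_that("pattern enumeration and id convention match the landscape labelling", {
  P <- enumerate_patterns(9L)
  expect_equal(dim(P), c(512L, 9L))
  expect_equal(unname(P[1, ]), rep(-1, 9))
  expect_equal(nrow(unique(P)), 512L)

  # single active assemblage #6 -> P-#33; active {4, 8} -> P-#137
  s33 <- rep(-1, 9); s33[6] <- 1
  expect_equal(pattern_id(s33), 33L)
  s137 <- rep(-1, 9); s137[c(4, 8)] <- 1
  expect_equal(pattern_id(s137), 137L)
  expect_equal(pattern_id(rep(-1, 9)), 1L)
  expect_equal(pattern_id(rep(1, 9)), 512L)

  # encode/decode round-trip over all 512 patterns
  expect_equal(pattern_id(P), seq_len(512L))
  expect_equal(decode_pattern(seq_len(512L), 9L), P, ignore_attr = TRUE)
  expect_equal(enumerate_patterns(1L), rbind(-1, 1), ignore_attr = TRUE)
  expect_error(enumerate_patterns(21L), "2\\^I")
  expect_error(decode_pattern(513L, 9L), "out of range")
})

test_that("pattern energy follows the Ising form", {
  I <- 4L
  p0 <- maxent_params(rep(0, I))
  expect_equal(pattern_energy(enumerate_patterns(I), p0), rep(0, 16))

  # direct evaluation: h = (1, 0), g12 = 0.5, sigma = (+1, +1)
  p <- maxent_params(c(1, 0), matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(pattern_energy(c(1, 1), p), -1.5)

  # spin-flip symmetry at h = 0
  g <- matrix(rnorm(16), 4); g <- (g + t(g)) / 2; diag(g) <- 0
  ph <- maxent_params(rep(0, 4), g)
  s <- c(1, -1, 1, 1)
  expect_equal(pattern_energy(s, ph), pattern_energy(-s, ph))
  expect_error(pattern_energy(c(1, 1, 1), p), "length")
  expect_error(maxent_params(c(0, 0), matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("pattern distribution is normalized, stable and logistic at g = 0", {
  u <- pattern_distribution(maxent_params(rep(0, 9)))
  expect_equal(u, rep(1 / 512, 512))

  # extreme field: no overflow, marginal ~ 1/(1 + exp(-2 h1))
  p <- maxent_params(c(10, 0, 0))
  prob <- pattern_distribution(p)
  expect_equal(sum(prob), 1, tolerance = 1e-12)
  P <- enumerate_patterns(3L)
  marg <- sum(prob[P[, 1] == 1])
  expect_gt(marg, 0.999)
  expect_equal(marg, 1 / (1 + exp(-2 * 10)), tolerance = 1e-10)

  # normalization across random parameter draws
  for (s in 1:100) {
    set.seed(s)
    g <- matrix(rnorm(25), 5); g <- (g + t(g)) / 2; diag(g) <- 0
    pr <- pattern_distribution(maxent_params(rnorm(5), g))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr > 0))
  }
})

test_that("empirical moments are sample averages with unit diagonal", {
  occ <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  m <- empirical_moments(occ)
  expect_equal(m$first, c(0, 0))
  expect_equal(m$second, diag(2), ignore_attr = TRUE)
  m1 <- empirical_moments(matrix(1, 3, 2))
  expect_equal(m1$first, c(1, 1))
  expect_true(all(m1$second == 1))
  m2 <- empirical_moments(rbind(c(1, 1), c(-1, -1)))
  expect_equal(m2$first, c(0, 0))
  expect_equal(m2$second[1, 2], 1)
  expect_error(empirical_moments(matrix(numeric(0), 0, 2)), "empty")
})

test_that("model moments match the independent-spin and two-spin closed forms", {
  m0 <- model_moments(maxent_params(rep(0, 4)))
  expect_equal(m0$first, rep(0, 4))
  expect_equal(m0$second, diag(4), ignore_attr = TRUE)

  h <- c(0.7, -0.4, 0.1)
  mh <- model_moments(maxent_params(h))
  expect_equal(mh$first, tanh(h), tolerance = 1e-10)
  expect_equal(mh$second[1, 2], tanh(h[1]) * tanh(h[2]), tolerance = 1e-10)
  expect_equal(mh$second[2, 3], tanh(h[2]) * tanh(h[3]), tolerance = 1e-10)

  for (t_ in c(-1.2, -0.3, 0.4, 2)) {
    m2 <- model_moments(maxent_params(c(0, 0), matrix(c(0, t_, t_, 0), 2)))
    expect_equal(m2$second[1, 2], tanh(t_), tolerance = 1e-10)
    expect_equal(m2$first, c(0, 0), tolerance = 1e-12)
  }
})

test_that("moment matching recovers parameters from exact moments", {
  set.seed(13)
  for (rep_ in 1:3) {
    I <- 3L
    g <- matrix(rnorm(I * I, sd = 0.4), I); g <- (g + t(g)) / 2; diag(g) <- 0
    truth <- maxent_params(rnorm(I, sd = 0.5), g)
    emp <- model_moments(truth)
    fit <- mela:::fit_maxent_moments(emp, I, epsilon = 0.1, tol = 1e-7,
                                     max_iter = 100000L)
    expect_true(fit$report$converged)
    expect_equal(fit$params$h, truth$h, tolerance = 1e-4)
    expect_equal(fit$params$g, truth$g, tolerance = 1e-4)
  }
})

test_that("fit_maxent matches a generic likelihood maximizer on I = 2 data", {
  set.seed(17)
  truth <- maxent_params(c(0.4, -0.6), matrix(c(0, 0.5, 0.5, 0), 2))
  occ <- sample_boltzmann_patterns(truth, 2000L, seed = 3L)
  fit <- fit_maxent(occ, tol = 1e-8, max_iter = 100000L)

  # independent oracle: BFGS on the exact log-likelihood
  nll <- function(par) {
    p <- maxent_params(par[1:2], matrix(c(0, par[3], par[3], 0), 2))
    -maxent_log_likelihood(occ, p)
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(fit$params$h, opt$par[1:2], tolerance = 1e-3)
  expect_equal(fit$params$g[1, 2], opt$par[3], tolerance = 1e-3)
})

test_that("fit_maxent is exact on zero-moment data and rejects bad input", {
  occ <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  fit <- fit_maxent(occ)
  expect_equal(fit$params$h, c(0, 0), tolerance = 1e-6)
  expect_equal(fit$params$g[1, 2], 0, tolerance = 1e-6)
  expect_equal(fit$report$iterations, 1L)
  expect_error(fit_maxent(matrix(c(0, 1, 1, -1), 2)), "\\+1 or -1")
  expect_error(fit_maxent(occ, epsilon = 0), "> 0")
  expect_warning(fit_maxent(rbind(c(1, 1), c(1, -1)), max_iter = 5L),
                 "did not reach")
})

test_that("log-likelihood is uniform at zero params, gauge invariant, maximized by the fit", {
  set.seed(23)
  occ <- sample_boltzmann_patterns(
    maxent_params(c(0.3, -0.2, 0.1), matrix(c(0, 0.6, 0, 0.6, 0, 0, 0, 0, 0), 3)),
    500L, seed = 5L)
  I <- 3L
  expect_equal(maxent_log_likelihood(occ, maxent_params(rep(0, I))),
               500 * log(1 / 2^I))
  fit <- fit_maxent(occ)
  ll_fit <- maxent_log_likelihood(occ, fit)
  expect_lte(ll_fit, 0)
  expect_gt(ll_fit, maxent_log_likelihood(occ, maxent_params(rep(0, I))))
  # trace endpoint agrees with the direct evaluation at the fitted params
  expect_equal(unname(tail(fit$report$log_likelihood_trace, 1)), ll_fit,
               tolerance = 1e-8)
  # logLik method exposes df and nobs
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 6)
  expect_equal(attr(ll, "nobs"), 500)
})

test_that("log-likelihood trace is monotone for moderate steps, with and without adaptation", {
  set.seed(31)
  g <- matrix(rnorm(16, sd = 0.5), 4); g <- (g + t(g)) / 2; diag(g) <- 0
  occ <- sample_boltzmann_patterns(maxent_params(rnorm(4, sd = 0.4), g),
                                   1000L, seed = 7L)
  for (ad in c(TRUE, FALSE)) {
    fit <- fit_maxent(occ, epsilon = 0.2, max_iter = 20000L, adapt = ad)
    expect_true(all(diff(fit$report$log_likelihood_trace) > -1e-10))
  }
})
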