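# Moment matching, Gamma fitting, re-convolution validation, and the
# Gamma-vs-lognormal model comparison.

test_that("summarize_moments returns count, mean and unbiased variance", {
  m <- summarize_moments(c(7, 7, 7))
  expect_equal(c(m$n, m$mean, m$variance), c(3, 7, 0))
  m2 <- summarize_moments(c(1, 3))
  expect_equal(c(m2$mean, m2$variance), c(2, 2))
  x <- sample_signal(signal_params(2, 3), 1e5, seed = 4)
  expect_lt(abs(summarize_moments(x)$mean - 6), 3 * sqrt(18 / 1e5))
  expect_error(summarize_moments(7), "at least 2")
})

test_that("deconvolve_moments applies the additive-independence identities", {
  raw <- summarize_moments(c(1, 3)); raw$mean <- 12; raw$variance <- 9
  noise <- summarize_moments(c(1, 3)); noise$mean <- 4; noise$variance <- 5
  expect_equal(deconvolve_moments(raw, noise), c(mean = 8, variance = 4))
  zero <- summarize_moments(c(1, 3)); zero$mean <- 0; zero$variance <- 0
  expect_equal(deconvolve_moments(raw, zero), c(mean = 12, variance = 9))
  bad <- noise; bad$variance <- 20
  expect_error(deconvolve_moments(raw, bad), "noise-dominated.*variance")
  worse <- noise; worse$mean <- 15
  expect_error(deconvolve_moments(raw, worse), "noise-dominated.*mean")
})

test_that("fit_gamma inverts the Gamma moment relations", {
  f <- fit_gamma(1, 1)
  expect_equal(c(f$shape, f$scale), c(1, 1))
  f2 <- fit_gamma(10, 5)
  expect_equal(c(f2$shape, f2$scale), c(20, 0.5))
  # property: exact round trip over random parameters
  set.seed(17)
  for (i in 1:50) {
    k <- runif(1, 0.05, 50); th <- exp(runif(1, -3, 7))
    ff <- fit_gamma(k * th, k * th^2)
    expect_equal(ff$shape, k, tolerance = 1e-12)
    expect_equal(ff$scale, th, tolerance = 1e-12)
  }
  expect_error(fit_gamma(-1, 2))
  # Monte-Carlo recovery from sample moments
  x <- sample_signal(signal_params(0.3, 300), 1e5, seed = 6)
  fm <- fit_gamma(mean(x), var(x))
  expect_equal(fm$shape, 0.3, tolerance = 0.05)
  expect_equal(fm$scale, 300, tolerance = 0.05)
})

test_that("signal_density is the Gamma pdf, normalized, with the right mode", {
  expect_equal(signal_density(fit_gamma(1, 1), 1), exp(-1))
  g <- fit_gamma(3 * 2, 3 * 4)  # k = 3, theta = 2
  s <- seq(0, 3 * 2 + 20 * sqrt(3) * 2, length.out = 20001)
  d <- signal_density(g, s)
  trap <- sum((d[-1] + d[-length(d)]) / 2 * diff(s))
  expect_equal(trap, 1, tolerance = 1e-4)
  expect_true(all(d >= 0))
  expect_equal(s[which.max(d)], (3 - 1) * 2, tolerance = diff(s)[1] * 1.5)
  expect_error(signal_density(g, -1), ">= 0")
})

test_that("deconvolve recovers generating parameters end to end", {
  nm <- std_noise(100, 225)
  pop <- synthesize_population(signal_params(1, 50), nm, n = 3e4, seed = 41)
  ctrl <- sample_noise(nm, 3e4, seed = 42)
  fit <- deconvolve(pop, ctrl)
  expect_equal(unname(coef(fit)), c(1, 50), tolerance = 0.05)
  # same sample as raw and control: no signal left
  expect_error(deconvolve(ctrl, ctrl), "noise-dominated")
  # degenerate constant-noise control: exact up to the signal draws alone
  s <- sample_signal(signal_params(2, 10), 5000, seed = 43)
  fit2 <- deconvolve(s + 5, rep(5, 1000))
  ref <- fit_gamma(mean(s), var(s))
  expect_equal(fit2$signal$shape, ref$shape)
  expect_equal(fit2$signal$scale, ref$scale)
})

test_that("reconvolution adds a Gamma draw to a control resample", {
  g <- fit_gamma(50, 2500)
  rc <- reconvolve(g, control = rep(5, 100), n = 2000, seed = 51)
  expect_true(all(rc > 5))
  expect_equal(mean(rc - 5), 50, tolerance = 3 * 50 / sqrt(2000) / 50)
  expect_identical(reconvolve(g, control = c(1, 5, 9), n = 50, seed = 1),
                   reconvolve(g, control = c(1, 5, 9), n = 50, seed = 1))
  expect_error(reconvolve(g, control = numeric(0), n = 10), "non-empty")
  # via the fit object: moments of reconvolved match the measured raw data
  nm <- std_noise()
  pop <- synthesize_population(signal_params(1, 50), nm, n = 3e4, seed = 52)
  fit <- deconvolve(pop, sample_noise(nm, 3e4, seed = 53))
  rc2 <- simulate(fit, seed = 54)
  expect_identical(length(rc2), fit$n)
  se_mean <- sqrt(var(fit$raw) / fit$n)
  expect_lt(abs(mean(rc2) - mean(fit$raw)), 3 * sqrt(2) * se_mean)
})

test_that("validate_reconvolution measures the ECDF discrepancy", {
  x <- c(1, 2, 3)
  expect_equal(validate_reconvolution(x, x)$D, 0)
  rep_ <- validate_reconvolution(1:10, 100:110)
  expect_equal(rep_$D, 1)
  expect_true(rep_$location >= 10 && rep_$location <= 100)
  expect_error(validate_reconvolution(numeric(0), x), "non-empty")
  # correctly specified model at study size: D small
  nm <- std_noise()
  pop <- synthesize_population(signal_params(1, 50), nm, n = 3e4, seed = 61)
  fit <- deconvolve(pop, sample_noise(nm, 3e4, seed = 62))
  D <- validate_reconvolution(fit$raw, simulate(fit, seed = 63))$D
  expect_lte(D, 0.02)
})

test_that("model comparison ranks the generating family first", {
  nm <- std_noise()
  ctrl <- sample_noise(nm, 3e4, seed = 71)
  # Gamma-generated signal
  gpop <- synthesize_population(signal_params(0.7, 80), nm, n = 3e4,
                                seed = 72)
  wins_g <- vapply(1:5, function(i) {
    compare_signal_models(gpop, ctrl, seed = 100 + i)$best
  }, character(1))
  expect_gte(sum(wins_g == "gamma", na.rm = TRUE), 3)
  # lognormal-generated signal with strong skew, matched moments
  ln <- c(meanlog = log(50), sdlog = 1.2)
  lsig <- with(as.list(ln), rlnorm(3e4, meanlog, sdlog))
  set.seed(73)
  lraw <- lsig + sample_noise(nm, 3e4)
  wins_l <- vapply(1:5, function(i) {
    compare_signal_models(lraw, ctrl, seed = 200 + i)$best
  }, character(1))
  expect_gte(sum(wins_l == "lognormal", na.rm = TRUE), 3)
  # vanishing signal variance: families indistinguishable -> tie, not error
  tiny <- sample_signal(signal_params(1e6, 5e-5), 2e4, seed = 74) + 5
  cmp <- compare_signal_models(tiny, rep(5, 1000), seed = 75)
  expect_true(cmp$tie)
  expect_identical(cmp$best, NA_character_)
})

test_that("deconvolution inverts convolution in moments (property)", {
  set.seed(81)
  for (i in 1:5) {
    k <- runif(1, 0.3, 4); th <- exp(runif(1, 0, 4)); n <- 2e4
    s <- rgamma(n, k, scale = th)
    nz <- rgamma(n, 25, scale = 4)
    sm <- deconvolve_moments(summarize_moments(s + nz),
                             summarize_moments(nz))
    # with a shared noise sample the only stochastic term left is the
    # sample covariance: Var(S+N) - Var(N) - Var(S) = 2 cov(S, N)
    se_m <- sqrt((k * th^2 + 400) / n) * sqrt(2)
    se_v <- 2 * sqrt(k * th^2 * 400 / n)
    expect_lt(abs(sm[["mean"]] - mean(s)), 3 * se_m + 1e-9)
    expect_lt(abs(sm[["variance"]] - var(s)), 3 * se_v + 1e-9)
  }
})
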