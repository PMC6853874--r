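# The generator must reproduce the statistical structure the analysis
# assumes: additive R = S + N, Gamma signal moments, exponential-tilting
# behaviour under survival thinning, and shared-factor dual reporters.

test_that("sample_signal handles the empty case, seeds, and Gamma moments", {
  sp <- signal_params(0.5, 100)
  expect_identical(sample_signal(signal_params(1, 1), 0), numeric(0))
  expect_identical(sample_signal(signal_params(2, 3), 100, seed = 42),
                   sample_signal(signal_params(2, 3), 100, seed = 42))
  x <- sample_signal(sp, 1e5, seed = 1)
  expect_true(all(x > 0))
  # sample mean within 3 standard errors of k*theta
  se <- sqrt(0.5 * 100^2 / 1e5)
  expect_lt(abs(mean(x) - 50), 3 * se)
  expect_error(signal_params(-1, 2))
  expect_error(signal_params(1, 0))
})

test_that("synthesized events satisfy R = S + N exactly", {
  tab <- synthesize_population(signal_params(2, 5),
                               noise_model("constant", 5), n = 4, seed = 3)
  expect_equal(tab$FL1, tab$latent_signal + 5)
  expect_identical(tab$FL1 - (tab$latent_signal + tab$latent_noise),
                   rep(0, 4))
  tab2 <- synthesize_population(signal_params(1, 10), std_noise(4, 2),
                                n = 5000, seed = 9)
  expect_identical(tab2$FL1 - (tab2$latent_signal + tab2$latent_noise),
                   rep(0, 5000))
  empty <- synthesize_population(signal_params(1, 1), std_noise(), n = 0)
  expect_identical(nrow(empty), 0L)
})

test_that("population moments match the additive decomposition", {
  tab <- synthesize_population(signal_params(1, 10), std_noise(4, 2),
                               n = 30000, seed = 11)
  expect_equal(var(tab$FL1), var(tab$latent_signal) + var(tab$latent_noise),
               tolerance = 0.05)
  # against the generating truth: mean -> k*theta + <N>, var -> k*theta^2 + Var(N)
  expect_equal(mean(tab$FL1), 10 + 4, tolerance = 3 * sqrt(102 / 30000) / 14)
  expect_equal(var(tab$FL1), 100 + 2, tolerance = 0.05)
})

test_that("noise models produce non-negative draws with the stated moments", {
  for (nm in list(std_noise(100, 225),
                  noise_model("lognormal", 100, 400),
                  noise_model_empirical(c(0, 2, 5, 9)))) {
    x <- sample_noise(nm, 2e4, seed = 5)
    expect_true(all(x >= 0))
    expect_equal(mean(x), nm$mean, tolerance = 0.05)
  }
  expect_error(noise_model_empirical(numeric(0)), "empty")
  expect_error(noise_model("constant", 5, variance = 2))
  expect_identical(sample_noise(noise_model("constant", 7), 3), rep(7, 3))
})

test_that("survival thinning: identity, total-killing limit, and cap warning", {
  tab <- synthesize_population(signal_params(2, 1), std_noise(1, 0.25),
                               n = 2000, seed = 2)
  keep_all <- apply_survival_thinning(tab, survival_model(1, 0), seed = 1)
  expect_identical(nrow(keep_all), nrow(tab))
  expect_true(all(keep_all$condition == "post"))
  none <- apply_survival_thinning(tab, survival_model(1e-12, 0), seed = 1)
  expect_identical(nrow(none), 0L)
  expect_warning(
    apply_survival_thinning(tab, survival_model(0.5, 1.5), seed = 1),
    "not.*normalizable|normalizable")
  expect_error(apply_survival_thinning(data.frame(FL1 = 1:5),
                                       survival_model(1, 0)),
               "latent_signal")
})

test_that("exponential thinning of a Gamma tilts shape-preservingly", {
  # survivors of p(s) = p0 e^{0.5 s} applied to Gamma(2, 1) should follow
  # Gamma(2, 1/(1 - 0.5)) = Gamma(2, 2); checked two ways: against fresh
  # closed-form draws and against the generating rejection mechanism itself
  tab <- synthesize_population(signal_params(2, 1), std_noise(1, 0.25),
                               n = 2e6, seed = 21)
  post <- apply_survival_thinning(tab, survival_model(3e-4, 0.5), seed = 22)
  expect_gt(nrow(post), 1500)
  ref <- sample_signal(signal_params(2, 2), nrow(post), seed = 23)
  ks <- suppressWarnings(stats::ks.test(post$latent_signal, ref))
  expect_gt(ks$p.value, 0.01)
  # moments of the tilted law: mean 4, variance 8
  expect_equal(mean(post$latent_signal), 4, tolerance = 0.1)
})

test_that("dual reporters: pure-extrinsic, independence, and closed-form r", {
  # intrinsic CV = 0, no autofluorescence: channels exactly proportional
  prop <- synthesize_dual_reporter(
    dual_reporter_params(0.8, 0, channel_means = c(50, 200), n = 500),
    seed = 31)
  expect_equal(prop$FL2, prop$FL1 * 4)
  expect_equal(cor(prop$FL1, prop$FL2), 1)
  # extrinsic CV = 0: channels independent up to sampling error
  ind <- synthesize_dual_reporter(
    dual_reporter_params(0, 0.6, n = 1e4), seed = 32)
  expect_lt(abs(cor(ind$FL1, ind$FL2)), 0.05)
  # general case: r -> ce^2 / (ce^2 + ci^2 + ce^2 ci^2)
  both <- synthesize_dual_reporter(
    dual_reporter_params(0.5, 0.5, n = 1e5), seed = 33)
  expect_equal(cor(both$FL1, both$FL2), 0.25 / (0.25 + 0.25 + 0.0625),
               tolerance = 0.02 / 0.444)
})

test_that("scenario synthesis: cardinality, seed streams, pre/post pairs", {
  mk <- function(extra = NULL) {
    pops <- list(
      a = list(signal = signal_params(1, 50), noise = std_noise(), n = 4000),
      b = list(signal = signal_params(1, 50), noise = std_noise(), n = 4000),
      sel = list(signal = signal_params(2, 1),
                 noise = std_noise(1, 0.25), n = 4000,
                 survival = survival_model(0.5, 0.1)))
    scenario_config(c(pops, extra), seed = 7)
  }
  tabs <- synthesize_scenario(mk())
  expect_setequal(names(tabs), c("a", "b", "sel", "sel_post"))
  expect_identical(nrow(tabs$a), 4000L)
  # same parameters, different derived streams: different values, same moments
  expect_false(any(tabs$a$FL1 == tabs$b$FL1))
  expect_equal(mean(tabs$a$FL1), mean(tabs$b$FL1), tolerance = 0.05)
  # full reproducibility and label-stream independence
  tabs2 <- synthesize_scenario(mk())
  expect_identical(tabs2$a$FL1, tabs$a$FL1)
  tabs3 <- synthesize_scenario(
    mk(list(z = list(signal = signal_params(3, 2), noise = std_noise(),
                     n = 100))))
  expect_identical(tabs3$a$FL1, tabs$a$FL1)
  expect_error(scenario_config(list(a = list(), a = list())), "named")
})
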