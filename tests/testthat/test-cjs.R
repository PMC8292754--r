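test_that("the marginal likelihood matches worked values", {
  expect_equal(cjs_log_likelihood(rbind(c(1, 1)), 0.5, 0.5), log(0.25),
               tolerance = 1e-12)
  expect_equal(exp(cjs_log_likelihood(rbind(c(1, 0, 0)), 0.5, 0.5)), 0.6875,
               tolerance = 1e-12)

  # degenerate parameters: a gap after first capture is impossible
  expect_equal(cjs_log_likelihood(rbind(c(1, 0, 1)), 1, 1), -Inf)

  expect_error(cjs_log_likelihood(rbind(c(0, 0, 0)), 0.5, 0.5),
               class = "spotmatch_invalid_argument")
  expect_error(cjs_log_likelihood(rbind(c(1, 1)), 1.5, 0.5),
               class = "spotmatch_invalid_argument")
})

test_that("the forward recursion equals exhaustive latent-path enumeration", {
  set.seed(9)
  for (T in 2:4) {
    for (k in 1:10) {
      h <- integer(T)
      f <- sample.int(T, 1)
      h[f] <- 1L
      if (f < T) h[(f + 1):T] <- rbinom(T - f, 1, 0.5)
      phi <- runif(1); p <- runif(1)
      exact <- enumerate_cjs_likelihood(h, phi, p)
      expect_equal(exp(cjs_log_likelihood(rbind(h), phi, p)), exact,
                   tolerance = 1e-12)
    }
  }
})

test_that("likelihoods over all continuation histories sum to one", {
  for (T in 1:4) {
    phi <- 0.7; p <- 0.4
    total <- 0
    for (code in 0:(2^T - 1)) {
      h <- c(1L, as.integer(bitwAnd(code, 2^(0:(T - 1))) > 0))
      total <- total + exp(cjs_log_likelihood(rbind(h), phi, p))
    }
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("HPD intervals are shortest and contained in the sample range", {
  set.seed(4)
  u <- runif(50000)
  hi <- hpd_interval(u)
  expect_lt(abs(diff(hi) - 0.95), 0.01)

  const <- rep(0.3, 500)
  expect_equal(hpd_interval(const), c(0.3, 0.3))

  x <- rbeta(5000, 8, 2)
  h <- hpd_interval(x)
  expect_gte(h[1], min(x)); expect_lte(h[2], max(x))
  # shorter than the equal-tailed interval
  et <- unname(quantile(x, c(0.025, 0.975)))
  expect_lte(diff(h), diff(et) + 1e-9)

  expect_error(hpd_interval(numeric(0)), class = "spotmatch_invalid_argument")
})

test_that("posterior sampling recovers simulated parameters", {
  y <- simulate_capture_histories(250, 12, phi = 0.8, p = 0.5, seed = 31)
  fit <- fit_cjs(y, n_samples = 2000, seed = 1, chains = 2)
  cf <- coef(fit)
  expect_lt(abs(cf["phi"] - 0.8), 0.05)
  expect_lt(abs(cf["p"] - 0.5), 0.05)
  s <- summary(fit)
  expect_true(all(s$hpd_lower <= s$mean & s$mean <= s$hpd_upper))
  expect_true(all(s$rhat < 1.1))

  # reproducibility
  fit2 <- fit_cjs(y, n_samples = 2000, seed = 1, chains = 2)
  expect_identical(fit$samples, fit2$samples)

  # near-saturated detection concentrates both parameters near 1
  ysat <- simulate_capture_histories(80, 8, phi = 1, p = 1, seed = 5)
  fsat <- fit_cjs(ysat, n_samples = 1500, seed = 2, chains = 2)
  expect_gt(coef(fsat)["phi"], 0.95)
  expect_gt(coef(fsat)["p"], 0.95)
})

test_that("the latent-state Gibbs sampler agrees with the marginal sampler", {
  y <- simulate_capture_histories(120, 10, phi = 0.75, p = 0.55, seed = 41)
  fm <- fit_cjs(y, n_samples = 2000, seed = 1, chains = 2)
  fl <- fit_cjs(y, n_samples = 2000, seed = 1, chains = 2, method = "latent")
  expect_lt(max(abs(coef(fm) - coef(fl))), 0.02)
})

test_that("histories without recaptures leave the posterior near the prior", {
  y <- diag(1L, 8, 8)  # eight singletons
  expect_warning(fit <- fit_cjs(y, n_samples = 1500, seed = 1, chains = 2),
                 "no recaptures")
  # p posterior stays diffuse (prior sd of U(0,1) is ~0.29)
  expect_gt(sd(fit$samples[, "p"]), 0.15)
})

test_that("cjs_fit provides the standard modelling methods", {
  y <- simulate_capture_histories(60, 8, phi = 0.8, p = 0.5, seed = 51)
  fit <- fit_cjs(y, n_samples = 1000, seed = 1, chains = 2)
  expect_named(coef(fit), c("phi", "p"))
  expect_s3_class(fit, "cjs_fit")
  expect_output(print(fit), "Cormack-Jolly-Seber")
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 2)
  expect_lt(as.numeric(ll), 0)
  sims <- simulate(fit, nsim = 2)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(y))
  pdf(NULL); plot(fit); dev.off()
})
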