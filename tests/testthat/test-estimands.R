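# Estimand calculations on fabricated posterior draws with known answers.

draws_m3 <- function(n = 500, mu_a1 = -1, mu2 = 0.5, mu3 = 0.5,
                     sigma_a = 1, sigma_c = 0.4) {
  cbind("mu_a1" = rep(mu_a1, n), "mu_c[2]" = rep(mu2, n),
        "mu_c[3]" = rep(mu3, n), "sigma_a" = rep(sigma_a, n),
        "sigma_c" = rep(sigma_c, n))
}

test_that("conditional contrasts are antisymmetric and transitive", {
  set.seed(4)
  d <- cbind("mu_c[2]" = rnorm(2000, 0.5, 0.1),
             "mu_c[3]" = rnorm(2000, 0.8, 0.1), sigma_c = rep(0.3, 2000))
  f <- fake_fit(d, spec = model_spec(2))
  zy <- conditional_contrast(f, 3, 2)
  expect_equal(zy$median, median(d[, "mu_c[3]"] - d[, "mu_c[2]"]))
  yz <- conditional_contrast(f, 2, 3)
  expect_equal(yz$median, -zy$median)
  expect_equal(yz$ci_low, -zy$ci_high)
  # transitivity holds draw-wise, exactly
  expect_equal(abnma:::contrast_draws(f, 3, 1),
               abnma:::contrast_draws(f, 3, 2) + abnma:::contrast_draws(f, 2, 1))
  expect_warning(deg <- conditional_contrast(f, 2, 2), "degenerate")
  expect_equal(deg$median, 0)
  expect_equal(conditional_contrast(f, 2, 2, scale = "or")$median |>
                 suppressWarnings(), 1)
})

test_that("marginal means integrate expit over the fitted heterogeneity", {
  # degenerate heterogeneity: pi_k = expit(mean)
  f0 <- fake_fit(draws_m3(sigma_a = 0, sigma_c = 0))
  expect_equal(marginal_mean(f0, 1)$median, expit(-1), tolerance = 1e-8)
  expect_equal(marginal_mean(f0, 2)$median, expit(-0.5), tolerance = 1e-8)
  # symmetric heterogeneity about 0: pi = 0.5 exactly
  fs <- fake_fit(draws_m3(mu_a1 = 0, mu2 = 0, sigma_a = 1.3, sigma_c = 0.6))
  expect_equal(marginal_mean(fs, 2)$median, 0.5, tolerance = 1e-10)
  # mean -1, total sd 1: against direct numerical integration
  f1 <- fake_fit(draws_m3(mu_a1 = -1, sigma_a = 1, sigma_c = 0))
  oracle <- integrate(function(t) expit(t) * dnorm(t, -1, 1), -Inf, Inf)$value
  expect_equal(marginal_mean(f1, 1)$median, oracle, tolerance = 1e-6)
  # model 3 non-reference arm adds contrast heterogeneity to the mixture
  f2 <- fake_fit(draws_m3(mu_a1 = -1, mu2 = 0.5, sigma_a = 0.8,
                          sigma_c = 0.6))
  oracle2 <- integrate(function(t) {
    expit(t) * dnorm(t, -0.5, sqrt(0.8^2 + 0.6^2))
  }, -Inf, Inf)$value
  expect_equal(marginal_mean(f2, 2)$median, oracle2, tolerance = 1e-6)
  # bounds hold draw-wise for noisy draws
  set.seed(5)
  fn <- fake_fit(cbind("mu_a1" = rnorm(300, -1, 0.3),
                       "mu_c[2]" = rnorm(300, 0.5, 0.2),
                       "mu_c[3]" = rnorm(300, 0.5, 0.2),
                       "sigma_a" = runif(300, 0.1, 2),
                       "sigma_c" = runif(300, 0.1, 1)))
  mm <- marginal_mean(fn, 3)
  expect_true(mm$ci_low > 0 && mm$ci_high < 1)
})

test_that("fixed-intercept fits refuse marginal estimands", {
  f <- fake_fit(cbind("mu_c[2]" = rnorm(100), sigma_c = rep(0.2, 100)),
                spec = model_spec(2))
  expect_error(marginal_mean(f, 2), "fixed intercepts")
  expect_error(marginal_contrast(f, 2), "fixed intercepts")
})

test_that("marginal contrasts collapse to conditional when heterogeneity
           vanishes and attenuate otherwise", {
  f0 <- fake_fit(draws_m3(sigma_a = 0, sigma_c = 0))
  expect_equal(marginal_contrast(f0, 2, 1, "logit")$median, 0.5,
               tolerance = 1e-6)
  # identical arms: zero for every link
  fid <- fake_fit(draws_m3(mu2 = 0, mu3 = 0, sigma_a = 1, sigma_c = 0))
  for (lk in c("logit", "identity", "log")) {
    expect_equal(marginal_contrast(fid, 2, 1, lk)$median, 0,
                 tolerance = 1e-10)
  }
  # nonzero heterogeneity: marginal log OR strictly nearer 0 than the
  # conditional log OR
  fh <- fake_fit(draws_m3(mu_a1 = -1, mu2 = 0.8, sigma_a = 1.2,
                          sigma_c = 0))
  mg <- marginal_contrast(fh, 2, 1, "logit")$median
  expect_lt(mg, 0.8)
  expect_gt(mg, 0)
  # identity link is the marginal risk difference, inside (-1, 1)
  rd <- marginal_contrast(fh, 2, 1, "identity")$median
  expect_true(rd > -1 && rd < 1)
})

test_that("model 4 marginal means use the arm covariance row", {
  d4 <- cbind("mu_a[1]" = rep(-1, 200), "mu_a[2]" = rep(-0.5, 200),
              "mu_a[3]" = rep(-0.5, 200),
              "mu_c[2]" = rep(0.5, 200), "mu_c[3]" = rep(0.5, 200),
              "sigma_a" = rep(0.9, 200), "sigma_c" = rep(0.4, 200),
              "rho_a" = rep(0.9, 200))
  f4 <- fake_fit(d4, spec = model_spec(4))
  oracle <- integrate(function(t) expit(t) * dnorm(t, -0.5, 0.9),
                      -Inf, Inf)$value
  expect_equal(marginal_mean(f4, 2)$median, oracle, tolerance = 1e-6)
})

test_that("external-risk targeting applies the conditional OR correctly", {
  f <- fake_fit(draws_m3(mu2 = 0.5, sigma_c = 0.4))
  # log OR 0.5 applied to r = 0.5: expit(0.5) - 0.5
  rd <- external_target(f, 0.5, 2, 1)
  expect_equal(rd$median, expit(0.5) - 0.5, tolerance = 1e-10)
  # zero contrast: zero risk difference
  f0 <- fake_fit(draws_m3(mu2 = 0))
  expect_equal(external_target(f0, 0.3, 2, 1)$median, 0, tolerance = 1e-10)
  expect_error(external_target(f, 1.2, 2), "external_risk")
  expect_error(external_target(f, 0, 2), "external_risk")
  # integrating heterogeneity moves the estimate with expit's curvature:
  # upward for r below 1/2 here (convex region), matching quadrature
  r <- 0.15
  plug <- external_target(f, r, 2, 1)$median
  integ <- external_target(f, r, 2, 1, integrate_heterogeneity = TRUE)$median
  oracle <- integrate(function(t) {
    expit(logit(r) + t) * dnorm(t, 0.5, 0.4)
  }, -Inf, Inf)$value - r
  expect_equal(integ, oracle, tolerance = 1e-6)
  expect_gt(integ, plug)
})
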