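# Structural linear predictors, log-posterior evaluation, and the
# algebraic relations between model parameterizations.

test_that("linear predictors follow each model's structural equation", {
  net <- star_net()
  st <- random_state(model_spec(2), net)
  # model 1: reference arm is the intercept exactly
  expect_equal(linear_predictor(model_spec(1),
                                parameter_state(alpha = c(-1, -2, 0, 1),
                                                delta = rep(0.3, 4)),
                                net, 1, 1), -1)
  # model 2 CB: alpha + delta
  expect_equal(linear_predictor(model_spec(2),
                                parameter_state(alpha = rep(-1, 4),
                                                delta = cbind(0, 0.5, 0.2)),
                                net, 1, 2), -0.5)
  # model 2 AB: alpha + mu_c + eta
  st_ab <- parameter_state(alpha = rep(-1, 4), mu_c = c(0, 0.4, 0.1),
                           eta = matrix(0.05, 4, 3))
  expect_equal(linear_predictor(model_spec(2, "ab"), st_ab, net, 2, 2),
               -1 + 0.4 + 0.05)
  # model 4 AB: theta directly
  st4 <- parameter_state(theta = matrix(seq(-1.2, 0, length.out = 12), 4, 3))
  expect_equal(linear_predictor(model_spec(4), st4, net, 3, 2), st4$theta[3, 2])
  expect_error(linear_predictor(model_spec(2), st, net, 1, 9), "1..3")
})

test_that("log-posterior reduces to the binomial likelihood term by term", {
  net <- nma_network(data.frame(study = c(1, 1), treatment = c(1, 2),
                                events = c(1, 1), size = c(2, 2)))
  st <- parameter_state(alpha = 0, delta = cbind(0, 0), mu_c = c(0, 0),
                        sigma_c2 = 0.1)
  lp <- log_posterior(model_spec(2), st, net, include_prior = FALSE)
  comp <- attr(lp, "components")
  # both arms have theta = 0: each contributes log C(2,1) 0.5^2 = log(0.5)
  expect_equal(comp[["loglik"]], 2 * log(0.5))
  # probability-zero data under a degenerate theta drive it to -Inf
  st_inf <- parameter_state(alpha = -Inf, delta = cbind(0, 0),
                            mu_c = c(0, 0), sigma_c2 = 0.1)
  expect_equal(attr(log_posterior(model_spec(2), st_inf, net,
                                  include_prior = FALSE),
                    "components")[["loglik"]], -Inf)
})

test_that("models 1 and 2 differ by a constant free of location parameters", {
  # the all-arms model adds unobserved contrasts; at their conditional
  # means given the observed contrast, the joint density differs from the
  # observed-arms model only through variance-dependent normalization
  net <- star_net()
  spec1 <- model_spec(1)
  spec2 <- model_spec(2)
  sc2 <- 0.2
  Sc <- ch_contrast_cov(sc2, 3)
  diffs <- sapply(1:6, function(r) {
    set.seed(r)
    alpha <- rnorm(4, -1, 1)
    mu_c <- c(0, rnorm(2))
    dobs <- rnorm(4, 0.4, 0.5)
    st1 <- parameter_state(alpha = alpha, delta = dobs, mu_c = mu_c,
                           sigma_c2 = sc2)
    # map: observed contrast in its slot, unobserved at conditional mean
    delta2 <- matrix(0, 4, 3)
    for (i in 1:4) {
      k_obs <- setdiff(net$designs[[i]], 1)
      k_un <- setdiff(2:3, k_obs)
      delta2[i, k_obs] <- dobs[i]
      delta2[i, k_un] <- mu_c[k_un] +
        Sc[k_un - 1, k_obs - 1] / Sc[k_obs - 1, k_obs - 1] *
          (dobs[i] - mu_c[k_obs])
    }
    st2 <- parameter_state(alpha = alpha, delta = delta2, mu_c = mu_c,
                           sigma_c2 = sc2)
    log_posterior(spec2, st2, net, include_prior = FALSE) -
      log_posterior(spec1, st1, net, include_prior = FALSE)
  })
  expect_lt(diff(range(diffs)), 1e-8)
})

test_that("log-posterior is invariant to consistent relabeling (models 2-4)", {
  net <- star_net()
  perm <- c(1, 3, 2)  # swap the non-reference treatments
  arms2 <- net$arms
  arms2$treatment <- perm[arms2$treatment]
  net_p <- nma_network(arms2)
  for (m in 2:4) {
    spec <- model_spec(m)
    st <- random_state(spec, net, rng = m)
    st_p <- st
    st_p$delta <- st$delta[, perm]
    st_p$eta <- st$eta[, perm]
    st_p$theta <- st$theta[, perm]
    st_p$mu_c <- st$mu_c[perm]
    st_p$mu_a <- st$mu_a[perm]
    expect_equal(log_posterior(spec, st_p, net_p),
                 log_posterior(spec, st, net))
  }
})

test_that("CB and AB forms of the arm-based model give the same density", {
  # the (alpha, delta) parameterization is a linear change of variables of
  # theta with unit Jacobian, so joint densities agree pointwise
  net <- star_net()
  st <- random_state(model_spec(4), net)
  theta <- st$theta
  st_cb <- st
  st_cb$alpha <- theta[, 1]
  st_cb$delta <- theta - theta[, 1]
  ab <- log_posterior(model_spec(4, "ab"), st, net, include_prior = FALSE)
  cb <- log_posterior(model_spec(4, "cb"), st_cb, net, include_prior = FALSE)
  expect_equal(as.numeric(ab), as.numeric(cb))
})

test_that("vanishing heterogeneity recovers the common-effect density", {
  net <- star_net()
  spec <- model_spec(2)
  mu_c <- c(0, 0.4, 0.6)
  alpha <- c(-1, -0.8, -1.2, -0.9)
  common_loglik <- sum(apply(net$arms, 1, function(r) {
    th <- alpha[r["study"]] + mu_c[r["treatment"]]
    dbinom(r["events"], r["size"], expit(th), log = TRUE)
  }))
  delta_at_mean <- matrix(mu_c, 4, 3, byrow = TRUE)
  lps <- sapply(c(1e-2, 1e-4, 1e-6), function(s2) {
    st <- parameter_state(alpha = alpha, delta = delta_at_mean, mu_c = mu_c,
                          sigma_c2 = s2)
    attr(log_posterior(spec, st, net, include_prior = FALSE),
         "components")[["loglik"]]
  })
  expect_equal(lps[3], common_loglik, tolerance = 1e-10)
})

test_that("derived contrasts are reference-anchored and shift-invariant", {
  spec4 <- model_spec(4)
  st <- parameter_state(mu_a = c(-1, -0.5, -0.5))
  expect_equal(derived_contrasts(spec4, st), c(0, 0.5, 0.5))
  st2 <- parameter_state(mu_a = c(-1, -0.5, -0.5) + 3)
  expect_equal(derived_contrasts(spec4, st2), c(0, 0.5, 0.5))
  st3 <- parameter_state(mu_a = rep(2, 4))
  expect_equal(derived_contrasts(spec4, st3), rep(0, 4))
  stc <- parameter_state(mu_c = c(0, 0.3, -0.2))
  expect_equal(derived_contrasts(model_spec(2), stc), c(0, 0.3, -0.2))
})
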