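# Joint log-posterior of the structural models, in plain R.
#
# This is an exact, unoptimized evaluation of the same joint density that
# the JAGS programs in jags.R sample from.  It exists so that tests can
# check the sampler against an independent route (quadrature oracles,
# algebraic model equivalences) and so that users can inspect the model
# density directly.

#' Construct a parameter state
#'
#' A point in the parameter space of a structural model.  Only the fields a
#' given model uses need to be supplied; covariance matrices are derived
#' from scalar variance components for common-heterogeneity models.
#'
#' @param alpha per-study intercept log-odds (length n).
#' @param delta study contrasts: length-n vector for model 1 (the non-base
#'   arm's contrast), or an n x K matrix with first column zero for
#'   models 2-4 (CB forms).
#' @param eta n x K matrix of arm effects (model 2, AB form).
#' @param theta n x K matrix of arm log-odds (model 4, AB form).
#' @param mu_c length-K mean contrast vector with `mu_c[1] = 0`.
#' @param mu_a length-K arm mean vector (model 4), or a scalar reference
#'   arm mean (model 3).
#' @param sigma_c2 contrast heterogeneity variance.
#' @param sigma_a2 arm heterogeneity variance (models 3-4).
#' @param rho_a intercept-effect correlation (model 4 CH).
#' @param Sigma_c,Sigma_a explicit covariance matrices (NCH models).
#' @return a list of class `parameter_state`.
#' @export
parameter_state <- function(alpha = NULL, delta = NULL, eta = NULL,
                            theta = NULL, mu_c = NULL, mu_a = NULL,
                            sigma_c2 = NULL, sigma_a2 = NULL, rho_a = NULL,
                            Sigma_c = NULL, Sigma_a = NULL) {
  st <- list(alpha = alpha, delta = delta, eta = eta, theta = theta,
             mu_c = mu_c, mu_a = mu_a, sigma_c2 = sigma_c2,
             sigma_a2 = sigma_a2, rho_a = rho_a,
             Sigma_c = Sigma_c, Sigma_a = Sigma_a)
  if (!is.null(sigma_c2) && sigma_c2 < 0) stop("sigma_c2 must be >= 0")
  if (!is.null(sigma_a2) && sigma_a2 < 0) stop("sigma_a2 must be >= 0")
  structure(st, class = "parameter_state")
}

# Base treatment of study i for model 1: lowest-numbered treatment in the
# design (equals the reference in every network considered in practice).
base_treatment <- function(net, i) min(net$designs[[i]])

# Resolve the model's covariance matrices from scalar components when CH.
state_covariances <- function(spec, state, K) {
  if (spec$heterogeneity == "ch") {
    if (spec$model %in% c(2, 3) && spec$form == "cb") {
      state$Sigma_c <- ch_contrast_cov(state$sigma_c2, K)
    }
    if (spec$model == 4) {
      state$sigma_a2 <- state$sigma_c2 / (2 * (1 - state$rho_a))
      state$Sigma_a <- model4_ch_cov(state$sigma_a2, state$rho_a, K)
    }
  }
  state
}

#' Structural linear predictor for one arm
#'
#' The arm log-odds `theta_ik` implied by a parameter state under a model's
#' structural equation.
#'
#' @param spec a [model_spec()].
#' @param state a [parameter_state()].
#' @param net an [nma_network()].
#' @param study study index (1..n).
#' @param treatment treatment index (1..K).
#' @return the log-odds of an event in that arm.
#' @export
linear_predictor <- function(spec, state, net, study, treatment) {
  K <- net$n_treatments
  if (!(treatment %in% seq_len(K))) {
    stop("treatment must be in 1..", K)
  }
  i <- study; k <- treatment
  switch(as.character(spec$model),
    "1" = {
      b <- base_treatment(net, i)
      if (k == b) state$alpha[i] else state$alpha[i] + state$delta[i]
    },
    "2" = if (spec$form == "cb") {
      state$alpha[i] + state$delta[i, k]
    } else {
      state$alpha[i] + state$mu_c[k] + state$eta[i, k]
    },
    "3" = state$alpha[i] + state$delta[i, k],
    "4" = if (spec$form == "ab") {
      state$theta[i, k]
    } else {
      state$alpha[i] + state$delta[i, k]
    })
}

#' Joint log-posterior density
#'
#' Binomial log-likelihood over observed arms, plus the structural
#' random-effects log-densities, plus log-priors.  Variance-component
#' priors are evaluated on the scale the sampler uses (the log-variance for
#' lognormal priors).  Returns `-Inf` for states outside the support, e.g.
#' a singular random-effects covariance in a direction the data constrain.
#'
#' @inheritParams linear_predictor
#' @param include_prior if `FALSE`, return log-likelihood plus structural
#'   densities only.
#' @return a single number; attribute `"components"` carries the breakdown.
#' @export
log_posterior <- function(spec, state, net, include_prior = TRUE) {
  K <- net$n_treatments
  n <- net$n_studies
  prior <- spec$prior
  state <- state_covariances(spec, state, K)

  ll <- 0
  a <- net$arms
  for (j in seq_len(nrow(a))) {
    th <- linear_predictor(spec, state, net, a$study[j], a$treatment[j])
    ll <- ll + stats::dbinom(a$events[j], a$size[j], expit(th), log = TRUE)
  }

  struct <- 0
  m <- spec$model
  if (m == 1) {
    for (i in seq_len(n)) {
      d <- net$designs[[i]]
      if (length(d) != 2) stop("model 1 supports two-arm studies only")
      b <- base_treatment(net, i)
      k <- setdiff(d, b)
      struct <- struct + stats::dnorm(state$delta[i],
                                      state$mu_c[k] - state$mu_c[b],
                                      sqrt(state$sigma_c2), log = TRUE)
    }
  } else if (m == 2 && spec$form == "cb") {
    for (i in seq_len(n)) {
      struct <- struct + log_dmvnorm(state$delta[i, 2:K], state$mu_c[2:K],
                                     state$Sigma_c)
    }
  } else if (m == 2 && spec$form == "ab") {
    struct <- sum(stats::dnorm(state$eta, 0, sqrt(state$sigma_c2 / 2),
                               log = TRUE))
  } else if (m == 3) {
    for (i in seq_len(n)) {
      struct <- struct + log_dmvnorm(state$delta[i, 2:K], state$mu_c[2:K],
                                     state$Sigma_c)
    }
    struct <- struct + sum(stats::dnorm(state$alpha, state$mu_a[1],
                                        sqrt(state$sigma_a2), log = TRUE))
  } else if (m == 4 && spec$form == "ab") {
    for (i in seq_len(n)) {
      struct <- struct + log_dmvnorm(state$theta[i, ], state$mu_a,
                                     state$Sigma_a)
    }
  } else if (m == 4 && spec$form == "cb") {
    Sst <- sigma_star(state$Sigma_a, K)
    mu_st <- c(state$mu_a[1], state$mu_a[2:K] - state$mu_a[1])
    for (i in seq_len(n)) {
      struct <- struct + log_dmvnorm(c(state$alpha[i], state$delta[i, 2:K]),
                                     mu_st, Sst)
    }
  }

  lp <- 0
  if (include_prior) {
    fe <- prior$fixed_effect_sd
    if (m %in% c(1, 2)) {
      lp <- lp + sum(stats::dnorm(state$alpha, 0, fe, log = TRUE))
    }
    if (m == 4) {
      lp <- lp + sum(stats::dnorm(state$mu_a, 0, fe, log = TRUE))
    } else {
      lp <- lp + sum(stats::dnorm(state$mu_c[2:K], 0, fe, log = TRUE))
      if (m == 3) lp <- lp + stats::dnorm(state$mu_a[1], 0, fe, log = TRUE)
    }
    if (spec$heterogeneity == "ch") {
      lp <- lp + stats::dnorm(log(state$sigma_c2), prior$het_meanlog,
                              prior$het_sdlog, log = TRUE)
      if (m == 3) {
        lp <- lp + stats::dnorm(log(state$sigma_a2), prior$arm_het_meanlog,
                                prior$arm_het_sdlog, log = TRUE)
      }
      if (m == 4) {
        # joint prior on (log sigma_c2, rho_a): the sigma_c2 lognormal
        # above times the density of the independent lognormal on the
        # derived sigma_a2, with Jacobian dsigma_a2/drho = sigma_a2/(1-rho)
        lo <- -1 / (K - 1) + prior$rho_eps
        hi <- 1 - prior$rho_eps
        if (state$rho_a <= lo || state$rho_a >= hi) return(-Inf)
        lp <- lp + stats::dnorm(log(state$sigma_a2), prior$arm_het_meanlog,
                                prior$arm_het_sdlog, log = TRUE) -
          log(1 - state$rho_a)
      }
    } else {
      np <- nch_prior_matrix(spec, K)
      Sig <- if (m == 4) state$Sigma_a else state$Sigma_c
      lp <- lp + log_dinvwish(Sig, np$S, np$df)
    }
  }

  total <- ll + struct + lp
  attr(total, "components") <- c(loglik = ll, structural = struct, prior = lp)
  total
}

# Covariance of (alpha_i, delta_i[2:K]) implied by an arm covariance
# Sigma_a: the CB form of the arm-based model.
sigma_star <- function(Sigma_a, K) {
  T <- rbind(c(1, rep(0, K - 1)),
             cbind(-1, diag(1, K - 1)))
  T %*% Sigma_a %*% t(T)
}

#' Mean contrasts implied by a state
#'
#' For the arm-based model the parameters of interest are differences of
#' arm means, `mu_c[k] = mu_a[k] - mu_a[1]`; for the contrast-based models
#' the mean contrasts are model parameters and pass through unchanged.
#'
#' @inheritParams linear_predictor
#' @return length-K vector of mean contrasts versus treatment 1 (first
#'   element zero).
#' @export
derived_contrasts <- function(spec, state) {
  if (spec$model == 4) {
    state$mu_a - state$mu_a[1]
  } else {
    mc <- state$mu_c
    mc - mc[1]
  }
}
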