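# MCMC fitting via JAGS.
#
# Each model_spec is translated into a JAGS program sampling the same joint
# density that log_posterior() evaluates.  Compound-symmetry structures are
# sampled through either a hierarchical decomposition (models 2-3:
# P(0.5) splits into a shared plus an independent normal component, which
# avoids matrix inversion) or an analytic precision matrix (model 4).
# Lognormal variance priors are placed on the log variance; NCH covariances
# get Wishart-distributed precisions (inverse-Wishart covariances).

#' MCMC chain configuration
#'
#' Defaults follow the long single-chain regime used for all headline
#' results: 50 000 burn-in updates then 200 000 updates thinned to every
#' 20th, retaining 10 000 draws.
#'
#' @param burn_in burn-in updates.
#' @param post_burn post-burn-in updates.
#' @param thin keep every `thin`-th update.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param n_chains number of chains (default 1).
#' @param n_adapt sampler adaptation updates before burn-in.
#' @return a list of class `chain_config`.
#' @export
chain_config <- function(burn_in = 50000, post_burn = 200000, thin = 20,
                         seed = 1L, n_chains = 1L, n_adapt = 1000L) {
  stopifnot(burn_in >= 0, post_burn >= 1, thin >= 1, n_chains >= 1)
  structure(list(burn_in = as.integer(burn_in),
                 post_burn = as.integer(post_burn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt)),
            class = "chain_config")
}

# ---- JAGS program builders ---------------------------------------------

# Joint prior for the compound-symmetry model, parameterized in
# (log sigma_c2, rho_a): the shared lognormal on sigma_c2 plus a
# lognormal on the derived sigma_a2 = sigma_c2 / (2 (1 - rho_a))
# (the same arm-variance prior as model 3), restricted to the
# positive-definite range of rho_a.  The sigma_a2 factor enters through a
# zeros-trick potential: with base measure rho_a ~ uniform, the extra
# density is dlnorm(sigma_a2) * dsigma_a2/drho = exp(-z^2/2) / (1 - rho),
# z = (log sigma_a2 - arm_mean) / arm_sd.
m4_ch_prior_block <- function() {
  paste0(
    "  lsc2 ~ dnorm(het_mean, het_prec)\n",
    "  sigma_c2 <- exp(lsc2)\n",
    "  sigma_c <- sqrt(sigma_c2)\n",
    "  rho_a ~ dunif(rho_lo, rho_hi)\n",
    "  sigma_a2 <- sigma_c2 / (2 * (1 - rho_a))\n",
    "  sigma_a <- sqrt(sigma_a2)\n",
    "  z_arm <- (log(sigma_a2) - arm_mean) * sqrt(arm_prec)\n",
    "  phi_arm <- 0.5 * z_arm * z_arm + log(1 - rho_a) + 10\n",
    "  zero_arm ~ dpois(phi_arm)\n")
}

bugs_model_code <- function(spec, K) {
  m <- spec$model
  ch <- spec$heterogeneity == "ch"
  lik <- "  for (j in 1:Na) {\n    y[j] ~ dbin(p[j], n[j])\n"
  het_ch <- paste(
    "  lsc2 ~ dnorm(het_mean, het_prec)",
    "  sigma_c2 <- exp(lsc2)",
    "  sigma_c <- sqrt(sigma_c2)", sep = "\n")
  mu_free <- paste(
    "  mu_c[1] <- 0",
    "  for (k in 2:K) { mu_c[k] ~ dnorm(0, fe_prec) }", sep = "\n")

  if (m == 1) {
    code <- paste0(
      "model {\n", lik,
      "    logit(p[j]) <- alpha[s[j]] + delta[s[j]] * (1 - equals(t[j], b[s[j]]))\n  }\n",
      "  for (i in 1:Ns) {\n",
      "    alpha[i] ~ dnorm(0, fe_prec)\n",
      "    delta[i] ~ dnorm(mu_c[nb[i]] - mu_c[b[i]], 1 / sigma_c2)\n",
      "  }\n", mu_free, "\n", het_ch, "\n}\n")
  } else if (m == 2 && spec$form == "cb" && ch) {
    code <- paste0(
      "model {\n", lik,
      "    logit(p[j]) <- alpha[s[j]] + d[s[j], t[j]]\n  }\n",
      "  for (i in 1:Ns) {\n",
      "    alpha[i] ~ dnorm(0, fe_prec)\n",
      "    u[i] ~ dnorm(0, 2 / sigma_c2)\n",
      "    d[i, 1] <- 0\n",
      "    for (k in 2:K) {\n",
      "      e[i, k - 1] ~ dnorm(0, 2 / sigma_c2)\n",
      "      d[i, k] <- mu_c[k] + u[i] + e[i, k - 1]\n",
      "    }\n  }\n", mu_free, "\n", het_ch, "\n}\n")
  } else if (m == 2 && spec$form == "cb") {   # NCH
    code <- paste0(
      "model {\n", lik,
      "    logit(p[j]) <- alpha[s[j]] + d[s[j], t[j]]\n  }\n",
      "  for (i in 1:Ns) {\n",
      "    alpha[i] ~ dnorm(0, fe_prec)\n",
      "    d[i, 1] <- 0\n",
      "    dd[i, 1:(K-1)] ~ dmnorm(mu_c[2:K], Omega_c[,])\n",
      "    for (k in 2:K) { d[i, k] <- dd[i, k - 1] }\n  }\n",
      mu_free, "\n",
      "  Omega_c ~ dwish(S_c[,], df_c)\n",
      "  Sigma_c <- inverse(Omega_c)\n",
      "  for (k in 1:(K-1)) { vC[k] <- Sigma_c[k, k] }\n",
      "  sigma_c <- sqrt(mean(vC))\n}\n")
  } else if (m == 2 && spec$form == "ab") {
    code <- paste0(
      "model {\n", lik,
      "    logit(p[j]) <- alpha[s[j]] + mu_c[t[j]] + eta[s[j], t[j]]\n  }\n",
      "  for (i in 1:Ns) {\n",
      "    alpha[i] ~ dnorm(0, fe_prec)\n",
      "    for (k in 1:K) { eta[i, k] ~ dnorm(0, 2 / sigma_c2) }\n  }\n",
      mu_free, "\n", het_ch, "\n}\n")
  } else if (m == 3) {
    alpha_re <- paste0(
      "    alpha[i] ~ dnorm(mu_a1, 1 / sigma_a2)\n")
    arm_het <- paste(
      "  mu_a1 ~ dnorm(0, fe_prec)",
      "  lsa2 ~ dnorm(arm_mean, arm_prec)",
      "  sigma_a2 <- exp(lsa2)",
      "  sigma_a <- sqrt(sigma_a2)", sep = "\n")
    if (ch) {
      code <- paste0(
        "model {\n", lik,
        "    logit(p[j]) <- alpha[s[j]] + d[s[j], t[j]]\n  }\n",
        "  for (i in 1:Ns) {\n", alpha_re,
        "    u[i] ~ dnorm(0, 2 / sigma_c2)\n",
        "    d[i, 1] <- 0\n",
        "    for (k in 2:K) {\n",
        "      e[i, k - 1] ~ dnorm(0, 2 / sigma_c2)\n",
        "      d[i, k] <- mu_c[k] + u[i] + e[i, k - 1]\n",
        "    }\n  }\n", mu_free, "\n", het_ch, "\n", arm_het, "\n}\n")
    } else {
      code <- paste0(
        "model {\n", lik,
        "    logit(p[j]) <- alpha[s[j]] + d[s[j], t[j]]\n  }\n",
        "  for (i in 1:Ns) {\n", alpha_re,
        "    d[i, 1] <- 0\n",
        "    dd[i, 1:(K-1)] ~ dmnorm(mu_c[2:K], Omega_c[,])\n",
        "    for (k in 2:K) { d[i, k] <- dd[i, k - 1] }\n  }\n",
        mu_free, "\n",
        "  Omega_c ~ dwish(S_c[,], df_c)\n",
        "  Sigma_c <- inverse(Omega_c)\n",
        "  for (k in 1:(K-1)) { vC[k] <- Sigma_c[k, k] }\n",
        "  sigma_c <- sqrt(mean(vC))\n", arm_het, "\n}\n")
    }
  } else if (m == 4 && spec$form == "ab" && ch) {
    code <- paste0(
      "model {\n", lik,
      "    logit(p[j]) <- theta_v[s[j], t[j]]\n  }\n",
      "  for (i in 1:Ns) { theta_v[i, 1:K] ~ dmnorm(mu_a[], Omega_a[,]) }\n",
      "  for (k in 1:K) { mu_a[k] ~ dnorm(0, fe_prec) }\n",
      "  mu_c[1] <- 0\n",
      "  for (k in 2:K) { mu_c[k] <- mu_a[k] - mu_a[1] }\n",
      m4_ch_prior_block(),
      "  cA <- (1 / sigma_a2) * (1 + (K - 2) * rho_a) / ((1 - rho_a) * (1 + (K - 1) * rho_a))\n",
      "  cB <- -(1 / sigma_a2) * rho_a / ((1 - rho_a) * (1 + (K - 1) * rho_a))\n",
      "  for (k in 1:K) { for (l in 1:K) {\n",
      "    Omega_a[k, l] <- equals(k, l) * cA + (1 - equals(k, l)) * cB\n",
      "  } }\n}\n")
  } else if (m == 4 && spec$form == "ab") {   # NCH
    code <- paste0(
      "model {\n", lik,
      "    logit(p[j]) <- theta_v[s[j], t[j]]\n  }\n",
      "  for (i in 1:Ns) { theta_v[i, 1:K] ~ dmnorm(mu_a[], Omega_a[,]) }\n",
      "  for (k in 1:K) { mu_a[k] ~ dnorm(0, fe_prec) }\n",
      "  mu_c[1] <- 0\n",
      "  for (k in 2:K) { mu_c[k] <- mu_a[k] - mu_a[1] }\n",
      "  Omega_a ~ dwish(S_a[,], df_a)\n",
      "  Sigma_a <- inverse(Omega_a)\n",
      "  for (k in 1:K) { vA[k] <- Sigma_a[k, k] }\n",
      "  sigma_a <- sqrt(mean(vA))\n",
      "  for (k in 2:K) { vCk[k - 1] <- Sigma_a[1, 1] - 2 * Sigma_a[1, k] + Sigma_a[k, k] }\n",
      "  sigma_c <- sqrt(mean(vCk))\n}\n")
  } else {                                     # model 4, CB form (CH)
    code <- paste0(
      "model {\n", lik,
      "    logit(p[j]) <- ad[s[j], 1] + d[s[j], t[j]]\n  }\n",
      "  for (i in 1:Ns) {\n",
      "    ad[i, 1:K] ~ dmnorm(mu_st[], Omega_st[,])\n",
      "    d[i, 1] <- 0\n",
      "    for (k in 2:K) { d[i, k] <- ad[i, k] }\n  }\n",
      "  mu_a1 ~ dnorm(0, fe_prec)\n",
      "  mu_st[1] <- mu_a1\n",
      "  mu_c[1] <- 0\n",
      "  for (k in 2:K) { mu_c[k] ~ dnorm(0, fe_prec); mu_st[k] <- mu_c[k] }\n",
      "  for (k in 1:K) { mu_a[k] <- mu_a1 + mu_c[k] }\n",
      m4_ch_prior_block(),
      "  Sigma_st[1, 1] <- sigma_a2\n",
      "  for (k in 2:K) {\n",
      "    Sigma_st[1, k] <- -sigma_c2 / 2\n",
      "    Sigma_st[k, 1] <- -sigma_c2 / 2\n",
      "    Sigma_st[k, k] <- sigma_c2\n",
      "  }\n",
      "  for (k in 2:(K-1)) { for (l in (k+1):K) {\n",
      "    Sigma_st[k, l] <- sigma_c2 / 2\n",
      "    Sigma_st[l, k] <- sigma_c2 / 2\n",
      "  } }\n",
      "  Omega_st <- inverse(Sigma_st)\n}\n")
  }
  code
}

jags_data <- function(spec, net) {
  prior <- spec$prior
  a <- net$arms
  K <- net$n_treatments
  dat <- list(Na = nrow(a), Ns = net$n_studies, K = K,
              s = a$study, t = a$treatment, y = a$events, n = a$size,
              fe_prec = 1 / prior$fixed_effect_sd^2)
  ch <- spec$heterogeneity == "ch"
  if (ch) {
    dat$het_mean <- prior$het_meanlog
    dat$het_prec <- 1 / prior$het_sdlog^2
  }
  if (spec$model == 1) {
    two_arm <- vapply(net$designs, length, 1L) == 2
    if (!all(two_arm)) {
      stop("model 1 supports two-arm studies only; offending study id(s): ",
           paste(net$study_labels[!two_arm], collapse = ", "))
    }
    dat$b <- vapply(net$designs, min, 1L)
    dat$nb <- vapply(net$designs, max, 1L)
  }
  if (spec$model == 3) {
    dat$arm_mean <- prior$arm_het_meanlog
    dat$arm_prec <- 1 / prior$arm_het_sdlog^2
  }
  if (spec$model == 4 && spec$heterogeneity == "ch") {
    dat$rho_lo <- -1 / (K - 1) + prior$rho_eps
    dat$rho_hi <- 1 - prior$rho_eps
    dat$arm_mean <- prior$arm_het_meanlog
    dat$arm_prec <- 1 / prior$arm_het_sdlog^2
    dat$zero_arm <- 0
  }
  if (spec$heterogeneity == "nch") {
    np <- nch_prior_matrix(spec, K)
    if (np$dim < 2) stop("NCH needs at least 3 treatments (models 2-3)")
    if (spec$model == 4) {
      dat$S_a <- np$S; dat$df_a <- np$df
    } else {
      dat$S_c <- np$S; dat$df_c <- np$df
    }
    dat$het_mean <- NULL; dat$het_prec <- NULL
  }
  dat
}

# Empirical-logit initial values (0.5 continuity correction used for
# initialization only, never in the likelihood).
jags_inits <- function(spec, net, chain_seed) {
  a <- net$arms
  K <- net$n_treatments
  n <- net$n_studies
  elogit <- log((a$events + 0.5) / (a$size - a$events + 0.5))
  # study x treatment matrix of observed empirical logits
  em <- matrix(NA_real_, n, K)
  em[cbind(a$study, a$treatment)] <- elogit
  ref_logit <- vapply(seq_len(n), function(i) {
    d <- net$designs[[i]]
    em[i, min(d)]
  }, 0)
  prior <- spec$prior
  ini <- list(.RNG.name = "base::Mersenne-Twister",
              .RNG.seed = as.integer(chain_seed))
  m <- spec$model
  ch <- spec$heterogeneity == "ch"
  if (m == 1) {
    ini$alpha <- ref_logit
    ini$delta <- vapply(seq_len(n), function(i) {
      d <- net$designs[[i]]
      em[i, max(d)] - em[i, min(d)]
    }, 0)
    ini$mu_c <- c(NA, rep(0, K - 1))
    ini$lsc2 <- prior$het_meanlog
  } else if (m == 2 && spec$form == "cb") {
    ini$alpha <- ref_logit
    ini$mu_c <- c(NA, rep(0, K - 1))
    if (ch) {
      ini$u <- rep(0, n)
      ini$e <- matrix(0, n, K - 1)
      ini$lsc2 <- prior$het_meanlog
    } else {
      np <- nch_prior_matrix(spec, K)
      ini$dd <- matrix(0, n, K - 1)
      ini$Omega_c <- solve(np$S) * np$df
    }
  } else if (m == 2 && spec$form == "ab") {
    ini$alpha <- ref_logit
    ini$mu_c <- c(NA, rep(0, K - 1))
    ini$eta <- matrix(0, n, K)
    ini$lsc2 <- prior$het_meanlog
  } else if (m == 3) {
    ini$alpha <- ref_logit
    ini$mu_c <- c(NA, rep(0, K - 1))
    ini$mu_a1 <- mean(ref_logit)
    ini$lsa2 <- prior$arm_het_meanlog
    if (ch) {
      ini$u <- rep(0, n)
      ini$e <- matrix(0, n, K - 1)
      ini$lsc2 <- prior$het_meanlog
    } else {
      np <- nch_prior_matrix(spec, K)
      ini$dd <- matrix(0, n, K - 1)
      ini$Omega_c <- solve(np$S) * np$df
    }
  } else if (m == 4 && spec$form == "ab") {
    th <- em
    for (i in seq_len(n)) th[i, is.na(th[i, ])] <- mean(em[i, ], na.rm = TRUE)
    ini$theta_v <- th
    ini$mu_a <- rep(mean(elogit), K)
    if (ch) {
      ini$lsc2 <- prior$het_meanlog
      ini$rho_a <- 0.5
    } else {
      np <- nch_prior_matrix(spec, K)
      ini$Omega_a <- solve(np$S) * np$df
    }
  } else {                       # model 4 CB
    ad <- cbind(ref_logit, matrix(0, n, K - 1))
    for (i in seq_len(n)) {
      for (k in 2:K) if (!is.na(em[i, k])) ad[i, k] <- em[i, k] - ref_logit[i]
    }
    ini$ad <- ad
    ini$mu_a1 <- mean(ref_logit)
    ini$mu_c <- c(NA, rep(0, K - 1))
    ini$lsc2 <- prior$het_meanlog
    ini$rho_a <- 0.5
  }
  ini
}

jags_monitors <- function(spec, K) {
  m <- spec$model
  mon <- c("mu_c", "sigma_c")
  if (m %in% 1:3) mon <- c(mon, "alpha")
  if (m == 3) mon <- c(mon, "sigma_a", "mu_a1")
  if (m == 4) mon <- c(mon, "sigma_a", "mu_a")
  if (m == 4 && spec$heterogeneity == "ch") mon <- c(mon, "rho_a")
  if (spec$heterogeneity == "nch") {
    mon <- c(mon, if (m == 4) "Sigma_a" else "Sigma_c")
  }
  mon
}

#' Fit a structural NMA model by MCMC
#'
#' Translates the model specification into a JAGS program, runs the chain
#' regime in `config`, and returns the retained posterior draws.  With a
#' fixed `config$seed` repeated calls return identical draws.
#'
#' Monitored parameters always include the mean contrasts `mu_c[k]` and
#' the contrast heterogeneity sd `sigma_c`; models 3-4 add the arm
#' heterogeneity sd `sigma_a`, and model 4 with common heterogeneity adds
#' the intercept-effect correlation `rho_a`.
#'
#' @param spec a [model_spec()].
#' @param net an [nma_network()]; model 1 requires all studies two-arm.
#' @param config a [chain_config()].
#' @param monitor extra JAGS node names to monitor.
#' @param quiet suppress JAGS progress output (default `TRUE`).
#' @return An object of class `nma_fit`: list with `draws` (matrix, one
#'   column per monitored scalar), `chain` (chain index per row), `spec`,
#'   `config`, `network` and `data_hash`.
#' @export
nma_fit <- function(spec, net, config = chain_config(), monitor = NULL,
                    quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(net, "nma_network"),
            inherits(config, "chain_config"))
  K <- net$n_treatments
  code <- bugs_model_code(spec, K)
  dat <- jags_data(spec, net)
  inits <- lapply(seq_len(config$n_chains), function(c_) {
    jags_inits(spec, net, config$seed + c_ - 1)
  })
  mon <- unique(c(jags_monitors(spec, K), monitor))
  jm <- tryCatch(
    rjags::jags.model(textConnection(code), data = dat, inits = inits,
                      n.chains = config$n_chains, n.adapt = config$n_adapt,
                      quiet = quiet),
    error = function(e) {
      stop("JAGS could not initialize the model (", conditionMessage(e),
           "); initial values: ",
           paste(utils::capture.output(utils::str(inits[[1]])), collapse = " "))
    })
  if (config$burn_in > 0) {
    update(jm, config$burn_in, progress.bar = if (quiet) "none" else "text")
  }
  sm <- rjags::coda.samples(jm, variable.names = mon,
                            n.iter = config$post_burn, thin = config$thin,
                            progress.bar = if (quiet) "none" else "text")
  draws <- do.call(rbind, lapply(sm, as.matrix))
  chain <- rep(seq_len(config$n_chains),
               each = nrow(draws) / config$n_chains)
  structure(list(draws = draws, chain = chain, params = colnames(draws),
                 spec = spec, config = config, network = net,
                 data_hash = content_hash(net$arms)),
            class = "nma_fit")
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("nma_fit:", model_label(x$spec), "fitted to", x$network$n_studies,
      "studies /", x$network$n_treatments, "treatments\n")
  cat(nrow(x$draws), "retained draws (", x$config$n_chains, "chain(s), thin",
      x$config$thin, ")\n")
  core <- intersect(c(grep("^mu_c\\[", x$params, value = TRUE),
                      "sigma_c", "sigma_a", "rho_a"), x$params)
  sm <- posterior_summary(x)
  print(sm[sm$parameter %in% core, ], row.names = FALSE)
  invisible(x)
}

# Draw-wise mean contrast k vs k2 (k2 defaults to the reference 1).
contrast_draws <- function(fit, k, k2 = 1) {
  col <- function(kk) {
    if (kk == 1) return(rep(0, nrow(fit$draws)))
    nm <- sprintf("mu_c[%d]", kk)
    if (!nm %in% fit$params) stop("contrast parameter ", nm, " not monitored")
    fit$draws[, nm]
  }
  col(k) - col(k2)
}
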