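# Model specifications and prior configuration.
#
# The four structural models share the exact binomial arm likelihood
# y_ik ~ Binomial(n_ik, expit(theta_ik)) and differ in the structural model
# for the arm log-odds theta_ik:
#
#   model 1  theta_ik = alpha_i(b_i) + delta_i(b_i,k),  fixed intercepts at a
#            study-specific base treatment b_i; contrasts
#            delta ~ N(mu_c[k] - mu_c[b_i], sigma_c2).  Two-arm studies only.
#   model 2  theta_ik = alpha_i + delta_ik for all K arms, delta_i ~
#            MVN(mu_c, Sigma_c) (CB form), or the symmetric AB form
#            theta_ik = alpha_i + mu_c[k] + eta_ik, eta_i ~ MVN(0, Sigma_a2).
#   model 3  model 2 plus random intercepts alpha_i ~ N(mu_a1, sigma_a2).
#   model 4  theta_i ~ MVN(mu_a, Sigma_a) (AB form), equivalently
#            (alpha_i, delta_i) ~ MVN(mu_star, Sigma_star) (CB form);
#            intercepts and effects may be correlated.
#
# Heterogeneity is either common (CH: one contrast variance for all pairs,
# compound symmetry in model 4) or non-common (NCH: unstructured covariance
# with an inverse-Wishart prior).

#' Prior configuration
#'
#' Priors are matched across models so that model comparisons reflect
#' structure, not priors.  Unconstrained location parameters (fixed study
#' intercepts, mean effects) get normal priors with variance
#' `fixed_effect_sd^2` (default variance 1000).  The contrast heterogeneity
#' variance `sigma_c2` gets a lognormal prior: the shipped default
#' `(het_meanlog, het_sdlog) = (-2.56, 1.74)` is an evidence-based
#' predictive distribution for log-odds-ratio heterogeneity in
#' pharmacological-versus-placebo comparisons (Turner et al. 2012, subjective
#' outcomes); it is a configurable default, not a universal constant.
#' Every model variant derives its variance-component prior from this one:
#'
#' * models 1-3 CH place the lognormal directly on `sigma_c2`;
#' * model 4 CH is parameterized in `(sigma_c2, rho_a)` with the same
#'   lognormal on `sigma_c2` and, on the derived arm variance
#'   `sigma_a2 = sigma_c2 / (2 (1 - rho_a))`, the same lognormal used for
#'   model 3's intercept variance, restricted to the positive-definite
#'   range of `rho_a`;
#' * NCH models use an inverse-Wishart with `dim + nch_df_extra` degrees of
#'   freedom and scale matrix chosen so the prior mean of the *log*
#'   contrast variances (and, for model 4, log arm variances) equals the
#'   corresponding lognormal's meanlog (moment matching on the log scale).
#'
#' The intercept variance `sigma_a2` in model 3 is a separate quantity
#' (variation in underlying risk, typically larger than contrast
#' heterogeneity) and gets its own, deliberately weak, lognormal prior.
#'
#' @param fixed_effect_sd sd of the normal prior on location parameters.
#' @param het_meanlog,het_sdlog lognormal prior parameters for `sigma_c2`.
#' @param arm_het_meanlog,arm_het_sdlog lognormal prior parameters for the
#'   model-3 intercept variance `sigma_a2`.
#' @param nch_df_extra degrees of freedom above the matrix dimension for
#'   the NCH inverse-Wishart prior (default 2, so the prior mean equals the
#'   scale matrix).
#' @param rho_eps the uniform prior on `rho_a` is over
#'   `(-1/(K-1) + rho_eps, 1 - rho_eps)`; the margin keeps the covariance
#'   numerically invertible at the boundary.
#' @return a list of class `prior_config`.
#' @export
prior_config <- function(fixed_effect_sd = sqrt(1000),
                         het_meanlog = -2.56, het_sdlog = 1.74,
                         arm_het_meanlog = 0, arm_het_sdlog = 2,
                         nch_df_extra = 2, rho_eps = 1e-3) {
  stopifnot(fixed_effect_sd > 0, het_sdlog > 0, arm_het_sdlog > 0,
            nch_df_extra >= 1, rho_eps > 0, rho_eps < 0.5)
  structure(list(fixed_effect_sd = fixed_effect_sd,
                 het_meanlog = het_meanlog, het_sdlog = het_sdlog,
                 arm_het_meanlog = arm_het_meanlog,
                 arm_het_sdlog = arm_het_sdlog,
                 nch_df_extra = nch_df_extra, rho_eps = rho_eps),
            class = "prior_config")
}

# Inverse-Wishart scale matrix and df for the NCH prior on the model's
# native covariance (Sigma_c for models 2-3, Sigma_a for model 4).
#
# Matching rule: for Sigma ~ IW(S, df) any quadratic form v'Sigma v is
# inverse-gamma with E[log v'Sigma v] = log(v'Sv) - log 2 - digamma(a),
# a = (df - p + 1)/2.  The scale S is chosen so the prior mean of the log
# contrast variances equals the CH lognormal's meanlog (and, for model 4,
# the mean log arm variance equals the arm prior's meanlog).  The spread
# of the log variances is set by df and cannot also be matched; with
# df = p + 2 it is about 0.97, of the same order as the lognormal
# defaults.
nch_prior_matrix <- function(spec, K) {
  prior <- spec$prior
  if (spec$model == 4) p <- K else p <- K - 1
  df <- p + prior$nch_df_extra
  kappa <- 2 * exp(digamma((df - p + 1) / 2))
  c_target <- kappa * exp(prior$het_meanlog)     # contrast variances
  if (spec$model == 4) {
    a_target <- kappa * exp(prior$arm_het_meanlog)  # arm variances
    S <- matrix(a_target - c_target / 2, K, K)
    diag(S) <- a_target
    if (a_target <= c_target / 2) stop("NCH arm/contrast targets not PSD")
  } else {
    S <- c_target * p_matrix(K - 1, 0.5)
  }
  list(S = S, df = df, dim = p)
}

#' Specify a structural NMA model
#'
#' @param model integer 1-4 selecting the structural model (see the package
#'   vignette): 1 = contrast-based with fixed intercepts at a study base
#'   treatment, 2 = contrast-based describing all arms, 3 = random study
#'   intercepts independent of effects, 4 = arm-based with correlated
#'   random intercepts.
#' @param form `"cb"` or `"ab"`: parameterization used for sampling.  Only
#'   models 2 and 4 have both forms (they give the same posterior); default
#'   is `"cb"` for model 2 and `"ab"` for model 4.
#' @param heterogeneity `"ch"` (common) or `"nch"` (non-common).  Model 1
#'   supports CH only; use model 2 for NCH.
#' @param prior a [prior_config()].
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(model, form = NULL,
                       heterogeneity = c("ch", "nch"),
                       prior = prior_config()) {
  heterogeneity <- match.arg(heterogeneity)
  stopifnot(length(model) == 1, model %in% 1:4)
  model <- as.integer(model)
  if (model == 1 && heterogeneity == "nch") {
    stop("model 1 supports common heterogeneity only; ",
         "use model 2 for non-common heterogeneity")
  }
  if (is.null(form)) form <- if (model == 4) "ab" else "cb"
  form <- match.arg(form, c("cb", "ab"))
  if (model %in% c(1, 3) && form == "ab") {
    stop("models 1 and 3 have only a contrast-based form")
  }
  if (model == 2 && form == "ab" && heterogeneity == "nch") {
    stop("the arm-based form of model 2 is implemented for common ",
         "heterogeneity only; use the contrast-based form for NCH")
  }
  stopifnot(inherits(prior, "prior_config"))
  structure(list(model = model, form = form, heterogeneity = heterogeneity,
                 prior = prior),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model %d (%s form), %s heterogeneity\n", x$model,
              toupper(x$form), toupper(x$heterogeneity)))
  invisible(x)
}

# Short label used in reports, matching the conventional numbering.
model_label <- function(spec) {
  sprintf("model %d %s", spec$model, toupper(spec$heterogeneity))
}

#' Serialize / restore a model specification
#'
#' `spec_to_list()` turns a `model_spec` into plain lists suitable for JSON
#' or YAML; `spec_from_list()` inverts it.  Fitted results store the fully
#' resolved configuration this way.
#'
#' @param spec a `model_spec`.
#' @return a plain list.
#' @export
spec_to_list <- function(spec) {
  list(model = spec$model, form = spec$form,
       heterogeneity = spec$heterogeneity,
       prior = unclass(spec$prior))
}

#' @rdname spec_to_list
#' @param x a list as produced by `spec_to_list()`.
#' @export
spec_from_list <- function(x) {
  model_spec(x$model, form = x$form, heterogeneity = x$heterogeneity,
             prior = do.call(prior_config, x$prior))
}

#' Sample from the prior
#'
#' Draws the quantities used to verify that priors are comparable across
#' model variants: mean contrasts, the contrast heterogeneity sd
#' `sigma_c` (for NCH, the sd of each contrast versus the reference), and
#' where defined the arm heterogeneity sd `sigma_a` and correlation `rho_a`.
#'
#' @param spec a [model_spec()].
#' @param n_draws number of independent prior draws.
#' @param seed integer seed.
#' @param K number of treatments the network will have (default 3).
#' @return data frame of prior draws.
#' @export
sample_prior <- function(spec, n_draws, seed = 1L, K = 3) {
  stopifnot(n_draws >= 1, K >= 2)
  prior <- spec$prior
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- data.frame(row.names = seq_len(n_draws))
  for (k in 2:K) {
    out[[sprintf("mu_c[%d]", k)]] <- stats::rnorm(n_draws, 0, prior$fixed_effect_sd)
  }
  if (spec$heterogeneity == "ch") {
    sc2 <- stats::rlnorm(n_draws, prior$het_meanlog, prior$het_sdlog)
    out$sigma_c <- sqrt(sc2)
    if (spec$model == 3) {
      out$sigma_a <- sqrt(stats::rlnorm(n_draws, prior$arm_het_meanlog,
                                        prior$arm_het_sdlog))
    }
    if (spec$model == 4) {
      # independent lognormals on (sigma_c2, sigma_a2), kept in the
      # positive-definite range of rho_a by rejection
      lo <- -1 / (K - 1) + prior$rho_eps
      hi <- 1 - prior$rho_eps
      rho <- sa2 <- numeric(n_draws)
      todo <- seq_len(n_draws)
      while (length(todo)) {
        cand <- stats::rlnorm(length(todo), prior$arm_het_meanlog,
                              prior$arm_het_sdlog)
        r <- 1 - sc2[todo] / (2 * cand)
        ok <- r > lo & r < hi
        sa2[todo[ok]] <- cand[ok]
        rho[todo[ok]] <- r[ok]
        todo <- todo[!ok]
      }
      out$rho_a <- rho
      out$sigma_a <- sqrt(sa2)
    }
  } else {
    np <- nch_prior_matrix(spec, K)
    Winv <- solve(np$S)
    draws <- stats::rWishart(n_draws, np$df, Winv)
    for (j in seq_len(n_draws)) {
      Sig <- solve(draws[, , j])
      if (spec$model == 4) {
        cv <- vapply(2:K, function(k) contrast_variance(Sig, 1, k), 0)
        out[j, paste0("sigma_c[", 2:K, "]")] <- sqrt(cv)
        out[j, "sigma_a"] <- sqrt(mean(diag(Sig)))
      } else {
        out[j, paste0("sigma_c[", 2:K, "]")] <- sqrt(diag(Sig))
      }
    }
    cs <- grep("^sigma_c\\[", names(out))
    out$sigma_c <- sqrt(rowMeans(as.matrix(out[cs])^2))
  }
  out
}

# Save/restore the global RNG state so sampling helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
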