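# Posterior summaries and chain diagnostics.

get_param_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "nma_fit"))
  if (!parameter %in% fit$params) {
    stop("parameter '", parameter, "' was not monitored; available: ",
         paste(utils::head(fit$params, 20), collapse = ", "),
         if (length(fit$params) > 20) ", ...")
  }
  fit$draws[, parameter]
}

#' Sample autocorrelation of a thinned chain
#'
#' Computed on the retained (post-thinning) draws, per chain, then averaged
#' across chains.  A constant chain has undefined autocorrelation and
#' returns 0 with a warning, so diagnostic tables stay numeric.
#'
#' @param fit an [nma_fit()].
#' @param parameter monitored parameter name.
#' @param lag positive integer lag (in retained draws).
#' @return the autocorrelation estimate.
#' @export
autocorrelation <- function(fit, parameter, lag = 1) {
  stopifnot(lag >= 1)
  x <- get_param_draws(fit, parameter)
  per_chain <- vapply(unique(fit$chain), function(c_) {
    xc <- x[fit$chain == c_]
    if (stats::var(xc) == 0) {
      warning("constant chain for '", parameter, "'; autocorrelation set to 0")
      return(0)
    }
    if (length(xc) <= lag + 1) stop("not enough retained draws for lag ", lag)
    stats::acf(xc, lag.max = lag, plot = FALSE, demean = TRUE)$acf[lag + 1]
  }, 0)
  mean(per_chain)
}

#' Posterior medians and 95% credible intervals
#'
#' Central intervals use `stats::quantile()` type 7 (linear interpolation
#' of order statistics).
#'
#' @param fit an [nma_fit()].
#' @param parameter a parameter name, or `NULL` for all monitored ones.
#' @return data frame with columns `parameter`, `median`, `ci_low`,
#'   `ci_high`.
#' @export
posterior_summary <- function(fit, parameter = NULL) {
  pars <- parameter %||% fit$params
  rows <- lapply(pars, function(p) {
    x <- get_param_draws(fit, p)
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(parameter = p, median = q[2], ci_low = q[1], ci_high = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior regression slope between two monitored parameters
#'
#' Least-squares slope of the `y` draws on the `x` draws across retained
#' samples; a draw-level summary of how strongly two parameters co-move in
#' the joint posterior.
#'
#' @param fit an [nma_fit()].
#' @param y,x monitored parameter names (response, regressor).
#' @return the slope `cov(x, y) / var(x)`.
#' @export
posterior_slope <- function(fit, y, x) {
  yd <- get_param_draws(fit, y)
  xd <- get_param_draws(fit, x)
  v <- stats::var(xd)
  if (v == 0) stop("zero variance in regressor '", x, "'")
  stats::cov(xd, yd) / v
}

#' Monte Carlo standard error of a posterior median
#'
#' Batch-means estimate: the chain is split into consecutive batches, the
#' median is computed per batch, and the standard error of the batch
#' medians' mean is returned.  Conservative for autocorrelated chains with
#' enough batches.
#'
#' @param x numeric vector of draws.
#' @param n_batches number of consecutive batches (default 20).
#' @return standard error estimate.
#' @export
mcse_median <- function(x, n_batches = 20) {
  n <- length(x)
  n_batches <- min(n_batches, n)
  idx <- cut(seq_len(n), n_batches, labels = FALSE)
  bm <- tapply(x, idx, stats::median)
  stats::sd(bm) / sqrt(n_batches)
}

#' Diagnostics table for a fit
#'
#' Autocorrelations at a range of post-thinning lags for every monitored
#' parameter, as used to check the chain regime.
#'
#' @param fit an [nma_fit()].
#' @param lags integer vector of lags (default 1:20).
#' @param parameters parameter subset (default: all monitored).
#' @return data frame, one row per parameter, one column per lag.
#' @export
autocorrelation_table <- function(fit, lags = 1:20, parameters = NULL) {
  pars <- parameters %||% fit$params
  out <- data.frame(parameter = pars)
  for (L in lags) {
    out[[paste0("lag", L)]] <- vapply(pars, function(p) {
      suppressWarnings(autocorrelation(fit, p, L))
    }, 0)
  }
  rownames(out) <- NULL
  out
}
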