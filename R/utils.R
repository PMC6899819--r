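# Internal numerical helpers.

#' Inverse logit
#'
#' @param x numeric vector of log-odds.
#' @return event probabilities `1 / (1 + exp(-x))`.
#' @export
expit <- function(x) stats::plogis(x)

#' Logit
#'
#' @param p numeric vector of probabilities in (0, 1).
#' @return log-odds `log(p / (1 - p))`.
#' @export
logit <- function(p) stats::qlogis(p)

# Round half away from zero (half-up for the non-negative expected counts
# used here); base round() rounds half to even, which we do not want for
# reproducible expected-count data construction.
round_half_up <- function(x) floor(x + 0.5)

# Log-density of a multivariate normal evaluated via Cholesky.
# Returns -Inf for covariance matrices that are singular in a direction the
# deviation x - mean actually uses.
log_dmvnorm <- function(x, mean, Sigma) {
  d <- as.numeric(x - mean)
  p <- length(d)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    # PSD but singular: project onto range space
    eg <- eigen(Sigma, symmetric = TRUE)
    pos <- eg$values > max(eg$values, 0) * 1e-12
    z <- crossprod(eg$vectors, d)
    if (any(abs(z[!pos]) > 1e-8)) return(-Inf)
    if (!any(pos)) return(if (all(abs(d) < 1e-8)) 0 else -Inf)
    return(-0.5 * (sum(pos) * log(2 * pi) + sum(log(eg$values[pos])) +
                     sum(z[pos]^2 / eg$values[pos])))
  }
  z <- backsolve(ch, d, transpose = TRUE)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# Log-density of an inverse-Wishart(S, df) evaluated at Sigma (p x p).
# Parameterized so that E[Sigma] = S / (df - p - 1).
log_dinvwish <- function(Sigma, S, df) {
  p <- nrow(S)
  chS <- chol(S)
  chX <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  lgammap <- sum(lgamma((df + 1 - seq_len(p)) / 2)) + p * (p - 1) / 4 * log(pi)
  ldetS <- 2 * sum(log(diag(chS)))
  ldetX <- 2 * sum(log(diag(chX)))
  tr <- sum(diag(chol2inv(chX) %*% S))
  df / 2 * ldetS - (df * p / 2) * log(2) - lgammap -
    (df + p + 1) / 2 * ldetX - 0.5 * tr
}

# md5 content hash of an arbitrary R object (used to fingerprint inputs in
# result bundles so reruns can verify they used identical data/config).
content_hash <- function(object) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(object, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
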