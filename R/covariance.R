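# Heterogeneity covariance structures.
#
# All between-study covariance structures used by the four structural
# models are built from the exchangeable-correlation matrix P_n(rho): unit
# diagonal, all off-diagonals rho.  P_n(rho) is positive definite for
# rho in (-1/(n-1), 1).

#' Exchangeable correlation matrix
#'
#' @param n dimension (>= 1).
#' @param rho common off-diagonal correlation.
#' @return the `n` x `n` matrix with 1 on the diagonal and `rho` elsewhere.
#' @export
p_matrix <- function(n, rho) {
  stopifnot(n >= 1)
  m <- matrix(rho, n, n)
  diag(m) <- 1
  m
}

#' Common-heterogeneity contrast covariance
#'
#' Covariance of the (K-1)-vector of study-level contrasts versus the
#' reference treatment under common heterogeneity: every pairwise contrast
#' (including those not involving the reference) then has the same
#' heterogeneity variance `sigma_c2`.
#'
#' @param sigma_c2 contrast heterogeneity variance (>= 0).
#' @param K number of treatments (>= 2).
#' @return the (K-1) x (K-1) matrix `sigma_c2 * p_matrix(K - 1, 0.5)`.
#' @export
ch_contrast_cov <- function(sigma_c2, K) {
  if (sigma_c2 < 0) stop("sigma_c2 must be non-negative")
  stopifnot(K >= 2)
  sigma_c2 * p_matrix(K - 1, 0.5)
}

#' Arm-effect covariance for the symmetric form of the all-arms model
#'
#' In the arm-based rewriting of the all-arms contrast model, iid arm
#' effects with variance `sigma_c2 / 2` induce exactly the common
#' heterogeneity `sigma_c2` for every pairwise contrast.
#'
#' @inheritParams ch_contrast_cov
#' @return the K x K matrix `0.5 * sigma_c2 * I`.
#' @export
model2_ab_arm_cov <- function(sigma_c2, K) {
  if (sigma_c2 < 0) stop("sigma_c2 must be non-negative")
  diag(0.5 * sigma_c2, K)
}

#' Compound-symmetry arm covariance for the arm-based model
#'
#' The arm-based model with common heterogeneity uses
#' `Sigma_a = sigma_a2 * P_K(rho_a)`: one arm heterogeneity variance and
#' one intercept-effect correlation.  The induced contrast heterogeneity is
#' `2 * sigma_a2 * (1 - rho_a)` for every pair; `rho_a = 1` means
#' treatment contrasts are homogeneous (and unrelated to underlying risk).
#'
#' @param sigma_a2 arm heterogeneity variance (>= 0).
#' @param rho_a correlation in `(-1/(K-1), 1]`.
#' @param K number of treatments.
#' @return the K x K matrix `sigma_a2 * p_matrix(K, rho_a)`.
#' @export
model4_ch_cov <- function(sigma_a2, rho_a, K) {
  if (sigma_a2 < 0) stop("sigma_a2 must be non-negative")
  if (rho_a <= -1 / (K - 1) || rho_a > 1) {
    stop("rho_a must lie in (-1/(K-1), 1] for a valid covariance")
  }
  sigma_a2 * p_matrix(K, rho_a)
}

#' Diagonal arm covariance (for comparison only)
#'
#' The diagonal structure `diag(sigma_k2)` forces every contrast
#' heterogeneity to exceed every arm heterogeneity, which is rarely
#' plausible; it is provided for comparison tests, not as a recommended
#' modeling choice.
#'
#' @param sigma_k2 vector of per-arm variances.
#' @return diagonal matrix.
#' @export
diag_arm_cov <- function(sigma_k2) {
  if (any(sigma_k2 < 0)) stop("variances must be non-negative")
  diag(sigma_k2, length(sigma_k2))
}

#' Heterogeneity variance of a pairwise contrast
#'
#' @param Sigma arm (or contrast) covariance matrix.
#' @param k,k2 distinct indices into `Sigma`.
#' @return `Sigma[k,k] - 2 * Sigma[k,k2] + Sigma[k2,k2]`.
#' @export
contrast_variance <- function(Sigma, k, k2) {
  if (k == k2) stop("k and k2 must differ")
  Sigma[k, k] - 2 * Sigma[k, k2] + Sigma[k2, k2]
}

#' Contrast heterogeneity implied by the compound-symmetry arm covariance
#'
#' @inheritParams model4_ch_cov
#' @return `2 * sigma_a2 * (1 - rho_a)`.
#' @export
sigma_c_from_arm <- function(sigma_a2, rho_a) {
  if (sigma_a2 < 0) stop("sigma_a2 must be non-negative")
  2 * sigma_a2 * (1 - rho_a)
}
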