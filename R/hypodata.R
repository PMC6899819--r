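# Deterministic hypothetical NMA data sets with known truth.
#
# Ten constructed data sets for a three-treatment network (X = 1, Y = 2,
# Z = 3) in which Y and Z are identical treatments, every study has an X
# arm, and no study compares Y with Z head to head.  The Z-versus-Y
# contrast (truth: 0) is then estimated purely indirectly, which makes the
# data sets sharp probes of how much between-study information a model
# uses and of what happens when study design is associated with underlying
# risk.
#
# Scenarios (see scenario_spec): 1 no effect, 2 constant effect 0.5,
# 3 constant effect 0.5 with small arms, 4/5 effect decreasing/increasing
# in underlying risk with average 0.5.  Type a interleaves Y-vs-X and
# Z-vs-X designs across the whole underlying-risk grid; type b gives Y-vs-X
# studies the low-risk half and Z-vs-X studies the high-risk half, so that
# between-study information disagrees with within-study information.
#
# Event counts are expected counts rounded half-up, not binomial samples:
# the data sets are fixed constructions, so analyses of them are exactly
# reproducible.  Binomial sampling is available behind `sample_counts` for
# robustness studies.

#' Specify a hypothetical data scenario
#'
#' @param scenario integer 1-5: treatment-effect pattern and arm size
#'   (1: log OR 0, 200/arm; 2: log OR 0.5, 200/arm; 3: log OR 0.5, 50/arm;
#'   4/5: log OR averaging 0.5, decreasing/increasing with underlying risk,
#'   200/arm).
#' @param subtype `"a"` (similar designs interleaved across the risk grid,
#'   11 studies) or `"b"` (Y-vs-X studies low risk, Z-vs-X high risk,
#'   10 studies).
#' @return list of class `scenario_spec` with the X log-odds grid, design
#'   assignment, arm size and effect rule parameters.
#' @export
scenario_spec <- function(scenario, subtype = c("a", "b")) {
  subtype <- match.arg(subtype)
  stopifnot(length(scenario) == 1, scenario %in% 1:5)
  scenario <- as.integer(scenario)
  arm_size <- if (scenario == 3) 50L else 200L
  if (subtype == "a") {
    x_grid <- seq(-2, 0, length.out = 11)
    # interleave six Y-vs-X with five Z-vs-X designs
    comparator <- rep(c(2L, 3L), length.out = 11)
  } else {
    x_grid <- c(seq(-2, -1.2, by = 0.2), seq(-0.8, 0, by = 0.2))
    comparator <- rep(c(2L, 3L), each = 5)
  }
  # Linear effect rule delta(alpha) = 0.5 - slope * sgn * (alpha - mean(alpha));
  # slope calibrated so the type-b between-design gap in mean true effects
  # is exactly -0.5 (scenario 4) / +0.5 (scenario 5): the design-mean X
  # log-odds differ by 1.2 under the grids above.
  slope <- switch(as.character(scenario), "4" = 0.5 / 1.2, "5" = -0.5 / 1.2, 0)
  base_effect <- if (scenario == 1) 0 else 0.5
  structure(list(scenario = scenario, subtype = subtype,
                 arm_size = arm_size, x_grid = x_grid,
                 comparator = comparator,
                 base_effect = base_effect, slope = slope),
            class = "scenario_spec")
}

#' True study-level treatment effect under a scenario
#'
#' The log odds ratio (Y/Z versus X) of the study whose X-arm log-odds is
#' `x_logodds`: constant (0 or 0.5) for scenarios 1-3, linear in the
#' centered X log-odds for scenarios 4-5, averaging 0.5 over the grid.
#'
#' @param spec a [scenario_spec()].
#' @param x_logodds study-level log odds on treatment X.
#' @return the true log odds ratio(s).
#' @export
effect_rule <- function(spec, x_logodds) {
  stopifnot(inherits(spec, "scenario_spec"))
  spec$base_effect - spec$slope * (x_logodds - mean(spec$x_grid))
}

#' Generate a hypothetical data set
#'
#' @param scenario integer 1-5 or a [scenario_spec()].
#' @param subtype `"a"` or `"b"` (ignored when `scenario` is already a
#'   spec).
#' @param sample_counts if `TRUE`, draw binomial counts instead of rounding
#'   expected counts (requires `seed`).
#' @param seed RNG seed used only when `sample_counts = TRUE`.
#' @return list of class `nma_hypodata` with elements `network` (an
#'   [nma_network()] with treatments X=1, Y=2, Z=3), `truth` (data frame of
#'   per-study true log ORs) and `spec`.
#' @export
generate_scenario <- function(scenario, subtype = "a",
                              sample_counts = FALSE, seed = NULL) {
  spec <- if (inherits(scenario, "scenario_spec")) scenario else
    scenario_spec(scenario, subtype)
  alpha <- spec$x_grid
  delta <- effect_rule(spec, alpha)
  n_arm <- spec$arm_size
  p_x <- expit(alpha)
  p_t <- expit(alpha + delta)
  if (sample_counts) {
    if (is.null(seed)) stop("sample_counts = TRUE requires a seed")
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    ev_x <- stats::rbinom(length(alpha), n_arm, p_x)
    ev_t <- stats::rbinom(length(alpha), n_arm, p_t)
  } else {
    ev_x <- round_half_up(n_arm * p_x)
    ev_t <- round_half_up(n_arm * p_t)
  }
  ns <- length(alpha)
  arms <- rbind(
    data.frame(study = seq_len(ns), treatment = 1L, events = ev_x, size = n_arm),
    data.frame(study = seq_len(ns), treatment = spec$comparator,
               events = ev_t, size = n_arm))
  truth <- data.frame(study = seq_len(ns), comparator = spec$comparator,
                      x_logodds = alpha, true_logOR = delta)
  structure(list(network = nma_network(arms, reference = 1),
                 truth = truth, spec = spec,
                 overall = c(logOR_YX = mean(delta), logOR_ZX = mean(delta),
                             logOR_ZY = 0)),
            class = "nma_hypodata")
}

#' @export
print.nma_hypodata <- function(x, ...) {
  cat(sprintf("hypothetical data %d%s: %d studies, %d per arm\n",
              x$spec$scenario, x$spec$subtype,
              x$network$n_studies, x$spec$arm_size))
  invisible(x)
}

#' Expected direct-comparison bias of the Z-versus-Y contrast
#'
#' Bookkeeping oracle for generator calibration: the difference between the
#' design-stratified means of the true study effects (mean true log OR
#' among Z-vs-X studies minus that among Y-vs-X studies).  An analysis
#' using between-study or design-level information on a type-b data set is
#' pulled by roughly this amount; for type-a (and constant-effect)
#' data sets it is zero.
#'
#' @param hd an `nma_hypodata`.
#' @return the expected bias (0 for type-a data).
#' @export
design_bias_oracle <- function(hd) {
  stopifnot(inherits(hd, "nma_hypodata"))
  if (hd$spec$subtype == "a") return(0)
  tr <- hd$truth
  mean(tr$true_logOR[tr$comparator == 3]) -
    mean(tr$true_logOR[tr$comparator == 2])
}

#' All ten hypothetical data sets
#'
#' @return named list of `nma_hypodata` objects, `"1a"` through `"5b"`.
#' @export
all_scenarios <- function() {
  out <- list()
  for (sc in 1:5) for (ty in c("a", "b")) {
    out[[paste0(sc, ty)]] <- generate_scenario(sc, ty)
  }
  out
}
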