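# Reproducible run bundles and model-comparison tables.
#
# run_fit() ties the modules together: resolve a data source, fit a model,
# and write a bundle of plain-text artifacts (draws CSV, summary CSV,
# autocorrelation diagnostics, resolved config JSON including seed and
# input content hashes) so a run can be reproduced from the config alone.

#' Fit a model and write a result bundle
#'
#' @param spec a [model_spec()].
#' @param net an [nma_network()].
#' @param config a [chain_config()].
#' @param out_dir output directory (created if needed).
#' @param label file-name stem for the bundle (default from the model).
#' @param diag_lags lags for the autocorrelation report.
#' @param ac_warn warn if any monitored parameter's autocorrelation at
#'   `max(diag_lags)` is at or above this (default 0.2); the warning is
#'   recorded in the diagnostics file, and the run still succeeds.
#' @return the [nma_fit()] object, invisibly, with attribute `"files"`.
#' @export
run_fit <- function(spec, net, config = chain_config(), out_dir,
                    label = NULL, diag_lags = 1:20, ac_warn = 0.2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  label <- label %||% gsub(" ", "_", model_label(spec))
  fit <- nma_fit(spec, net, config)
  f_draws <- file.path(out_dir, paste0(label, "_draws.csv"))
  utils::write.csv(as.data.frame(fit$draws), f_draws, row.names = FALSE)
  f_sum <- file.path(out_dir, paste0(label, "_summary.csv"))
  utils::write.csv(posterior_summary(fit), f_sum, row.names = FALSE)
  ac <- autocorrelation_table(fit, lags = diag_lags)
  f_diag <- file.path(out_dir, paste0(label, "_diagnostics.csv"))
  worst <- max(abs(ac[[paste0("lag", max(diag_lags))]]))
  if (worst >= ac_warn) {
    warning(sprintf(
      "autocorrelation %.2f at lag %d still >= %.2f for some parameter",
      worst, max(diag_lags), ac_warn))
  }
  utils::write.csv(ac, f_diag, row.names = FALSE)
  f_cfg <- file.path(out_dir, paste0(label, "_config.json"))
  jsonlite::write_json(
    list(model = spec_to_list(spec), chain = unclass(fit$config),
         data_hash = fit$data_hash,
         config_hash = content_hash(list(spec_to_list(spec),
                                         unclass(fit$config))),
         n_studies = net$n_studies, n_treatments = net$n_treatments,
         worst_autocorrelation = worst),
    f_cfg, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(draws = f_draws, summary = f_sum, diagnostics = f_diag,
             config = f_cfg)
  attr(fit, "files") <- files
  invisible(fit)
}

#' Forest table comparing models on one contrast
#'
#' @param fits named list of [nma_fit()] objects sharing one network.
#' @param k,k2 the contrast to tabulate (default `k` versus reference).
#' @return data frame with one row per fit: `model`, `median`, `ci_low`,
#'   `ci_high` of the `k` vs `k2` log odds ratio.
#' @export
compare_fits <- function(fits, k, k2 = 1) {
  if (length(fits) == 0) stop("no fits supplied")
  hashes <- vapply(fits, function(f) f$data_hash, "")
  if (length(unique(hashes)) != 1) {
    stop("fits were run on different networks; refusing to tabulate")
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    s <- conditional_contrast(f, k, k2)
    data.frame(model = names(fits)[i] %||% model_label(f$spec),
               median = s$median, ci_low = s$ci_low, ci_high = s$ci_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
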