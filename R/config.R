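#' Pipeline configuration
#'
#' One document holding the tunable defaults of every pipeline stage, so a
#' run can be reproduced from its configuration file alone. \code{...} or
#' a YAML file override the defaults; unknown keys are rejected.
#'
#' @param path Optional YAML file of overrides.
#' @param ... Named overrides applied after the file.
#' @return Named list of class \code{"pipeline_config"} with entries:
#'   \code{mu_soft} (cm^-1), \code{T_phys} (h), \code{sigma0}/\code{slope}
#'   (collimator response), \code{n_views}, \code{seconds_per_view},
#'   \code{sensitivity_cpm_per_mbq}, \code{n_iterations}/\code{n_subsets}
#'   (OS-EM), \code{body_threshold} (scatter-window contour),
#'   \code{voi_threshold}, \code{bin_width} (h), \code{fit_weighting},
#'   \code{n_boot}, \code{seed}.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    mu_soft = 0.15, T_phys = 6.0,
    sigma0 = 0.2, slope = 0.02,
    n_views = 120, seconds_per_view = 8,
    sensitivity_cpm_per_mbq = 5005,
    n_iterations = 5, n_subsets = 16,
    body_threshold = 0.20, voi_threshold = 0.40,
    bin_width = 1 / 6, fit_weighting = "equal",
    n_boot = 2000, seed = 1)
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    utils::modifyList(cfg, over)
  }
  if (!is.null(path))
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  over <- list(...)
  if (length(over))
    cfg <- apply_over(cfg, over, "arguments")
  structure(cfg, class = "pipeline_config")
}

#' @method print pipeline_config
#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' @rdname pipeline_config
#' @param config A \code{"pipeline_config"}.
#' @param path Output YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
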