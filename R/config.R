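#' Analysis configuration
#'
#' Thresholds shared across the pipeline: minimum bootstrap support (percent)
#' and Bayesian posterior for accepting a lineage as supported, and the
#' identity/coverage thresholds for assigning environmental query sequences.
#'
#' @param bootstrap_support_min minimum bootstrap percentage for a supported
#'   lineage (default 70).
#' @param posterior_min minimum Bayesian posterior probability, used only
#'   when posterior values are supplied (default 0.95).
#' @param identity_min assignment requires identity strictly greater than
#'   this fraction (default 0.97).
#' @param coverage_required minimum fraction of the reference region a query
#'   must cover to be assignable (default 1.0).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(bootstrap_support_min = 70, posterior_min = 0.95,
                            identity_min = 0.97, coverage_required = 1.0) {
  if (!is.numeric(bootstrap_support_min) || bootstrap_support_min < 0 ||
      bootstrap_support_min > 100)
    stop("bootstrap_support_min must be a percentage in [0, 100]")
  if (!is.numeric(posterior_min) || posterior_min < 0 || posterior_min > 1)
    stop("posterior_min must be a probability in [0, 1]")
  if (!is.numeric(identity_min) || identity_min < 0 || identity_min > 1)
    stop("identity_min must be a fraction in [0, 1]")
  if (!is.numeric(coverage_required) || coverage_required < 0 ||
      coverage_required > 1)
    stop("coverage_required must be a fraction in [0, 1]")
  structure(list(bootstrap_support_min = bootstrap_support_min,
                 posterior_min = posterior_min,
                 identity_min = identity_min,
                 coverage_required = coverage_required),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  bootstrap support >= %g%%; posterior >= %g (when supplied)\n",
              x$bootstrap_support_min, x$posterior_min))
  cat(sprintf("  query assignment: identity > %g, coverage >= %g\n",
              x$identity_min, x$coverage_required))
  invisible(x)
}
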