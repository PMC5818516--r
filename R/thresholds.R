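#' Pipeline thresholds
#'
#' Bundle of the four cut-offs that drive the gene-prioritization funnel. The
#' defaults are the conventional values used throughout the package: a gene is
#' copy-number-gained (CNG) when its gain/loss sample ratio exceeds
#' `ratio_cutoff`, a CNG gene is "frequent" when strictly more than
#' `min_cng_samples` samples carry a gain, a sample is over-expressed when its
#' expression Z-score strictly exceeds `z_cutoff`, and a gene is a key gene
#' when strictly more than `min_concordant_samples` samples are concordantly
#' gained and over-expressed.
#'
#' All comparisons downstream are strict (`>`), so e.g. a gene with exactly 30
#' gained samples does not pass the frequent-CNG filter.
#'
#' @param ratio_cutoff Gain/loss (and loss/gain) sample-count ratio above which
#'   a gene is classified CNG (resp. CNL). Default 2.
#' @param min_cng_samples Minimum number of gained samples (strict) for the
#'   frequent-CNG filter. Default 30.
#' @param z_cutoff Z-score above which a sample is called over-expressed
#'   (below `-z_cutoff`: under-expressed). Default 2.
#' @param min_concordant_samples Minimum number of gain+over-expression
#'   concordant samples (strict) for key-gene selection. Default 20.
#'
#' @return An object of class `pipeline_thresholds` (a named list).
#' @export
#' @examples
#' pipeline_thresholds()
#' pipeline_thresholds(min_cng_samples = 50)
pipeline_thresholds <- function(ratio_cutoff = 2,
                                min_cng_samples = 30,
                                z_cutoff = 2,
                                min_concordant_samples = 20) {
  th <- list(
    ratio_cutoff = ratio_cutoff,
    min_cng_samples = min_cng_samples,
    z_cutoff = z_cutoff,
    min_concordant_samples = min_concordant_samples
  )
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  structure(th, class = "pipeline_thresholds")
}

#' @export
print.pipeline_thresholds <- function(x, ...) {
  cat("<pipeline_thresholds>\n")
  cat("  gain/loss ratio cutoff      >", x$ratio_cutoff, "\n")
  cat("  frequent-CNG sample cutoff  >", x$min_cng_samples, "\n")
  cat("  over-expression Z cutoff    >", x$z_cutoff, "\n")
  cat("  key-gene concordant cutoff  >", x$min_concordant_samples, "\n")
  invisible(x)
}

as_thresholds <- function(thresholds) {
  if (inherits(thresholds, "pipeline_thresholds")) {
    return(thresholds)
  }
  if (is.list(thresholds)) {
    return(do.call(pipeline_thresholds, thresholds))
  }
  stop("`thresholds` must be a pipeline_thresholds object or a named list",
    call. = FALSE
  )
}
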