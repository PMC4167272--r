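#' Worked-example agreement data
#'
#' Bundled worked-example inputs for the agreement toolkit, representative of
#' a chronic LAD-territory infarct cohort of eleven animals scored on the
#' 16-segment AHA model (176 segments) by two blinded reviewers with both
#' infarct classifiers: the four pooled cross-tabulations of ADC-positive
#' versus LGE-positive segments, and the regional group means.
#'
#' `example_location_tables()` returns a named list of
#' [contingency_from_counts()] tables (`r1_fwhm`, `r1_threshold`, `r2_fwhm`,
#' `r2_threshold`); `example_group_means()` returns the regional trace-ADC
#' (um^2/ms) and wall-motion (mm) levels for remote myocardium and for
#' infarct delineated by each classifier.
#'
#' @return See description.
#' @export
example_location_tables <- function() {
  list(
    r1_fwhm = contingency_from_counts(51, 1, 4, 120),
    r1_threshold = contingency_from_counts(52, 7, 8, 109),
    r2_fwhm = contingency_from_counts(45, 2, 2, 127),
    r2_threshold = contingency_from_counts(53, 6, 9, 108)
  )
}

#' @rdname example_location_tables
#' @export
example_group_means <- function() {
  data.frame(
    region = c("remote", "infarct_fwhm", "infarct_threshold"),
    adc_mean = c(1.4, 2.4, 2.4),
    adc_sd = c(0.3, 0.2, 0.3),
    rwm_mean = c(8.3, 0.9, 1.0),
    rwm_sd = c(0.1, 0.4, 0.4)
  )
}

#' Percent elevation of one group mean over another
#'
#' Convenience used to express the infarct-over-remote ADC increase:
#' `100 * (a - b) / b`.
#'
#' @param a,b group means.
#' @return Percentage.
#' @export
percent_increase <- function(a, b) 100 * (a - b) / b
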