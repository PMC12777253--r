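#' Engine configuration
#'
#' Named constants of the reanalysis engine, all overridable.
#'
#' @param lambda_min,lambda_max Calibration bounds for the likelihood of a
#'   gene zygosity that matches a disease's gene link: the likelihood is
#'   `lambda_min + (lambda_max - lambda_min) * (severity / 5) * penetrance`.
#'   Defaults 0.05 and 0.95.
#' @param phi False-positive rate: the likelihood of observing a damaged
#'   gene zygosity under a disease not linked to that gene (an incidental
#'   damaged gene). Default 0.01.
#' @param epsilon_onset Multiplicative down-weight applied to a present
#'   finding whose onset falls outside the association's onset window.
#'   Default 0.1.
#' @param af_multiplier Multiplier on the incidence-derived allele-frequency
#'   threshold of the variant frequency filter; absorbs penetrance and
#'   prevalence slack. Default 1.
#' @param min_depth Read-depth threshold below which a supporting variant
#'   earns the zygosity a `low_depth` consistency flag. Default 10.
#' @param severity_table Named numeric vector mapping consequence classes to
#'   base severity scores on the 0-5 scale.
#' @return A `reanalysis_config` list.
#' @export
reanalysis_config <- function(lambda_min = 0.05, lambda_max = 0.95,
                              phi = 0.01, epsilon_onset = 0.1,
                              af_multiplier = 1, min_depth = 10,
                              severity_table = c(
                                lof = 5, missense_damaging = 3,
                                missense_benign = 1, synonymous = 0.5,
                                noncoding = 0.5, other = 1)) {
  stopifnot(lambda_min > 0, lambda_max < 1, lambda_min < lambda_max,
            phi > 0, phi < 1, epsilon_onset > 0, epsilon_onset <= 1,
            af_multiplier > 0, min_depth >= 0,
            all(severity_table >= 0), all(severity_table <= 5))
  structure(
    list(lambda_min = lambda_min, lambda_max = lambda_max, phi = phi,
         epsilon_onset = epsilon_onset, af_multiplier = af_multiplier,
         min_depth = min_depth, severity_table = severity_table),
    class = "reanalysis_config"
  )
}
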