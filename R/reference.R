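#' Literature-reported GLCM group means for ovarian carcinoma cell lines
#'
#' Group-mean texture features (offset distance 10, angle 0, 150 x 150 px
#' patches at 256 gray levels) reported in the originating study for
#' wild-type (WT) and cisplatin-resistant (CP) sublines of three ovarian
#' carcinoma cell lines, with the corresponding published combined S/N
#' scores. Values are on their natural scale (the source prints contrast
#' as multiples of 10^3, energy of 10^-3 and homogeneity of 10^-1).
#'
#' These means are useful as a convention check: applying the pooled
#' combiner of [combined_snr()] to a group's four mean feature values
#' reproduces the published OVCAR-4 S/N scores to within 0.2 dB, which is
#' what motivated the default pooling rule.
#'
#' @return data.frame with columns `cell_line`, `group`, `contrast`,
#'   `entropy`, `energy`, `homogeneity`, `snr_published`.
#' @export
reference_feature_means <- function() {
  data.frame(
    cell_line = rep(c("OVCAR-4", "A2780", "IGROV1"), each = 2),
    group = rep(c("WT", "CP"), 3),
    contrast = c(0.54, 0.53, 0.91, 1.35, 0.74, 1.32) * 1e3,
    entropy = c(6.36, 7.70, 8.23, 8.85, 7.92, 9.41),
    energy = c(3.80, 0.83, 0.45, 0.20, 0.61, 0.18) * 1e-3,
    homogeneity = c(1.99, 0.99, 0.60, 0.40, 0.71, 0.33) * 1e-1,
    snr_published = c(17.93, 21.76, 23.37, 24.44, 22.81, 25.09),
    stringsAsFactors = FALSE
  )
}
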