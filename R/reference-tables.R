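#' Published variance components for the Norway spruce provenance trial
#'
#' REML variance components (individual and residual; plus the provenance
#' component for the across-provenance "Overall" rows) for the four drought
#' response indicators in the 11-provenance Norway spruce trial the pipeline
#' emulates, together with the published repeatability (`r_printed`, `NA`
#' where not estimable) and its published significance flag. Used to check
#' that [repeatability_ratio()] reproduces every published ratio and that
#' [select_subset_qd()] reproduces the published provenance subset
#' \{R06, d14, I19, Q14, R13, S10\}.
#'
#' @return data.frame `scope, trait, sigma2_prov, sigma2_ind, sigma2_res,
#'   r_printed, significant`.
#' @export
provenance_trial_varcomp <- function() {
  path <- system.file("extdata", "provenance_trial_varcomp.csv",
                      package = "dendrogwas", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
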