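#' Bundled example: combined-environment means of a wheat diallel trial
#'
#' Adjusted overall means (across two Moroccan locations and two
#' seasons) of 18 elite spring bread wheat parents and their 23 F1
#' hybrids for biomass (BM, t/ha), thousand kernel weight (TKW, g) and
#' grain yield (YLD, t/ha), as printed in the trial report the package
#' reproduces. Useful as input to [heterosis_table()].
#'
#' @return data frame with columns \code{genotype}, \code{role},
#'   \code{trait}, \code{estimate}.
#' @export
#' @examples
#' head(diallel_example_means())
diallel_example_means <- function() {
  path <- system.file("extdata", "wheat_diallel_overall_means.csv",
                      package = "diallelkit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Bundled example: the 7 x 11 partial-diallel crossing plan
#'
#' The 23 realized crosses of the bundled wheat trial: 7 male lines
#' (P1, P3, P4, P9, P10, P13, P16) by 11 female testers. Hybrid labels
#' follow the trial's MALE/FEMALE naming.
#'
#' @return a [crossing_plan()].
#' @export
diallel_example_plan <- function() {
  path <- system.file("extdata", "wheat_diallel_crossing_plan.csv",
                      package = "diallelkit", mustWork = TRUE)
  read_crossing_plan(path)
}

#' Bundled example: hybrid-analysis variance components
#'
#' Printed combining-ability variance components of the bundled wheat
#' trial (hybrids analyzed separately) for the eight plot traits:
#' per-parent GCA variance, SCA variance, GCA x location variance and
#' plot error variance, in trait units squared.
#'
#' @return data frame with columns \code{trait}, \code{sigma2_gca},
#'   \code{sigma2_sca}, \code{sigma2_gca_location}, \code{sigma2_e}.
#' @export
diallel_example_ca_varcomps <- function() {
  data.frame(
    trait = c("DH", "PLH", "SPL", "SPS", "TLP", "BM", "TKW", "YLD"),
    sigma2_gca = c(0.19, 2.64, 0.03, 0.07, 0.05, 0.08, 0.09, 0.07),
    sigma2_sca = c(0, 0, 0, 0, 0.02, 0.015, 0.08, 0.011),
    sigma2_gca_location = c(0.09, 0, 0, 0.02, 0, 0.07, 0.04, 0.02),
    sigma2_e = c(3.31, 11.45, 53.61, 101.17, 82.46, 2.91, 9.27, 1.06),
    stringsAsFactors = FALSE
  )
}
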