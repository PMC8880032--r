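#' Trait registry for hybrid wheat trial phenotypes
#'
#' Returns the metadata table for the traits handled by the package:
#' phenology and agronomic traits scored on yield-trial plots (DH, PLH,
#' SPL, SPS, TLP, BM, TKW, YLD), male floral traits scored in crossing
#' blocks (VAE, PM, PSH, AL, GYS) and hybrid seed set on male-sterile
#' females (SEEDSET). Visual scores (VAE, PSH) carry 1-9 scale bounds;
#' all other traits are unbounded measurements.
#'
#' @param names optional character vector to subset the registry; unknown
#'   names raise an error.
#' @return A data frame with columns \code{name}, \code{units},
#'   \code{scale_min}, \code{scale_max} (NA unless the trait is a 1-9
#'   visual score) and \code{higher_is_better}.
#' @export
#' @examples
#' trait_registry(c("YLD", "VAE"))
trait_registry <- function(names = NULL) {
  reg <- data.frame(
    name = c("DH", "PLH", "SPL", "SPS", "TLP", "BM", "TKW", "YLD",
             "VAE", "PM", "PSH", "AL", "GYS", "SEEDSET"),
    units = c("days", "cm", "cm", "spikelets/spike", "tillers/plant",
              "t/ha", "g", "t/ha", "1-9 score", "mg", "1-9 score", "mm",
              "mg", "seeds/spike"),
    scale_min = NA_real_,
    scale_max = NA_real_,
    higher_is_better = TRUE,
    stringsAsFactors = FALSE
  )
  score <- reg$name %in% c("VAE", "PSH")
  reg$scale_min[score] <- 1
  reg$scale_max[score] <- 9
  if (!is.null(names)) {
    bad <- setdiff(names, reg$name)
    if (length(bad)) {
      stop("unknown trait(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    reg <- reg[match(names, reg$name), , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' Is a trait a bounded visual score?
#' @param trait character vector of trait names.
#' @param registry trait registry data frame.
#' @return logical vector.
#' @keywords internal
is_score_trait <- function(trait, registry = trait_registry()) {
  !is.na(registry$scale_min[match(trait, registry$name)])
}
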