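#' Five-year age bands used throughout the model
#'
#' The model stratifies every quantity by 5-year age band from 0-4 up to the
#' open-ended 100+ band (21 bands) and by sex. Bands are non-overlapping and
#' contiguous; all bands are 5 years wide except the open top band.
#'
#' @return A data.frame with columns `label`, `lower` and `upper` (years;
#'   `upper` is `Inf` for the open top band).
#' @export
#' @examples
#' age_bands()
age_bands <- function() {
  lower <- seq(0L, 100L, by = 5L)
  upper <- c(lower[-1] - 1L, Inf)
  label <- c(paste0(lower[-length(lower)], "-", upper[-length(upper)]), "100+")
  data.frame(label = label, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' @rdname age_bands
#' @export
band_labels <- function() age_bands()$label

#' @rdname age_bands
#' @export
model_sexes <- function() c("male", "female")

n_bands <- function() 21L

# index of the first band whose lower bound is >= age
band_index_from_age <- function(age) {
  findInterval(age, age_bands()$lower)
}

# coarse severity-split groups mapped onto 5-year bands by containment;
# bands below the first group's lower bound fall into the first group
severity_group_for_band <- function(groups_lower) {
  ab <- age_bands()
  idx <- findInterval(ab$lower, groups_lower)
  idx[idx == 0L] <- 1L
  idx
}
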