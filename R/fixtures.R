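#' @title Northwest-Oregon reference values
#' @description Published regional reference values for the five most common
#'   northwest-Oregon tree species: fitted height-model parameters, the
#'   regional live-tree carbon ranges by calculation approach and correlation
#'   assumption, and the crown-truncation convention. Used as worked-example
#'   inputs for the uncertainty metrics and as regression fixtures.
#' @name nwor_reference
NULL

#' The five northwest-Oregon target species
#'
#' Three conifers and two hardwoods that together account for about 90% of
#' the region's live trees.
#'
#' @return character vector of five binomials.
#' @export
nwor_species <- function() {
  c("Picea sitchensis", "Pseudotsuga menziesii", "Tsuga heterophylla",
    "Acer macrophyllum", "Alnus rubra")
}

#' Published height-model parameters for northwest Oregon
#'
#' Asymptotic height-DBH parameters fitted to regional inventory class means
#' weighted by 1/DBH (see [predict_height()]); `n` and `mse` are the
#' published fit metadata.
#'
#' @return named list of [height_params()] by species.
#' @seealso [nwor_height_table()] for the same values as a data frame.
#' @export
nwor_height_params <- function() {
  tb <- nwor_height_table()
  out <- lapply(seq_len(nrow(tb)), function(i)
    height_params(tb$species[i], tb$b0[i], tb$b1[i], tb$b2[i],
                  n = tb$n[i], mse = tb$mse[i]))
  stats::setNames(out, tb$species)
}

#' @rdname nwor_height_params
#' @export
nwor_height_table <- function() {
  data.frame(
    species = nwor_species(),
    b0 = c(62.5163, 63.054, 53.7148, 30.8836, 32.2499),
    b0_se = c(1.5675, 2.9339, 2.2051, 1.5888, 2.1472),
    b1 = c(-0.0122, -0.016, -0.0175, -0.0388, -0.0271),
    b1_se = c(0.00246, 0.00109, 0.00242, 0.00729, 0.00558),
    b2 = c(1.0123, 1.0711, 0.9956, 0.9151, 0.7346),
    b2_se = c(0.0724, 0.0338, 0.0536, 0.0901, 0.0489),
    n = c(121L, 142L, 103L, 80L, 71L),
    mse = c(25.11, 6.95, 10.08, 15.70, 7.51),
    stringsAsFactors = FALSE
  )
}

#' Published northwest-Oregon live-tree carbon ranges
#'
#' Regional live-tree carbon bounds (Tg C, trees 3-66 cm DBH) by species,
#' calculation approach (1 = uncorrected extrapolation, 2 = developmental
#' range only, 3 = extrapolation with corrections) and component-correlation
#' assumption, with the published integer uncertainty percents. The `"NWOR
#' total"` rows are the published totals; species bounds do not sum exactly
#' to them because the printed values are rounded.
#'
#' @return data frame: `correlation, approach, species, min_tg, max_tg,
#'   uncertainty_pct`.
#' @export
nwor_carbon_ranges <- function() {
  sp <- c(nwor_species(), "NWOR total")
  pos <- data.frame(
    correlation = "positive",
    approach = rep(1:3, each = 6),
    species = rep(sp, 3),
    min_tg = c(1.54, 9.56, 10.54, 1.48, 2.40, 25.53,
               1.53, 31.26, 11.40, 1.92, 10.13, 56.43,
               1.55, 18.57, 10.99, 1.83, 2.98, 35.92),
    max_tg = c(4.75, 455.32, 32.11, 3.12, 16.19, 512.21,
               4.13, 70.40, 26.33, 2.76, 15.59, 119.19,
               4.39, 135.57, 30.57, 3.13, 19.40, 193.26),
    uncertainty_pct = c(51, 96, 51, 36, 75, 91,
                        46, 38, 40, 18, 20, 36,
                        50, 76, 47, 26, 73, 68),
    stringsAsFactors = FALSE
  )
  neg <- data.frame(
    correlation = "negative",
    approach = rep(1:3, each = 6),
    species = rep(sp, 3),
    min_tg = c(2.26, 28.30, 15.58, 1.90, 5.10, 53.05,
               1.93, 38.18, 14.07, 2.08, 11.85, 68.11,
               2.13, 38.47, 14.93, 2.16, 7.78, 65.48),
    max_tg = c(3.61, 215.23, 23.97, 2.70, 14.40, 259.91,
               3.37, 60.68, 21.08, 2.63, 14.08, 101.83,
               3.57, 98.05, 23.92, 2.78, 14.40, 142.73),
    uncertainty_pct = c(23, 77, 21, 17, 48, 66,
                        27, 23, 20, 11, 9, 20,
                        25, 44, 23, 13, 30, 37),
    stringsAsFactors = FALSE
  )
  rbind(pos, neg)
}

#' Crown-truncation DBH conventions for northwest Oregon
#'
#' DBH class (cm) above which crown-component predictions are held flat under
#' the modified-extrapolation approach: the middle of each species' regional
#' DBH range. Alnus rubra (54 cm) is the only target species whose truncation
#' falls inside the 3-66 cm assessment grid; the others' truncations lie
#' above it and so never fire there, and are returned as `NA`.
#'
#' @return named numeric vector (species -> DBH class, cm).
#' @export
nwor_crown_truncation <- function() {
  c("Picea sitchensis" = NA_real_, "Pseudotsuga menziesii" = NA_real_,
    "Tsuga heterophylla" = NA_real_, "Acer macrophyllum" = NA_real_,
    "Alnus rubra" = 54)
}
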