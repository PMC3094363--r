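#' @title Regional assessment
#' @description Scale total-tree carbon envelopes to a regional inventory via
#'   per-tree expansion factors and summarise the resulting model-selection
#'   uncertainty.
#' @name regional_assessment
NULL

KG_PER_TG <- 1e9

#' Read an inventory file
#'
#' CSV with columns `species, dbh_cm, expansion_factor`. The expansion factor
#' is the number of trees in the population represented by the record.
#'
#' @param path CSV path.
#' @return data frame of tree records.
#' @export
read_inventory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!identical(names(df), c("species", "dbh_cm", "expansion_factor")))
    stopf("inventory header mismatch: expected species,dbh_cm,expansion_factor")
  validate_inventory(df)
}

validate_inventory <- function(df) {
  if (nrow(df)) {
    if (any(df$dbh_cm <= 0)) stopf("inventory DBH must be positive")
    if (any(df$expansion_factor <= 0))
      stopf("expansion factors must be positive")
  }
  df
}

# map tree DBHs to envelope grid classes (class label treated as the DBH
# input, so trees are binned to the nearest 1-cm class label)
dbh_to_class <- function(dbh, grid) {
  cls <- round_half_away(dbh)
  match(cls, grid)
}

#' Apply total-tree envelopes to an inventory
#'
#' Each tree's envelope bounds at its DBH class are multiplied by its
#' expansion factor; sums by species give regional bounds in Tg carbon
#' (1 Tg = 1e9 kg).
#'
#' @param inventory data frame with `species, dbh_cm, expansion_factor`.
#' @param envelopes named list of total-tree envelopes in kg-C, keyed by
#'   species.
#' @return data frame: `species, min_tg, max_tg`.
#' @export
apply_envelope <- function(inventory, envelopes) {
  validate_inventory(inventory)
  species <- sort(unique(inventory$species))
  unknown <- setdiff(species, names(envelopes))
  if (length(unknown))
    stopf("no envelope for species: %s", paste(unknown, collapse = ", "))
  res <- lapply(species, function(sp) {
    env <- envelopes[[sp]]
    if (env$units != "kg-C") stopf("envelope for %s is not in kg-C", sp)
    tr <- inventory[inventory$species == sp, , drop = FALSE]
    idx <- dbh_to_class(tr$dbh_cm, env$grid)
    bad <- is.na(idx) | !env$defined[idx]
    if (any(bad))
      stopf("species %s: %d trees fall in undefined DBH classes (%s)",
            sp, sum(bad),
            paste(utils::head(unique(round_half_away(tr$dbh_cm[bad])), 10),
                  collapse = ", "))
    data.frame(species = sp,
               min_tg = sum(tr$expansion_factor * env$lower[idx]) / KG_PER_TG,
               max_tg = sum(tr$expansion_factor * env$upper[idx]) / KG_PER_TG,
               stringsAsFactors = FALSE)
  })
  if (!length(res))
    return(data.frame(species = character(), min_tg = numeric(),
                      max_tg = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Half-range uncertainty as a percentage of the midpoint
#'
#' `100 * ((hi - lo)/2) / ((hi + lo)/2)`: half the width of a prediction
#' range expressed as a percentage of its midpoint. This is the uncertainty
#' metric reported throughout the regional assessment.
#'
#' @param lo,hi interval bounds (vectorised); `lo <= hi`, `lo + hi > 0`.
#' @return percent uncertainty, full precision (use [round_half_away()] for
#'   table presentation).
#' @export
#' @examples
#' uncertainty_percent(56.43, 119.19)  # ~35.7, prints as 36
uncertainty_percent <- function(lo, hi) {
  if (any(lo > hi)) stopf("lo must not exceed hi")
  if (any(lo + hi <= 0)) stopf("midpoint must be positive")
  100 * (hi - lo) / (hi + lo)
}

#' Species shares of regional uncertainty and of the midpoint estimate
#'
#' A species' uncertainty share is its half-width as a fraction of the summed
#' half-widths; its midpoint share is its interval midpoint as a fraction of
#' the summed midpoints. Each set of shares sums to 100 up to rounding.
#'
#' @param bounds data frame with `species, min_tg, max_tg` (one row per
#'   species).
#' @return the input with `uncertainty_share_pct` and `midpoint_share_pct`
#'   appended (full precision).
#' @export
species_shares <- function(bounds) {
  if (!nrow(bounds)) stopf("need at least one species")
  hw <- (bounds$max_tg - bounds$min_tg) / 2
  mid <- (bounds$max_tg + bounds$min_tg) / 2
  if (sum(hw) <= 0) stopf("all intervals are degenerate; shares undefined")
  bounds$uncertainty_share_pct <- 100 * hw / sum(hw)
  bounds$midpoint_share_pct <- 100 * mid / sum(mid)
  bounds
}

#' Regional estimate summary
#'
#' Per-species bounds plus a total row (totals are exact sums of the species
#' bounds), uncertainty percents and species shares.
#'
#' @param bounds output of [apply_envelope()].
#' @param total_label label for the total row.
#' @return data frame with one row per species plus the total row; columns
#'   `species, min_tg, max_tg, uncertainty_pct, uncertainty_share_pct,
#'   midpoint_share_pct` (shares `NA` on the total row).
#' @export
regional_estimate <- function(bounds, total_label = "Total") {
  b <- species_shares(bounds)
  b$uncertainty_pct <- uncertainty_percent(b$min_tg, b$max_tg)
  tot <- data.frame(species = total_label,
                    min_tg = sum(b$min_tg), max_tg = sum(b$max_tg),
                    uncertainty_share_pct = NA_real_,
                    midpoint_share_pct = NA_real_,
                    stringsAsFactors = FALSE)
  tot$uncertainty_pct <- uncertainty_percent(tot$min_tg, tot$max_tg)
  cols <- c("species", "min_tg", "max_tg", "uncertainty_pct",
            "uncertainty_share_pct", "midpoint_share_pct")
  rbind(b[cols], tot[cols])
}
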