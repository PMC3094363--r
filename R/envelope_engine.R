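#' @title Prediction envelopes
#' @description Per species x component x 1-cm DBH class, the interval between
#'   the lowest and highest predictions across all admissible equations and
#'   density conversion factors.
#' @name envelope_engine
NULL

ENVELOPE_UNITS <- c("m3", "kg-biomass", "kg-C")

CROWN_COMPONENTS_PATTERN <- "branch|foliage|crown"

is_crown_component <- function(component) {
  grepl(CROWN_COMPONENTS_PATTERN, tolower(component))
}

#' Construct a prediction envelope
#'
#' @param species species code.
#' @param component component name.
#' @param units one of `"m3"`, `"kg-biomass"`, `"kg-C"`.
#' @param grid strictly increasing 1-cm DBH classes (cm).
#' @param lower,upper per-class bounds; `lower <= upper` wherever defined.
#' @param defined logical coverage mask per class (classes with no admissible
#'   equation under approach 2 are undefined).
#' @param lower_eq,upper_eq provenance: id of the bounding candidate per class.
#' @return an object of class `envelope`.
#' @export
envelope <- function(species, component, units, grid, lower, upper,
                     defined = rep(TRUE, length(grid)),
                     lower_eq = rep(NA_character_, length(grid)),
                     upper_eq = rep(NA_character_, length(grid))) {
  if (!units %in% ENVELOPE_UNITS)
    stopf("units must be one of %s", paste(ENVELOPE_UNITS, collapse = ", "))
  if (is.unsorted(grid, strictly = TRUE)) stopf("grid must be strictly increasing")
  n <- length(grid)
  stopifnot(length(lower) == n, length(upper) == n, length(defined) == n)
  if (any(defined & (lower > upper + 1e-12), na.rm = TRUE))
    stopf("lower bound exceeds upper bound at some defined class")
  structure(list(species = species, component = component, units = units,
                 grid = grid, lower = lower, upper = upper, defined = defined,
                 lower_eq = lower_eq, upper_eq = upper_eq),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %s / %s [%s], %d classes (%g-%g cm), %d defined\n",
              x$species, x$component, x$units, length(x$grid),
              min(x$grid), max(x$grid), sum(x$defined)))
  invisible(x)
}

#' @export
as.data.frame.envelope <- function(x, ...) {
  data.frame(species = x$species, component = x$component, units = x$units,
             dbh_class = x$grid, lower = x$lower, upper = x$upper,
             defined = x$defined, lower_eq_id = x$lower_eq,
             upper_eq_id = x$upper_eq, stringsAsFactors = FALSE)
}

#' Serialize envelopes to CSV lookup tables
#'
#' @param env an `envelope` or list of envelopes.
#' @param path output CSV path.
#' @export
write_envelope <- function(env, path) {
  if (inherits(env, "envelope")) env <- list(env)
  utils::write.csv(do.call(rbind, lapply(env, as.data.frame)), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extrapolation policy for envelope construction
#'
#' The three contrasting treatments of equations outside their developmental
#' DBH range: approach 1 evaluates every equation over the whole grid with no
#' corrections (negative predictions retained); approach 2 evaluates each
#' equation only inside its developmental range (classes with no admissible
#' equation are undefined); approach 3 extrapolates like approach 1 but
#' applies an ordered list of modification rules intended to keep estimates
#' reasonable.
#'
#' @param approach 1, 2 or 3.
#' @param crown_truncation_dbh named numeric vector (species -> DBH class, cm)
#'   above which crown-component predictions are held flat (approach 3 only).
#' @param modifications ordered rule names for approach 3; subset of
#'   `c("clip-negative", "crown-truncation")`.
#' @return an `approach_policy` object.
#' @export
approach_policy <- function(approach = 1,
                            crown_truncation_dbh = NULL,
                            modifications = c("clip-negative", "crown-truncation")) {
  if (!approach %in% 1:3) stopf("approach must be 1, 2 or 3")
  modifications <- match.arg(modifications,
                             c("clip-negative", "crown-truncation"),
                             several.ok = TRUE)
  structure(list(approach = as.integer(approach),
                 crown_truncation_dbh = crown_truncation_dbh,
                 modifications = if (approach == 3) modifications else character()),
            class = "approach_policy")
}

#' Hold crown-component predictions flat above a truncation DBH
#'
#' Crown mass (branches, foliage) is not expected to keep increasing after a
#' tree reaches maturity, so for modified extrapolation the prediction at the
#' truncation class is applied to all larger classes.
#'
#' @param predictions numeric predictions parallel to `grid`.
#' @param grid DBH classes (cm).
#' @param truncation_dbh class (cm) at which to truncate; must be in `grid`.
#' @param component component name; must be a crown component (branches,
#'   foliage, live crown).
#' @return modified predictions.
#' @export
apply_crown_truncation <- function(predictions, grid, truncation_dbh,
                                   component = "branches total") {
  if (!is_crown_component(component))
    stopf("crown truncation applies only to crown components, not '%s'",
          component)
  i <- match(truncation_dbh, grid)
  if (is.na(i)) stopf("truncation DBH %g is not a grid class", truncation_dbh)
  predictions[grid > truncation_dbh] <- predictions[i]
  predictions
}

# expand one included equation into candidate prediction series on the grid.
# A volume equation contributes two candidates (rho_min, rho_max); a biomass
# equation contributes one. Returns list of list(id=, values=, units=).
equation_candidates <- function(eq, grid, heights, densities) {
  h <- if (identical(eq$predictors, "DBH-and-height")) {
    if (is.null(heights))
      stopf("equation '%s' needs heights; supply height_params", eq$id)
    heights
  } else NULL
  pred <- evaluate_equation(eq, grid, h)
  if (eq$response_kind == "biomass") {
    list(list(id = eq$id, values = pred, units = "kg-biomass"))
  } else {
    if (is.null(densities))
      return(list(list(id = eq$id, values = pred, units = "m3")))
    rho <- lookup_density(densities, eq$species, eq$component)
    list(list(id = paste0(eq$id, ":rho_min"), values = pred * rho$rho_min,
              units = "kg-biomass"),
         list(id = paste0(eq$id, ":rho_max"), values = pred * rho$rho_max,
              units = "kg-biomass"))
  }
}

#' Build a component prediction envelope
#'
#' For each 1-cm DBH class, the lower/upper bound is the min/max over all
#' admissible candidate predictions for the species and component. Volume
#' equations contribute two candidates (lowest and highest retained density)
#' before the min/max; approach 2 restricts each equation to its
#' developmental DBH range; approach 3 applies the policy's modification
#' rules in order.
#'
#' @param catalog an `allom_catalog` that already passed
#'   [apply_inclusion_rules()].
#' @param species,component selection keys.
#' @param grid DBH classes, default `3:66` cm.
#' @param policy an [approach_policy()].
#' @param height_params a [height_params()] for the species, required when
#'   any selected equation uses height.
#' @param densities density table, required when volume and biomass equations
#'   are mixed for the component.
#' @return an [envelope()]; units `"kg-biomass"` (or `"m3"` when all
#'   equations are volume equations and no densities are supplied).
#' @export
component_envelope <- function(catalog, species, component, grid = 3:66,
                               policy = approach_policy(1),
                               height_params = NULL, densities = NULL) {
  df <- as.data.frame(catalog)
  df <- df[df$species == species & df$component == component, , drop = FALSE]
  if (!nrow(df))
    stopf("no equations for %s / %s", species, component)
  heights <- if (!is.null(height_params)) predict_height(height_params, grid)
  cand <- list(); adm <- list()
  for (i in seq_len(nrow(df))) {
    eq <- df[i, ]
    ci <- equation_candidates(eq, grid, heights, densities)
    admissible <- if (policy$approach == 2) {
      if (is.na(eq$dev_min_cm) || is.na(eq$dev_max_cm))
        stopf("equation '%s' lacks a developmental range; approach 2 forbids its use",
              eq$id)
      grid >= eq$dev_min_cm & grid <= eq$dev_max_cm
    } else rep(TRUE, length(grid))
    for (cc in ci) {
      if (policy$approach == 3) {
        for (rule in policy$modifications) {
          if (rule == "clip-negative") cc$values <- pmax(cc$values, 0)
          if (rule == "crown-truncation" && is_crown_component(component)) {
            td <- policy$crown_truncation_dbh[[species]] %||% NULL
            if (!is.null(td) && !is.na(td) && td <= max(grid))
              cc$values <- apply_crown_truncation(cc$values, grid, td, component)
          }
        }
      }
      cand[[length(cand) + 1L]] <- cc
      adm[[length(adm) + 1L]] <- admissible
    }
  }
  units <- unique(vapply(cand, `[[`, "", "units"))
  if (length(units) != 1L)
    stopf("unit mixing for %s / %s: supply a density table to convert volume equations",
          species, component)
  n <- length(grid)
  lower <- rep(NA_real_, n); upper <- rep(NA_real_, n)
  lower_eq <- rep(NA_character_, n); upper_eq <- rep(NA_character_, n)
  defined <- rep(FALSE, n)
  vals <- vapply(cand, `[[`, numeric(n), "values")
  vals <- matrix(vals, nrow = n)
  admm <- matrix(unlist(adm), nrow = n)
  ids <- vapply(cand, `[[`, "", "id")
  for (j in seq_len(n)) {
    ok <- which(admm[j, ])
    if (!length(ok)) next
    v <- vals[j, ok]
    defined[j] <- TRUE
    lower[j] <- min(v); upper[j] <- max(v)
    lower_eq[j] <- ids[ok[which.min(v)]]
    upper_eq[j] <- ids[ok[which.max(v)]]
  }
  if (!any(defined))
    stopf("empty admissible set for %s / %s over the whole grid", species,
          component)
  envelope(species, component, units, grid, lower, upper, defined,
           lower_eq, upper_eq)
}

#' Convert a volume envelope to biomass
#'
#' The lower bound is multiplied by the lowest retained density and the upper
#' bound by the highest, so density uncertainty widens the envelope.
#'
#' @param env an `envelope` in m^3.
#' @param density one matching density row (see [density_record()]).
#' @return an `envelope` in kg oven-dry biomass.
#' @export
volume_to_biomass <- function(env, density) {
  stopifnot(inherits(env, "envelope"))
  if (env$units != "m3") stopf("envelope is not in volume units")
  if (!identical(density$species, env$species) ||
      !identical(density$component, env$component))
    stopf("density record does not match envelope species/component")
  # lower * rho_min / upper * rho_max; on classes where extrapolation left a
  # negative bound the interval product is taken properly so ordering holds
  envelope(env$species, env$component, "kg-biomass", env$grid,
           pmin(env$lower * density$rho_min, env$lower * density$rho_max),
           pmax(env$upper * density$rho_min, env$upper * density$rho_max),
           env$defined, env$lower_eq, env$upper_eq)
}

#' Convert a biomass envelope to carbon
#'
#' Carbon content of dry biomass is close to 50% but uncertain; minima are
#' multiplied by `c_min` and maxima by `c_max` (default 48% and 52%) so the
#' conversion-factor uncertainty is folded into the envelope.
#'
#' @param env an `envelope` in kg biomass.
#' @param c_min,c_max carbon fractions applied to the lower/upper bound.
#' @return an `envelope` in kg carbon.
#' @export
biomass_to_carbon <- function(env, c_min = 0.48, c_max = 0.52) {
  stopifnot(inherits(env, "envelope"))
  if (env$units != "kg-biomass") stopf("envelope is not in biomass units")
  # minima x c_min, maxima x c_max; negative bounds (possible under
  # uncorrected extrapolation) take the proper interval product
  envelope(env$species, env$component, "kg-C", env$grid,
           pmin(env$lower * c_min, env$lower * c_max),
           pmax(env$upper * c_min, env$upper * c_max),
           env$defined, env$lower_eq, env$upper_eq)
}
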