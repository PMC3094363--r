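#' @title Allometric equation catalogs
#' @description Data model, file I/O, validation and evaluation for published
#'   allometric volume/biomass equations and wood-density records.
#' @name equation_catalog
NULL

# columns of the catalog CSV dialect, in order; strict header checking
CATALOG_COLUMNS <- c(
  "id", "species", "component", "response_kind", "form_id", "coefficients",
  "predictors", "dev_min_cm", "dev_max_cm", "stump_height_cm",
  "extends_to_top", "log_base_e", "mse_log", "source", "dev_range_waiver"
)

DENSITY_COLUMNS <- c("species", "component", "rho_min", "rho_max")

EQUATION_FORMS <- c("linear-combination", "power", "log-log", "combined-variable")
VALID_PREDICTORS <- c("DBH-only", "DBH-and-height")
VALID_STUMP_HEIGHTS <- c(10, 15, 30)

#' Construct a single allometric equation record
#'
#' One published regression relating DBH (and optionally height) to stem
#' volume or oven-dry biomass of a tree component. Units are fixed across the
#' package: DBH in cm, height in m, volume in m^3, biomass in kg oven-dry.
#'
#' @param id opaque identifier, unique within a catalog.
#' @param species species code or binomial.
#' @param component component name from the aggregation-roadmap vocabulary
#'   (e.g. "stem wood", "stem bark", "branches total", "foliage total",
#'   "roots coarse", "aboveground total", "total tree").
#' @param response_kind `"volume"` (m^3) or `"biomass"` (kg oven-dry).
#' @param form_id one of `"linear-combination"` (y = c0 + c1 D \[+ c2 H\]),
#'   `"power"` (y = a D^b \[H^c\]), `"log-log"` (ln y = a + b ln D \[+ c ln H\]),
#'   `"combined-variable"` (y = a + b D^2 H).
#' @param coefficients numeric vector of ordered coefficients for the form.
#' @param predictors `"DBH-only"` or `"DBH-and-height"`; other strings are
#'   accepted at construction so that inclusion-rule filtering can reject
#'   them with an explicit reason.
#' @param dev_min_cm,dev_max_cm developmental DBH range (cm): the diameter
#'   interval of the trees used to fit the equation. `NA` if unreported.
#' @param stump_height_cm stump height convention in cm (10, 15 or 30 are the
#'   admissible conventions), or `NA` when not applicable (non-stem
#'   components).
#' @param extends_to_top does a stem equation predict to the stem tip?
#' @param log_base_e response modelled on the natural-log scale (required
#'   TRUE for `"log-log"` forms, FALSE otherwise).
#' @param mse_log residual mean square on the log scale, if reported.
#' @param source citation key.
#' @param dev_range_waiver per-record waiver of the developmental-range
#'   inclusion rule (used for institutional equations kept despite missing
#'   range metadata).
#' @return a one-row `allom_catalog` data frame.
#' @seealso [allom_catalog()], [evaluate_equation()], [apply_inclusion_rules()]
#' @export
allom_equation <- function(id, species, component, response_kind, form_id,
                           coefficients, predictors = "DBH-only",
                           dev_min_cm = NA_real_, dev_max_cm = NA_real_,
                           stump_height_cm = NA_real_, extends_to_top = TRUE,
                           log_base_e = form_id == "log-log",
                           mse_log = NA_real_, source = "synthetic",
                           dev_range_waiver = FALSE) {
  stopifnot(is_chr1(id), is_chr1(species), is_chr1(component))
  if (!response_kind %in% c("volume", "biomass"))
    stopf("equation '%s': response_kind must be 'volume' or 'biomass'", id)
  if (!form_id %in% EQUATION_FORMS)
    stopf("equation '%s': unknown form_id '%s'", id, form_id)
  coefficients <- as.numeric(coefficients)
  if (!length(coefficients) || any(!is.finite(coefficients)))
    stopf("equation '%s': coefficients must be finite", id)
  if (!is.na(dev_min_cm) || !is.na(dev_max_cm)) {
    if (is.na(dev_min_cm) || is.na(dev_max_cm) || dev_min_cm <= 0 ||
        dev_min_cm >= dev_max_cm)
      stopf("equation '%s': dev range must satisfy 0 < min < max", id)
  }
  if (form_id == "log-log" && !isTRUE(log_base_e))
    stopf("equation '%s': log-log form implies log_base_e", id)
  if (form_id != "log-log" && isTRUE(log_base_e))
    stopf("equation '%s': log_base_e is only defined for log-log forms", id)
  df <- data.frame(
    id = id, species = species, component = component,
    response_kind = response_kind, form_id = form_id,
    coefficients = paste(format(coefficients, digits = 17, trim = TRUE),
                         collapse = ";"),
    predictors = predictors, dev_min_cm = dev_min_cm, dev_max_cm = dev_max_cm,
    stump_height_cm = stump_height_cm, extends_to_top = extends_to_top,
    log_base_e = log_base_e, mse_log = mse_log, source = source,
    dev_range_waiver = dev_range_waiver,
    stringsAsFactors = FALSE
  )
  class(df) <- c("allom_catalog", "data.frame")
  df
}

#' Bind equation records into a catalog
#'
#' @param ... one-row records from [allom_equation()] or `allom_catalog`
#'   data frames.
#' @return an `allom_catalog` data frame (one row per equation).
#' @export
allom_catalog <- function(...) {
  parts <- list(...)
  if (!length(parts)) stopf("empty catalog")
  cat <- do.call(rbind, lapply(parts, as.data.frame))
  if (anyDuplicated(cat$id))
    stopf("duplicate equation ids: %s",
          paste(unique(cat$id[duplicated(cat$id)]), collapse = ", "))
  class(cat) <- c("allom_catalog", "data.frame")
  cat
}

#' @export
print.allom_catalog <- function(x, ...) {
  cat(sprintf("<allom_catalog> %d equations, %d species, %d components\n",
              nrow(x), length(unique(x$species)),
              length(unique(x$component))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

eq_coefs <- function(eq) as.numeric(strsplit(eq$coefficients, ";", fixed = TRUE)[[1]])

#' Read / write equation catalogs and density tables
#'
#' Catalog files are CSV with exactly the columns documented in
#' [allom_equation()] (coefficients as a `;`-delimited list), or JSON (an
#' array of objects with the same fields, coefficients as a JSON array).
#' Headers are checked strictly; files are UTF-8.
#'
#' @param path file path.
#' @return `read_catalog()` / `read_catalog_json()`: an `allom_catalog`;
#'   `read_densities()`: a density data frame.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!identical(names(df), CATALOG_COLUMNS))
    stopf("catalog header mismatch: expected %s",
          paste(CATALOG_COLUMNS, collapse = ","))
  validate_catalog_df(df)
}

#' @rdname read_catalog
#' @export
read_catalog_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  required <- setdiff(CATALOG_COLUMNS, c("dev_range_waiver", "mse_log",
                                         "stump_height_cm", "dev_min_cm",
                                         "dev_max_cm"))
  rows <- lapply(recs, function(r) {
    missing <- setdiff(required, names(r))
    if (length(missing))
      stopf("catalog JSON record missing fields: %s",
            paste(missing, collapse = ", "))
    if (!is.numeric(r$coefficients))
      stopf("catalog JSON record '%s': coefficients must be numeric",
            r$id %||% "?")
    allom_equation(
      id = r$id, species = r$species, component = r$component,
      response_kind = r$response_kind, form_id = r$form_id,
      coefficients = r$coefficients, predictors = r$predictors,
      dev_min_cm = r$dev_min_cm %||% NA_real_,
      dev_max_cm = r$dev_max_cm %||% NA_real_,
      stump_height_cm = r$stump_height_cm %||% NA_real_,
      extends_to_top = isTRUE(r$extends_to_top),
      log_base_e = isTRUE(r$log_base_e),
      mse_log = r$mse_log %||% NA_real_, source = r$source,
      dev_range_waiver = isTRUE(r$dev_range_waiver)
    )
  })
  do.call(allom_catalog, rows)
}

#' @rdname read_catalog
#' @param catalog an `allom_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog)[CATALOG_COLUMNS], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_catalog
#' @export
read_densities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!identical(names(df), DENSITY_COLUMNS))
    stopf("density header mismatch: expected %s",
          paste(DENSITY_COLUMNS, collapse = ","))
  validate_densities(df)
}

validate_catalog_df <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    allom_equation(
      id = r$id, species = r$species, component = r$component,
      response_kind = r$response_kind, form_id = r$form_id,
      coefficients = as.numeric(strsplit(as.character(r$coefficients),
                                         ";", fixed = TRUE)[[1]]),
      predictors = r$predictors, dev_min_cm = r$dev_min_cm,
      dev_max_cm = r$dev_max_cm, stump_height_cm = r$stump_height_cm,
      extends_to_top = as.logical(r$extends_to_top),
      log_base_e = as.logical(r$log_base_e), mse_log = r$mse_log,
      source = r$source, dev_range_waiver = isTRUE(as.logical(r$dev_range_waiver))
    )
  })
  do.call(allom_catalog, rows)
}

#' Wood-density records
#'
#' Minimum and maximum oven-dry wood density retained per species and
#' component, used to convert volume predictions to the two biomass bounds.
#'
#' @param species,component keys matching the equation catalog.
#' @param rho_min,rho_max density bounds in kg per m^3; `0 < rho_min <= rho_max`.
#' @return a density data frame.
#' @export
density_record <- function(species, component, rho_min, rho_max) {
  df <- data.frame(species = species, component = component,
                   rho_min = rho_min, rho_max = rho_max,
                   stringsAsFactors = FALSE)
  validate_densities(df)
}

validate_densities <- function(df) {
  bad <- !(df$rho_min > 0 & df$rho_min <= df$rho_max)
  if (any(bad))
    stopf("density rows violate 0 < rho_min <= rho_max: %s",
          paste(which(bad), collapse = ", "))
  df
}

lookup_density <- function(densities, species, component) {
  hit <- densities$species == species & densities$component == component
  if (sum(hit) != 1L)
    stopf("need exactly one density record for %s / %s (found %d)",
          species, component, sum(hit))
  densities[hit, ]
}

#' Evaluate an allometric equation
#'
#' Deterministic prediction in the equation's response units. Log-log forms
#' are exponentiated back to natural units; no back-transformation bias
#' correction is applied unless `correct_log_bias = TRUE` (the usual practice
#' with published equations is to use them as printed).
#'
#' @param eq a one-row `allom_catalog` (or a row extracted from one).
#' @param dbh DBH in cm (vectorised); must be positive.
#' @param height height in m, required when `predictors == "DBH-and-height"`.
#' @param correct_log_bias multiply log-log predictions by the lognormal
#'   correction `exp(mse_log/2)` (see [correct_log_bias()]).
#' @return numeric vector of predictions (m^3 or kg per `response_kind`).
#' @export
#' @examples
#' eq <- allom_equation("ex", "PSME", "stem wood", "biomass", "log-log",
#'                      c(-2, 2.4), dev_min_cm = 5, dev_max_cm = 80)
#' evaluate_equation(eq, 10)  # exp(-2 + 2.4 * log(10))
evaluate_equation <- function(eq, dbh, height = NULL, correct_log_bias = FALSE) {
  if (any(dbh <= 0)) stopf("dbh must be positive")
  cf <- eq_coefs(eq)
  needs_h <- identical(eq$predictors, "DBH-and-height")
  if (needs_h) {
    if (is.null(height)) stopf("equation '%s' requires height", eq$id)
    height <- rep_len(height, length(dbh))
  }
  y <- switch(eq$form_id,
    "linear-combination" = {
      if (needs_h) {
        if (length(cf) != 3L)
          stopf("equation '%s': linear-combination with height takes 3 coefficients", eq$id)
        cf[1] + cf[2] * dbh + cf[3] * height
      } else {
        if (length(cf) != 2L)
          stopf("equation '%s': linear-combination takes 2 coefficients", eq$id)
        cf[1] + cf[2] * dbh
      }
    },
    "power" = {
      if (needs_h) {
        if (length(cf) != 3L)
          stopf("equation '%s': power with height takes 3 coefficients", eq$id)
        cf[1] * dbh^cf[2] * height^cf[3]
      } else {
        if (length(cf) != 2L)
          stopf("equation '%s': power takes 2 coefficients", eq$id)
        cf[1] * dbh^cf[2]
      }
    },
    "log-log" = {
      ln <- if (needs_h) {
        if (length(cf) != 3L)
          stopf("equation '%s': log-log with height takes 3 coefficients", eq$id)
        cf[1] + cf[2] * log(dbh) + cf[3] * log(height)
      } else {
        if (length(cf) != 2L)
          stopf("equation '%s': log-log takes 2 coefficients", eq$id)
        cf[1] + cf[2] * log(dbh)
      }
      exp(ln)
    },
    "combined-variable" = {
      if (!needs_h)
        stopf("equation '%s': combined-variable form requires height", eq$id)
      if (length(cf) != 2L)
        stopf("equation '%s': combined-variable takes 2 coefficients", eq$id)
      cf[1] + cf[2] * dbh^2 * height
    },
    stopf("equation '%s': unknown form_id '%s'", eq$id, eq$form_id)
  )
  if (isTRUE(correct_log_bias)) y <- y * log_bias_factor(eq)
  if (any(!is.finite(y))) stopf("equation '%s': non-finite prediction", eq$id)
  y
}

#' Lognormal back-transformation correction factor
#'
#' Predictions from a regression fit on the natural-log scale are biased low
#' when simply exponentiated; the standard correction multiplies by
#' `exp(mse_log / 2)`, where `mse_log` is the residual mean square on the log
#' scale. Correction is opt-in: published equations are typically applied
#' uncorrected.
#'
#' @param eq a log-scale (`log_base_e`) equation with `mse_log` recorded.
#' @return scalar multiplicative correction factor, `>= 1`.
#' @export
correct_log_bias <- function(eq) log_bias_factor(eq)

log_bias_factor <- function(eq) {
  if (!isTRUE(eq$log_base_e))
    stopf("equation '%s' is not modelled on the log scale", eq$id)
  if (is.na(eq$mse_log))
    stopf("equation '%s' has no recorded log-scale residual mean square", eq$id)
  exp(eq$mse_log / 2)
}

#' Partition a catalog by the inclusion rules
#'
#' Applies the four screening rules used to admit published equations into
#' the analysis: (1) predictors must be DBH only or DBH and height;
#' (2) the developmental DBH range must be reported (waivable per record);
#' (3) stump height, when stated, must be one of the 10/15/30 cm conventions;
#' (4) stem equations must extend to the top of the stem. Each excluded
#' equation carries exactly one reason code, the first rule it fails.
#'
#' @param catalog an `allom_catalog`.
#' @return list with elements `included` (an `allom_catalog`, possibly empty
#'   data frame) and `excluded` (the excluded rows plus a `reason` column in
#'   `c("extra-predictor", "no-dev-range", "bad-stump-height", "not-to-top")`).
#' @export
apply_inclusion_rules <- function(catalog) {
  df <- as.data.frame(catalog)
  reason <- rep(NA_character_, nrow(df))
  r1 <- !(df$predictors %in% VALID_PREDICTORS)
  reason[r1] <- "extra-predictor"
  r2 <- is.na(reason) & (is.na(df$dev_min_cm) | is.na(df$dev_max_cm)) &
    !df$dev_range_waiver
  reason[r2] <- "no-dev-range"
  r3 <- is.na(reason) & !is.na(df$stump_height_cm) &
    !(df$stump_height_cm %in% VALID_STUMP_HEIGHTS)
  reason[r3] <- "bad-stump-height"
  r4 <- is.na(reason) & !df$extends_to_top
  reason[r4] <- "not-to-top"
  inc <- df[is.na(reason), , drop = FALSE]
  exc <- df[!is.na(reason), , drop = FALSE]
  exc$reason <- reason[!is.na(reason)]
  class(inc) <- c("allom_catalog", "data.frame")
  list(included = inc, excluded = exc)
}

#' Additivity error of component equations against an aggregate equation
#'
#' Component equations fitted independently rarely sum exactly to an
#' aggregate equation fitted to the same trees. The deviation at DBH class d
#' is `100 * (sum of component predictions - aggregate prediction) /
#' aggregate prediction`.
#'
#' @param component_eqs `allom_catalog` of the component equations (one
#'   species).
#' @param aggregate_eq one-row `allom_catalog` for the aggregate component.
#' @param grid DBH classes (cm); must lie inside the intersection of all
#'   developmental ranges.
#' @param heights optional numeric heights (m) parallel to `grid`, needed
#'   when any equation uses height.
#' @return list with `mean` (signed mean percent deviation), `max_abs`
#'   (largest absolute percent deviation) and `per_class` data frame.
#' @export
additivity_error <- function(component_eqs, aggregate_eq, grid,
                             heights = NULL) {
  all_eqs <- rbind(as.data.frame(component_eqs), as.data.frame(aggregate_eq))
  if (length(unique(all_eqs$species)) != 1L)
    stopf("all equations must share a species")
  lo <- max(all_eqs$dev_min_cm, na.rm = TRUE)
  hi <- min(all_eqs$dev_max_cm, na.rm = TRUE)
  if (lo > hi) stopf("developmental ranges do not intersect")
  grid <- grid[grid >= lo & grid <= hi]
  if (!length(grid)) stopf("grid does not intersect the shared developmental range")
  comp_sum <- Reduce(`+`, lapply(seq_len(nrow(component_eqs)), function(i)
    evaluate_equation(component_eqs[i, ], grid, heights)))
  agg <- evaluate_equation(aggregate_eq, grid, heights)
  if (any(agg <= 0)) stopf("aggregate prediction non-positive on grid")
  dev <- 100 * (comp_sum - agg) / agg
  list(mean = mean(dev), max_abs = max(abs(dev)),
       per_class = data.frame(dbh = grid, deviation_pct = dev))
}
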