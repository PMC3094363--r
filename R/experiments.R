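#' @title Uncertainty-reduction and auxiliary experiments
#' @description The envelope-subdivision thought experiment, the
#'   developmental-range-distance probe, a delta-method estimate of DBH
#'   measurement error, single-source point estimates, and the equation-form
#'   agreement comparison.
#' @name experiments
NULL

#' Envelope subdivision experiment
#'
#' If equations could be correctly assigned to subpopulations of trees, the
#' full envelope would shrink to sub-envelopes. Per DBH class the `[lo, hi]`
#' interval is split into `k` equal-width sub-intervals; trees are assigned
#' round-robin across the `k` groups within each species x DBH class (any
#' remainder trees go to the lower-indexed groups); each group is summed
#' against its own sub-envelope and the group minima/maxima are summed back
#' to the regional level. When class counts divide evenly by `k` and
#' expansion factors are equal within a class, the resulting uncertainty is
#' exactly `1/k` of the full-envelope uncertainty.
#'
#' @param inventory tree records (`species, dbh_cm, expansion_factor`).
#' @param envelopes named list of total-tree kg-C envelopes by species.
#' @param k number of sub-envelopes (positive integer).
#' @return list with `ratio` (subdivided / full uncertainty percent),
#'   `full_pct`, `subdivided_pct`, and the subdivided regional bounds
#'   `min_tg`, `max_tg`.
#' @export
subdivision_experiment <- function(inventory, envelopes, k) {
  if (length(k) != 1L || k < 1 || k != round(k)) stopf("k must be a positive integer")
  full <- apply_envelope(inventory, envelopes)
  full_lo <- sum(full$min_tg); full_hi <- sum(full$max_tg)
  full_pct <- uncertainty_percent(full_lo, full_hi)

  lo_tg <- 0; hi_tg <- 0
  for (sp in unique(inventory$species)) {
    env <- envelopes[[sp]]
    tr <- inventory[inventory$species == sp, , drop = FALSE]
    idx <- dbh_to_class(tr$dbh_cm, env$grid)
    # round-robin group assignment within each DBH class
    g <- integer(nrow(tr))
    for (cls in unique(idx)) {
      at <- which(idx == cls)
      g[at] <- ((seq_along(at) - 1L) %% k) + 1L
    }
    w <- (env$upper[idx] - env$lower[idx]) / k
    sub_lo <- env$lower[idx] + (g - 1L) * w
    sub_hi <- env$lower[idx] + g * w
    lo_tg <- lo_tg + sum(tr$expansion_factor * sub_lo) / KG_PER_TG
    hi_tg <- hi_tg + sum(tr$expansion_factor * sub_hi) / KG_PER_TG
  }
  sub_pct <- uncertainty_percent(lo_tg, hi_tg)
  list(ratio = sub_pct / full_pct, full_pct = full_pct,
       subdivided_pct = sub_pct, min_tg = lo_tg, max_tg = hi_tg)
}

#' Developmental-range distance experiment
#'
#' For each target DBH class, equations are categorised by where their
#' developmental range lies relative to the target: `spanning` (range covers
#' the target), `below` (range ends at or below half the target) and `above`
#' (range starts at or above twice the target). Each category's equations are
#' evaluated at the target; categories whose ranges lie far from the target
#' are expected to produce wider prediction ranges with shifted midpoints.
#'
#' @param catalog an `allom_catalog` (equations with developmental ranges).
#' @param targets target DBH classes, cm (default `c(20, 60, 100)`).
#' @param height_params optional [height_params()] when equations use height.
#' @param densities optional density table for volume equations.
#' @return data frame: `target_dbh, category, n, min, max, midpoint` (`NA`
#'   bounds for empty categories).
#' @export
dev_range_distance_experiment <- function(catalog, targets = c(20, 60, 100),
                                          height_params = NULL,
                                          densities = NULL) {
  df <- as.data.frame(catalog)
  if (!nrow(df)) stopf("empty catalog")
  rows <- list()
  any_nonempty <- FALSE
  for (t in targets) {
    h <- if (!is.null(height_params)) predict_height(height_params, t)
    cats <- list(
      spanning = df$dev_min_cm <= t & df$dev_max_cm >= t,
      below = df$dev_max_cm <= t / 2,
      above = df$dev_min_cm >= 2 * t
    )
    for (nm in names(cats)) {
      sel <- which(!is.na(cats[[nm]]) & cats[[nm]])
      if (length(sel)) {
        any_nonempty <- TRUE
        preds <- unlist(lapply(sel, function(i)
          vapply(equation_candidates(df[i, ], t, h, densities),
                 `[[`, 0, "values")))
        rows[[length(rows) + 1L]] <- data.frame(
          target_dbh = t, category = nm, n = length(sel),
          min = min(preds), max = max(preds),
          midpoint = (min(preds) + max(preds)) / 2)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          target_dbh = t, category = nm, n = 0L,
          min = NA_real_, max = NA_real_, midpoint = NA_real_)
      }
    }
  }
  if (!any_nonempty) stopf("no equation falls in any category at any target")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delta-method estimate of DBH measurement error at the regional level
#'
#' Diameter measurement variation is taken as `rel_error` of diameter
#' expressed as a 95% confidence interval, so the per-tree diameter standard
#' deviation is `rel_error * D / z`. The induced prediction standard error is
#' `|dy/dD| * sd(D)` (delta method, central-difference derivative) and, with
#' independent per-tree errors, the regional standard error is
#' `sqrt(sum((expansion * SE_tree)^2))`.
#'
#' @param inventory tree records.
#' @param eq a DBH-only equation applied to every tree.
#' @param rel_error relative measurement error as a 95% CI half-width
#'   (default 0.02).
#' @param z quantile converting the CI half-width to a standard deviation
#'   (default 1.96).
#' @return list with `se_total` (equation response units) and `se_total_tg`.
#' @export
dbh_measurement_error <- function(inventory, eq, rel_error = 0.02, z = 1.96) {
  if (!identical(eq$predictors, "DBH-only"))
    stopf("measurement-error estimate requires a DBH-only equation")
  validate_inventory(inventory)
  d <- inventory$dbh_cm
  sd_d <- rel_error * d / z
  h <- pmax(1e-4 * d, 1e-6)
  dydd <- (evaluate_equation(eq, d + h) - evaluate_equation(eq, d - h)) / (2 * h)
  se_tree <- abs(dydd) * sd_d
  se_total <- sqrt(sum((inventory$expansion_factor * se_tree)^2))
  list(se_total = se_total, se_total_tg = se_total / KG_PER_TG)
}

#' Single-source point estimate
#'
#' Regional carbon from one internally consistent set of equations (one
#' equation per species and leaf component) with a flat biomass-to-carbon
#' conversion, for comparison against the envelope bounds. Volume equations
#' are converted with the density midpoint.
#'
#' @param equation_set `allom_catalog` with exactly one equation per
#'   (species, component) for every component in `components`.
#' @param inventory tree records.
#' @param components leaf components that must be covered per species.
#' @param conversion carbon fraction of biomass (default 0.5).
#' @param height_params named list of [height_params()] by species, when
#'   needed.
#' @param densities density table for volume equations.
#' @return point estimate in Tg C.
#' @export
single_source_estimate <- function(equation_set, inventory,
                                   components = c("stem wood", "stem bark",
                                                  "branches total",
                                                  "foliage total",
                                                  "roots coarse"),
                                   conversion = 0.5, height_params = NULL,
                                   densities = NULL) {
  df <- as.data.frame(equation_set)
  validate_inventory(inventory)
  total_kg <- 0
  for (sp in unique(inventory$species)) {
    tr <- inventory[inventory$species == sp, , drop = FALSE]
    hp <- height_params[[sp]]
    for (comp in components) {
      hit <- df[df$species == sp & df$component == comp, , drop = FALSE]
      if (nrow(hit) != 1L)
        stopf("equation set must cover %s / %s exactly once (found %d)",
              sp, comp, nrow(hit))
      eq <- hit[1, ]
      h <- if (identical(eq$predictors, "DBH-and-height")) {
        if (is.null(hp)) stopf("height params needed for %s", sp)
        predict_height(hp, tr$dbh_cm)
      }
      pred <- evaluate_equation(eq, tr$dbh_cm, h)
      if (eq$response_kind == "volume") {
        rho <- lookup_density(densities, sp, comp)
        pred <- pred * (rho$rho_min + rho$rho_max) / 2
      }
      total_kg <- total_kg + sum(tr$expansion_factor * pred)
    }
  }
  conversion * total_kg / KG_PER_TG
}

#' Equation-form agreement along alternative plotting axes
#'
#' Evaluates the DBH-only ("local") and DBH-and-height ("standard") subsets
#' of a component's equations over a DBH grid and reports the relative spread
#' `(max - min) / midpoint` per grid point, together with the D, H and D^2 H
#' axis values. If height made standard equations more universally
#' applicable, their predictions would converge when plotted against D^2 H;
#' no such convergence is asserted here - the table is for inspection.
#'
#' @param catalog an `allom_catalog`.
#' @param species,component selection keys.
#' @param grid DBH classes, cm.
#' @param height_params [height_params()] supplying H for the grid.
#' @param densities optional density table for volume equations.
#' @return data frame: `subset, d, h, d2h, min, max, spread` (one row per
#'   subset x grid point).
#' @export
form_agreement <- function(catalog, species, component, grid = 3:66,
                           height_params, densities = NULL) {
  df <- as.data.frame(catalog)
  df <- df[df$species == species & df$component == component, , drop = FALSE]
  h <- predict_height(height_params, grid)
  subsets <- split(df, ifelse(df$predictors == "DBH-and-height",
                              "standard", "local"))
  out <- lapply(names(subsets), function(nm) {
    sub <- subsets[[nm]]
    if (nrow(sub) < 2L)
      stopf("need at least 2 equations in the %s subset (found %d)",
            nm, nrow(sub))
    preds <- vapply(seq_len(nrow(sub)), function(i) {
      cc <- equation_candidates(sub[i, ], grid, h, densities)
      # midpoint across density candidates so volume equations enter once
      rowMeans(vapply(cc, `[[`, numeric(length(grid)), "values"))
    }, numeric(length(grid)))
    lo <- apply(preds, 1, min); hi <- apply(preds, 1, max)
    data.frame(subset = nm, d = grid, h = h, d2h = grid^2 * h,
               min = lo, max = hi,
               spread = (hi - lo) / ((hi + lo) / 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
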