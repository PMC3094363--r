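#' @title Synthetic equation libraries and inventories
#' @description Generators that emulate the statistical structure of the
#'   published-equation compilations and the regional inventory: equation
#'   libraries drawn as noisy log-log perturbations of a known true
#'   allometry over varied developmental DBH ranges, and right-skewed DBH
#'   inventories with positive expansion factors. They provide ground truth
#'   for recovery tests of every pipeline stage.
#' @name synthetic_data
NULL

LEAF_COMPONENTS <- c("stem wood", "stem bark", "branches total",
                     "foliage total", "roots coarse")

#' A known true allometry
#'
#' Per species, leaf-component biomass follows a power law
#' `biomass = a * D^b` (kg, D in cm); aggregate components are sums of their
#' leaves, so the truth is additive by construction. Each species carries a
#' wood density (kg/m^3) per component and height-model parameters.
#'
#' @param species character vector of species codes.
#' @param params optional data frame `species, component, a, b, rho`
#'   overriding the defaults (defaults: plausible Pacific Northwest
#'   magnitudes, exponents in `[1.5, 3]`).
#' @param height named list of [height_params()] by species; defaults to the
#'   published northwest-Oregon parameters when the species is one of the
#'   five target species, else the Pseudotsuga parameters.
#' @return object of class `true_allometry`.
#' @export
true_allometry <- function(species = nwor_species(), params = NULL,
                           height = NULL) {
  defaults <- data.frame(
    component = LEAF_COMPONENTS,
    a = c(0.040, 0.008, 0.015, 0.070, 0.010),
    b = c(2.60, 2.40, 2.30, 1.60, 2.50),
    rho = c(450, 550, 500, 400, 480),
    stringsAsFactors = FALSE
  )
  if (is.null(params)) {
    params <- do.call(rbind, lapply(species, function(sp)
      cbind(species = sp, defaults, stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("species", "component", "a", "b", "rho") %in% names(params)))
  if (any(params$a <= 0)) stopf("power-law scale a must be positive")
  if (is.null(height)) {
    hp <- nwor_height_params()
    height <- lapply(stats::setNames(species, species), function(sp)
      hp[[sp]] %||% hp[["Pseudotsuga menziesii"]])
  }
  structure(list(species = species, params = params, height = height),
            class = "true_allometry")
}

#' True biomass of a component
#'
#' Leaf components evaluate their power law; `"bole"`, `"aboveground total"`
#' and `"total tree"` are sums of their constituent leaves.
#'
#' @param truth a [true_allometry()].
#' @param species species code.
#' @param component component name.
#' @param dbh DBH in cm (vectorised).
#' @return biomass in kg.
#' @export
truth_biomass <- function(truth, species, component, dbh) {
  stopifnot(inherits(truth, "true_allometry"))
  leaves <- switch(component,
    "bole" = c("stem wood", "stem bark"),
    "aboveground total" = c("stem wood", "stem bark", "branches total",
                            "foliage total"),
    "total tree" = LEAF_COMPONENTS,
    component
  )
  p <- truth$params[truth$params$species == species &
                      truth$params$component %in% leaves, , drop = FALSE]
  if (nrow(p) != length(leaves))
    stopf("truth has no parameters for %s / %s", species, component)
  Reduce(`+`, lapply(seq_len(nrow(p)), function(i) p$a[i] * dbh^p$b[i]))
}

#' Synthetic-library specification
#'
#' Controls the heterogeneity of a generated equation library: how many
#' equations per component, the mix of functional forms, how developmental
#' DBH ranges are drawn as sub-intervals of `[3, 250]` cm, the log-scale
#' noise standard deviation of the pseudodata each equation is refit on, and
#' the proportion of stem-wood equations expressed as volume rather than
#' biomass.
#'
#' @param n_equations equations per species x component (default 6, the
#'   scale of a typical regional compilation for a well-studied component).
#' @param form_mix named proportions over
#'   `c("power", "log-log", "combined-variable")`; must sum to 1.
#' @param noise_sd log-scale residual standard deviation of the pseudodata
#'   (default 0.3: roughly 30% relative disagreement among library members,
#'   the scale needed for regional model-selection uncertainty in the
#'   20-40% band reported for real equation compilations).
#' @param p_volume probability that a stem-wood equation is a volume
#'   equation (default 0.3).
#' @param dev_range_min_width,dev_range_max_width bounds (cm) on the width of
#'   sampled developmental ranges.
#' @param density_jitter densities are jittered within +/- this fraction of
#'   the true value (default 0.10, matching the observed spread of the
#'   volume-to-carbon conversion around its midpoint).
#' @return a `library_spec` object.
#' @export
library_spec <- function(n_equations = 6,
                         form_mix = c("power" = 0.4, "log-log" = 0.4,
                                      "combined-variable" = 0.2),
                         noise_sd = 0.3, p_volume = 0.3,
                         dev_range_min_width = 20, dev_range_max_width = 150,
                         density_jitter = 0.10) {
  if (abs(sum(form_mix) - 1) > 1e-8) stopf("form_mix must sum to 1")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (n_equations < 1) stopf("need at least one equation per component")
  structure(list(n_equations = n_equations, form_mix = form_mix,
                 noise_sd = noise_sd, p_volume = p_volume,
                 dev_range_min_width = dev_range_min_width,
                 dev_range_max_width = dev_range_max_width,
                 density_jitter = density_jitter),
            class = "library_spec")
}

# fit one synthetic "published" equation: refit the truth on noisy
# pseudodata over the sampled developmental range, in the sampled form
fit_synthetic_equation <- function(id, truth, sp, comp, form, response,
                                   dev, noise_sd, full_range = FALSE) {
  d <- seq(dev[1], dev[2], length.out = 25)
  y <- truth_biomass(truth, sp, comp, d) * exp(stats::rnorm(length(d), 0, noise_sd))
  if (response == "volume") {
    rho <- truth$params$rho[truth$params$species == sp &
                              truth$params$component == comp]
    y <- y / rho
  }
  stump <- if (grepl("stem", comp)) sample(c(10, 15, 30), 1) else NA_real_
  if (form %in% c("power", "log-log")) {
    fit <- stats::lm(log(y) ~ log(d))
    cf <- unname(stats::coef(fit))
    mse <- sum(stats::resid(fit)^2) / max(stats::df.residual(fit), 1)
    if (form == "power") {
      allom_equation(id, sp, comp, response, "power", c(exp(cf[1]), cf[2]),
                     dev_min_cm = dev[1], dev_max_cm = dev[2],
                     stump_height_cm = stump, source = "synthetic")
    } else {
      allom_equation(id, sp, comp, response, "log-log", cf,
                     dev_min_cm = dev[1], dev_max_cm = dev[2],
                     stump_height_cm = stump, mse_log = mse,
                     source = "synthetic")
    }
  } else { # combined-variable
    h <- predict_height(truth$height[[sp]], d)
    # weighted fit (weights 1/(D^2 H)^2), the standard treatment of the
    # strongly heteroscedastic scatter in combined-variable equations;
    # keeps intercepts on the scale of a small tree, as published ones are
    x <- d^2 * h
    fit <- stats::lm(y ~ x, weights = 1 / x^2)
    allom_equation(id, sp, comp, response, "combined-variable",
                   unname(stats::coef(fit)), predictors = "DBH-and-height",
                   dev_min_cm = dev[1], dev_max_cm = dev[2],
                   stump_height_cm = stump, source = "synthetic")
  }
}

#' Generate a synthetic equation catalog and density table
#'
#' Every synthetic equation is the true allometry refit on noisy pseudodata
#' over its own sampled developmental DBH range, in a randomly drawn
#' functional form - emulating a heterogeneous published-equation library
#' whose members disagree through sampling noise, range truncation, and form
#' misspecification. The first equation of each component spans the full
#' `[3, 250]` cm range so approach-2 envelopes have no coverage gaps on the
#' default grid. Densities are jittered within `+/- density_jitter` of the
#' truth. All draws are fixed by `seed`.
#'
#' @param truth a [true_allometry()].
#' @param spec a [library_spec()].
#' @param seed integer seed fixing all draws.
#' @param components components to generate (default the five leaves).
#' @return list with `catalog` (an `allom_catalog`), `densities`, `seed`.
#' @export
generate_catalog <- function(truth, spec = library_spec(), seed = 1L,
                             components = LEAF_COMPONENTS) {
  stopifnot(inherits(truth, "true_allometry"), inherits(spec, "library_spec"))
  if (!length(components)) stopf("zero components requested")
  set.seed(seed)
  rows <- list()
  for (sp in truth$species) {
    for (comp in components) {
      for (i in seq_len(spec$n_equations)) {
        # the first equation of each component is a full-range log-log fit:
        # the wide-range equations in published libraries are log-log/power,
        # while linear combined-variable forms are only fit locally
        form <- if (i == 1L) "log-log" else
          sample(names(spec$form_mix), 1, prob = spec$form_mix)
        response <- if (comp == "stem wood" &&
                        stats::runif(1) < spec$p_volume) "volume" else "biomass"
        dev <- if (i == 1L) c(3, 250) else {
          # ranges start small (saplings are easy to sample) and vary in
          # width, emulating the limited sample DBH ranges of the literature
          width <- stats::runif(1, spec$dev_range_min_width,
                                spec$dev_range_max_width)
          lo <- stats::runif(1, 3, 30)
          c(lo, min(lo + width, 250))
        }
        dev <- round(dev, 1)
        id <- sprintf("%s|%s|%02d", abbreviate(sp, 6), abbreviate(comp, 6), i)
        rows[[length(rows) + 1L]] <-
          fit_synthetic_equation(id, truth, sp, comp, form, response, dev,
                                 spec$noise_sd)
      }
    }
  }
  catalog <- do.call(allom_catalog, rows)
  dens <- do.call(rbind, lapply(truth$species, function(sp) {
    p <- truth$params[truth$params$species == sp, ]
    data.frame(species = sp, component = p$component,
               rho_min = p$rho * (1 - stats::runif(nrow(p), 0, spec$density_jitter)),
               rho_max = p$rho * (1 + stats::runif(nrow(p), 0, spec$density_jitter)),
               stringsAsFactors = FALSE)
  }))
  list(catalog = catalog, densities = validate_densities(dens), seed = seed)
}

#' Generate a synthetic inventory
#'
#' DBHs are drawn from a right-skewed Weibull distribution truncated to
#' `[dbh_min, dbh_max]` (defaults: shape 1.3, scale 18, on 3-66 cm - most
#' trees small, a long right tail); expansion factors are positive
#' (lognormal by default). All draws are fixed by `seed`.
#'
#' @param n_trees number of tree records (`>= 0`).
#' @param species_mix named sampling probabilities by species.
#' @param shape,scale Weibull DBH parameters.
#' @param dbh_min,dbh_max truncation bounds, cm.
#' @param expansion_meanlog,expansion_sdlog lognormal expansion-factor
#'   parameters (defaults give a median of about 20 trees represented per
#'   record).
#' @param seed integer seed.
#' @return data frame `species, dbh_cm, expansion_factor`.
#' @export
generate_inventory <- function(n_trees,
                               species_mix = c("Pseudotsuga menziesii" = 0.45,
                                               "Tsuga heterophylla" = 0.25,
                                               "Alnus rubra" = 0.15,
                                               "Picea sitchensis" = 0.08,
                                               "Acer macrophyllum" = 0.07),
                               shape = 1.3, scale = 18,
                               dbh_min = 3, dbh_max = 66,
                               expansion_meanlog = log(20),
                               expansion_sdlog = 0.7,
                               seed = 1L) {
  if (n_trees < 0) stopf("n_trees must be non-negative")
  if (shape <= 0 || scale <= 0) stopf("invalid Weibull parameters")
  if (dbh_min <= 0 || dbh_min >= dbh_max) stopf("invalid DBH truncation bounds")
  set.seed(seed)
  if (n_trees == 0)
    return(data.frame(species = character(), dbh_cm = numeric(),
                      expansion_factor = numeric(), stringsAsFactors = FALSE))
  species <- sample(names(species_mix), n_trees, replace = TRUE,
                    prob = species_mix)
  # inverse-CDF sampling from the truncated Weibull
  plo <- stats::pweibull(dbh_min, shape, scale)
  phi <- stats::pweibull(dbh_max, shape, scale)
  u <- stats::runif(n_trees, plo, phi)
  dbh <- stats::qweibull(u, shape, scale)
  ef <- stats::rlnorm(n_trees, expansion_meanlog, expansion_sdlog)
  data.frame(species = species, dbh_cm = dbh, expansion_factor = ef,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on a synthetic library
#'
#' Convenience wrapper used by recovery tests and examples: builds per-leaf
#' component envelopes from a catalog (converting volume equations with the
#' density table), converts to carbon, folds the roadmap, and applies the
#' totals to an inventory.
#'
#' @param catalog an `allom_catalog` (screened by inclusion rules inside).
#' @param densities density table.
#' @param inventory tree records.
#' @param truth a [true_allometry()] supplying height parameters (or a named
#'   list of [height_params()]).
#' @param policy an [approach_policy()].
#' @param roadmap a roadmap; default [default_roadmap()].
#' @param mode correlation mode.
#' @param grid DBH classes.
#' @return list with `estimate` (the [regional_estimate()] table),
#'   `bounds` (per-species Tg bounds), and `totals` (named list of total-tree
#'   envelopes by species).
#' @export
assess_region <- function(catalog, densities, inventory, truth,
                          policy = approach_policy(1),
                          roadmap = default_roadmap(),
                          mode = c("positive", "negative"), grid = 3:66) {
  mode <- match.arg(mode)
  screened <- apply_inclusion_rules(catalog)$included
  heights <- if (inherits(truth, "true_allometry")) truth$height else truth
  species <- unique(inventory$species)
  totals <- lapply(stats::setNames(species, species), function(sp) {
    comps <- lapply(stats::setNames(LEAF_COMPONENTS, LEAF_COMPONENTS),
                    function(comp) {
      env <- component_envelope(screened, sp, comp, grid = grid,
                                policy = policy,
                                height_params = heights[[sp]],
                                densities = densities)
      biomass_to_carbon(env)
    })
    total_tree_envelope(roadmap, comps, mode)$total
  })
  bounds <- apply_envelope(inventory, totals)
  list(estimate = regional_estimate(bounds), bounds = bounds, totals = totals)
}
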