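# independent brute-force oracles

# per-class min/max over every (equation x density bound) candidate for one
# species/component, by direct looping (independent of component_envelope's
# vectorised bookkeeping)
brute_force_component_bounds <- function(catalog, species, component, grid,
                                         approach = 1, height_params = NULL,
                                         densities = NULL) {
  df <- as.data.frame(catalog)
  df <- df[df$species == species & df$component == component, , drop = FALSE]
  lower <- rep(NA_real_, length(grid))
  upper <- rep(NA_real_, length(grid))
  for (j in seq_along(grid)) {
    d <- grid[j]
    vals <- c()
    for (i in seq_len(nrow(df))) {
      eq <- df[i, ]
      if (approach == 2 && (d < eq$dev_min_cm || d > eq$dev_max_cm)) next
      h <- if (identical(eq$predictors, "DBH-and-height"))
        predict_height(height_params, d)
      p <- evaluate_equation(eq, d, h)
      if (eq$response_kind == "volume") {
        rho <- densities[densities$species == species &
                           densities$component == component, ]
        vals <- c(vals, p * rho$rho_min, p * rho$rho_max)
      } else vals <- c(vals, p)
    }
    if (length(vals)) { lower[j] <- min(vals); upper[j] <- max(vals) }
  }
  list(lower = lower, upper = upper)
}

# exhaustive enumeration of total-tree carbon bounds over every combination
# of (pathway, one candidate per component, carbon factor per component).
# Candidates per component are biomass predictions (density bounds already
# expanded); carbon factors 0.48/0.52 are treated as one more model choice.
# Pathway 1 sums all five leaves; pathway 2 uses a direct aboveground
# equation set plus roots (only if `aboveground` candidates are supplied).
enumerate_total_bounds <- function(cand, grid, c_lo = 0.48, c_hi = 0.52) {
  leaf_sets <- cand[c("stem wood", "stem bark", "branches total",
                      "foliage total")]
  enumerate_pathway <- function(component_sets) {
    # component_sets: named list of matrices (class x candidate)
    sets <- lapply(component_sets, function(m) {
      k <- ncol(m)
      cbind(m * c_lo, m * c_hi) # carbon factor choice per component
    })
    idx <- expand.grid(lapply(sets, function(m) seq_len(ncol(m))))
    totals <- matrix(NA_real_, nrow = length(grid), ncol = nrow(idx))
    for (r in seq_len(nrow(idx))) {
      tot <- 0
      for (nm in names(sets)) tot <- tot + sets[[nm]][, idx[r, nm]]
      totals[, r] <- tot
    }
    totals
  }
  t1 <- enumerate_pathway(c(leaf_sets, cand["roots coarse"]))
  all_tot <- t1
  if (!is.null(cand[["aboveground total"]])) {
    t2 <- enumerate_pathway(cand[c("aboveground total", "roots coarse")])
    all_tot <- cbind(all_tot, t2)
  }
  list(lower = apply(all_tot, 1, min), upper = apply(all_tot, 1, max))
}

# candidate prediction matrices (class x candidate) per component for a
# catalog of biomass equations
candidate_matrices <- function(catalog, species, grid, height_params = NULL) {
  df <- as.data.frame(catalog)
  df <- df[df$species == species, , drop = FALSE]
  out <- list()
  for (comp in unique(df$component)) {
    sub <- df[df$component == comp, , drop = FALSE]
    m <- vapply(seq_len(nrow(sub)), function(i) {
      eq <- sub[i, ]
      h <- if (identical(eq$predictors, "DBH-and-height"))
        predict_height(height_params, grid)
      evaluate_equation(eq, grid, h)
    }, numeric(length(grid)))
    out[[comp]] <- matrix(m, nrow = length(grid))
  }
  out
}
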