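mk_total_env <- function(lo, hi, grid = 3:66, species = "SP",
                         defined = rep(TRUE, length(grid))) {
  envelope(species, "total tree", "kg-C", grid,
           rep_len(lo, length(grid)), rep_len(hi, length(grid)), defined)
}

test_that("envelope bounds scale to regional totals by expansion factors", {
  # two trees, expansions 10 and 20, class bounds [1,2] and [3,4] kg
  env <- envelope("SP", "total tree", "kg-C", c(10, 20),
                  c(1, 3), c(2, 4))
  inv <- data.frame(species = "SP", dbh_cm = c(10, 20),
                    expansion_factor = c(10, 20))
  b <- apply_envelope(inv, list(SP = env))
  expect_equal(b$min_tg * 1e9, 10 * 1 + 20 * 3)
  expect_equal(b$max_tg * 1e9, 10 * 2 + 20 * 4)
  # single tree, expansion 1: pure unit conversion kg -> Tg
  b1 <- apply_envelope(data.frame(species = "SP", dbh_cm = 10,
                                  expansion_factor = 1), list(SP = env))
  expect_equal(c(b1$min_tg, b1$max_tg), c(1e-9, 2e-9))
  # empty inventory
  b0 <- apply_envelope(data.frame(species = character(), dbh_cm = numeric(),
                                  expansion_factor = numeric()),
                       list(SP = env))
  expect_equal(nrow(b0), 0)
  expect_equal(sum(b0$min_tg), 0)
})

test_that("undefined classes and unknown species are errors listing offenders", {
  env <- mk_total_env(1, 2, defined = (3:66) >= 10)
  inv <- data.frame(species = "SP", dbh_cm = c(5, 6, 30),
                    expansion_factor = 1)
  expect_error(apply_envelope(inv, list(SP = env)), "2 trees.*undefined")
  inv2 <- data.frame(species = "OTHER", dbh_cm = 30, expansion_factor = 1)
  expect_error(apply_envelope(inv2, list(SP = env)), "OTHER")
})

test_that("regional bounds are additive over inventory partitions", {
  env <- mk_total_env(0, 0)
  env$lower <- 0.02 * env$grid^2; env$upper <- 0.05 * env$grid^2
  inv <- generate_inventory(400, species_mix = c(SP = 1), seed = 5)
  whole <- apply_envelope(inv, list(SP = env))
  half1 <- apply_envelope(inv[1:200, ], list(SP = env))
  half2 <- apply_envelope(inv[201:400, ], list(SP = env))
  expect_equal(whole$min_tg, half1$min_tg + half2$min_tg)
  expect_equal(whole$max_tg, half1$max_tg + half2$max_tg)
})

test_that("uncertainty percent is half-range over midpoint, scale-invariant", {
  expect_equal(uncertainty_percent(50, 150), 50)
  expect_equal(uncertainty_percent(7, 7), 0)
  set.seed(9)
  for (i in 1:20) {
    lo <- runif(1, 0.1, 10); hi <- lo + runif(1, 0, 10); cc <- runif(1, 0.01, 100)
    expect_equal(uncertainty_percent(cc * lo, cc * hi),
                 uncertainty_percent(lo, hi))
  }
  expect_error(uncertainty_percent(2, 1), "exceed")
  expect_error(uncertainty_percent(-2, 2), "midpoint")
})

test_that("species shares split half-widths and midpoints, summing to 100", {
  b <- data.frame(species = c("a", "b", "c"),
                  min_tg = c(1, 2, 3), max_tg = c(3, 2.5, 7))
  s <- species_shares(b)
  expect_equal(sum(s$uncertainty_share_pct), 100)
  expect_equal(sum(s$midpoint_share_pct), 100)
  expect_equal(s$uncertainty_share_pct[1], 100 * 1 / (1 + 0.25 + 2))
  one <- species_shares(data.frame(species = "a", min_tg = 1, max_tg = 2))
  expect_equal(one$uncertainty_share_pct, 100)
  expect_equal(one$midpoint_share_pct, 100)
  expect_error(species_shares(data.frame(species = "a", min_tg = 1,
                                         max_tg = 1)), "degenerate")
})

test_that("regional estimate totals are exact sums of species bounds", {
  b <- data.frame(species = c("a", "b"), min_tg = c(1, 2), max_tg = c(3, 5))
  est <- regional_estimate(b)
  tot <- est[est$species == "Total", ]
  expect_equal(tot$min_tg, 3)
  expect_equal(tot$max_tg, 8)
  expect_equal(tot$uncertainty_pct, uncertainty_percent(3, 8))
})

test_that("subdivision reduces uncertainty by exactly 1/k on divisible inventories", {
  env <- mk_total_env(0, 0)
  env$lower <- 0.3 * env$grid^2; env$upper <- 0.8 * env$grid^2
  inv <- divisible_inventory("SP", classes = c(10, 25, 40), per_class = 60)
  for (k in c(1, 2, 3, 4, 5, 10)) {
    res <- subdivision_experiment(inv, list(SP = env), k)
    expect_equal(res$ratio, 1 / k, tolerance = 1e-12)
  }
  expect_error(subdivision_experiment(inv, list(SP = env), 0), "positive")
})

test_that("developmental-range distance inflates prediction spread", {
  # spanning equations: refits over ranges covering 60 cm; 'below' equations
  # end at 30 cm and must extrapolate to 60
  tr <- true_allometry("SP")
  set.seed(77)
  rows <- list()
  for (i in 1:5) {
    d1 <- seq(20, 100, length.out = 25)
    y1 <- truth_biomass(tr, "SP", "stem wood", d1) * exp(rnorm(25, 0, 0.2))
    f1 <- lm(log(y1) ~ log(d1))
    rows[[length(rows) + 1]] <- loglog_eq(paste0("span", i), coef(f1)[1],
                                          coef(f1)[2], dev = c(20, 100))
    d2 <- seq(5, 30, length.out = 25)
    y2 <- truth_biomass(tr, "SP", "stem wood", d2) * exp(rnorm(25, 0, 0.2))
    f2 <- lm(log(y2) ~ log(d2))
    rows[[length(rows) + 1]] <- loglog_eq(paste0("below", i), coef(f2)[1],
                                          coef(f2)[2], dev = c(5, 30))
  }
  cat60 <- do.call(allom_catalog, rows)
  res <- dev_range_distance_experiment(cat60, targets = 60)
  span <- res[res$category == "spanning", ]
  below <- res[res$category == "below", ]
  expect_equal(span$n, 5); expect_equal(below$n, 5)
  expect_lt(span$max - span$min, below$max - below$min)
  # no equation starts at >= 120: 'above' category reported empty
  above <- res[res$category == "above", ]
  expect_equal(above$n, 0)
  expect_true(is.na(above$min))
  # all-spanning consistency: category range equals the envelope at the class
  span_cat <- do.call(allom_catalog,
                      rows[grep("span", vapply(rows, function(r) r$id, ""))])
  env <- component_envelope(span_cat, "SP", "stem wood", grid = 59:61)
  res2 <- dev_range_distance_experiment(span_cat, targets = 60)
  expect_equal(res2$min[res2$category == "spanning"], env$lower[env$grid == 60])
  expect_equal(res2$max[res2$category == "spanning"], env$upper[env$grid == 60])
})

test_that("DBH measurement error propagates by the delta method", {
  eq <- allom_equation("q", "SP", "stem wood", "biomass", "power", c(0.3, 2),
                       dev_min_cm = 3, dev_max_cm = 100)
  one <- data.frame(species = "SP", dbh_cm = 10, expansion_factor = 1)
  res <- dbh_measurement_error(one, eq)
  # y = 0.3 D^2: dy/dD = 0.6 D; sd(D) = 0.02*10/1.96
  expect_equal(res$se_total, 0.6 * 10 * (0.02 * 10 / 1.96), tolerance = 1e-6)
  expect_equal(dbh_measurement_error(one, eq, rel_error = 0)$se_total, 0)
  # n identical independent trees: SE grows as sqrt(n)
  n <- 49
  many <- data.frame(species = "SP", dbh_cm = rep(10, n),
                     expansion_factor = 1)
  expect_equal(dbh_measurement_error(many, eq)$se_total,
               sqrt(n) * res$se_total, tolerance = 1e-6)
  hteq <- allom_equation("h", "SP", "stem wood", "biomass",
                         "combined-variable", c(0, 1),
                         predictors = "DBH-and-height",
                         dev_min_cm = 3, dev_max_cm = 100)
  expect_error(dbh_measurement_error(one, hteq), "DBH-only")
})

test_that("single-source estimates fall inside the matching envelope", {
  comps <- c("stem wood", "stem bark", "branches total", "foliage total",
             "roots coarse")
  a_set <- do.call(allom_catalog, lapply(seq_along(comps), function(i)
    power_eq(paste0("a", i), 0.02 * i, 2.2, component = comps[i])))
  b_set <- do.call(allom_catalog, lapply(seq_along(comps), function(i)
    power_eq(paste0("b", i), 0.03 * i, 2.25, component = comps[i])))
  # two-equation toy set on two trees matches hand computation
  toy_inv <- data.frame(species = "SP", dbh_cm = c(10, 20),
                        expansion_factor = c(2, 3))
  est_a <- single_source_estimate(a_set, toy_inv)
  hand <- 0.5 * sum(vapply(c(10, 20), function(d)
    sum(0.02 * (1:5) * d^2.2), 0) * c(2, 3)) / 1e9
  expect_equal(est_a, hand, tolerance = 1e-12)
  # containment: any single source from the catalog lies inside the
  # approach-1 positive envelope totals built from both sources
  cat2 <- allom_catalog(a_set, b_set)
  envs <- lapply(setNames(comps, comps), function(cp)
    biomass_to_carbon(component_envelope(cat2, "SP", cp, grid = 3:66)))
  tot <- total_tree_envelope(default_roadmap(), envs, "positive")$total
  inv <- generate_inventory(200, species_mix = c(SP = 1), seed = 3)
  inv$dbh_cm <- round(inv$dbh_cm) # envelopes are indexed by 1-cm class label
  bounds <- apply_envelope(inv, list(SP = tot))
  for (s in list(a_set, b_set)) {
    est <- single_source_estimate(s, inv)
    expect_gte(est, bounds$min_tg)
    expect_lte(est, bounds$max_tg)
  }
  # the everywhere-lower source with matched conversion hits the lower bound
  est_lo <- single_source_estimate(a_set, inv, conversion = 0.48)
  expect_equal(est_lo, bounds$min_tg, tolerance = 1e-12)
})

test_that("form agreement tables match direct recomputation", {
  hp <- height_params("SP", 55, -0.02, 1.1)
  cat <- allom_catalog(
    power_eq("l1", 0.04, 2.5),
    power_eq("l2", 0.05, 2.45),
    allom_equation("s1", "SP", "stem wood", "biomass", "combined-variable",
                   c(2, 0.012), predictors = "DBH-and-height",
                   dev_min_cm = 3, dev_max_cm = 100),
    allom_equation("s2", "SP", "stem wood", "biomass", "combined-variable",
                   c(8, 0.012), predictors = "DBH-and-height",
                   dev_min_cm = 3, dev_max_cm = 100)
  )
  grid <- seq(10, 60, by = 10)
  res <- form_agreement(cat, "SP", "stem wood", grid = grid,
                        height_params = hp)
  std <- res[res$subset == "standard", ]
  # intercept-only difference: constant absolute spread along D^2 H
  expect_equal(std$max - std$min, rep(6, nrow(std)))
  expect_equal(std$d2h, grid^2 * predict_height(hp, grid))
  loc <- res[res$subset == "local", ]
  expect_equal(loc$min, pmin(0.04 * grid^2.5, 0.05 * grid^2.45))
  expect_equal(loc$max, pmax(0.04 * grid^2.5, 0.05 * grid^2.45))
  # identical equations give zero spread
  cat0 <- allom_catalog(power_eq("l1", 0.04, 2.5), power_eq("l2", 0.04, 2.5),
                        cat[3:4, ])
  res0 <- form_agreement(cat0, "SP", "stem wood", grid = grid,
                         height_params = hp)
  expect_true(all(res0$spread[res0$subset == "local"] == 0))
  expect_error(form_agreement(cat[c(1, 3, 4), ], "SP", "stem wood",
                              grid = grid, height_params = hp),
               "at least 2")
})
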