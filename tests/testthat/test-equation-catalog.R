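test_that("equation evaluation matches closed forms", {
  # identity line
  expect_equal(evaluate_equation(linear_eq("l", 0, 1), 10), 10)
  # hand-evaluated log-log form
  ll <- loglog_eq("ll", -2.0, 2.4)
  expect_equal(evaluate_equation(ll, 10), exp(-2.0 + 2.4 * log(10)))
  expect_equal(round(evaluate_equation(ll, 10), 1), 34.0)
  # combined-variable arithmetic and intercept limit
  cv <- allom_equation("cv", "SP", "stem wood", "biomass",
                       "combined-variable", c(5, 0.01),
                       predictors = "DBH-and-height",
                       dev_min_cm = 3, dev_max_cm = 100)
  expect_equal(evaluate_equation(cv, 10, height = 20), 5 + 0.01 * 100 * 20)
  expect_equal(evaluate_equation(cv, 1e-9, height = 20), 5, tolerance = 1e-6)
  # power form, with and without height
  expect_equal(evaluate_equation(power_eq("p", 0.1, 2.5), 12), 0.1 * 12^2.5)
})

test_that("evaluation errors on missing height and bad preconditions", {
  cv <- allom_equation("cv", "SP", "stem wood", "biomass",
                       "combined-variable", c(5, 0.01),
                       predictors = "DBH-and-height",
                       dev_min_cm = 3, dev_max_cm = 100)
  expect_error(evaluate_equation(cv, 10), "height")
  expect_error(evaluate_equation(linear_eq("l", 0, 1), -2), "positive")
  expect_error(allom_equation("x", "SP", "stem wood", "biomass", "spline",
                              c(1, 2)), "form_id")
  expect_error(allom_equation("x", "SP", "stem wood", "biomass", "power",
                              c(1, NA)), "finite")
  expect_error(allom_equation("x", "SP", "stem wood", "biomass", "power",
                              c(1, 2), dev_min_cm = 40, dev_max_cm = 10),
               "dev range")
})

test_that("power and log-log forms are monotone in DBH for positive slopes", {
  set.seed(11)
  d <- sort(runif(30, 3, 120))
  for (i in 1:20) {
    a <- runif(1, 0.001, 2); b <- runif(1, 0.5, 3)
    expect_true(all(diff(evaluate_equation(power_eq("p", a, b), d)) > 0))
    expect_true(all(diff(evaluate_equation(loglog_eq("q", log(a), b), d)) > 0))
  }
})

test_that("inclusion rules partition with one reason each and are idempotent", {
  cat <- allom_catalog(
    linear_eq("ok", 1, 2),
    allom_equation("cr", "SP", "branches total", "biomass", "power", c(1, 2),
                   predictors = "DBH-and-crown-ratio",
                   dev_min_cm = 3, dev_max_cm = 50),
    allom_equation("nr", "SP", "stem wood", "biomass", "power", c(1, 2)),
    allom_equation("st", "SP", "stem wood", "volume", "power", c(1, 2),
                   dev_min_cm = 3, dev_max_cm = 50, stump_height_cm = 20),
    allom_equation("nt", "SP", "stem wood", "volume", "power", c(1, 2),
                   dev_min_cm = 3, dev_max_cm = 50, stump_height_cm = 30,
                   extends_to_top = FALSE),
    allom_equation("wv", "SP", "stem wood", "volume", "power", c(1, 2),
                   stump_height_cm = 30, dev_range_waiver = TRUE)
  )
  res <- apply_inclusion_rules(cat)
  expect_setequal(res$included$id, c("ok", "wv")) # waiver admits 'wv'
  reasons <- setNames(res$excluded$reason, res$excluded$id)
  expect_equal(reasons[["cr"]], "extra-predictor")
  expect_equal(reasons[["nr"]], "no-dev-range")
  expect_equal(reasons[["st"]], "bad-stump-height")
  expect_equal(reasons[["nt"]], "not-to-top")
  # exhaustive and disjoint
  expect_equal(nrow(res$included) + nrow(res$excluded), nrow(cat))
  expect_length(intersect(res$included$id, res$excluded$id), 0)
  # idempotence: re-screening the union reproduces the partition
  again <- apply_inclusion_rules(allom_catalog(
    res$included, res$excluded[setdiff(names(res$excluded), "reason")]))
  expect_setequal(again$included$id, res$included$id)
  expect_equal(setNames(again$excluded$reason, again$excluded$id)[names(reasons)],
               reasons)
})

test_that("log back-transformation correction is exp(mse/2) and multiplicative", {
  e0 <- loglog_eq("e0", -2, 2.4, mse_log = 0)
  expect_equal(correct_log_bias(e0), 1)
  e1 <- loglog_eq("e1", -2, 2.4, mse_log = 0.1)
  expect_equal(correct_log_bias(e1), exp(0.05))
  d <- c(5, 17, 60)
  expect_equal(evaluate_equation(e1, d, correct_log_bias = TRUE),
               evaluate_equation(e1, d) * exp(0.05))
  expect_error(correct_log_bias(power_eq("p", 1, 2)), "log scale")
  expect_error(correct_log_bias(loglog_eq("e2", -2, 2.4)), "residual")
})

test_that("additivity error measures component-sum deviation from aggregates", {
  # components built to sum exactly to the aggregate
  comps <- allom_catalog(linear_eq("a", 1, 2, component = "stem wood"),
                         linear_eq("b", 2, 3, component = "stem bark"))
  agg <- linear_eq("t", 3, 5, component = "bole")
  res <- additivity_error(comps, agg, 5:50)
  expect_equal(res$max_abs, 0)
  # constant 2% inflation
  comps2 <- allom_catalog(linear_eq("a", 1.02 * 3, 1.02 * 5))
  res2 <- additivity_error(comps2, agg, 5:50)
  expect_equal(res2$mean, 2, tolerance = 1e-10)
  expect_equal(res2$max_abs, 2, tolerance = 1e-10)
  # log-log components vs an independently specified aggregate match a
  # direct per-class recomputation
  comps3 <- allom_catalog(loglog_eq("sw", -2, 2.4, component = "stem wood"),
                          loglog_eq("sb", -3.5, 2.2, component = "stem bark"))
  agg3 <- loglog_eq("ag", -1.8, 2.38, component = "bole")
  res3 <- additivity_error(comps3, agg3, 10:40)
  d <- 10:40
  dev <- 100 * (exp(-2 + 2.4 * log(d)) + exp(-3.5 + 2.2 * log(d)) -
                  exp(-1.8 + 2.38 * log(d))) / exp(-1.8 + 2.38 * log(d))
  expect_equal(res3$per_class$deviation_pct, dev)
  expect_equal(res3$mean, mean(dev))
  expect_error(additivity_error(comps, agg, 200:210), "intersect")
})

test_that("catalog and density files round-trip through CSV and JSON", {
  cat <- allom_catalog(
    loglog_eq("e1", -2, 2.4, mse_log = 0.08),
    power_eq("e2", 0.05, 2.5, response = "volume", stump_height_cm = 30)
  )
  f <- tempfile(fileext = ".csv")
  write_catalog(cat, f)
  back <- read_catalog(f)
  expect_equal(evaluate_equation(back[1, ], 17), evaluate_equation(cat[1, ], 17))
  expect_equal(back$mse_log, cat$mse_log)
  # strict header check
  bad <- tempfile(fileext = ".csv")
  writeLines("id,species\na,b", bad)
  expect_error(read_catalog(bad), "header")
  # JSON alternative
  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(
    id = "j1", species = "SP", component = "stem wood",
    response_kind = "biomass", form_id = "power", coefficients = c(0.1, 2.2),
    predictors = "DBH-only", dev_min_cm = 3, dev_max_cm = 90,
    extends_to_top = TRUE, log_base_e = FALSE, source = "synthetic"
  )), j, auto_unbox = TRUE)
  cj <- read_catalog_json(j)
  expect_equal(evaluate_equation(cj[1, ], 10), 0.1 * 10^2.2)
  # densities
  fd <- tempfile(fileext = ".csv")
  utils::write.csv(density_record("SP", "stem wood", 400, 500), fd,
                   row.names = FALSE)
  expect_equal(read_densities(fd)$rho_max, 500)
  expect_error(density_record("SP", "stem wood", 500, 400), "rho_min")
})
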