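# small hand-built equations and catalogs used across tests

linear_eq <- function(id, c0, c1, species = "SP", component = "stem wood",
                      dev = c(3, 100), ...) {
  allom_equation(id, species, component, "biomass", "linear-combination",
                 c(c0, c1), dev_min_cm = dev[1], dev_max_cm = dev[2], ...)
}

loglog_eq <- function(id, a, b, species = "SP", component = "stem wood",
                      dev = c(3, 100), mse_log = NA_real_, ...) {
  allom_equation(id, species, component, "biomass", "log-log", c(a, b),
                 dev_min_cm = dev[1], dev_max_cm = dev[2],
                 mse_log = mse_log, ...)
}

power_eq <- function(id, a, b, species = "SP", component = "stem wood",
                     dev = c(3, 100), response = "biomass", ...) {
  allom_equation(id, species, component, response, "power", c(a, b),
                 dev_min_cm = dev[1], dev_max_cm = dev[2], ...)
}

# inventory where every (species, class) count is divisible by k for all
# k in 1..5 and 10, with constant expansion factors (subdivision exactness)
divisible_inventory <- function(species, classes = c(10, 20, 30),
                                per_class = 60, expansion = 25) {
  do.call(rbind, lapply(species, function(sp)
    data.frame(species = sp,
               dbh_cm = rep(classes, each = per_class),
               expansion_factor = expansion, stringsAsFactors = FALSE)))
}
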