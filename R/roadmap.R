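#' @title Component aggregation roadmap
#' @description Directed acyclic calculation scheme combining component
#'   envelopes into a total-tree envelope through addition (+) and comparison
#'   (OR) steps, under an explicit correlation assumption at each addition.
#' @name aggregation_roadmap
NULL

#' Interval addition of two envelopes under a correlation assumption
#'
#' Because ranges rather than points are summed, the assumed "correlation"
#' between components changes the width of the sum. Under positive
#' correlation extremes co-occur: `[la + lb, ua + ub]`. Under negative
#' correlation one component's maximum pairs with the other's minimum
#' (cross-pairing): `[min(la + ub, ua + lb), max(la + ub, ua + lb)]`, which is
#' never wider than the positive-mode sum. Neither mode is claimed realistic;
#' they bracket the possibilities. The result is defined where both inputs
#' are defined.
#'
#' @param a,b envelopes on the same species, grid and units.
#' @param mode `"positive"` or `"negative"`.
#' @param component name for the output envelope.
#' @return an `envelope`.
#' @export
add_envelopes <- function(a, b, mode = c("positive", "negative"),
                          component = paste(a$component, "+", b$component)) {
  mode <- match.arg(mode)
  check_compatible(a, b)
  defined <- a$defined & b$defined
  if (mode == "positive") {
    lower <- a$lower + b$lower
    upper <- a$upper + b$upper
  } else {
    x <- a$lower + b$upper
    y <- a$upper + b$lower
    lower <- pmin(x, y)
    upper <- pmax(x, y)
  }
  lower[!defined] <- NA_real_; upper[!defined] <- NA_real_
  envelope(a$species, component, a$units, a$grid, lower, upper, defined)
}

#' Union of alternative-pathway envelopes (comparison / OR step)
#'
#' Alternative calculation pathways for the same component are compared by
#' retaining, per DBH class, the outermost bounds across all alternatives
#' that are defined there.
#'
#' @param alternatives non-empty list of envelopes (same species/grid/units).
#' @param component name for the output envelope.
#' @return an `envelope`, defined where any alternative is defined.
#' @export
union_envelopes <- function(alternatives,
                            component = alternatives[[1]]$component) {
  if (!length(alternatives)) stopf("empty list of alternative envelopes")
  a <- alternatives[[1]]
  for (b in alternatives[-1]) check_compatible(a, b)
  n <- length(a$grid)
  lower <- rep(NA_real_, n); upper <- rep(NA_real_, n)
  defined <- rep(FALSE, n)
  for (e in alternatives) {
    d <- e$defined
    lower[d] <- pmin(lower[d], e$lower[d], na.rm = TRUE)
    upper[d] <- pmax(upper[d], e$upper[d], na.rm = TRUE)
    defined <- defined | d
  }
  envelope(a$species, component, a$units, a$grid, lower, upper, defined)
}

check_compatible <- function(a, b) {
  stopifnot(inherits(a, "envelope"), inherits(b, "envelope"))
  if (!identical(a$species, b$species))
    stopf("species mismatch: %s vs %s", a$species, b$species)
  if (!identical(a$units, b$units))
    stopf("unit mismatch: %s vs %s", a$units, b$units)
  if (!identical(a$grid, b$grid)) stopf("grid mismatch")
  invisible(TRUE)
}

#' Load and validate a calculation roadmap
#'
#' A roadmap is a JSON object with `nodes` (component names) and `steps`, an
#' ordered array of `{"op": "add"|"or", "inputs": [...], "output": "..."}`.
#' The induced input -> output graph must be acyclic with exactly one
#' terminal node, and evaluation follows the listed order (which matters for
#' the non-associative negative-correlation addition).
#'
#' @param path JSON file path.
#' @return a `roadmap` object: list with `nodes`, `steps`, `terminal`,
#'   `leaves` (nodes never produced by a step) and `add_leaves` (leaves that
#'   feed addition steps and are therefore required).
#' @export
read_roadmap <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(spec$nodes) || is.null(spec$steps))
    stopf("roadmap JSON needs 'nodes' and 'steps'")
  steps <- lapply(spec$steps, function(s) {
    if (!s$op %in% c("add", "or")) stopf("unknown roadmap op '%s'", s$op)
    list(op = s$op, inputs = unlist(s$inputs), output = s$output)
  })
  nodes <- unlist(spec$nodes)
  used <- unique(unlist(lapply(steps, function(s) c(s$inputs, s$output))))
  if (length(setdiff(used, nodes)))
    stopf("roadmap steps reference undeclared nodes: %s",
          paste(setdiff(used, nodes), collapse = ", "))
  edges <- do.call(rbind, lapply(steps, function(s)
    cbind(from = s$inputs, to = s$output)))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE,
                                     vertices = nodes)
  if (!igraph::is_dag(g)) stopf("roadmap graph contains a cycle")
  outputs <- vapply(steps, `[[`, "", "output")
  if (anyDuplicated(outputs))
    stopf("each node may be produced by at most one step")
  inputs <- unique(unlist(lapply(steps, `[[`, "inputs")))
  terminal <- setdiff(outputs, inputs)
  if (length(terminal) != 1L)
    stopf("roadmap must have exactly one terminal node (found: %s)",
          paste(terminal, collapse = ", "))
  leaves <- setdiff(nodes, outputs)
  add_leaves <- intersect(leaves, unique(unlist(
    lapply(steps[vapply(steps, `[[`, "", "op") == "add"], `[[`, "inputs"))))
  structure(list(nodes = nodes, steps = steps, terminal = terminal,
                 leaves = leaves, add_leaves = add_leaves),
            class = "roadmap")
}

#' @export
print.roadmap <- function(x, ...) {
  cat(sprintf("<roadmap> %d nodes, %d steps, terminal '%s'\n",
              length(x$nodes), length(x$steps), x$terminal))
  for (s in x$steps)
    cat(sprintf("  %s(%s) -> %s\n", toupper(s$op),
                paste(s$inputs, collapse = ", "), s$output))
  invisible(x)
}

#' Default total-tree roadmap
#'
#' Stem wood + stem bark form the bole; bole + branches + foliage form one
#' aboveground pathway, compared (OR) with direct aboveground-total
#' equations where they exist; aboveground + coarse roots give total tree.
#'
#' @return a `roadmap`.
#' @export
default_roadmap <- function() {
  read_roadmap(system.file("extdata", "roadmap_default.json",
                           package = "allomenv", mustWork = TRUE))
}

#' Fold component envelopes into a total-tree envelope
#'
#' Evaluates the roadmap's steps in their listed (topological) order. OR
#' steps tolerate missing alternatives (published libraries do not cover
#' every pathway for every species) but require at least one; addition steps
#' require all inputs.
#'
#' @param roadmap a `roadmap`.
#' @param component_envelopes named list of leaf envelopes (all same
#'   species/grid/units, typically kg-C).
#' @param mode correlation mode applied at every addition step, `"positive"`
#'   or `"negative"`.
#' @return list with `total` (the terminal envelope), `intermediates` (named
#'   list of all computed node envelopes), and `mode`.
#' @export
total_tree_envelope <- function(roadmap, component_envelopes,
                                mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(roadmap, "roadmap"))
  env <- component_envelopes
  for (s in roadmap$steps) {
    avail <- s$inputs[s$inputs %in% names(env)]
    if (s$op == "add") {
      if (length(avail) != length(s$inputs))
        stopf("addition step '%s' is missing inputs: %s", s$output,
              paste(setdiff(s$inputs, avail), collapse = ", "))
      # left-to-right fold in the listed order (negative mode is
      # non-associative, so the order is part of the definition)
      acc <- env[[s$inputs[1]]]
      for (nm in s$inputs[-1])
        acc <- add_envelopes(acc, env[[nm]], mode, component = s$output)
      acc$component <- s$output
      env[[s$output]] <- acc
    } else {
      if (!length(avail))
        stopf("comparison step '%s' has no available alternatives", s$output)
      env[[s$output]] <- union_envelopes(env[avail], component = s$output)
    }
  }
  if (is.null(env[[roadmap$terminal]]))
    stopf("terminal node '%s' was not produced", roadmap$terminal)
  list(total = env[[roadmap$terminal]],
       intermediates = env[setdiff(names(env), names(component_envelopes))],
       mode = mode)
}
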