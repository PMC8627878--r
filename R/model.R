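# -- generic simulatable ODE system ------------------------------------------

#' Construct a simulatable ODE system
#'
#' Light container shared by contour-derived models and the classical
#' oscillator registry: a right-hand-side function, named parameters and
#' named initial state.
#'
#' @param name model name.
#' @param rhs function `(t, y, p)` returning the derivative vector.
#' @param parameters named numeric vector.
#' @param initials named numeric vector (state variable order defines the
#'   trajectory column order).
#' @param notes free-text provenance/regime notes.
#' @param default_tend suggested simulation horizon (time units).
#' @return object of class `ode_system`.
#' @export
ode_system <- function(name, rhs, parameters, initials, notes = "",
                       default_tend = 100) {
  stopifnot(is.function(rhs), is.numeric(parameters), is.numeric(initials),
            !is.null(names(initials)))
  structure(list(name = name, rhs = rhs,
                 parameters = parameters, initials = initials,
                 notes = notes, default_tend = default_tend),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat("ode_system '", x$name, "': ", length(x$initials),
      " state variable(s) [", paste(names(x$initials), collapse = ", "),
      "]\n", sep = "")
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Override parameters of an ODE system
#'
#' @param system an `ode_system`.
#' @param overrides named numeric values; unknown names are an error.
#' @return the system with updated parameters.
#' @export
set_parameters <- function(system, overrides) {
  if (length(overrides) == 0L) return(system)
  overrides <- unlist(overrides)
  bad <- setdiff(names(overrides), names(system$parameters))
  if (length(bad) > 0L)
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         " (model '", system$name, "' has: ",
         paste(names(system$parameters), collapse = ", "), ")",
         call. = FALSE)
  system$parameters[names(overrides)] <- overrides
  if ("h" %in% names(overrides) && overrides[["h"]] < 1)
    stop("hill exponent h must be >= 1", call. = FALSE)
  if ("K" %in% names(overrides) && overrides[["K"]] <= 0)
    stop("half-saturation K must be > 0", call. = FALSE)
  system
}

# -- contour -> Goodwin-type ODE model ---------------------------------------

#' Build the ODE model of a contour
#'
#' Reconstructs a Goodwin-type kinetic model from a contour and its parent
#' graph. The state variables are the contour substances in pathway order.
#' The regulated entry reaction `r0` gets a Hill-inhibited rate
#' `v0 = V * prod(boundary substrates) / (K + inhibitor^h)`; every other
#' contour reaction `ri` gets linear mass action `vi = k_ri * si *
#' prod(boundary substrates)`. Each state obeys
#' `d si/dt = v(producing) - v(consuming) - kD_si * si`; the last substance
#' has no consuming contour reaction, so its only outflow is degradation.
#' Off-contour co-substrates and co-products are boundary species held at
#' fixed concentration (co-substrate concentrations multiply the rate and
#' are absorbable into the rate constants at their default value 1).
#'
#' Default parameters (all overridable via `params`): rate constants
#' `k_* = 1` (1/time), Hill numerator scale `V = 1` (conc/time),
#' half-saturation `K = 1` (conc^h), Hill exponent `h = 4`, degradation
#' `kD_* = 0.5` (1/time), initial concentrations 0.1, boundary
#' concentrations 1. The degradation default keeps the chain's relaxation
#' rates commensurate (removal poles `k + kD` vs the end product's `kD`),
#' which is what makes the canonical Goodwin chain oscillation-capable at
#' moderate cooperativity; a much smaller `kD` makes the end-product pole
#' so slow that the loop is stable for any Hill exponent of practical
#' interest.
#'
#' @param x a [contour()].
#' @param graph the parent `typed_graph`.
#' @param params named list/vector of overrides. Scalar shortcuts `k`,
#'   `kD`, `initial`, `boundary_conc` apply to every reaction/substance;
#'   individual entries use the flat names `k_<reaction>`, `kD_<substance>`,
#'   `b_<substance>`, `V`, `K`, `h`.
#' @return object of classes `contour_ode` and `ode_system`, with extra
#'   fields `state`, `boundary`, `reactions` (structure tables used by
#'   [export_sbml()]).
#' @export
build_contour_model <- function(x, graph, params = list()) {
  validate_contour(x, graph)
  k <- length(x$substances)
  rids <- c(x$regulated_reaction, x$reactions)
  state_ids <- x$substances

  params <- as.list(params)
  scalar <- function(nm, default) {
    if (!is.null(params[[nm]])) params[[nm]] else default
  }
  h <- scalar("h", 4)
  K <- scalar("K", 1)
  V <- scalar("V", 1)
  if (h < 1) stop("hill exponent h must be >= 1", call. = FALSE)
  if (K <= 0) stop("half-saturation K must be > 0", call. = FALSE)

  boundary_ids <- character()
  reactions <- vector("list", k)
  for (i in seq_len(k)) {
    rid <- rids[i]
    subs <- reaction_substrates(graph, rid)
    prods <- reaction_products(graph, rid)
    bnd_sub <- setdiff(subs, state_ids)
    boundary_ids <- union(boundary_ids, union(bnd_sub,
                                              setdiff(prods, state_ids)))
    law <- if (i == 1L) {
      list(form = "hill_inhibited", reaction_id = rid,
           inhibitor = x$substances[k],
           boundary_factors = bnd_sub)
    } else {
      list(form = "mass_action", reaction_id = rid,
           substrate = x$substances[i - 1L],
           boundary_factors = bnd_sub)
    }
    reactions[[i]] <- list(id = rid, name = node_name(graph, rid),
                           substrates = subs, products = prods,
                           modifiers = if (i == 1L) x$substances[k]
                                       else character(),
                           law = law)
  }

  p <- c(V = V, K = K, h = h)
  k_default <- scalar("k", 1)
  for (rid in x$reactions) {
    p[paste0("k_", rid)] <- scalar(paste0("k_", rid), k_default)
  }
  kD_default <- scalar("kD", 0.5)
  for (sid in state_ids) {
    kD <- scalar(paste0("kD_", sid), kD_default)
    if (kD < 0) stop("degradation constant kD_", sid, " must be >= 0",
                     call. = FALSE)
    p[paste0("kD_", sid)] <- kD
  }
  b_default <- scalar("boundary_conc", 1)
  for (bid in boundary_ids) {
    p[paste0("b_", bid)] <- scalar(paste0("b_", bid), b_default)
  }
  known <- c("h", "K", "V", "k", "kD", "initial", "boundary_conc",
             paste0("k_", x$reactions), paste0("kD_", state_ids),
             paste0("b_", boundary_ids))
  bad <- setdiff(names(params), known)
  if (length(bad) > 0L)
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  init_default <- scalar("initial", 0.1)
  y0 <- stats::setNames(rep(init_default, k), state_ids)

  inhibitor <- x$substances[k]
  bnd_first <- reactions[[1L]]$law$boundary_factors
  mass_sub <- vapply(reactions[-1L], function(r) r$law$substrate,
                     character(1))
  mass_bnd <- lapply(reactions[-1L], function(r) r$law$boundary_factors)
  k_names <- paste0("k_", x$reactions)
  kD_names <- paste0("kD_", state_ids)

  rhs <- function(t, y, p) {
    v <- numeric(k)
    bprod <- if (length(bnd_first) > 0L)
      prod(p[paste0("b_", bnd_first)]) else 1
    v[1L] <- p[["V"]] * bprod / (p[["K"]] + max(y[k], 0)^p[["h"]])
    if (k > 1L) {
      for (i in 2:k) {
        bp <- if (length(mass_bnd[[i - 1L]]) > 0L)
          prod(p[paste0("b_", mass_bnd[[i - 1L]])]) else 1
        v[i] <- p[[k_names[i - 1L]]] * y[i - 1L] * bp
      }
    }
    consume <- c(v[-1L], 0)
    v - consume - p[kD_names] * y
  }

  sys <- ode_system(
    name = paste0("contour_", substr(x$canonical_id, 1, 40)),
    rhs = rhs, parameters = p, initials = y0,
    notes = paste0("Goodwin-type chain generated from contour ",
                   x$canonical_id),
    default_tend = 500)
  sys$state <- data.frame(id = state_ids,
                          name = node_name(graph, state_ids),
                          initial = unname(y0), stringsAsFactors = FALSE)
  sys$boundary <- if (length(boundary_ids) > 0L)
    data.frame(id = boundary_ids, name = node_name(graph, boundary_ids),
               conc = unname(p[paste0("b_", boundary_ids)]),
               stringsAsFactors = FALSE)
    else data.frame(id = character(), name = character(), conc = numeric(),
                    stringsAsFactors = FALSE)
  sys$reactions <- reactions
  sys$contour <- x
  sys$sbml_id <- gsub("[^A-Za-z0-9_]", "_",
                      paste0("contour_", x$regulated_reaction))
  class(sys) <- c("contour_ode", "ode_system")
  sys
}

#' Closed-form-style steady state of a contour model (h = 1 chains)
#'
#' For the generated Goodwin-type chain the fixed point satisfies a single
#' scalar equation in the last substance's concentration; this helper solves
#' it by root bracketing ([stats::uniroot()]) and back-substitutes the chain.
#' Used as an independent check of the generated right-hand side.
#'
#' @param model a `contour_ode`.
#' @return named numeric steady state.
#' @export
contour_steady_state <- function(model) {
  p <- model$parameters
  k <- nrow(model$state)
  state_ids <- model$state$id
  k_names <- paste0("k_", vapply(model$reactions[-1L], `[[`, "", "id"))
  kD <- p[paste0("kD_", state_ids)]
  bprod1 <- local({
    b <- model$reactions[[1L]]$law$boundary_factors
    if (length(b) > 0L) prod(p[paste0("b_", b)]) else 1
  })
  bnd_i <- vapply(seq_len(k - 1L), function(i) {
    b <- model$reactions[[i + 1L]]$law$boundary_factors
    if (length(b) > 0L) prod(p[paste0("b_", b)]) else 1
  }, numeric(1))
  # forward map: given v0, chain concentrations
  chain <- function(v0) {
    y <- numeric(k)
    vin <- v0
    for (i in seq_len(k)) {
      out_rate <- if (i < k) p[[k_names[i]]] * bnd_i[i] else 0
      y[i] <- vin / (out_rate + kD[i])
      vin <- out_rate * y[i]
    }
    y
  }
  f <- function(z) {
    v0 <- p[["V"]] * bprod1 / (p[["K"]] + max(z, 0)^p[["h"]])
    chain(v0)[k] - z
  }
  z <- stats::uniroot(f, c(0, p[["V"]] * bprod1 / p[["K"]] /
                             min(kD[k], 1) + 10),
                      tol = 1e-14)$root
  v0 <- p[["V"]] * bprod1 / (p[["K"]] + z^p[["h"]])
  stats::setNames(chain(v0), state_ids)
}
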