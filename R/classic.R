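# -- registry of classical oscillator models ---------------------------------
# Each entry implements the standard published form of the model it names
# and records the primary citation in its notes. These are the calibration
# fixtures for the trajectory classifier: their dynamic regimes under the
# default parameters are documented and verified by the test suite.

classic_specs <- function() {
  list(
    lotka1910 = list(
      dimension = 2L,
      parameters = c(k0 = 1, k1 = 1, k2 = 1),
      initials = c(x = 2, y = 1),
      notes = paste0("Lotka (1910) chemical oscillator with constant ",
                     "substrate inflow: dx/dt = k0 - k1*x*y, ",
                     "dy/dt = k1*x*y - k2*y. Damped oscillations into a ",
                     "stable focus under the defaults (the classifier's ",
                     "damped control)."),
      default_tend = 40,
      rhs = function(t, y, p) {
        c(p[["k0"]] - p[["k1"]] * y[1] * y[2],
          p[["k1"]] * y[1] * y[2] - p[["k2"]] * y[2])
      }),
    lotka_volterra = list(
      dimension = 2L,
      parameters = c(a = 1, b = 1, c = 1, d = 1),
      initials = c(x = 1.5, y = 1),
      notes = paste0("Lotka (1920) / Volterra (1928) predator-prey system: ",
                     "dx/dt = a*x - b*x*y, dy/dt = -c*y + d*x*y. Neutral ",
                     "(non-limit-cycle) closed orbits; first integral ",
                     "d*x - c*log x + b*y - a*log y."),
      default_tend = 120,
      rhs = function(t, y, p) {
        c(p[["a"]] * y[1] - p[["b"]] * y[1] * y[2],
          -p[["c"]] * y[2] + p[["d"]] * y[1] * y[2])
      }),
    van_der_pol = list(
      dimension = 2L,
      parameters = c(alpha = 1, omega = 1),
      initials = c(x = 2, v = 0),
      notes = paste0("van der Pol & van der Mark (1928) relaxation ",
                     "oscillator, first-order form: dx/dt = v, ",
                     "dv/dt = alpha*(1 - x^2)*v - omega^2*x. Limit cycle ",
                     "for alpha > 0; harmonic with period 2*pi/omega at ",
                     "alpha = 0."),
      default_tend = 150,
      rhs = function(t, y, p) {
        c(y[2],
          p[["alpha"]] * (1 - y[1]^2) * y[2] - p[["omega"]]^2 * y[1])
      }),
    goodwin3 = list(
      dimension = 3L,
      parameters = c(a = 1, K = 1, kd = 0.5, h = 12),
      initials = c(x1 = 0.2, x2 = 0.2, x3 = 0.2),
      notes = paste0("Goodwin (1965) genetic-control loop, 3-stage Hill-",
                     "repression form: dx1/dt = a/(K + x3^h) - kd*x1, ",
                     "dx2/dt = x1 - kd*x2, dx3/dt = x2 - kd*x3. With equal ",
                     "degradation the secant condition puts the Hopf point ",
                     "near h = 9-10 for these a, K, kd: sustained at the ",
                     "default h = 12, stable at h <= 8."),
      default_tend = 400,
      rhs = function(t, y, p) {
        c(p[["a"]] / (p[["K"]] + max(y[3], 0)^p[["h"]]) - p[["kd"]] * y[1],
          y[1] - p[["kd"]] * y[2],
          y[2] - p[["kd"]] * y[3])
      }),
    selkov = list(
      dimension = 2L,
      parameters = c(a = 0.08, b = 0.6),
      initials = c(x = 1, y = 1),
      notes = paste0("Sel'kov (1968) glycolytic (phosphofructokinase) ",
                     "oscillator, reduced dimensionless 2-variable form: ",
                     "dx/dt = -x + a*y + x^2*y, dy/dt = b - a*y - x^2*y. ",
                     "Limit cycle at the defaults a = 0.08, b = 0.6."),
      default_tend = 300,
      rhs = function(t, y, p) {
        c(-y[1] + p[["a"]] * y[2] + y[1]^2 * y[2],
          p[["b"]] - p[["a"]] * y[2] - y[1]^2 * y[2])
      }),
    cicr = list(
      dimension = 2L,
      parameters = c(v0 = 1, v1 = 7.3, beta = 0.301, VM2 = 65, VM3 = 500,
                     K2 = 1, KR = 2, KA = 0.9, n = 2, m = 2, pexp = 4,
                     kf = 1, kout = 10),
      initials = c(Z = 0.3, Y = 1.5),
      notes = paste0("Dupont & Goldbeter (1989) minimal calcium-induced ",
                     "calcium release model: cytosolic (Z) and stored (Y) ",
                     "Ca2+; dZ/dt = v0 + v1*beta - v2 + v3 + kf*Y - k*Z, ",
                     "dY/dt = v2 - v3 - kf*Y with Hill-type pump v2 and ",
                     "release v3 terms. Sustained Ca2+ spiking at the ",
                     "documented defaults."),
      default_tend = 50,
      rhs = function(t, y, p) {
        Z <- max(y[1], 0); Y <- max(y[2], 0)
        v2 <- p[["VM2"]] * Z^p[["n"]] / (p[["K2"]]^p[["n"]] + Z^p[["n"]])
        v3 <- p[["VM3"]] *
          (Y^p[["m"]] / (p[["KR"]]^p[["m"]] + Y^p[["m"]])) *
          (Z^p[["pexp"]] / (p[["KA"]]^p[["pexp"]] + Z^p[["pexp"]]))
        c(p[["v0"]] + p[["v1"]] * p[["beta"]] - v2 + v3 +
            p[["kf"]] * y[2] - p[["kout"]] * y[1],
          v2 - v3 - p[["kf"]] * y[2])
      })
  )
}

#' Names and notes of the classical oscillator registry
#'
#' @return data.frame with columns `name`, `dimension`, `notes`.
#' @export
classic_registry <- function() {
  specs <- classic_specs()
  data.frame(
    name = names(specs),
    dimension = vapply(specs, `[[`, integer(1), "dimension"),
    notes = vapply(specs, `[[`, character(1), "notes"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Instantiate a classical oscillator model
#'
#' Builds a simulatable [ode_system()] from the registry of classical
#' oscillators: `lotka1910` (damped chemical oscillations),
#' `lotka_volterra` (neutral predator-prey cycles), `van_der_pol`
#' (relaxation limit cycle), `goodwin3` (3-stage Hill-repression
#' genetic-control loop), `selkov` (reduced glycolytic oscillator) and
#' `cicr` (minimal calcium-induced calcium release). Default parameters are
#' each model's documented regime; see [classic_registry()] for notes.
#'
#' @param name registry name.
#' @param overrides named parameter overrides (e.g. `c(alpha = 0)`).
#' @param initials optional named initial state override.
#' @return an [ode_system()].
#' @examples
#' vdp <- make_classic("van_der_pol")
#' tr <- integrate_model(vdp, t_end = 100)
#' detect_oscillation(tr)$overall_label
#' @export
make_classic <- function(name, overrides = NULL, initials = NULL) {
  specs <- classic_specs()
  if (!name %in% names(specs))
    stop("unknown classical model '", name, "'; registry: ",
         paste(names(specs), collapse = ", "), call. = FALSE)
  sp <- specs[[name]]
  sys <- ode_system(name = name, rhs = sp$rhs, parameters = sp$parameters,
                    initials = sp$initials, notes = sp$notes,
                    default_tend = sp$default_tend)
  if (!is.null(overrides)) sys <- set_parameters(sys, overrides)
  if (!is.null(initials)) {
    bad <- setdiff(names(initials), names(sys$initials))
    if (length(bad) > 0L)
      stop("unknown state variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    sys$initials[names(initials)] <- unlist(initials)
  }
  sys
}

#' Lotka-Volterra first integral
#'
#' The conserved quantity `d*x - c*log(x) + b*y - a*log(y)` of the
#' predator-prey system, evaluated along a trajectory; a diagnostic of
#' integration accuracy.
#'
#' @param trajectory a [trajectory] of the `lotka_volterra` model.
#' @param parameters the model's parameter vector.
#' @return numeric vector, one value per time point.
#' @export
lotka_volterra_invariant <- function(trajectory, parameters) {
  x <- trajectory$states[, 1]
  y <- trajectory$states[, 2]
  p <- parameters
  p[["d"]] * x - p[["c"]] * log(x) + p[["b"]] * y - p[["a"]] * log(y)
}
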