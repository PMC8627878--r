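# -- numerical integration ---------------------------------------------------

#' Integrate an ODE system
#'
#' Stiff-capable integration (deSolve's `lsoda`, automatic stiff/non-stiff
#' switching) on a uniform output grid. Divergence — any state exceeding the
#' overflow guard or turning non-finite — truncates the trajectory at the
#' last accepted time and sets the `diverged` flag instead of failing.
#'
#' @param system an [ode_system()] (classical model or contour model).
#' @param t_end end time (> 0).
#' @param n_points number of output points (uniform grid from 0).
#' @param initials optional named initial-state override.
#' @param rtol,atol relative/absolute integration tolerances. The tight
#'   defaults (1e-8, 1e-10) keep period estimates accurate.
#' @param method deSolve method name.
#' @param overflow guard on `abs(state)` above which the trajectory is
#'   declared divergent.
#' @return object of class `trajectory`: list with `times`, `states`
#'   (matrix, one column per state variable), `variable_names`, `diverged`,
#'   and `meta` (tolerances, method, step diagnostics).
#' @export
integrate_model <- function(system, t_end = NULL, n_points = 2000L,
                            initials = NULL, rtol = 1e-8, atol = 1e-10,
                            method = "lsoda", overflow = 1e8) {
  if (is.null(t_end)) t_end <- system$default_tend
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0",
                                             call. = FALSE)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  y0 <- system$initials
  if (!is.null(initials)) {
    bad <- setdiff(names(initials), names(y0))
    if (length(bad) > 0L)
      stop("unknown state variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    y0[names(initials)] <- unlist(initials)
  }
  times <- seq(0, t_end, length.out = n_points)
  p <- system$parameters
  fn <- function(t, y, parms) list(system$rhs(t, y, parms))
  sol <- tryCatch(
    suppressWarnings(
      deSolve::ode(y = y0, times = times, func = fn, parms = p,
                   method = method, rtol = rtol, atol = atol)),
    error = function(e) {
      stop("integration of '", system$name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  m <- as.matrix(sol)
  tcol <- m[, 1]
  states <- m[, -1, drop = FALSE]
  bad_row <- which(!is.finite(rowSums(states)) |
                     apply(abs(states), 1, max) > overflow)
  diverged <- length(bad_row) > 0L || nrow(states) < n_points
  if (length(bad_row) > 0L) {
    keep <- seq_len(min(bad_row) - 1L)
    tcol <- tcol[keep]
    states <- states[keep, , drop = FALSE]
  }
  if (nrow(states) < 2L)
    stop("integration of '", system$name,
         "' diverged immediately (last accepted time ",
         if (length(tcol) > 0) max(tcol) else 0, ")", call. = FALSE)
  colnames(states) <- names(y0)
  structure(list(times = tcol, states = states,
                 variable_names = names(y0), diverged = diverged,
                 meta = list(rtol = rtol, atol = atol, method = method,
                             t_end = t_end, n_points = n_points)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", length(x$times), " points over t = [",
      min(x$times), ", ", max(x$times), "], variables: ",
      paste(x$variable_names, collapse = ", "),
      if (x$diverged) " [DIVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' @param trajectory a `trajectory`.
#' @param path output file (column `time` plus one column per variable).
#' @return invisibly, `path`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(time = trajectory$times, trajectory$states,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- peak analysis -----------------------------------------------------------

# local maxima with topographic prominence >= min_prom; returns index,
# parabolic-refined time and value, and prominence per peak
find_peaks <- function(t, x, min_prom) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), time = numeric(),
                                value = numeric(), prominence = numeric()))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] &
                  x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(data.frame(index = integer(),
                                            time = numeric(),
                                            value = numeric(),
                                            prominence = numeric()))
  prom <- vapply(cand, function(i) {
    # walk left/right to the first strictly higher sample (or the border),
    # tracking the minimum on each side; prominence = peak - higher key col
    left <- if (i == 1L) x[1] else {
      j <- i - 1L; lo <- x[j]
      while (j > 1L && x[j] <= x[i]) { j <- j - 1L; lo <- min(lo, x[j]) }
      lo
    }
    right <- if (i == n) x[n] else {
      j <- i + 1L; lo <- x[j]
      while (j < n && x[j] <= x[i]) { j <- j + 1L; lo <- min(lo, x[j]) }
      lo
    }
    x[i] - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prom
  cand <- cand[keep]; prom <- prom[keep]
  # parabolic refinement of peak time and height
  ref <- vapply(cand, function(i) {
    if (i <= 1L || i >= n) return(c(t[i], x[i]))
    y1 <- x[i - 1L]; y2 <- x[i]; y3 <- x[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom >= 0 || abs(denom) < .Machine$double.eps)
      return(c(t[i], x[i]))
    d <- 0.5 * (y1 - y3) / denom
    d <- max(min(d, 0.5), -0.5)
    dt <- t[i + 1L] - t[i]
    c(t[i] + d * dt, y2 - 0.25 * (y1 - y3) * d)
  }, numeric(2))
  data.frame(index = cand, time = ref[1, ], value = ref[2, ],
             prominence = prom)
}

#' Default oscillation-detection settings
#'
#' @param transient_frac fraction of the time window discarded as transient
#'   before analysis.
#' @param prom_frac required peak prominence as a fraction of the
#'   post-transient signal range.
#' @param min_peaks minimum number of post-transient peaks for a sustained
#'   call.
#' @param cv_tol maximum coefficient of variation of the inter-peak
#'   intervals for a regular (sustained) rhythm.
#' @param amp_band admissible last/first peak-amplitude ratio for a
#'   sustained call; below it the signal is damped, above it growing.
#' @param min_rel_amp minimum mean peak amplitude relative to the mean
#'   absolute signal level (guards against numerical ripple).
#' @param steady_eps relative signal range below which a trace counts as
#'   constant.
#' @param overall_rule `"any"` (default: sustained if any variable is) or
#'   `"all"`.
#' @return named list of settings.
#' @export
detection_settings <- function(transient_frac = 0.5, prom_frac = 0.05,
                               min_peaks = 5L, cv_tol = 0.05,
                               amp_band = c(0.9, 1.1), min_rel_amp = 0.01,
                               steady_eps = 1e-6, overall_rule = "any") {
  stopifnot(transient_frac >= 0, transient_frac < 1, prom_frac > 0,
            min_peaks >= 2L, cv_tol > 0, length(amp_band) == 2L,
            amp_band[1] < amp_band[2], overall_rule %in% c("any", "all"))
  list(transient_frac = transient_frac, prom_frac = prom_frac,
       min_peaks = as.integer(min_peaks), cv_tol = cv_tol,
       amp_band = amp_band, min_rel_amp = min_rel_amp,
       steady_eps = steady_eps, overall_rule = overall_rule)
}

classify_signal <- function(t, x, s, diverged) {
  rec <- list(label = "inconclusive", n_peaks = 0L, period_mean = NA_real_,
              period_cv = NA_real_, amplitude_mean = NA_real_,
              amplitude_trend_ratio = NA_real_)
  if (diverged) { rec$label <- "growing"; return(rec) }
  rng <- max(x) - min(x)
  level <- mean(abs(x))
  if (rng <= s$steady_eps * max(level, 1e-300)) {
    rec$label <- "steady"
    return(rec)
  }
  pk <- find_peaks(t, x, min_prom = s$prom_frac * rng)
  rec$n_peaks <- nrow(pk)
  if (nrow(pk) == 0L) { rec$label <- "steady"; return(rec) }
  # overall envelope decay across the window: range of the second half
  # relative to the first half (robust for fast-decaying spirals whose
  # later peaks fall below the prominence threshold)
  mid <- min(t) + (max(t) - min(t)) / 2
  r1 <- diff(range(x[t < mid]))
  r2 <- diff(range(x[t >= mid]))
  range_ratio <- if (r1 > 0) r2 / r1 else 1
  # peak amplitudes: drop the first and last peak when enough are
  # available — their prominences are truncated by the window edges
  sel <- if (nrow(pk) >= 4L) 2L:(nrow(pk) - 1L) else seq_len(nrow(pk))
  rec$amplitude_mean <- mean(pk$prominence[sel])
  if (nrow(pk) >= 2L) {
    periods <- diff(pk$time)
    rec$period_mean <- mean(periods)
    rec$period_cv <- if (length(periods) >= 2L)
      stats::sd(periods) / mean(periods) else 0
    rec$amplitude_trend_ratio <-
      pk$prominence[sel[length(sel)]] / pk$prominence[sel[1L]]
  }
  tr <- rec$amplitude_trend_ratio
  rel_amp <- rec$amplitude_mean / max(abs(mean(x)), .Machine$double.xmin)
  if (!is.na(tr) && rec$n_peaks >= s$min_peaks &&
      rec$period_cv <= s$cv_tol &&
      tr >= s$amp_band[1] && tr <= s$amp_band[2] &&
      range_ratio >= s$amp_band[1] && range_ratio <= 1 / s$amp_band[1]) {
    rec$label <- if (rel_amp >= s$min_rel_amp) "sustained" else "steady"
    return(rec)
  }
  if ((!is.na(tr) && tr < s$amp_band[1]) || range_ratio < s$amp_band[1]) {
    rec$label <- "damped"
    return(rec)
  }
  if ((!is.na(tr) && tr > s$amp_band[2]) ||
      range_ratio > 1 / s$amp_band[1]) {
    rec$label <- "growing"
    return(rec)
  }
  if (!is.na(rec$period_cv) && rec$n_peaks >= s$min_peaks &&
      rec$period_cv > s$cv_tol) {
    rec$label <- "irregular"
    return(rec)
  }
  rec$label <- "inconclusive"
  rec
}

#' Classify a trajectory as steady / damped / sustained / growing / irregular
#'
#' Operationalizes "stable limit cycle" on a finite trajectory. Per
#' variable, the transient fraction of the window is discarded, local
#' maxima with prominence above `prom_frac` times the post-transient range
#' are located (peak times refined by parabolic interpolation), and the
#' peak series is classified: enough peaks with a regular period
#' (`period_cv <= cv_tol`), stable amplitude (last/first prominence ratio
#' inside `amp_band`) and non-negligible relative amplitude is
#' `sustained`; a shrinking amplitude is `damped`; a growing amplitude or
#' a divergent integration is `growing`; irregular periods are
#' `irregular`; a flat or peak-free trace is `steady`. Note the classifier
#' detects sustained periodicity, not structural stability of a cycle:
#' neutral conservative oscillations (Lotka-Volterra) classify as
#' sustained.
#'
#' @param trajectory a [trajectory] with at least 100 points.
#' @param settings see [detection_settings()].
#' @return object of class `oscillation_report`: list with `variables`
#'   (one row per state variable: label, n_peaks, period_mean, period_cv,
#'   amplitude_mean, amplitude_trend_ratio), `overall_label`, `period`
#'   (mean period over sustained variables) and `settings`. Deterministic
#'   for a fixed trajectory and settings.
#' @export
detect_oscillation <- function(trajectory, settings = detection_settings()) {
  if (!inherits(trajectory, "trajectory"))
    stop("expected a trajectory from integrate_model()", call. = FALSE)
  if (length(trajectory$times) < 100L)
    stop("trajectory has fewer than 100 points; integrate with a finer grid",
         call. = FALSE)
  s <- settings
  t_all <- trajectory$times
  cut <- min(t_all) + s$transient_frac * (max(t_all) - min(t_all))
  keep <- t_all >= cut
  rows <- lapply(seq_along(trajectory$variable_names), function(j) {
    rec <- classify_signal(t_all[keep], trajectory$states[keep, j],
                           s, trajectory$diverged)
    data.frame(variable = trajectory$variable_names[j],
               label = rec$label, n_peaks = rec$n_peaks,
               period_mean = rec$period_mean, period_cv = rec$period_cv,
               amplitude_mean = rec$amplitude_mean,
               amplitude_trend_ratio = rec$amplitude_trend_ratio,
               stringsAsFactors = FALSE)
  })
  vars <- do.call(rbind, rows)
  sus <- vars$label == "sustained"
  overall <- if (s$overall_rule == "any") {
    if (any(sus)) "sustained"
    else if (any(vars$label == "growing")) "growing"
    else if (any(vars$label == "irregular")) "irregular"
    else if (any(vars$label == "damped")) "damped"
    else if (any(vars$label == "inconclusive")) "inconclusive"
    else "steady"
  } else {
    if (all(sus)) "sustained"
    else if (any(vars$label == "growing")) "growing"
    else if (any(vars$label == "irregular")) "irregular"
    else if (any(vars$label == "damped")) "damped"
    else if (any(vars$label == "inconclusive")) "inconclusive"
    else "steady"
  }
  structure(list(variables = vars, overall_label = overall,
                 period = if (any(sus)) mean(vars$period_mean[sus])
                          else NA_real_,
                 settings = s),
            class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat("oscillation report: overall =", x$overall_label)
  if (!is.na(x$period)) cat(" (period ", signif(x$period, 6), ")", sep = "")
  cat("\n")
  print(x$variables, row.names = FALSE)
  invisible(x)
}

#' Write an oscillation report as JSON or TSV
#'
#' @param report an `oscillation_report`.
#' @param path output file; format chosen by extension (`.json` or `.tsv`).
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(overall_label = report$overall_label, period = report$period,
           variables = report$variables),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    utils::write.table(report$variables, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# -- phase portraits ---------------------------------------------------------

#' Post-transient phase portrait of two variables
#'
#' Returns the post-transient `(x, y)` samples suitable for plotting,
#' together with a closed-loop diagnostic: the distance from the first
#' post-transient point to its nearest later return (computed after the
#' orbit has travelled at least half its diameter away), relative to the
#' orbit diameter. A closed orbit has a return distance much smaller than
#' its diameter.
#'
#' @param trajectory a [trajectory].
#' @param var_x,var_y state-variable names.
#' @param transient_frac fraction of the window discarded first.
#' @return data.frame with columns `x`, `y` and attributes
#'   `return_distance`, `orbit_diameter`.
#' @export
phase_portrait <- function(trajectory, var_x, var_y, transient_frac = 0.5) {
  vn <- trajectory$variable_names
  for (v in c(var_x, var_y)) {
    if (!v %in% vn)
      stop("unknown variable '", v, "'; trajectory has: ",
           paste(vn, collapse = ", "), call. = FALSE)
  }
  t_all <- trajectory$times
  cut <- min(t_all) + transient_frac * (max(t_all) - min(t_all))
  keep <- which(t_all >= cut)
  x <- trajectory$states[keep, var_x]
  y <- trajectory$states[keep, var_y]
  diam <- sqrt((max(x) - min(x))^2 + (max(y) - min(y))^2)
  ret <- NA_real_
  if (length(x) > 2L && diam > 0) {
    d <- sqrt((x - x[1])^2 + (y - y[1])^2)
    arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    far <- which(arc > diam / 2)
    if (length(far) > 0L) ret <- min(d[far])
  } else if (diam == 0) {
    ret <- 0
  }
  out <- data.frame(x = x, y = y)
  names(out) <- c("x", "y")
  attr(out, "return_distance") <- ret
  attr(out, "orbit_diameter") <- diam
  out
}

# -- parameter scans ---------------------------------------------------------

#' Scan the Hill-exponent / half-saturation plane for oscillatory regimes
#'
#' Re-simulates and classifies the model at every grid point `(h, K)` —
#' the cooperativity and saturation of the inhibition term. Works for any
#' [ode_system()] whose parameters include `h` (and `K` when a K grid is
#' given), i.e. generated contour models and `goodwin3`. Integration or
#' classification failures in a cell are recorded in its label, not fatal.
#'
#' @param system an [ode_system()].
#' @param h_values numeric vector of Hill exponents (all >= 1).
#' @param K_values numeric vector of half-saturations (all > 0); use the
#'   model's current K with `K_values = NULL`.
#' @param t_end,n_points simulation window per cell.
#' @param settings classification settings, see [detection_settings()].
#' @return data.frame with one row per cell: `h`, `K`, `overall_label`,
#'   `period`, `sustained` (the machine-readable oscillatory-region mask).
#' @export
scan_parameters <- function(system, h_values, K_values = NULL,
                            t_end = NULL, n_points = 2000L,
                            settings = detection_settings()) {
  if (length(h_values) == 0L) stop("empty h grid", call. = FALSE)
  if (any(h_values < 1)) stop("hill exponents must be >= 1", call. = FALSE)
  if (!is.null(K_values) && any(K_values <= 0))
    stop("half-saturations must be > 0", call. = FALSE)
  if (!"h" %in% names(system$parameters))
    stop("model '", system$name, "' has no Hill exponent parameter 'h'",
         call. = FALSE)
  Ks <- if (is.null(K_values)) system$parameters[["K"]] else K_values
  grid <- expand.grid(h = h_values, K = Ks, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- tryCatch({
      sys_i <- set_parameters(system, c(h = grid$h[i], K = grid$K[i]))
      tr <- integrate_model(sys_i, t_end = t_end, n_points = n_points)
      rep_i <- detect_oscillation(tr, settings)
      list(label = rep_i$overall_label, period = rep_i$period)
    }, error = function(e) list(label = paste0("error: ",
                                               conditionMessage(e)),
                                period = NA_real_))
    data.frame(h = grid$h[i], K = grid$K[i], overall_label = res$label,
               period = res$period, sustained = res$label == "sustained",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
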