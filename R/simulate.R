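#' Integrate a CRISPRi reaction system over time
#'
#' Solves the system's ODEs on a regular output grid with a stiff-capable
#' adaptive integrator (the identical-site occupancy chain can be fast
#' relative to dilution). Integration is deterministic.
#'
#' @param system A `crispri_system` from [build_model()].
#' @param horizon Simulation end time in hours (default 200).
#' @param output_step Output grid spacing in hours (default 1).
#' @param times Optional explicit output times (strictly increasing, starting
#'   at 0); overrides `horizon`/`output_step`.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param method deSolve integration method; `"lsoda"` switches automatically
#'   between stiff and non-stiff solvers.
#' @return An object of class `crispri_trajectory`: list with `times` (hours),
#'   `states` (time-by-species matrix, columns named as in `system$species`),
#'   and the originating `architecture` and `params`.
#' @examples
#' traj <- simulate_system(build_model(architecture(0, "none"),
#'                                     crispri_params()), horizon = 48)
#' head(gfp(traj))
#' @export
simulate_system <- function(system, horizon = 200, output_step = 1,
                            times = NULL, rtol = 1e-8, atol = 1e-10,
                            method = "lsoda") {
  stopifnot(inherits(system, "crispri_system"))
  if (is.null(times)) {
    if (!is.numeric(horizon) || horizon <= 0)
      stop("horizon must be > 0", call. = FALSE)
    times <- seq(0, horizon, by = output_step)
    if (times[length(times)] < horizon) times <- c(times, horizon)
  } else {
    if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
      stop("times must be strictly increasing and start at 0", call. = FALSE)
  }

  out <- deSolve::ode(
    y = system$y0, times = times,
    func = function(t, y, p) list(system$deriv(t, y, p)),
    parms = system$params, method = method, rtol = rtol, atol = atol)

  istate <- attr(out, "istate")[1L]
  if (!is.null(istate) && istate < 0 || nrow(out) < length(times))
    stop(sprintf(
      "integrator failed for %s at t ~ %.3g h (istate = %d); last state: %s",
      architecture_label(system$architecture), out[nrow(out), 1L], istate,
      paste(sprintf("%s=%.3g", colnames(out)[-1L], out[nrow(out), -1L]),
            collapse = ", ")), call. = FALSE)

  states <- out[, -1L, drop = FALSE]
  # tolerance-level negative undershoot is clipped; anything larger is real
  neg <- states < 0
  if (any(states[neg] < -1e-9)) {
    w <- which(states < -1e-9, arr.ind = TRUE)[1L, ]
    warning(sprintf("negative concentration %s = %.3g at t = %g h",
                    colnames(states)[w[2L]], states[w[1L], w[2L]],
                    times[w[1L]]), call. = FALSE)
  }
  states[neg] <- 0

  structure(
    list(times = times, states = states,
         architecture = system$architecture, params = system$params),
    class = "crispri_trajectory")
}

#' Extract one species' time series from a trajectory
#'
#' @param trajectory A `crispri_trajectory`.
#' @param species Species name (default `"G"`, the GFP reporter).
#' @return Numeric vector aligned with `trajectory$times`.
#' @export
species_series <- function(trajectory, species = "G") {
  stopifnot(inherits(trajectory, "crispri_trajectory"))
  if (!species %in% colnames(trajectory$states))
    stop("no species '", species, "' in this trajectory", call. = FALSE)
  trajectory$states[, species]
}

#' @rdname species_series
#' @export
gfp <- function(trajectory) species_series(trajectory, "G")

#' Long-format data frame of a trajectory
#'
#' @param x A `crispri_trajectory`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return Data frame with columns `time_h`, `species`, `value`, `mode`,
#'   `n_sites` — the CSV-ready long format.
#' @export
as.data.frame.crispri_trajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  sp <- colnames(x$states)
  data.frame(
    time_h  = rep(x$times, times = length(sp)),
    species = rep(sp, each = length(x$times)),
    value   = as.vector(x$states),
    mode    = x$architecture$mode,
    n_sites = x$architecture$n_sites,
    stringsAsFactors = FALSE)
}

#' @export
print.crispri_trajectory <- function(x, ...) {
  cat("CRISPRi trajectory:", architecture_label(x$architecture),
      sprintf("| %d species x %d time points over [0, %g] h\n",
              ncol(x$states), length(x$times), max(x$times)))
  cat(sprintf("  GFP: peak %.4g at t = %g h, final %.4g\n",
              max(gfp(x)), x$times[which.max(gfp(x))],
              gfp(x)[length(x$times)]))
  invisible(x)
}

#' Closed-form GFP for the base-expression system
#'
#' The unregulated reporter obeys `dG/dt = alpha_G*V2 - lambda*G` with
#' `V2 = D2*exp(-lambda*t)` and `G(0) = 0`, which integrates to
#' `G(t) = alpha_G * D2 * t * exp(-lambda*t)`. Used as an analytic oracle for
#' the numeric integrator and as the fast forward model inside fitting.
#'
#' @param params A [crispri_params()] set.
#' @param times Numeric vector of times (hours).
#' @return GFP (MEFL-equivalent molecules) at `times`.
#' @export
base_gfp_closed_form <- function(params, times) {
  params$alpha_G * params$D2 * times * exp(-params$lambda_dilution * times)
}
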