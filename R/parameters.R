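# Kinetic parameters for the CRISPRi transient-expression model.
#
# Units: molecules per cell for all state variables (reporter molecules are
# identified 1:1 with calibrated MEFL); hours for time; rate constants per
# hour, bimolecular constants per molecule per hour.

#' @keywords internal
.param_names <- c(
  "lambda_dilution", "delta_g", "alpha_r", "alpha_C", "alpha_G",
  "k_Cg", "k_on", "k_off", "k_scan", "rho", "D1", "D2"
)

#' Names of the rate-dimensioned parameters
#'
#' The nine rate constants of the model, i.e. every [crispri_params()] field
#' that carries units of "per hour" (or per molecule per hour). These are the
#' parameters perturbed by [scan_parameter()] and randomised by
#' [cell_variation()]; the unitless attenuation factor `rho` and the vector
#' dosages `D1`/`D2` are excluded.
#'
#' @return Character vector of parameter names.
#' @export
rate_parameters <- function() {
  c("lambda_dilution", "delta_g", "alpha_r", "alpha_C", "alpha_G",
    "k_Cg", "k_on", "k_off", "k_scan")
}

.default_params <- list(
  lambda_dilution = 0.02,  # dilution of stable species by cell division, /h
  delta_g         = 0.7,   # free-gRNA degradation, /h (fast vs dilution)
  alpha_r         = 5,     # gRNA transcription per gRNA-vector copy, /h
  alpha_C         = 5,     # dCas9 production per dCas9/GFP-vector copy, /h
  alpha_G         = 1000,  # GFP production per vector copy, MEFL-molecules/h
  k_Cg            = 0.01,  # dCas9 + gRNA complex formation, /molecule/h
  k_on            = 0.03,  # complex-DNA site association, /molecule/h
  k_off           = 0.05,  # site dissociation, /h
  k_scan          = 10,    # lateral transfer to an empty identical site, /h
  rho             = 0.1,   # per-occupied-site transcription attenuation
  D1              = 10,    # initial gRNA-vector copies, V1(0)
  D2              = 3      # initial dCas9/GFP-vector copies, V2(0)
)

#' Construct a CRISPRi model parameter set
#'
#' Returns the full kinetic parameter set for the two-vector transient CRISPRi
#' system, starting from package defaults and overriding any field passed by
#' name. All state variables are in molecules per cell and time is in hours.
#'
#' @details The fields are:
#' \describe{
#'   \item{lambda_dilution}{Dilution rate \eqn{\lambda} (/h) applied to every
#'     stable species: both vectors, dCas9, the dCas9-gRNA complex, and GFP.
#'     Transient expression peaks at \eqn{t = 1/\lambda} and declines as the
#'     vectors dilute through cell division.}
#'   \item{delta_g}{Free-gRNA degradation rate \eqn{\delta_g} (/h); must be at
#'     least `lambda_dilution` (gRNAs turn over faster than stable species).}
#'   \item{alpha_r}{gRNA transcription rate per gRNA-vector copy (/h).}
#'   \item{alpha_C, alpha_G}{Combined transcription-and-translation production
#'     rates per dCas9/GFP-vector copy for dCas9 and GFP respectively; the two
#'     instances of the protein production rate \eqn{\alpha_p}, separable so
#'     that each promoter's strength can be varied independently.}
#'   \item{k_Cg}{Bimolecular dCas9 + gRNA complex-formation constant
#'     \eqn{k_{C_g}} (/molecule/h).}
#'   \item{k_on, k_off}{Solution-phase association (/molecule/h) and
#'     dissociation (/h) of the dCas9-gRNA complex with a promoter target
#'     site.}
#'   \item{k_scan}{Lateral-transfer (scanning) rate (/h) from an occupied site
#'     to an empty *identical* neighbouring site; only meaningful for the
#'     identical-site architecture with at least two sites.}
#'   \item{rho}{Per-occupied-site transcription attenuation factor in (0, 1]:
#'     each occupied site multiplies the reporter production rate by `rho`.}
#'   \item{D1, D2}{Initial copy numbers of the gRNA vector (V1) and the
#'     dCas9/GFP vector (V2).}
#' }
#'
#' @param ... Named parameter overrides (any subset of the fields above).
#' @param base Parameter set to start from; defaults to the package defaults.
#' @return A named list of class `crispri_params`.
#' @examples
#' p <- crispri_params(k_scan = 0, rho = 0.4)
#' p$rho
#' @export
crispri_params <- function(..., base = NULL) {
  p <- if (is.null(base)) .default_params else unclass(base)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    bad <- setdiff(names(dots), .param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  p <- p[.param_names]
  class(p) <- "crispri_params"
  validate_params(p)
  p
}

#' Validate a CRISPRi parameter set
#'
#' Checks the parameter invariants: all rates non-negative, `0 < rho <= 1`,
#' `D1 >= 0`, `D2 > 0`, and `delta_g >= lambda_dilution`.
#'
#' @param params A `crispri_params` object or named list with the same fields.
#' @param check_delta_g Enforce `delta_g >= lambda_dilution`? One-at-a-time
#'   perturbation scans relax this single cross-parameter constraint.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_params <- function(params, check_delta_g = TRUE) {
  missing <- setdiff(.param_names, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  for (nm in .param_names) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c(rate_parameters(), "D1"))
    if (params[[nm]] < 0)
      stop("invariant violated: ", nm, " >= 0", call. = FALSE)
  if (params$rho <= 0 || params$rho > 1)
    stop("invariant violated: 0 < rho <= 1", call. = FALSE)
  if (params$D2 <= 0)
    stop("invariant violated: D2 > 0", call. = FALSE)
  if (check_delta_g && params$delta_g < params$lambda_dilution)
    stop("invariant violated: delta_g >= lambda_dilution (gRNA degrades ",
         "faster than stable species dilute)", call. = FALSE)
  invisible(params)
}

#' Read a parameter configuration file
#'
#' Reads a flat key-value YAML or JSON file (by extension) whose keys are
#' [crispri_params()] field names; unspecified fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `crispri_params` object.
#' @seealso [write_params()]
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension '.", ext, "' (use yaml or json)",
         call. = FALSE)
  )
  if (!is.list(vals)) vals <- as.list(vals)
  do.call(crispri_params, vals)
}

#' Write a parameter configuration file
#'
#' @param params A `crispri_params` object.
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @seealso [read_params()]
#' @export
write_params <- function(params, path) {
  validate_params(params, check_delta_g = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(params)
  switch(ext,
    yaml = ,
    yml  = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config extension '.", ext, "' (use yaml or json)",
         call. = FALSE)
  )
  invisible(path)
}

#' @export
print.crispri_params <- function(x, ...) {
  cat("CRISPRi model parameters (molecules/cell, hours):\n")
  for (nm in .param_names)
    cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}
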