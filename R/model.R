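# Combinatorial generation of the CRISPRi reaction systems.
#
# Kinetic scheme (molecules/cell, hours):
#   dV1/dt = -lambda*V1                 dV2/dt = -lambda*V2
# mode = none (base expression, "on" state): dCas9 retained but inert,
#   dC/dt = alpha_C*V2 - lambda*C,  dG/dt = alpha_G*V2 - lambda*G.
# mode = heterogeneous, sites i = 1..n, one gRNA species per site:
#   dg_i/dt  = alpha_r*V1 - delta_g*g_i - k_Cg*C*g_i
#   dC/dt    = alpha_C*V2 - lambda*C - sum_i k_Cg*C*g_i
#   dCg_i/dt = k_Cg*C*g_i - lambda*Cg_i
#   dtheta_i/dt = k_on*Cg_i*(1 - theta_i) - k_off*theta_i
#   reporter factor R = prod_i (1 - (1-rho)*theta_i)
# mode = identical, n sites, one shared gRNA species, occupancy chain over
# the number k of occupied sites (P_k fractions, k = 0..n):
#   up-rate  u_k = k_on*Cg*(n-k) + [k>=1]*k_scan*(n-k)
#   down-rate d_k = k_off*k
#   reporter factor R = sum_k P_k * rho^k
# Reporter: dG/dt = alpha_G*V2*R - lambda*G.
#
# Site occupancy does not consume free complex: promoter copies (<= D2 = 3)
# are negligible against complex counts, so occupancy is a fraction driven by
# the free-complex concentration.

#' Build the ODE reaction system for a CRISPRi architecture
#'
#' Combinatorially generates the species list, initial state and derivative
#' function for any promoter architecture: the unregulated base-expression
#' system, `n` heterogeneous gRNA target sites, or `n` identical sites with
#' lateral scanning. The full kinetic scheme is laid out in the package
#' vignette; [export_equations()] prints it for any built system.
#'
#' Species and roles by mode (in state-vector order):
#' * `none`: `V1`, `V2` (vectors), `C` (free dCas9, inert), `G` (reporter) —
#'   4 species.
#' * `heterogeneous`, n sites: `V1`, `V2`, `g1..gn` (free gRNAs), `C`,
#'   `Cg1..Cgn` (complexes), `theta1..thetan` (per-site occupancy fractions),
#'   `G` — `4 + 3n` species.
#' * `identical`, n sites: `V1`, `V2`, `g`, `C`, `Cg`, `P0..Pn` (occupancy-
#'   chain fractions, summing to 1), `G` — `n + 7` species.
#'
#' All non-vector species start at zero (occupancy chain at `P0 = 1`);
#' `V1(0) = D1`, `V2(0) = D2`.
#'
#' @param arch A [architecture()] object.
#' @param params A [crispri_params()] parameter set.
#' @return An object of class `crispri_system`: a list with `architecture`,
#'   `params`, `species` (data frame of `name`, `role`), `y0` (named initial
#'   state), and `deriv`, a `function(t, y, params)` returning the state
#'   time-derivatives (deSolve-compatible).
#' @examples
#' sys <- build_model(architecture(2, "identical"), crispri_params())
#' sys$species
#' @export
build_model <- function(arch, params) {
  if (!inherits(arch, "crispri_architecture"))
    stop("arch must be a crispri_architecture (see architecture())",
         call. = FALSE)
  if (!inherits(params, "crispri_params"))
    params <- do.call(crispri_params, as.list(params))
  validate_params(params)

  n <- arch$n_sites
  species <- switch(arch$mode,
    none = data.frame(
      name = c("V1", "V2", "C", "G"),
      role = c("vector", "vector", "free dCas9", "reporter"),
      stringsAsFactors = FALSE),
    heterogeneous = data.frame(
      name = c("V1", "V2", paste0("g", seq_len(n)), "C",
               paste0("Cg", seq_len(n)), paste0("theta", seq_len(n)), "G"),
      role = c("vector", "vector", rep("free gRNA", n), "free dCas9",
               rep("complex", n), rep("site occupancy", n), "reporter"),
      stringsAsFactors = FALSE),
    identical = data.frame(
      name = c("V1", "V2", "g", "C", "Cg", paste0("P", 0:n), "G"),
      role = c("vector", "vector", "free gRNA", "free dCas9", "complex",
               rep("occupancy-chain state", n + 1L), "reporter"),
      stringsAsFactors = FALSE)
  )

  y0 <- stats::setNames(numeric(nrow(species)), species$name)
  y0["V1"] <- params$D1
  y0["V2"] <- params$D2
  if (arch$mode == "identical") y0["P0"] <- 1

  deriv <- switch(arch$mode,
    none          = .deriv_none(),
    heterogeneous = .deriv_heterogeneous(n),
    identical     = .deriv_identical(n)
  )

  structure(
    list(architecture = arch, params = params, species = species,
         y0 = y0, deriv = deriv),
    class = "crispri_system")
}

# Index layout is fixed by the species order above; the closures capture only
# n and index vectors so the derivative is cheap inside the integrator.

.deriv_none <- function() {
  function(t, y, p) {
    lam <- p$lambda_dilution
    c(-lam * y[1L],                       # V1
      -lam * y[2L],                       # V2
      p$alpha_C * y[2L] - lam * y[3L],    # C (inert)
      p$alpha_G * y[2L] - lam * y[4L])    # G, R = 1
  }
}

.deriv_heterogeneous <- function(n) {
  ig  <- 2L + seq_len(n)
  iC  <- 3L + n
  iCg <- 3L + n + seq_len(n)
  ith <- 3L + 2L * n + seq_len(n)
  iG  <- 4L + 3L * n
  function(t, y, p) {
    lam <- p$lambda_dilution
    V1 <- y[1L]; V2 <- y[2L]
    g <- y[ig]; C <- y[iC]; Cg <- y[iCg]; th <- y[ith]
    bind <- p$k_Cg * C * g
    R <- prod(1 - (1 - p$rho) * th)
    d <- numeric(iG)
    d[1L]  <- -lam * V1
    d[2L]  <- -lam * V2
    d[ig]  <- p$alpha_r * V1 - p$delta_g * g - bind
    d[iC]  <- p$alpha_C * V2 - lam * C - sum(bind)
    d[iCg] <- bind - lam * Cg
    d[ith] <- p$k_on * Cg * (1 - th) - p$k_off * th
    d[iG]  <- p$alpha_G * V2 * R - lam * y[iG]
    d
  }
}

.deriv_identical <- function(n) {
  iP <- 5L + seq_len(n + 1L)   # P0..Pn
  iG <- 7L + n
  k  <- 0:n
  n_minus_k <- n - k
  scan_gate <- as.numeric(k >= 1L)   # scanning needs an anchored complex
  function(t, y, p) {
    lam <- p$lambda_dilution
    V1 <- y[1L]; V2 <- y[2L]
    g <- y[3L]; C <- y[4L]; Cg <- y[5L]; P <- y[iP]
    bind <- p$k_Cg * C * g
    # chain fluxes: up[j] moves P_{j-1} -> P_j, down[j] moves P_j -> P_{j-1}
    up_rate <- (p$k_on * Cg + scan_gate * p$k_scan) * n_minus_k  # from state k
    up   <- up_rate[seq_len(n)] * P[seq_len(n)]                  # k = 0..n-1
    down <- p$k_off * k[-1L] * P[-1L]                            # k = 1..n
    dP <- c(0, up) - c(up, 0) + c(down, 0) - c(0, down)
    R <- sum(P * p$rho^k)
    d <- numeric(iG)
    d[1L] <- -lam * V1
    d[2L] <- -lam * V2
    d[3L] <- p$alpha_r * V1 - p$delta_g * g - bind
    d[4L] <- p$alpha_C * V2 - lam * C - bind
    d[5L] <- bind - lam * Cg
    d[iP] <- dP
    d[iG] <- p$alpha_G * V2 * R - lam * y[iG]
    d
  }
}

#' Reporter production factor for a state
#'
#' Evaluates the promoter attenuation factor `R` in `[0, 1]` — the fraction
#' of full reporter production — for one state vector of a built system:
#' `prod(1 - (1-rho)*theta_i)` for heterogeneous sites, `sum(P_k * rho^k)`
#' for the identical-site occupancy chain, 1 for the base system.
#'
#' @param system A `crispri_system`.
#' @param state Named state vector (a row of a trajectory, or `system$y0`).
#' @return A single number in `[0, 1]`.
#' @export
reporter_factor <- function(system, state) {
  stopifnot(inherits(system, "crispri_system"))
  p <- system$params
  n <- system$architecture$n_sites
  switch(system$architecture$mode,
    none = 1,
    heterogeneous = prod(1 - (1 - p$rho) * state[paste0("theta", seq_len(n))]),
    identical = sum(state[paste0("P", 0:n)] * p$rho^(0:n))
  )
}

#' Export a reaction system as plain-text equations
#'
#' One line per state variable, in state-vector order; the output is
#' deterministic (the same system always exports byte-identical text).
#'
#' @param system A `crispri_system` from [build_model()].
#' @return A single UTF-8 string of newline-separated ODE lines.
#' @examples
#' cat(export_equations(build_model(architecture(2, "identical"),
#'                                  crispri_params())))
#' @export
export_equations <- function(system) {
  stopifnot(inherits(system, "crispri_system"))
  n <- system$architecture$n_sites
  mode <- system$architecture$mode
  lines <- c("dV1/dt = -lambda*V1", "dV2/dt = -lambda*V2")
  if (mode == "none") {
    lines <- c(lines,
      "dC/dt = alpha_C*V2 - lambda*C",
      "dG/dt = alpha_G*V2 - lambda*G")
  } else if (mode == "heterogeneous") {
    for (i in seq_len(n))
      lines <- c(lines, sprintf(
        "dg%d/dt = alpha_r*V1 - delta_g*g%d - k_Cg*C*g%d", i, i, i))
    lines <- c(lines, sprintf(
      "dC/dt = alpha_C*V2 - lambda*C - k_Cg*C*(%s)",
      paste0("g", seq_len(n), collapse = " + ")))
    for (i in seq_len(n))
      lines <- c(lines, sprintf(
        "dCg%d/dt = k_Cg*C*g%d - lambda*Cg%d", i, i, i))
    for (i in seq_len(n))
      lines <- c(lines, sprintf(
        "dtheta%d/dt = k_on*Cg%d*(1 - theta%d) - k_off*theta%d", i, i, i, i))
    lines <- c(lines, sprintf(
      "dG/dt = alpha_G*V2*%s - lambda*G",
      paste0("(1 - (1 - rho)*theta", seq_len(n), ")", collapse = "*")))
  } else {
    lines <- c(lines,
      "dg/dt = alpha_r*V1 - delta_g*g - k_Cg*C*g",
      "dC/dt = alpha_C*V2 - lambda*C - k_Cg*C*g",
      "dCg/dt = k_Cg*C*g - lambda*Cg")
    up <- function(k)  # transition propensity out of chain state k, upward
      if (k == 0) sprintf("%d*k_on*Cg", n - k)
      else sprintf("%d*(k_on*Cg + k_scan)", n - k)
    for (k in 0:n) {
      terms <- character(0)
      if (k >= 1) terms <- c(terms, sprintf("%s*P%d", up(k - 1L), k - 1L))
      if (k <= n - 1) terms <- c(terms, sprintf("%d*k_off*P%d", k + 1L, k + 1L))
      loss <- character(0)
      if (k <= n - 1) loss <- c(loss, sprintf("%s*P%d", up(k), k))
      if (k >= 1) loss <- c(loss, sprintf("%d*k_off*P%d", k, k))
      rhs <- paste(c(terms, paste0("- ", loss)), collapse = " ")
      lines <- c(lines, sprintf("dP%d/dt = %s", k, rhs))
    }
    lines <- c(lines, sprintf(
      "dG/dt = alpha_G*V2*(%s) - lambda*G",
      paste(sprintf("P%d*rho^%d", 0:n, 0:n), collapse = " + ")))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.crispri_system <- function(x, ...) {
  cat("CRISPRi reaction system:", architecture_label(x$architecture), "\n")
  cat(sprintf("  %d species: %s\n", nrow(x$species),
              paste(x$species$name, collapse = ", ")))
  invisible(x)
}
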