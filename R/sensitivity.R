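# Robustness analyses: one-at-a-time parameter perturbation, vector-dosage
# scans, and Monte-Carlo cell-to-cell variability. Each reports, per
# condition, the mean fold repression of every regulated architecture and
# whether the identical-site strategy dominates the heterogeneous one at
# every matched site count.

.dominance_flag <- function(tab) {
  # identical > heterogeneous at every matched n >= 2
  ns <- intersect(tab$n_sites[tab$mode == "identical"],
                  tab$n_sites[tab$mode == "heterogeneous"])
  ns <- ns[ns >= 2]
  if (!length(ns)) return(NA)
  all(vapply(ns, function(n) {
    tab$fold_repression[tab$mode == "identical" & tab$n_sites == n] >
      tab$fold_repression[tab$mode == "heterogeneous" & tab$n_sites == n]
  }, logical(1)))
}

#' One-at-a-time parameter perturbation scan
#'
#' Rescales a single rate parameter by each factor in a grid, rebuilds and
#' resimulates every architecture, and records mean fold repression plus a
#' dominance flag (identical strictly above heterogeneous at every matched
#' site count). The half-decade default grid spans two decades around the
#' base value. The `delta_g >= lambda_dilution` cross-parameter invariant is
#' relaxed during the scan (a one-at-a-time probe, not a claimed regime).
#'
#' @param params Base [crispri_params()] set.
#' @param name Parameter to perturb (one of [rate_parameters()], or `"rho"` /
#'   a dosage if you know what you are doing — `rho` factors must keep
#'   `rho <= 1`).
#' @param factors Positive multiplicative factors; should contain 1.
#' @param n_max,horizon,output_step,window As in [repression_table()].
#' @return Data frame of class `crispri_scan`: one row per
#'   (factor, architecture) with columns `parameter`, `factor`, `value`,
#'   `label`, `mode`, `n_sites`, `fold_repression`, `dominant` (flag,
#'   constant within a factor), `error` (NA or the integrator message for
#'   that cell).
#' @export
scan_parameter <- function(params, name,
                           factors = c(0.1, 0.3, 1, 3, 10),
                           n_max = 6, horizon = 200, output_step = 1,
                           window = c(72, 96)) {
  if (!inherits(params, "crispri_params"))
    params <- do.call(crispri_params, as.list(params))
  if (!name %in% .param_names)
    stop("unknown parameter: ", name, call. = FALSE)
  if (any(factors <= 0)) stop("factors must be > 0", call. = FALSE)
  rows <- list()
  for (f in factors) {
    p <- unclass(params)
    p[[name]] <- p[[name]] * f
    class(p) <- "crispri_params"
    validate_params(p, check_delta_g = FALSE)
    tab <- tryCatch(
      repression_table(p, n_max = n_max, horizon = horizon,
                       output_step = output_step, window = window),
      error = function(e) e)
    if (inherits(tab, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = name, factor = f, value = p[[name]],
        label = NA_character_, mode = NA_character_, n_sites = NA_integer_,
        fold_repression = NA_real_, dominant = NA,
        error = conditionMessage(tab), stringsAsFactors = FALSE)
    } else {
      df <- as.data.frame(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = name, factor = f, value = p[[name]],
        df[, c("label", "mode", "n_sites", "fold_repression")],
        dominant = .dominance_flag(df), error = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("crispri_scan", "data.frame")
  out
}

#' Vector-dosage tunability scan
#'
#' Fold repression across a grid of initial vector copy numbers: `D1` (gRNA
#' vector) by `D2` (dCas9/GFP vector). Dosage is the experimentally
#' accessible tuning knob of the two-vector design — co-delivered construct
#' stoichiometry is set at transformation time.
#'
#' @param params Base [crispri_params()] set.
#' @param d1_values,d2_values Non-negative copy-number grids (`D2` must stay
#'   positive).
#' @param n_max,horizon,output_step,window As in [repression_table()].
#' @return Data frame of class `crispri_scan`: one row per
#'   (D1, D2, architecture) with fold repression, dominance flag and error
#'   column as in [scan_parameter()].
#' @export
scan_dosage <- function(params, d1_values = c(0, 1, 3, 10, 30),
                        d2_values = c(1, 3, 10),
                        n_max = 6, horizon = 200, output_step = 1,
                        window = c(72, 96)) {
  if (!inherits(params, "crispri_params"))
    params <- do.call(crispri_params, as.list(params))
  if (any(d1_values < 0) || any(d2_values <= 0))
    stop("dosages must satisfy D1 >= 0, D2 > 0", call. = FALSE)
  rows <- list()
  for (d2 in d2_values) for (d1 in d1_values) {
    p <- crispri_params(D1 = d1, D2 = d2, base = params)
    tab <- tryCatch(
      repression_table(p, n_max = n_max, horizon = horizon,
                       output_step = output_step, window = window),
      error = function(e) e)
    if (inherits(tab, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        D1 = d1, D2 = d2, label = NA_character_, mode = NA_character_,
        n_sites = NA_integer_, fold_repression = NA_real_, dominant = NA,
        error = conditionMessage(tab), stringsAsFactors = FALSE)
    } else {
      df <- as.data.frame(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        D1 = d1, D2 = d2,
        df[, c("label", "mode", "n_sites", "fold_repression")],
        dominant = .dominance_flag(df), error = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("crispri_scan", "data.frame")
  out
}

#' Monte-Carlo cell-to-cell variability
#'
#' Simulates a population of cells whose rate parameters vary independently
#' around the base values with multiplicative lognormal noise — the standard
#' extrinsic-noise model: per cell, each rate in [rate_parameters()] is drawn
#' as `base * exp(N(0, sigma^2))`. Dosages and `rho` are held fixed. Fold
#' repression is computed per cell (each cell's own base-expression system is
#' the reference) for every architecture.
#'
#' Draws are made once per cell before any simulation, so the per-cell
#' parameter sets do not depend on the architecture list or its order.
#'
#' @param params Base [crispri_params()] set.
#' @param sigma Standard deviation of the log-parameter perturbations
#'   (`sigma = 0.5` is about a 53% coefficient of variation).
#' @param n_cells Number of simulated cells.
#' @param seed Integer seed; results are reproducible given it.
#' @param n_max,horizon,output_step,window As in [repression_table()].
#' @param probs Summary quantile levels.
#' @return List of class `crispri_variation`: `cells` (long data frame
#'   `cell`, `label`, `mode`, `n_sites`, `fold_repression`), `quantiles`
#'   (per architecture), `n_failed` (cells skipped on integrator failure),
#'   `sigma`, `n_cells`, `seed`.
#' @export
cell_variation <- function(params, sigma = 0.5, n_cells = 200, seed = 1L,
                           n_max = 6, horizon = 200, output_step = 1,
                           window = c(72, 96),
                           probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (!inherits(params, "crispri_params"))
    params <- do.call(crispri_params, as.list(params))
  stopifnot(sigma >= 0, n_cells >= 1)
  rates <- rate_parameters()

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(n_cells * length(rates), sd = sigma),
                  nrow = n_cells, dimnames = list(NULL, rates))

  cells <- list()
  n_failed <- 0L
  for (cell in seq_len(n_cells)) {
    p <- unclass(params)
    p[rates] <- unlist(p[rates]) * exp(draws[cell, ])
    class(p) <- "crispri_params"
    tab <- tryCatch(
      repression_table(p, n_max = n_max, horizon = horizon,
                       output_step = output_step, window = window),
      error = function(e) e)
    if (inherits(tab, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    df <- as.data.frame(tab)[, c("label", "mode", "n_sites",
                                 "fold_repression")]
    df$cell <- cell
    cells[[length(cells) + 1L]] <- df
  }
  if (!length(cells))
    stop("every cell failed to simulate", call. = FALSE)
  cells <- do.call(rbind, cells)
  qs <- do.call(rbind, lapply(split(cells, cells$label), function(d) {
    q <- stats::quantile(d$fold_repression, probs = probs, names = FALSE)
    data.frame(label = d$label[1L], mode = d$mode[1L],
               n_sites = d$n_sites[1L],
               t(stats::setNames(q, paste0("q", probs * 100))),
               stringsAsFactors = FALSE)
  }))
  qs <- qs[order(qs$mode, qs$n_sites), ]
  rownames(qs) <- NULL
  structure(
    list(cells = cells[, c("cell", "label", "mode", "n_sites",
                           "fold_repression")],
         quantiles = qs, n_failed = n_failed,
         sigma = sigma, n_cells = n_cells, seed = as.integer(seed)),
    class = "crispri_variation")
}

#' @export
print.crispri_variation <- function(x, ...) {
  cat(sprintf(
    "Cell-to-cell variation: %d cells, sigma = %g, seed = %d (%d failed)\n",
    x$n_cells, x$sigma, x$seed, x$n_failed))
  q <- x$quantiles
  q[-(1:3)] <- lapply(q[-(1:3)], signif, 4)
  print(q, row.names = FALSE)
  invisible(x)
}
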