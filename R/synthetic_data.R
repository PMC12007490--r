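# Synthetic calibrated-fluorescence time courses with the replicate
# structure of a transient agroinfiltration experiment: per time point,
# 3 plants x 3 leaves x 3 readings, in MEFL units.

#' Generate a synthetic MEFL time-course table
#'
#' Simulates the base-expression (no regulation) reporter trajectory and
#' wraps it in a three-level hierarchical lognormal noise model mirroring the
#' replicate structure of a transient-expression fluorometry experiment:
#' plant effects are shared across all that plant's leaves and readings, leaf
#' effects across that leaf's readings. Each reading is
#' `mefl = background + G(t) * exp(e_plant) * exp(e_leaf) * exp(e_read)`
#' with `e ~ N(0, sdlog^2)`, `sdlog = sqrt(log(1 + cv^2))` at each level.
#' Control rows carry background noise only.
#'
#' @param params Generating [crispri_params()] set (forward model).
#' @param n_timepoints Number of sampling times (default 18, evenly spaced
#'   from 0 to `horizon`).
#' @param horizon Last sampling time in hours (default 200).
#' @param plants,leaves,reads Replicate counts per level (defaults 3/3/3, so
#'   27 readings per time point and genotype).
#' @param plant_cv,leaf_cv,read_cv Coefficients of variation of the
#'   multiplicative noise at each hierarchy level.
#' @param background Additive MEFL offset (autofluorescence remaining after
#'   calibration; default 100).
#' @param include_control Also emit wild-type control rows (background only)?
#' @param seed Integer seed; the table is fully reproducible given it.
#' @return Data frame with columns `time_h`, `plant`, `leaf`, `read`,
#'   `genotype` (`"mEmerald"` or `"control"`), `mefl`.
#' @examples
#' tab <- generate_timecourse(crispri_params(), seed = 7)
#' nrow(tab[tab$genotype == "mEmerald", ])  # 18 x 27 = 486
#' @export
generate_timecourse <- function(params,
                                n_timepoints = 18, horizon = 200,
                                plants = 3, leaves = 3, reads = 3,
                                plant_cv = 0.3, leaf_cv = 0.2, read_cv = 0.1,
                                background = 100,
                                include_control = TRUE,
                                seed = 1L) {
  if (!inherits(params, "crispri_params"))
    params <- do.call(crispri_params, as.list(params))
  stopifnot(n_timepoints >= 1, plants >= 1, leaves >= 1, reads >= 1,
            plant_cv >= 0, leaf_cv >= 0, read_cv >= 0, background >= 0)
  timepoints <- seq(0, horizon, length.out = n_timepoints)
  grid <- sort(unique(c(0, timepoints)))
  if (length(grid) < 2L) grid <- c(0, horizon)
  g_model <- gfp(simulate_system(build_model(architecture(0, "none"), params),
                                 times = grid))[match(timepoints, grid)]

  cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  genotypes <- if (include_control) c("mEmerald", "control") else "mEmerald"
  out <- list()
  for (gt in genotypes) {
    # effects drawn per (timepoint, level): fluorometer readings at distinct
    # times are distinct physical measurements, so no longitudinal
    # autocorrelation is modelled
    e_plant <- matrix(stats::rnorm(n_timepoints * plants,
                                   sd = cv_to_sdlog(plant_cv)),
                      n_timepoints, plants)
    e_leaf <- array(stats::rnorm(n_timepoints * plants * leaves,
                                 sd = cv_to_sdlog(leaf_cv)),
                    c(n_timepoints, plants, leaves))
    e_read <- array(stats::rnorm(n_timepoints * plants * leaves * reads,
                                 sd = cv_to_sdlog(read_cv)),
                    c(n_timepoints, plants, leaves, reads))
    idx <- expand.grid(read = seq_len(reads), leaf = seq_len(leaves),
                       plant = seq_len(plants), t = seq_len(n_timepoints))
    noise <- exp(e_plant[cbind(idx$t, idx$plant)] +
                 e_leaf[cbind(idx$t, idx$plant, idx$leaf)] +
                 e_read[cbind(idx$t, idx$plant, idx$leaf, idx$read)])
    signal <- if (gt == "mEmerald") g_model[idx$t] else 0
    out[[gt]] <- data.frame(
      time_h = timepoints[idx$t],
      plant = idx$plant, leaf = idx$leaf, read = idx$read,
      genotype = gt,
      mefl = signal * noise + background * (if (gt == "control") noise else 1),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab[order(tab$time_h, tab$genotype, tab$plant, tab$leaf, tab$read), ,
      drop = FALSE]
}

#' Read / write a MEFL measurement table
#'
#' CSV schema: `time_h, plant, leaf, read, genotype, mefl` (RFC-4180, UTF-8).
#' `genotype` is optional on read.
#'
#' @param data Measurement data frame ([generate_timecourse()] schema).
#' @param path CSV path.
#' @return `read_timecourse` returns the data frame; `write_timecourse`
#'   returns `path` invisibly.
#' @export
write_timecourse <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "mefl")
  if (!all(need %in% names(tab)))
    stop("measurement CSV must have columns time_h and mefl", call. = FALSE)
  if (any(tab$mefl < 0)) stop("mefl values must be >= 0", call. = FALSE)
  tab
}
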