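# Shared fixtures: parameter sets and hand-built trajectories.

# unit-scale parameters: every species stays O(1-10), so absolute error
# tolerances in the 1e-8 range are meaningful
unit_params <- function(...) {
  crispri_params(alpha_G = 1, alpha_C = 0.5, alpha_r = 0.5, D1 = 2, D2 = 1,
                 k_Cg = 0.05, k_on = 0.1, ...)
}

# minimal trajectory object with a prescribed reporter series, for metric
# tests that need exact arithmetic
fake_trajectory <- function(times, g, mode = "none", n_sites = 0) {
  structure(
    list(times = times,
         states = matrix(g, ncol = 1, dimnames = list(NULL, "G")),
         architecture = architecture(n_sites, mode),
         params = crispri_params()),
    class = "crispri_trajectory")
}

fold_by <- function(tab, mode, n) {
  tab$fold_repression[tab$mode == mode & tab$n_sites == n]
}
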