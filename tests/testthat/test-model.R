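test_that("species lists follow the construction rules for every mode", {
  p <- crispri_params()
  base <- build_model(architecture(0, "none"), p)
  expect_identical(base$species$name, c("V1", "V2", "C", "G"))
  for (n in 1:6) {
    het <- build_model(architecture(n, "heterogeneous"), p)
    expect_identical(nrow(het$species), 4L + 3L * n)
    expect_identical(het$species$name[nrow(het$species)], "G")
    ide <- build_model(architecture(n, "identical"), p)
    expect_identical(nrow(ide$species), n + 7L)
    expect_setequal(paste0("P", 0:n),
                    grep("^P", ide$species$name, value = TRUE))
    expect_false(anyDuplicated(het$species$name) > 0)
    expect_false(anyDuplicated(ide$species$name) > 0)
  }
})

test_that("initial state carries dosages, occupancy at P0 = 1, rest zero", {
  p <- crispri_params(D1 = 7, D2 = 2)
  for (arch in list(architecture(0, "none"), architecture(3, "heterogeneous"),
                    architecture(3, "identical"))) {
    sys <- build_model(arch, p)
    expect_identical(unname(sys$y0["V1"]), 7)
    expect_identical(unname(sys$y0["V2"]), 2)
    rest <- setdiff(names(sys$y0), c("V1", "V2", "P0"))
    expect_true(all(sys$y0[rest] == 0))
    if (arch$mode == "identical") {
      expect_identical(unname(sys$y0["P0"]), 1)
      expect_identical(sum(sys$y0[paste0("P", 0:arch$n_sites)]), 1)
    }
    expect_equal(reporter_factor(sys, sys$y0), 1)
  }
  expect_error(build_model(list(n_sites = 2), p), "crispri_architecture")
})

test_that("equation export is deterministic and lists every state variable", {
  p <- crispri_params()
  base_txt <- export_equations(build_model(architecture(0, "none"), p))
  expect_match(base_txt, "dG/dt = alpha_G\\*V2 - lambda\\*G")
  ide2 <- build_model(architecture(2, "identical"), p)
  txt <- export_equations(ide2)
  for (k in 0:2) expect_match(txt, sprintf("dP%d/dt", k))
  expect_identical(txt, export_equations(ide2))  # byte-identical round trip
  het3 <- export_equations(build_model(architecture(3, "heterogeneous"), p))
  for (i in 1:3) expect_match(het3, sprintf("dtheta%d/dt", i))
  # one line per state variable
  expect_length(strsplit(txt, "\n")[[1]], nrow(ide2$species))
  expect_length(strsplit(het3, "\n")[[1]], 4L + 3L * 3L)
})

test_that("aggregated occupancy chain matches a site-level master equation", {
  # independent oracle for identical n = 2, no scanning: enumerate the four
  # site-level occupancy states {00, 10, 01, 11} with per-site association
  # k_on*Cg(t) and dissociation k_off, sharing the upstream gRNA/complex
  # kinetics; the chain aggregates these by occupied-site count
  p <- crispri_params(k_scan = 0)
  i2 <- simulate_system(build_model(architecture(2, "identical"), p))
  oracle_rhs <- function(t, y, q) {
    V1 <- y[1]; V2 <- y[2]; g <- y[3]; C <- y[4]; Cg <- y[5]
    s <- y[6:9]  # s00, s10, s01, s11
    a <- q$k_on * Cg; b <- q$k_off
    bind <- q$k_Cg * C * g
    list(c(-q$lambda_dilution * V1,
           -q$lambda_dilution * V2,
           q$alpha_r * V1 - q$delta_g * g - bind,
           q$alpha_C * V2 - q$lambda_dilution * C - bind,
           bind - q$lambda_dilution * Cg,
           -2 * a * s[1] + b * (s[2] + s[3]),
           a * s[1] - (a + b) * s[2] + b * s[4],
           a * s[1] - (a + b) * s[3] + b * s[4],
           a * (s[2] + s[3]) - 2 * b * s[4]))
  }
  y0 <- c(V1 = p$D1, V2 = p$D2, g = 0, C = 0, Cg = 0,
          s00 = 1, s10 = 0, s01 = 0, s11 = 0)
  me <- deSolve::ode(y0, times = i2$times, func = oracle_rhs, parms = p,
                     rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(i2$states[, "P0"] - me[, "s00"])), 1e-6)
  expect_lt(max(abs(i2$states[, "P1"] - (me[, "s10"] + me[, "s01"]))), 1e-6)
  expect_lt(max(abs(i2$states[, "P2"] - me[, "s11"])), 1e-6)
  # expected occupancy also matches the single-theta model driven by the
  # pooled complex: E[k] = n * theta (theta integrated jointly with the same
  # upstream kinetics so both see the identical Cg(t))
  joint <- deSolve::ode(
    c(V1 = p$D1, V2 = p$D2, g = 0, C = 0, Cg = 0, th = 0),
    times = i2$times,
    func = function(t, y, q) {
      bind <- q$k_Cg * y[4] * y[3]
      list(c(-q$lambda_dilution * y[1],
             -q$lambda_dilution * y[2],
             q$alpha_r * y[1] - q$delta_g * y[3] - bind,
             q$alpha_C * y[2] - q$lambda_dilution * y[4] - bind,
             bind - q$lambda_dilution * y[5],
             q$k_on * y[5] * (1 - y[6]) - q$k_off * y[6]))
    }, parms = p, rtol = 1e-10, atol = 1e-12)
  occ <- i2$states[, "P1"] + 2 * i2$states[, "P2"]
  expect_lt(max(abs(occ - 2 * joint[, "th"])), 1e-6)
})
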