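test_that("base-expression GFP matches its closed form", {
  for (p in list(crispri_params(), unit_params(),
                 crispri_params(lambda_dilution = 0.05, alpha_G = 20,
                                D2 = 8))) {
    tr <- simulate_system(build_model(architecture(0, "none"), p))
    ref <- base_gfp_closed_form(p, tr$times)
    expect_lt(max(abs(gfp(tr)[-1] - ref[-1]) / ref[-1]), 1e-6)
    expect_identical(gfp(tr)[1], 0)
    # argmax of t*exp(-lambda*t) is 1/lambda, within one output step
    expect_lt(abs(tr$times[which.max(gfp(tr))] - 1 / p$lambda_dilution), 1)
  }
  # no production, no reporter
  p0 <- crispri_params(alpha_G = 0)
  tr0 <- simulate_system(build_model(architecture(0, "none"), p0))
  expect_true(all(gfp(tr0) == 0))
})

test_that("trajectories respect bounds and occupancy conservation", {
  p <- crispri_params()
  for (arch in list(architecture(6, "identical"),
                    architecture(4, "heterogeneous"))) {
    tr <- simulate_system(build_model(arch, p))
    expect_true(all(tr$states >= 0))
    if (arch$mode == "identical") {
      P <- tr$states[, paste0("P", 0:arch$n_sites)]
      expect_true(all(P <= 1 + 1e-9))
      expect_lt(max(abs(rowSums(P) - 1)), 1e-6)  # drift over full 200 h
    } else {
      th <- tr$states[, paste0("theta", seq_len(arch$n_sites))]
      expect_true(all(th >= 0 & th <= 1 + 1e-9))
    }
  }
})

test_that("omitting the gRNA vector reduces every system to base expression", {
  p0 <- crispri_params(D1 = 0)
  base <- simulate_system(build_model(architecture(0, "none"), p0))
  for (arch in list(architecture(1, "heterogeneous"),
                    architecture(4, "heterogeneous"),
                    architecture(6, "identical"))) {
    tr <- simulate_system(build_model(arch, p0))
    expect_lt(max(abs(gfp(tr) - gfp(base)) / pmax(gfp(base), 1)), 1e-8)
  }
})

test_that("single-site heterogeneous and identical systems coincide", {
  # parameter-free structural property: with one site there is nothing to
  # scan to, so the two schemes are the same kinetic system
  for (p in list(unit_params(), unit_params(k_scan = 100, rho = 0.9),
                 crispri_params())) {
    h1 <- simulate_system(build_model(architecture(1, "heterogeneous"), p),
                          rtol = 1e-12, atol = 1e-14)
    i1 <- simulate_system(build_model(architecture(1, "identical"), p),
                          rtol = 1e-12, atol = 1e-14)
    shared_h <- c("V1", "V2", "g1", "C", "Cg1", "theta1", "G")
    shared_i <- c("V1", "V2", "g", "C", "Cg", "P1", "G")
    scale <- pmax(apply(abs(h1$states[, shared_h]), 2, max), 1)
    diff <- apply(abs(h1$states[, shared_h] - i1$states[, shared_i]), 2, max)
    expect_lt(max(diff / scale), 1e-8)
  }
})

test_that("integration is deterministic and stable under grid refinement", {
  p <- crispri_params()
  sys <- build_model(architecture(3, "identical"), p)
  t1 <- simulate_system(sys)
  t2 <- simulate_system(sys)
  expect_identical(t1$states, t2$states)
  base <- simulate_system(build_model(architecture(0, "none"), p))
  f1 <- as.numeric(fold_repression(base, t1))
  base_h <- simulate_system(build_model(architecture(0, "none"), p),
                            output_step = 0.5)
  f2 <- as.numeric(fold_repression(base_h,
                                   simulate_system(sys, output_step = 0.5)))
  expect_lt(abs(f1 - f2) / f1, 0.001)
})

test_that("simulation inputs are validated", {
  sys <- build_model(architecture(0, "none"), crispri_params())
  expect_error(simulate_system(sys, horizon = -1), "horizon")
  expect_error(simulate_system(sys, times = c(1, 2)), "start at 0")
  expect_error(simulate_system(sys, times = c(0, 2, 2)), "increasing")
  df <- as.data.frame(simulate_system(sys, horizon = 10))
  expect_named(df, c("time_h", "species", "value", "mode", "n_sites"))
  expect_identical(nrow(df), 11L * 4L)
})
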