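test_that("data generated at the initial guess gives a zero-residual fit", {
  truth <- crispri_params()
  tab <- generate_timecourse(truth, plant_cv = 0, leaf_cv = 0, read_cv = 0,
                             background = 0, seed = 1)
  fit <- fit_base_expression(tab, init = truth)
  expect_lt(fit$rss / sum(tab$mefl[tab$genotype == "mEmerald"]^2), 1e-12)
  expect_equal(unname(fit$estimates["alpha_G"]), truth$alpha_G,
               tolerance = 1e-6)
  expect_equal(unname(fit$estimates["lambda_dilution"]),
               truth$lambda_dilution, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lte(fit$rss, fit$rss_init)
})

test_that("noiseless synthetic data recovers the generating parameters", {
  truth <- crispri_params()
  tab <- generate_timecourse(truth, plant_cv = 0, leaf_cv = 0, read_cv = 0,
                             background = 0, seed = 1)
  init <- crispri_params(alpha_G = truth$alpha_G * 8,
                         lambda_dilution = truth$lambda_dilution / 5)
  fit <- fit_base_expression(tab, init = init)
  expect_lt(abs(fit$estimates["alpha_G"] - truth$alpha_G) / truth$alpha_G,
            0.01)
  expect_lt(abs(fit$estimates["lambda_dilution"] - truth$lambda_dilution) /
              truth$lambda_dilution, 0.01)
  expect_lte(fit$rss, fit$rss_init)
})

test_that("fits are scale-equivariant and idempotent", {
  truth <- crispri_params()
  tab <- generate_timecourse(truth, background = 0, seed = 11)
  init <- crispri_params(alpha_G = 400, lambda_dilution = 0.05)
  fit <- fit_base_expression(tab, init = init)
  tab2 <- tab
  tab2$mefl <- tab2$mefl * 3.7
  fit2 <- fit_base_expression(tab2, init = init)
  expect_equal(unname(fit2$estimates["alpha_G"]),
               unname(fit$estimates["alpha_G"]) * 3.7, tolerance = 1e-4)
  expect_equal(unname(fit2$estimates["lambda_dilution"]),
               unname(fit$estimates["lambda_dilution"]), tolerance = 1e-4)
  refit <- fit_base_expression(tab, init = fit$params)
  expect_equal(unname(refit$estimates), unname(fit$estimates),
               tolerance = 1e-4)
})

test_that("hierarchically noisy data recovers the dilution rate", {
  truth <- crispri_params()
  init <- crispri_params(alpha_G = 5000, lambda_dilution = 0.005)
  errs <- vapply(1:5, function(s) {
    tab <- generate_timecourse(truth, background = 0, seed = s)
    fit <- fit_base_expression(tab, init = init)
    abs(fit$estimates[["lambda_dilution"]] - truth$lambda_dilution) /
      truth$lambda_dilution
  }, 0)
  expect_true(all(errs < 0.2))
})

test_that("fitting inputs are validated", {
  truth <- crispri_params()
  tab <- generate_timecourse(truth, seed = 1)
  expect_error(fit_base_expression(tab, free = "k_scan"), "subset")
  expect_error(fit_base_expression(data.frame(time_h = 1, mefl = 2)),
               "2 distinct time points")
  expect_error(fit_base_expression(data.frame(x = 1)), "columns")
  bad <- crispri_params()
  bad$alpha_G <- -1
  expect_error(fit_base_expression(tab, init = bad), "alpha_G|positive")
  # D2 can be freed as a dosage-scale parameter (in place of alpha_G, with
  # which it is structurally confounded)
  fit <- fit_base_expression(tab, free = c("lambda_dilution", "D2"),
                             init = truth)
  expect_named(fit$estimates, c("lambda_dilution", "D2"))
  expect_true(all(fit$estimates > 0))
})
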