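test_that("the identity perturbation reproduces the repression table", {
  p <- crispri_params()
  ref <- as.data.frame(repression_table(p, n_max = 3))
  sc <- scan_parameter(p, "k_off", factors = c(0.5, 1), n_max = 3)
  at1 <- sc[sc$factor == 1, ]
  expect_equal(at1$fold_repression, ref$fold_repression, tolerance = 1e-12)
  expect_true(all(is.na(sc$error)))
  expect_true(all(at1$dominant))
  expect_identical(nrow(sc), 2L * 5L)  # 2 factors x 5 architectures
  expect_error(scan_parameter(p, "nope"), "unknown parameter")
  expect_error(scan_parameter(p, "k_on", factors = c(-1, 1)), "factors")
})

test_that("removing scanning degrades the identical-site advantage", {
  p <- crispri_params()
  with_scan <- as.data.frame(repression_table(p, n_max = 3))
  no_scan <- as.data.frame(repression_table(crispri_params(k_scan = 0),
                                            n_max = 3))
  expect_lt(fold_by(no_scan, "identical", 3), fold_by(with_scan, "identical", 3))
  # a x0-like scan is expressed by perturbing k_scan toward zero
  sc <- scan_parameter(p, "k_scan", factors = c(1e-9, 1), n_max = 3)
  tiny <- sc[sc$factor == 1e-9, ]
  expect_equal(fold_by(tiny, "identical", 3), fold_by(no_scan, "identical", 3),
               tolerance = 1e-4)
})

test_that("dosage scans show tunability and the no-gRNA limit", {
  p <- crispri_params()
  dos <- scan_dosage(p, d1_values = c(0, 3, 10, 30), d2_values = 3,
                     n_max = 3)
  # no gRNA vector delivered: nothing represses
  off <- dos[dos$D1 == 0, ]
  expect_true(all(abs(off$fold_repression - 1) < 1e-6))
  # the shipped base point sits in the scan
  ref <- as.data.frame(repression_table(p, n_max = 3))
  at_base <- dos[dos$D1 == 10 & dos$D2 == 3, ]
  expect_equal(at_base$fold_repression, ref$fold_repression,
               tolerance = 1e-12)
  # more gRNA vector, more repression
  for (lab in unique(dos$label)) {
    d <- dos[dos$label == lab, ]
    expect_true(all(diff(d$fold_repression[order(d$D1)]) > -1e-9))
  }
  expect_error(scan_dosage(p, d1_values = -1), "D1")
})

test_that("cell-to-cell variation is seeded, degenerate at sigma 0, and
           draw order is independent of the architecture set", {
  p <- crispri_params()
  v0 <- cell_variation(p, sigma = 0, n_cells = 3, seed = 1, n_max = 2)
  ref <- as.data.frame(repression_table(p, n_max = 2))
  for (cell in 1:3)
    expect_equal(v0$cells$fold_repression[v0$cells$cell == cell],
                 ref$fold_repression, tolerance = 1e-12)
  a <- cell_variation(p, sigma = 0.5, n_cells = 4, seed = 7, n_max = 2)
  b <- cell_variation(p, sigma = 0.5, n_cells = 4, seed = 7, n_max = 2)
  expect_identical(a$cells, b$cells)
  c2 <- cell_variation(p, sigma = 0.5, n_cells = 4, seed = 8, n_max = 2)
  expect_false(isTRUE(all.equal(a$cells$fold_repression,
                                c2$cells$fold_repression)))
  # per-cell parameter draws do not depend on how many architectures are
  # simulated afterwards: shared architectures agree across n_max
  big <- cell_variation(p, sigma = 0.5, n_cells = 4, seed = 7, n_max = 4)
  shared <- merge(a$cells, big$cells, by = c("cell", "label"))
  expect_equal(shared$fold_repression.x, shared$fold_repression.y,
               tolerance = 1e-12)
  # quantiles are ordered
  qcols <- grep("^q", names(a$quantiles))
  for (i in seq_len(nrow(a$quantiles)))
    expect_false(is.unsorted(as.numeric(a$quantiles[i, qcols])))
})
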