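test_that("memory correction applies the difference form once", {
  expect_equal(as.numeric(apply_memory_correction(c(0, -100), 0.02)),
               c(0, -102))
  expect_equal(as.numeric(apply_memory_correction(c(-100, -100), 0.04)),
               c(-100, -100))
  x <- c(-50, -80, -120)
  expect_equal(as.numeric(apply_memory_correction(x, 0)), x)
  # NA channels are skipped; predecessor is the last non-missing value
  y <- apply_memory_correction(c(0, NA, -100), 0.02)
  expect_equal(as.numeric(y), c(0, NA, -102))
  expect_error(apply_memory_correction(1:3, 0.6), "memory fraction")
})

test_that("memory correction is guarded against double application", {
  x <- c(0, -100, -40)
  once <- apply_memory_correction(x, 0.02)
  expect_error(apply_memory_correction(once, 0.02), "exactly once")
  # and it would not be idempotent if forced
  twice <- apply_memory_correction(as.numeric(once), 0.02)
  expect_false(isTRUE(all.equal(as.numeric(once), as.numeric(twice))))
})

test_that("memory fraction is recovered from deterministic carry-over", {
  cfg <- generator_config(seed = 2, noise_sd = 0, memory_fraction = 0.02,
                          drift_slope = 0)
  g <- generate_run(cfg)
  fit <- fit_memory_fraction(g$run, "H2", g$materials)
  # the difference form inverts recursive carry-over at m/(1-m)
  expect_equal(fit$m, 0.02 / 0.98, tolerance = 1e-6)
  expect_lt(abs(fit$m - 0.02), 0.001 + 1e-9)  # within one grid step
  expect_lt(fit$pooled_sd, 1e-8)

  cfg0 <- generator_config(seed = 2, noise_sd = 0, memory_fraction = 0)
  g0 <- generate_run(cfg0)
  expect_equal(fit_memory_fraction(g0$run, "H2", g0$materials)$m, 0)
})

test_that("memory fit degrades gracefully without replicates", {
  run <- manual_run(d2H = c(-130, -60, -100, -130, -60),
                    ids = c("A", "B", "S1", "A", "B"),
                    roles = c("standard", "standard", "sample",
                              "standard", "standard"))
  fit <- fit_memory_fraction(run, "H2", manual_materials())
  expect_equal(fit$m, 0)
  expect_match(fit$flags, "replicates")
})

test_that("fitted memory fraction on noisy paper-like runs is 1-3%", {
  # the carbon channel identifies m best at the configured precisions
  # (noise 0.2 permil against material contrasts of ~15 permil); on the
  # hydrogen channel, noise of 3 permil makes a 2% memory effect barely
  # identifiable and the fit legitimately shrinks toward 0.
  m_fitted <- vapply(1:5, function(s) {
    g <- generate_run(generator_config(seed = 100 + s))
    fit_memory_fraction(g$run, "C13", g$materials)$m
  }, numeric(1))
  expect_gte(median(m_fitted), 0.01)
  expect_lte(median(m_fitted), 0.03)
})

test_that("linear drift is removed exactly at zero noise", {
  cfg <- generator_config(seed = 3, noise_sd = 0, memory_fraction = 0,
                          drift_slope = 0.01)
  g <- generate_run(cfg)
  recs <- g$run$records
  dc <- drift_correction(recs$d18O_raw, recs$position, recs$material_id,
                         recs$role %in% c("standard", "qc"),
                         fit_ok = recs$role == "standard")
  expect_true(dc$applied)
  expect_equal(dc$slope, 0.01, tolerance = 1e-9)
  # residual trend on a repeated standard < 1e-9 permil/position
  sel <- recs$material_id == "CEL-A"
  resid_fit <- lm(dc$values[sel] ~ recs$position[sel])
  expect_lt(abs(coef(resid_fit)[2]), 1e-9)
})

test_that("sub-threshold drift is left uncorrected and flagged", {
  cfg <- generator_config(seed = 3, noise_sd = 0, memory_fraction = 0,
                          drift_slope = 0)
  g <- generate_run(cfg)
  recs <- g$run$records
  dc <- drift_correction(recs$d13C_raw, recs$position, recs$material_id,
                         recs$role %in% c("standard", "qc"),
                         fit_ok = recs$role == "standard")
  expect_false(dc$applied)
  expect_equal(dc$values, recs$d13C_raw)
  expect_match(dc$flags, "no drift applied")
})

test_that("a single standard block yields no drift correction", {
  run <- manual_run(d2H = c(-130, -130, -60, -60, -100),
                    ids = c("A", "A", "B", "B", "S1"),
                    roles = c(rep("standard", 4), "sample"))
  recs <- run$records
  dc <- drift_correction(recs$d2H_raw, recs$position, recs$material_id,
                         recs$role %in% c("standard", "qc"))
  expect_false(dc$applied)
  expect_match(dc$flags, "single standard block")
})

test_that("two-point calibration inverts affine distortion", {
  # exact standards: identity map
  cal <- fit_two_point_calibration(c(-28, -22), c(-28, -22))
  expect_equal(cal$gain, 1)
  expect_equal(cal$offset, 0)
  # 15% reactor carbon at -25 permil: measured = 0.85*true - 3.75
  cal <- fit_two_point_calibration(c(-12.25, -29.25), c(-10, -30))
  expect_equal(cal$gain, 1 / 0.85, tolerance = 1e-12)
  expect_equal(cal$gain * -20.75 + cal$offset, -20, tolerance = 1e-12)
  expect_equal(reactor_fraction_from_gain(cal$gain), 0.15,
               tolerance = 1e-12)
  expect_error(fit_two_point_calibration(-10, -10), ">= 2")
  expect_error(fit_two_point_calibration(c(-10, -20), c(-15, -15)),
               "span")
})

test_that("overdetermined calibration matches the normal equations", {
  set.seed(8)
  true <- c(-30, -25, -20, -12)
  meas <- 0.85 * true - 3.75 + rnorm(4, 0, 0.1)
  cal <- fit_two_point_calibration(meas, true)
  sxy <- sum((meas - mean(meas)) * (true - mean(true)))
  sxx <- sum((meas - mean(meas))^2)
  expect_equal(cal$gain, sxy / sxx, tolerance = 1e-12)
  expect_equal(cal$offset, mean(true) - cal$gain * mean(meas),
               tolerance = 1e-12)
})

test_that("calibration exactness holds for any affine distortion", {
  set.seed(9)
  for (i in 1:5) {
    gain <- runif(1, 0.7, 1.3)
    offs <- runif(1, -10, 10)
    cert <- c(-130, -130, -60, -60)
    run <- manual_run(d2H = c(gain * cert + offs, gain * -95 + offs,
                              gain * cert + offs),
                      d13C = -25, d18O = 25)
    red <- reduce_run(run, manual_materials(), x_e = 0)
    std <- red$results[red$results$role == "standard", ]
    expect_equal(std$d2H_e, rep(cert, 2), tolerance = 1e-9)
    expect_equal(red$results$d2H_e[5], -95, tolerance = 1e-9)
  }
})

test_that("pipeline with all effects off is the identity on raw deltas", {
  cfg <- generator_config(seed = 4, noise_sd = 0, memory_fraction = 0,
                          drift_slope = 0, reactor_carbon_fraction = 0,
                          water_id = NULL)
  g <- generate_run(cfg)
  red <- reduce_run(g$run, g$materials, x_e = 0)
  expect_equal(red$results$d13C, g$run$records$d13C_raw, tolerance = 1e-9)
  expect_equal(red$results$d18O, g$run$records$d18O_raw, tolerance = 1e-9)
  expect_equal(red$results$d2H_ne, g$run$records$d2H_raw,
               tolerance = 1e-9)
  expect_equal(red$calibration$H2$gain, 1, tolerance = 1e-9)
  expect_equal(red$calibration$H2$memory_fraction, 0)
})

test_that("full pipeline closure recovers generator truth at zero noise", {
  for (m in c(0, 0.03)) {
    for (drift in c(0, 0.02)) {
      for (f in c(0, 0.2)) {
        cfg <- generator_config(seed = 6, noise_sd = 0,
                                memory_fraction = m, drift_slope = drift,
                                reactor_carbon_fraction = f,
                                n_samples = 12)
        g <- generate_run(cfg)
        red <- reduce_run(g$run, g$materials)
        i <- match(red$results$material_id, g$truth$material_id)
        for (col in c("d13C", "d18O", "d2H_ne")) {
          err <- abs(red$results[[col]] - g$truth[[col]][i])
          expect_lt(max(err, na.rm = TRUE), 1e-6)
        }
      }
    }
  }
})

test_that("chromium runs reduce the hydrogen channel only", {
  cfg <- generator_config(seed = 10, reactor = "chromium", noise_sd = 0,
                          standard_ids = c("CEL-A", "CEL-B", "PEF"),
                          n_samples = 6)
  g <- generate_run(cfg)
  expect_equal(run_isotopes(g$run), "H2")
  red <- reduce_run(g$run, g$materials)
  expect_true(all(is.na(red$results$d13C)))
  expect_true(all(is.na(red$results$d18O)))
  expect_true(any(!is.na(red$results$d2H_ne)))
  i <- match(red$results$material_id, g$truth$material_id)
  expect_equal(red$results$d2H_ne, g$truth$d2H_ne[i], tolerance = 1e-6)
})

test_that("missing calibration standards skip the channel with a flag", {
  # no material certified for d18O
  mats <- reference_materials(data.frame(
    id = c("A", "B", "S1"), material_class = "cellulose",
    d2H = c(-130, -60, NA), d13C = c(-28, -22, NA), d18O = NA_real_,
    x_e = c(0.2, 0.2, NA), n_content_pct = 0, s_content_pct = 0,
    exchanges_h = TRUE))
  run <- manual_run(d2H = c(-130, -130, -60, -60, -95, -130, -130, -60,
                            -60))
  red <- reduce_run(run, mats, x_e = 0)
  expect_true(all(is.na(red$results$d18O)))
  expect_true(any(grepl("O18: channel skipped", red$results$flags)))
  expect_false(all(is.na(red$results$d2H_e)))
})

test_that("unknown sample materials are a hard error naming the id", {
  run <- manual_run(d2H = -100, ids = c("A", "A", "B", "B", "GHOST",
                                        "A", "A", "B", "B"))
  expect_error(reduce_run(run, manual_materials()), "GHOST")
})

test_that("pre-steady-state cellulose analyses are flagged and excluded", {
  cfg <- generator_config(
    seed = 12, noise_sd = 0, memory_fraction = 0, drift_slope = 0,
    n_samples = 12,
    equilibration_loss = list(initial_xe = 0.30, steadystate_xe = 0.20,
                              relaxation_minutes = 120))
  g <- generate_run(cfg)
  expect_equal(g$run$records$time_offset[1], 0)
  red <- reduce_run(g$run, g$materials)
  early <- red$results$flags[g$run$records$time_offset < 120 &
                               red$results$material_id == "CEL-A"]
  expect_true(all(grepl("pre-steady-state", early)))
  late <- red$results$flags[g$run$records$time_offset >= 120]
  expect_false(any(grepl("pre-steady-state", late)))
  # steady-state analyses still reduce to truth within the residual
  # relaxation (< 0.1 permil equivalent here)
  sel <- g$run$records$time_offset >= 240 &
    red$results$role == "sample"
  i <- match(red$results$material_id[sel], g$truth$material_id)
  expect_lt(max(abs(red$results$d2H_ne[sel] - g$truth$d2H_ne[i])), 1.0)
  # zero-blank autosampler: rule does not apply
  cfg2 <- generator_config(seed = 12, noise_sd = 0, memory_fraction = 0,
                           drift_slope = 0, n_samples = 12,
                           autosampler = "zero_blank",
                           start_delay_minutes = 0)
  g2 <- generate_run(cfg2)
  red2 <- reduce_run(g2$run, g2$materials)
  expect_false(any(grepl("pre-steady-state", red2$results$flags)))
})
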