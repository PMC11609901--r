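test_that("sequence validation flags structural defects, not errors", {
  g <- generate_run(generator_config(seed = 2))
  v <- validate_sequence(g$run, g$materials)
  expect_s3_class(v, "sequence_validation")
  expect_true(v$ok)

  # drop the terminal block
  recs <- g$run$records
  last_sample <- max(which(recs$role == "sample"))
  trunc <- run_sequence(recs[1:last_sample, ],
                        reactor = g$run$reactor,
                        equilibration_water_id =
                          g$run$equilibration_water_id,
                        autosampler = g$run$autosampler)
  v2 <- validate_sequence(trunc, g$materials)
  expect_true(any(grepl("terminal standard block", v2$warnings)))
})

test_that("narrow calibration spans raise a range warning", {
  mats <- reference_materials(data.frame(
    id = c("N1", "N2", "Q"), material_class = "cellulose",
    d2H = c(-100, -95, -85), d13C = c(-25, -24, -25.5),
    d18O = c(27, 28, 34), x_e = 0.2, n_content_pct = 0,
    s_content_pct = 0, exchanges_h = TRUE))
  cfg <- generator_config(seed = 2, standard_ids = c("N1", "N2"),
                          qc_id = "Q", n_samples = 6)
  g <- generate_run(cfg, mats)
  v <- validate_sequence(g$run, g$materials)
  expect_true(any(grepl("span.*H2", v$warnings)))
  expect_true(any(grepl("span.*C13", v$warnings)))
})

test_that("QC precision is zero for a noise-free run", {
  cfg <- generator_config(seed = 3, noise_sd = 0)
  g <- generate_run(cfg)
  red <- reduce_run(g$run, g$materials)
  qc <- qc_precision(red)
  expect_true(all(qc$sd[!is.na(qc$sd)] < 1e-8))
})

test_that("QC precision is translation invariant and gain covariant", {
  cfg <- generator_config(seed = 13, n_samples = 36)
  g <- generate_run(cfg)
  res <- reduce_run(g$run, g$materials)$results
  base <- qc_precision(res)
  shifted <- res
  shifted$d13C <- shifted$d13C + 5
  expect_equal(qc_precision(shifted)$sd[1], base$sd[1])
  scaled <- res
  scaled$d18O <- 1.7 * scaled$d18O
  expect_equal(qc_precision(scaled)$sd[2], 1.7 * base$sd[2],
               tolerance = 1e-12)
})

test_that("QC precision needs three replicates", {
  res <- tibble::tibble(
    material_id = "QC", role = "qc",
    d13C = c(-25.4, -25.6), d18O = NA_real_, d2H_e = NA_real_,
    d2H_ne = NA_real_, x_e_used = 0.36, flags = "")
  expect_warning(out <- qc_precision(res, "QC"), "replicates")
  expect_true(is.na(out$sd[out$isotope == "d13C"]))
})

test_that("element content scales with area per unit mass", {
  expect_equal(element_content(1000, 1, 1000, 1, 44.4), 44.4)
  expect_equal(element_content(500, 1, 1000, 1, 44.4), 22.2)
  expect_equal(element_content(2000, 2, 1000, 1, 44.4), 44.4)
  expect_error(element_content(0, 1, 1000, 1, 44.4), "> 0")
  expect_error(element_content(1000, 1, 1000, 0, 44.4), "> 0")
})

test_that("reactor comparison reproduces the packaged difference column", {
  t2 <- read_reactor_table()
  tab <- reactor_difference_table(
    data.frame(material_id = t2$material_id, d2H_ne = t2$d2H_ne_carbon,
               x_e = t2$x_e_carbon),
    data.frame(material_id = t2$material_id, d2H_ne = t2$d2H_ne_chromium,
               x_e = t2$x_e_chromium))
  expect_equal(tab$diff_display, t2$diff)
  expect_equal(tab$diff_display,
               c(-0.6, -5.2, 0.3, -1.5, 3.9))
})

test_that("reactor difference is antisymmetric and zero on identical runs", {
  a <- data.frame(material_id = c("M1", "M2"), d2H_ne = c(-118.1, -25.7))
  b <- data.frame(material_id = c("M1", "M2"), d2H_ne = c(-117.5, -27.2))
  ab <- reactor_difference_table(a, b)
  ba <- reactor_difference_table(b, a)
  expect_equal(ab$diff, -ba$diff)
  same <- reactor_difference_table(a, a)
  expect_equal(same$diff, c(0, 0))
  expect_warning(
    empty <- reactor_difference_table(
      a, data.frame(material_id = "M3", d2H_ne = -1)),
    "no shared")
  expect_equal(nrow(empty), 0)
})

test_that("nitrogen-bias regression matches the normal equations", {
  set.seed(14)
  for (i in 1:10) {
    tab <- data.frame(n_pct = runif(6, 0, 12), diff = rnorm(6, 0, 3))
    fit <- nitrogen_bias_regression(tab)
    x <- tab$n_pct
    y <- tab$diff
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    r2 <- slope^2 * sum((x - mean(x))^2) / sum((y - mean(y))^2)
    expect_equal(fit$slope, slope, tolerance = 1e-9)
    expect_equal(fit$intercept, intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, r2, tolerance = 1e-9)
  }
})

test_that("nitrogen-bias regression handles degenerate inputs", {
  zero <- data.frame(n_pct = c(1, 2, 3), diff = c(0, 0, 0))
  fit <- nitrogen_bias_regression(zero)
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, 0)
  collinear <- data.frame(n_pct = c(1, 2, 3), diff = c(-1, 1, 3))
  expect_equal(nitrogen_bias_regression(collinear)$r_squared, 1,
               tolerance = 1e-12)
  expect_error(nitrogen_bias_regression(
    data.frame(n_pct = 1, diff = 0)), "regression failure")
  expect_warning(
    two <- nitrogen_bias_regression(
      data.frame(n_pct = c(1, 2), diff = c(0, 1))),
    "degenerate")
  expect_equal(two$r_squared, 1)
})

test_that("interference screen flags N- and S-rich materials on glassy carbon", {
  mats <- default_materials()
  fl <- interference_flags(mats, "glassy_carbon")
  insect <- fl[fl$material_id == "INSECT", ]
  expect_match(insect$flags, "N interference")
  expect_equal(insect$predicted_bias, 3.4, tolerance = 0.05)
  cel <- fl[fl$material_id == "CEL-A", ]
  expect_equal(cel$flags, "")
  # chromium scavenges reactive elements: no flags at any N content
  fl_cr <- interference_flags(mats, "chromium")
  expect_true(all(fl_cr$flags == ""))
  # sulfur-rich material
  smat <- reference_materials(data.frame(
    id = "ALGAE", material_class = "other", d2H = -110, d13C = -20,
    d18O = 15, x_e = 0.26, n_content_pct = 1.27, s_content_pct = 2.29,
    exchanges_h = TRUE))
  expect_match(interference_flags(smat)$flags, "H2S")
})
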