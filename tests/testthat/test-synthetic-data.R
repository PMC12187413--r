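test_that("the generator is bit-identical under a fixed seed", {
  cfg <- study_config(exclusions = c(hormone = 1, flag = 1, missing = 2))
  s1 <- generate_dyad_study(cfg, seed = 42)
  s2 <- generate_dyad_study(cfg, seed = 42)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$latents, s2$truth$latents)
  s3 <- generate_dyad_study(cfg, seed = 43)
  expect_false(identical(s1$records, s3$records))
})

test_that("config validation catches impossible structures", {
  expect_error(study_config(n_pairs = 2), "at least 4")
  expect_error(study_config(icc = c(headbob = 1.2, shudder = 0.5,
                                    dorsal = 0.5, lateral = 0, uv = 0.2)),
               "\\[0, 1\\)")
  # icc 0.9 on dorsal over-commits the colour latent budget
  expect_error(study_config(icc = c(headbob = 0.5, shudder = 0.5,
                                    dorsal = 0.9, lateral = 0, uv = 0.2)),
               "over-committed")
  expect_error(study_config(pair_cor = 1.5), "pair_cor")
  cfg <- study_config(n_pairs = 4, n_controls = 0)
  expect_error(plant_exclusions(generate_dyad_study(cfg, 1)$records,
                                5, 2, 3), "more planted")
})

test_that("zero icc yields near-zero empirical within-pair correlation", {
  cfg <- study_config(
    n_pairs = 500,
    icc = c(headbob = 0, shudder = 0, dorsal = 0, lateral = 0, uv = 0))
  soc <- generate_dyad_study(cfg, seed = 202)$records
  soc <- soc[soc$group == "social", ]
  traits <- c("headbob", "shudder", "max_dorsal_jnd", "max_lateral_jnd")
  iccs <- vapply(soc[traits], double_entry_icc, numeric(1))
  # per trait: inside 3.5 Monte-Carlo standard errors of zero
  expect_true(all(abs(iccs) < 3.5 / sqrt(500)))
  # across the four independent traits the mean estimate is tightly zero
  expect_gt(mean(iccs), -0.1)
  expect_lt(mean(iccs), 0.1)
})

test_that("default iccs are realised on the emitted trait scale", {
  soc <- generate_dyad_study(study_config(n_pairs = 500),
                             seed = 203)$records
  soc <- soc[soc$group == "social", ]
  # count traits carry the configured icc on the count scale (calibrated)
  expect_lt(abs(double_entry_icc(soc$headbob) - 0.5), 0.1)
  expect_lt(abs(double_entry_icc(soc$shudder) - 0.5), 0.1)
  expect_lt(abs(double_entry_icc(soc$max_dorsal_jnd) - 0.5), 0.1)
  expect_lt(abs(double_entry_icc(soc$max_lateral_jnd)), 0.1)
})

test_that("generator marginals match their analytic values", {
  cfg <- study_config(n_pairs = 500, n_controls = 0)
  soc <- generate_dyad_study(cfg, seed = 204)$records
  n <- nrow(soc)
  # headbob: lognormal-Poisson mean exp(a + b^2/2)
  a <- cfg$counts$headbob[["log_mean"]]
  b <- cfg$counts$headbob[["slope"]]
  mu <- exp(a + b^2 / 2)
  vv <- exp(2 * a + b^2) * (exp(b^2) - 1) + mu
  expect_lt(abs(mean(soc$headbob) - mu), 3 * sqrt(vv / n))
  # induced testosterone: log-scale mean and sd
  expect_lt(abs(mean(log(soc$t_induced)) - log(300)),
            3 * 0.6 / sqrt(n))
  expect_lt(abs(sd(log(soc$t_induced)) - 0.6), 0.05)
  # svl inside range with within-pair gap <= 3 mm
  expect_true(all(soc$svl >= 112 & soc$svl <= 137))
  gaps <- abs(soc$svl[seq(1, n, 2)] - soc$svl[seq(2, n, 2)])
  expect_true(all(gaps <= 3))
})

test_that("controls display no headbobs or shudders and weaker colour", {
  s <- generate_dyad_study(study_config(), seed = 205)
  ctl <- s$records[s$records$group == "control", ]
  soc <- s$records[s$records$group == "social", ]
  expect_true(all(ctl$headbob == 0))
  expect_true(all(ctl$shudder == 0))
  expect_true(all(is.na(ctl$pair_id)))
  expect_lt(mean(ctl$max_dorsal_jnd), mean(soc$max_dorsal_jnd))
})

test_that("planted exclusions round-trip through the exclusion log", {
  cfg <- study_config(exclusions = c(hormone = 3, flag = 2, missing = 6))
  s <- generate_dyad_study(cfg, seed = 206)
  planted <- s$truth$planted_exclusions
  expect_equal(lengths(planted), c(hormone = 3L, flag = 2L, missing = 6L))
  expect_equal(length(unique(unlist(planted))), 11L)  # disjoint sets
  lg <- apply_exclusions(s$records, stage = "pca")$log
  expect_setequal(lg$individual_id, unlist(planted))
  # no planting leaves records untouched
  s0 <- generate_dyad_study(study_config(), seed = 206)
  pl <- plant_exclusions(s0$records, 0, 0, 0, seed = 1)
  expect_identical(pl$records, s0$records)
})

test_that("colour series plant a known argmax and respect monotonicity", {
  # zero amplitudes: every image is the grey itself
  z <- generate_colour_series(n_images = 4, amplitudes = rep(0, 4))
  expect_equal(z$truth$jnd, rep(0, 4), tolerance = 1e-9)
  expect_equal(z$truth$argmax, 1L)

  amps <- c(0.05, 0.1, 0.45, 0.08, 0.12)
  g <- generate_colour_series(n_images = 5, amplitudes = amps)
  m <- max_series_contrast(g$catches, g$reference, g$noise)
  expect_equal(m$argmax, 3L)
  expect_equal(m$argmax, g$truth$argmax)
  expect_equal(m$max_jnd, g$truth$jnd[3], tolerance = 1e-12)

  mono <- generate_colour_series(n_images = 6,
                                 amplitudes = seq(0, 0.5, 0.1))
  expect_true(all(diff(mono$truth$jnd) > 0))
  # randomly scheduled series still identify their own brute-force max
  r <- generate_colour_series(n_images = 8, seed = 31)
  expect_equal(max_series_contrast(r$catches, r$reference,
                                   r$noise)$argmax, r$truth$argmax)
})
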