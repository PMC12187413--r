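test_that("quantum catches match analytic integrals and scale linearly", {
  flat1 <- spectrum(c(300, 750), c(1, 1))
  box <- spectrum(400:500, rep(1, 101), label = "boxcar")
  half <- spectrum(400:500, rep(0.5, 101))
  q <- quantum_catches(flat1, flat1, list(box = box, half = half))
  expect_equal(as.numeric(q), c(100, 50), tolerance = 1e-12)

  sens <- gaussian_sensitivities()
  illum <- daylight_illuminant()
  q1 <- quantum_catches(flat_reflectance(0.4), illum, sens)
  q2 <- quantum_catches(flat_reflectance(0.8), illum, sens)
  expect_equal(as.numeric(q2) / as.numeric(q1), rep(2, 3),
               tolerance = 1e-12)
})

test_that("quantum catches agree with a 10x-finer-grid quadrature oracle", {
  wl <- 300:750
  sens <- gaussian_sensitivities(wavelengths = wl)
  illum <- daylight_illuminant(wl)
  ramp <- spectrum(wl, seq(0.1, 0.9, length.out = length(wl)))
  q <- quantum_catches(ramp, illum, sens)
  for (ch in names(sens)) {
    oracle <- fine_grid_catch(ramp, illum, sens[[ch]], step = 0.1)
    expect_equal(unname(q[ch]), oracle, tolerance = 1e-6)
  }
})

test_that("quantum catches reject degenerate inputs", {
  s_low <- spectrum(300:400, rep(1, 101))
  s_high <- spectrum(500:600, rep(1, 101))
  expect_error(quantum_catches(s_low, s_low, list(s_high)), "disjoint")
  # sensitivity identically zero on the common support
  zero <- spectrum(300:400, rep(0, 101))
  expect_error(quantum_catches(s_low, s_low, list(z = zero)), "degenerate")
  expect_error(quantum_catches(s_low, s_low, list()), "nonempty")
})

test_that("receptor noise follows e_i = weber / sqrt(eta_i / max eta)", {
  n <- receptor_noise(c(lw = 0.06, mw = 0.08, sw = 0.15), weber = 0.05)
  expect_equal(unname(n$e["sw"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(n$e["lw"]), 0.05 / sqrt(0.06 / 0.15),
               tolerance = 1e-12)
  expect_equal(unname(n$e["mw"]), 0.05 / sqrt(0.08 / 0.15),
               tolerance = 1e-12)
  expect_equal(unname(receptor_noise(c(1, 1), 0.1)$e), c(0.1, 0.1))
  expect_equal(unname(receptor_noise(c(0.25, 1), 0.05)$e), c(0.1, 0.05))
  expect_error(receptor_noise(c(0, 1), 0.05), "positive")
  expect_error(receptor_noise(c(1, 1), 1.5), "weber")
})

test_that("chromatic contrast matches the direct trichromatic formula", {
  noise <- receptor_noise(c(lw = 0.06, mw = 0.08, sw = 0.15), weber = 0.05)
  a <- cone_catch(c(2, 1, 1))
  b <- cone_catch(c(1, 1, 1))
  expect_equal(chromatic_contrast(a, b, noise),
               trichromat_ds(c(2, 1, 1), c(1, 1, 1), noise$e),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    qa <- exp(rnorm(3))
    qb <- exp(rnorm(3))
    expect_equal(chromatic_contrast(cone_catch(qa), cone_catch(qb), noise),
                 trichromat_ds(qa, qb, noise$e), tolerance = 1e-12)
  }
})

test_that("chromatic contrast is symmetric, achromatic-invariant and
           inversely proportional to the Weber fraction", {
  noise <- receptor_noise(c(0.06, 0.08, 0.15), weber = 0.05)
  noise2 <- receptor_noise(c(0.06, 0.08, 0.15), weber = 0.10)
  set.seed(7)
  for (i in 1:50) {
    a <- cone_catch(exp(rnorm(3)))
    b <- cone_catch(exp(rnorm(3)))
    ds <- chromatic_contrast(a, b, noise)
    expect_equal(ds, chromatic_contrast(b, a, noise), tolerance = 1e-12)
    # uniform scaling of either stimulus is achromatic
    sc <- exp(rnorm(1))
    expect_equal(chromatic_contrast(cone_catch(sc * as.numeric(a)), b,
                                    noise), ds, tolerance = 1e-9)
    # doubling weber halves dS exactly
    expect_equal(chromatic_contrast(a, b, noise2), ds / 2,
                 tolerance = 1e-12)
  }
  a <- cone_catch(c(1.3, 0.2, 5))
  expect_equal(chromatic_contrast(a, a, noise), 0)
  expect_equal(chromatic_contrast(cone_catch(c(3, 3, 3)),
                                  cone_catch(c(0.5, 0.5, 0.5)), noise), 0,
               tolerance = 1e-12)
  expect_error(chromatic_contrast(cone_catch(c(1, 1)), a, noise),
               "mismatch")
})

test_that("RNL coordinates reproduce the contrast as Euclidean distance", {
  noise <- receptor_noise(c(lw = 0.06, mw = 0.08, sw = 0.15))
  set.seed(11)
  for (i in 1:1000) {
    a <- cone_catch(exp(rnorm(3, sd = 2)))
    b <- cone_catch(exp(rnorm(3, sd = 2)))
    d_formula <- chromatic_contrast(a, b, noise)
    d_coords <- sqrt(sum((rnl_coordinates(a, noise) -
                            rnl_coordinates(b, noise))^2))
    expect_equal(d_coords, d_formula, tolerance = 1e-9)
  }
})

test_that("dichromat contrast reduces to the closed form", {
  noise <- receptor_noise(c(0.3, 0.9), weber = 0.07)
  set.seed(13)
  for (i in 1:200) {
    qa <- exp(rnorm(2))
    qb <- exp(rnorm(2))
    df <- log(qa) - log(qb)
    closed <- abs(df[1] - df[2]) / sqrt(sum(noise$e^2))
    expect_equal(chromatic_contrast(cone_catch(qa), cone_catch(qb), noise),
                 closed, tolerance = 1e-12)
    d2 <- abs(rnl_coordinates(cone_catch(qa), noise) -
                rnl_coordinates(cone_catch(qb), noise))
    expect_equal(as.numeric(d2), closed, tolerance = 1e-9)
  }
  # equal catches sit at the achromatic origin of the single axis
  p <- rnl_coordinates(cone_catch(c(1, 1)),
                       receptor_noise(c(1, 1), 0.1))
  expect_equal(as.numeric(p), 0, tolerance = 1e-12)
})

test_that("equal-noise trichromat matches the hand-computed case", {
  # with e = (v, v, v) and catches (e^1, 1, 1): df = (1, 0, 0),
  # dS^2 = v^2(0)^2+v^2(1)^2+v^2(1)^2 over 3v^4 = 2/(3v^2)
  v <- 0.08
  noise <- receptor_noise(c(1, 1, 1), weber = v)
  ds <- chromatic_contrast(cone_catch(c(exp(1), 1, 1)),
                           cone_catch(c(1, 1, 1)), noise)
  expect_equal(ds, sqrt(2 / 3) / v, tolerance = 1e-12)
})

test_that("max series contrast returns the earliest maximum", {
  noise <- receptor_noise(c(0.06, 0.08, 0.15))
  ref <- cone_catch(c(1, 1, 1))
  one <- list(cone_catch(c(2, 1, 1)))
  m1 <- max_series_contrast(one, ref, noise)
  expect_equal(m1$argmax, 1L)
  expect_equal(m1$max_jnd, chromatic_contrast(one[[1]], ref, noise))

  # planted larger log-contrast bump at index 4; brute-force check
  series <- lapply(c(1.2, 1.5, 1.1, 3.0, 1.4), function(s)
    cone_catch(c(s, 1, 1)))
  m <- max_series_contrast(series, ref, noise)
  brute <- vapply(series, chromatic_contrast, numeric(1), b = ref,
                  noise = noise)
  expect_equal(m$argmax, which.max(brute))
  expect_equal(m$argmax, 4L)
  expect_equal(m$max_jnd, max(brute))

  flat <- lapply(1:3, function(i) ref)
  mf <- max_series_contrast(flat, ref, noise)
  expect_equal(mf$max_jnd, 0)
  expect_equal(mf$argmax, 1L)
  expect_error(max_series_contrast(list(), ref, noise), "nonempty")
})

test_that("per-image catch tables reduce to per-individual maxima", {
  noise <- receptor_noise(c(0.06, 0.08, 0.15))
  ref <- cone_catch(c(1, 1, 1))
  d <- expand.grid(individual_id = c("a", "b"), image_index = 1:3,
                   region = c("dorsal", "lateral"),
                   stringsAsFactors = FALSE)
  set.seed(3)
  d$q_lw <- exp(rnorm(nrow(d)))
  d$q_mw <- exp(rnorm(nrow(d)))
  d$q_sw <- exp(rnorm(nrow(d)))
  out <- max_contrast_table(d, ref, noise)
  expect_equal(nrow(out), 4L)
  row <- out[out$individual_id == "a" & out$region == "dorsal", ]
  sub <- d[d$individual_id == "a" & d$region == "dorsal", ]
  brute <- vapply(seq_len(3), function(i)
    chromatic_contrast(cone_catch(c(sub$q_lw[i], sub$q_mw[i], sub$q_sw[i])),
                       ref, noise), numeric(1))
  expect_equal(row$max_jnd, max(brute))
  expect_equal(row$argmax_image, sub$image_index[which.max(brute)])
})
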