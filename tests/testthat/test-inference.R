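test_that("Bartlett sphericity is exact at R = I and matches the
           determinant formula", {
  # Helmert contrasts: zero-sum, mutually orthogonal columns => R = I
  H <- stats::contr.helmert(8)
  b <- bartlett_sphericity(H)
  expect_equal(b$chi2, 0, tolerance = 1e-12)
  expect_equal(b$p_value, 1)
  expect_equal(b$df, 7 * 6 / 2)

  # seeded Gaussian with 0.5 off-diagonal correlation, determinant oracle
  set.seed(8)
  n <- 40
  p <- 5
  S <- matrix(0.5, p, p)
  diag(S) <- 1
  X <- matrix(rnorm(n * p), n) %*% chol(S)
  b2 <- bartlett_sphericity(X)
  R <- stats::cor(X)
  chi2_direct <- -(n - 1 - (2 * p + 5) / 6) * log(det(R))
  expect_equal(b2$chi2, chi2_direct, tolerance = 1e-9)
  expect_equal(b2$p_value,
               pchisq(chi2_direct, p * (p - 1) / 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(bartlett_sphericity(cbind(X[, 1], X[, 1])), "singular")
})

test_that("Bartlett chi2 is invariant to per-column affine rescaling", {
  set.seed(9)
  X <- matrix(rnorm(150), 30)
  Y <- sweep(sweep(X, 2, c(2, -3, 0.5, 10, 1), "*"), 2,
             c(1, 0, -5, 2, 7), "+")
  expect_equal(bartlett_sphericity(X)$chi2, bartlett_sphericity(Y)$chi2,
               tolerance = 1e-9)
})

test_that("PCA eigenvalues match the characteristic-polynomial oracle and
           prcomp", {
  set.seed(10)
  X <- matrix(rnorm(200), 40) %*% chol(diag(5) * 0.5 + 0.5)
  colnames(X) <- letters[1:5]
  fit <- fit_pca(X)
  expect_equal(fit$eigenvalues, charpoly_eigenvalues(stats::cor(X)),
               tolerance = 1e-9)
  pr <- stats::prcomp(X, scale. = TRUE)
  expect_equal(fit$eigenvalues, unname(pr$sdev^2), tolerance = 1e-9)
  # loadings agree with prcomp up to the sign convention
  for (j in 1:5) {
    expect_equal(unname(abs(fit$loadings[, j])),
                 unname(abs(pr$rotation[, j])), tolerance = 1e-9)
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  }
})

test_that("a duplicated column concentrates exactly its shared variance", {
  H <- stats::contr.helmert(8)          # orthogonal base columns
  X <- cbind(a = H[, 1], b = H[, 1], H[, 2:4])
  fit <- fit_pca(X)
  expect_equal(fit$eigenvalues, c(2, 1, 1, 1, 0), tolerance = 1e-9)
  expect_null(fit$bartlett)             # singular R: no sphericity test
  expect_equal(fit$variance_share[1], 40, tolerance = 1e-9)
})

test_that("variance shares sum to 100 and eigenvalues survive column
           permutation", {
  set.seed(11)
  X <- matrix(rlnorm(150), 30)
  colnames(X) <- paste0("t", 1:5)
  fit <- fit_pca(X)
  expect_equal(sum(fit$variance_share), 100, tolerance = 1e-9)
  perm <- c(3, 1, 5, 2, 4)
  fit2 <- fit_pca(X[, perm])
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(fit2$loadings[colnames(X), ]), abs(fit$loadings),
               tolerance = 1e-9)
})

test_that("retained scores are uncorrelated and reproduce z %*% loadings", {
  set.seed(12)
  X <- matrix(rnorm(250), 50)
  fit <- fit_pca(X)
  cc <- stats::cor(fit$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  expect_equal(unname(fit$scores), unname(scale(X) %*% fit$loadings),
               tolerance = 1e-9)
})

test_that("clone pairs collapse the bootstrap to zero-width intervals", {
  rec <- make_clone_records(n_pairs = 12, seed = 21)
  bt <- dyad_bootstrap_pca(rec, n_iter = 50, seed = 99)
  expect_lt(max(abs(bt$upper - bt$lower)), 1e-10)
  expect_equal(bt$estimate, bt$lower, tolerance = 1e-10)
})

test_that("the bootstrap is bit-identical under a fixed seed", {
  s <- generate_dyad_study(study_config(n_pairs = 10, n_controls = 0),
                           seed = 55)
  b1 <- dyad_bootstrap_pca(s$records, n_iter = 40, seed = 7)
  b2 <- dyad_bootstrap_pca(s$records, n_iter = 40, seed = 7)
  expect_identical(b1$draws, b2$draws)
  r1 <- dyad_bootstrap_regression(
    s$records,
    stats::setNames(s$records$max_dorsal_jnd, s$records$individual_id),
    n_iter = 40, seed = 7)
  r2 <- dyad_bootstrap_regression(
    s$records,
    stats::setNames(s$records$max_dorsal_jnd, s$records$individual_id),
    n_iter = 40, seed = 7)
  expect_identical(r1$draws, r2$draws)
})

test_that("a broken pair is rejected by the bootstrap", {
  s <- generate_dyad_study(study_config(n_pairs = 8, n_controls = 0),
                           seed = 5)
  expect_error(dyad_bootstrap_pca(s$records[-1, ], n_iter = 10, seed = 1),
               "both members")
})

test_that("bootstrap intervals for block loadings typically exclude zero", {
  reps <- 50
  hits <- 0
  for (r in seq_len(reps)) {
    s <- generate_dyad_study(study_config(), seed = 300 + r)
    soc <- s$records[s$records$group == "social", ]
    bt <- dyad_bootstrap_pca(soc, n_iter = 100, seed = 700 + r)
    id <- identify_blocks(bt$estimate)
    excl <- function(tr, pc) bt$lower[tr, pc] > 0 || bt$upper[tr, pc] < 0
    hits <- hits +
      sum(vapply(behaviour_block, excl, TRUE, pc = id$behaviour),
          vapply(colour_block, excl, TRUE, pc = id$colour))
  }
  expect_gte(hits / (5 * reps), 0.9)
})

test_that("the regression recovers an exact linear response and is
           permutation-invariant", {
  set.seed(31)
  n <- 30
  T <- rlnorm(n, log(300), 0.6)
  C <- rlnorm(n, log(40), 0.5)
  svl <- runif(n, 112, 137)
  y <- 0.001 * T - 0.004 * C + 0 * svl
  fit <- fit_hormone_regression(y, T, C, svl)
  expect_equal(unname(fit$coefficients),
               c(0, 0.001, -0.004, 0), tolerance = 1e-10)
  perm <- sample(n)
  fit2 <- fit_hormone_regression(y[perm], T[perm], C[perm], svl[perm])
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_error(fit_hormone_regression(y, T, 2 * T, svl), "collinear")
  expect_error(fit_hormone_regression(y[1:4], T[1:4], C[1:4], svl[1:4]),
               "at least 6")
})

test_that("a planted positive testosterone effect is recovered in sign", {
  ok <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    n <- 46
    zt <- rnorm(n)
    T <- exp(log(300) + 0.6 * zt)
    C <- rlnorm(n, log(40), 0.5)
    svl <- runif(n, 112, 137)
    score <- 0.4 * zt + rnorm(n, sd = sqrt(1 - 0.16))
    fit <- fit_hormone_regression(score, T, C, svl)
    ok <- ok + (fit$coefficients[["t_induced"]] > 0)
  }
  expect_gte(ok / reps, 0.9)
})

test_that("zero-noise responses give degenerate regression bootstrap
           intervals", {
  s <- generate_dyad_study(study_config(n_pairs = 10, n_controls = 0),
                           seed = 77)
  rec <- s$records
  y <- 0.002 * rec$t_induced - 0.01 * rec$cort_induced + 0.05 * rec$svl
  bt <- dyad_bootstrap_regression(
    rec, stats::setNames(y, rec$individual_id), n_iter = 30, seed = 3)
  expect_lt(max(bt$upper - bt$lower), 1e-8)
  expect_equal(unname(bt$estimate),
               c(0, 0.002, -0.01, 0.05), tolerance = 1e-8)
})

test_that("a planted negative corticosterone effect on the colour composite
           is detected by the bootstrap interval", {
  reps <- 200
  ok <- 0
  for (r in seq_len(reps)) {
    s <- generate_dyad_study(study_config(), seed = 1300 + r)
    soc <- s$records[s$records$group == "social", ]
    comp <- as.numeric(scale(soc$max_dorsal_jnd) +
                         scale(soc$max_lateral_jnd))
    bt <- dyad_bootstrap_regression(
      soc, stats::setNames(comp, soc$individual_id),
      n_iter = 100, seed = 2300 + r)
    ok <- ok + (bt$upper[["cort_induced"]] < 0)
  }
  expect_gte(ok / reps, 0.9)
})
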