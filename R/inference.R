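# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Bartlett's test of sphericity
#'
#' Tests whether the Pearson correlation matrix of a trait matrix is the
#' identity (no associations to summarise - a pre-condition check for
#' PCA): \eqn{\chi^2 = -(n - 1 - (2p+5)/6)\,\ln\det R} on
#' \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param x Numeric matrix or data frame, n rows > p columns, complete.
#' @return List with `chi2`, `df`, `p_value`, `n`, `p`.
#' @export
bartlett_sphericity <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix must be complete", call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("need more rows than columns", call. = FALSE)
  R <- stats::cor(x)
  detR <- det(R)
  if (!is.finite(detR) || detR <= 1e-12) {
    stop("singular correlation matrix", call. = FALSE)
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = unname(chi2), df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE), n = n, p = p)
}

#' Principal component analysis of the trait matrix
#'
#' Eigendecomposition of the correlation matrix (`scale = TRUE`, the
#' default - the five traits mix counts, mm^2 and JND, so unit-variance
#' scaling prevents any one unit system dominating) or of the covariance
#' matrix. Components are ordered by decreasing eigenvalue and each
#' loading column is flipped so its largest-magnitude entry is positive
#' (a deterministic sign convention; eigenvector signs are otherwise
#' arbitrary).
#'
#' @param x Numeric matrix or data frame, complete, n rows > p columns.
#' @param scale Use the correlation matrix? Default `TRUE`.
#' @param k Number of retained components for reporting; default 2.
#' @return An object of class `signal_pca`: list with `loadings` (p x p,
#'   unit-norm columns), `eigenvalues`, `variance_share` (percent, all p
#'   components), `scores` (n x p), `k`, `center`, `scale_`, `bartlett`.
#' @export
fit_pca <- function(x, scale = TRUE, k = 2) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells: apply PCA-stage exclusions first",
                     call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("need more rows than columns", call. = FALSE)
  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, stats::sd) else rep(1, p)
  if (any(scl == 0)) stop("constant column: cannot scale", call. = FALSE)
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  S <- crossprod(z) / (n - 1)   # correlation matrix when scale = TRUE
  eg <- eigen(S, symmetric = TRUE)
  L <- eg$vectors
  for (j in seq_len(p)) {
    m <- which.max(abs(L[, j]))
    if (L[m, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(x), paste0("PC", seq_len(p)))
  scores <- z %*% L
  structure(list(loadings = L, eigenvalues = eg$values,
                 variance_share = 100 * eg$values / sum(eg$values),
                 scores = scores, k = k, center = ctr, scale_ = scl,
                 scaled = scale,
                 bartlett = tryCatch(bartlett_sphericity(x),
                                     error = function(e) NULL),
                 n = n),
            class = "signal_pca")
}

#' @export
print.signal_pca <- function(x, ...) {
  k <- x$k
  cat(sprintf("Principal component analysis (n = %d, %s matrix)\n", x$n,
              if (x$scaled) "correlation" else "covariance"))
  if (is.null(x$bartlett)) {
    cat("Bartlett sphericity: unavailable (singular correlation matrix)\n")
  } else {
    cat(sprintf("Bartlett sphericity: chi2 = %.2f, df = %d, p = %.3g\n",
                x$bartlett$chi2, x$bartlett$df, x$bartlett$p_value))
  }
  for (j in seq_len(k)) {
    cat(sprintf("PC%d: %.1f%% of variance\n", j, x$variance_share[j]))
  }
  cat("\nLoadings (retained components):\n")
  print(round(x$loadings[, seq_len(k), drop = FALSE], 3))
  invisible(x)
}

#' @export
summary.signal_pca <- function(object, ...) {
  print(object)
  cat("\nAll variance shares (%):\n")
  print(round(object$variance_share, 2))
  invisible(object)
}

#' @export
predict.signal_pca <- function(object, newdata, ...) {
  z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale_,
             "/")
  z %*% object$loadings
}

# Align a bootstrap loading matrix to the reference columns: components
# are matched greedily by largest |dot product| (a subsample's component
# order can differ from the full data's when eigenvalues are close), then
# each matched column is sign-flipped if its dot product with the
# reference is negative. Both indeterminacies would otherwise corrupt
# percentile intervals.
align_loadings <- function(L, ref) {
  k <- ncol(ref)
  d <- crossprod(L, ref)                 # p_fit x k dot products
  out <- matrix(NA_real_, nrow(ref), k, dimnames = dimnames(ref))
  used <- logical(nrow(d))
  for (step in seq_len(k)) {
    a <- abs(d)
    a[used, ] <- -Inf
    a[, colSums(!is.na(out)) > 0] <- -Inf
    pos <- arrayInd(which.max(a), dim(a))
    i <- pos[1L]
    j <- pos[2L]
    out[, j] <- if (d[i, j] < 0) -L[, i] else L[, i]
    used[i] <- TRUE
  }
  out
}

# Draw one individual per pair (controls dropped). Returns row indices
# into `records`.
sample_one_per_pair <- function(records) {
  soc <- which(records$group == "social")
  if (!length(soc)) stop("no social records", call. = FALSE)
  idx <- split(soc, records$pair_id[soc])
  bad <- vapply(idx, length, 0L) != 2L
  if (any(bad)) {
    stop("pair(s) without both members present: ",
         paste(names(idx)[bad], collapse = ", "), call. = FALSE)
  }
  vapply(idx, function(i) i[sample.int(2L, 1L)], 0L)
}

#' Dyad-aware bootstrap of the PCA loadings
#'
#' Traits are measured on both members of each dyad, so rows are not
#' independent. Each iteration keeps exactly one uniformly chosen member
#' of every pair (controls excluded), refits the PCA, aligns the fitted
#' components to the full-data reference loadings - components are matched
#' by largest absolute dot product (subsample component order can swap
#' when eigenvalues are close) and a matched column is flipped when its
#' dot product with the reference is negative - and collects the
#' loadings. Percentile 95% intervals are reported per loading.
#' Iterations whose subsample yields a singular correlation matrix are
#' redrawn (at most `10 * n_iter` attempts in total).
#'
#' @param records Data frame of PCA-stage records with intact pairs.
#' @param n_iter Bootstrap iterations; default 100.
#' @param seed Integer seed; draws are reproducible given the same seed.
#' @param scale,k Passed to [fit_pca()].
#' @return An object of class `dyad_boot`: list with `reference`
#'   (full-data `signal_pca`), `estimate`, `lower`, `upper` (p x k
#'   matrices), `draws` (n_iter x (p*k)), `n_iter`, `seed`,
#'   `n_redraws`.
#' @export
dyad_bootstrap_pca <- function(records, n_iter = 100, seed = NULL,
                               scale = TRUE, k = 2) {
  validate_trait_source(records)
  full <- fit_pca(build_trait_matrix(records[records$group == "social", ,
                                             drop = FALSE]),
                  scale = scale, k = k)
  ref <- full$loadings[, seq_len(k), drop = FALSE]
  p <- nrow(ref)
  draws <- matrix(NA_real_, n_iter, p * k)
  colnames(draws) <- paste(rep(rownames(ref), k),
                           rep(colnames(ref), each = p), sep = ".")
  n_redraws <- 0L
  with_seed(seed, {
    it <- 1L
    attempts <- 0L
    while (it <= n_iter) {
      attempts <- attempts + 1L
      if (attempts > 10L * n_iter) {
        stop("too many singular bootstrap subsamples", call. = FALSE)
      }
      idx <- sample_one_per_pair(records)
      fit <- tryCatch(
        fit_pca(build_trait_matrix(records[idx, , drop = FALSE]),
                scale = scale, k = k),
        error = function(e) NULL)
      if (is.null(fit)) {
        n_redraws <- n_redraws + 1L
        next
      }
      draws[it, ] <- as.numeric(align_loadings(fit$loadings, ref))
      it <- it + 1L
    }
  })
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  shape <- function(v) matrix(v, p, k, dimnames = dimnames(ref))
  structure(list(reference = full, estimate = ref,
                 lower = shape(qs[1L, ]), upper = shape(qs[2L, ]),
                 draws = draws, n_iter = n_iter, seed = seed,
                 n_redraws = n_redraws, what = "PCA loadings"),
            class = "dyad_boot")
}

#' @export
print.dyad_boot <- function(x, ...) {
  cat(sprintf("One-per-pair bootstrap of %s (%d iterations%s)\n", x$what,
              x$n_iter,
              if (is.null(x$seed)) "" else paste0(", seed ", x$seed)))
  est <- as.numeric(x$estimate)
  tab <- data.frame(estimate = round(est, 4),
                    lower = round(as.numeric(x$lower), 4),
                    upper = round(as.numeric(x$upper), 4))
  rownames(tab) <- if (is.matrix(x$estimate)) {
    paste(rep(rownames(x$estimate), ncol(x$estimate)),
          rep(colnames(x$estimate), each = nrow(x$estimate)), sep = ".")
  } else names(x$estimate)
  print(tab)
  invisible(x)
}

#' Hormone-signal regression
#'
#' Ordinary least squares of a composite signalling score (a PC score) on
#' interaction-induced testosterone and corticosterone (ng/ml) with
#' snout-vent length (mm) as covariate, all untransformed. Two-tailed
#' p-values on n - 4 degrees of freedom.
#'
#' @param score Numeric response vector (per-individual PC score).
#' @param t_induced,cort_induced,svl Predictor vectors, same length.
#' @param response Label for the response; default `"PC"`.
#' @return An object of class `hormone_reg`: list with `coefficients`,
#'   `se`, `t_values`, `p_values` (each length 4: intercept, t_induced,
#'   cort_induced, svl), `n`, `response`, `fit` (the underlying `lm`).
#' @export
fit_hormone_regression <- function(score, t_induced, cort_induced, svl,
                                   response = "PC") {
  d <- data.frame(score = score, t_induced = t_induced,
                  cort_induced = cort_induced, svl = svl)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 6L) stop("need at least 6 complete cases", call. = FALSE)
  X <- stats::model.matrix(~ t_induced + cort_induced + svl, d)
  if (kappa(X, exact = TRUE) > 1e10) {
    stop("collinear design: condition number exceeds 1e10", call. = FALSE)
  }
  fit <- stats::lm(score ~ t_induced + cort_induced + svl, data = d)
  # summary.lm warns on numerically perfect fits; those are legitimate
  # inputs here (noise-free planted responses)
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(coefficients = sm[, 1L], se = sm[, 2L],
                 t_values = sm[, 3L], p_values = sm[, 4L],
                 n = nrow(d), response = response, fit = fit),
            class = "hormone_reg")
}

#' @export
print.hormone_reg <- function(x, ...) {
  cat(sprintf("Hormone-signal regression, response %s (n = %d)\n",
              x$response, x$n))
  print(round(cbind(coef = x$coefficients, se = x$se, t = x$t_values,
                    p = x$p_values), 4))
  invisible(x)
}

#' @export
coef.hormone_reg <- function(object, ...) object$coefficients

#' @export
residuals.hormone_reg <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.hormone_reg <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}

#' Dyad-aware bootstrap of the regression coefficients
#'
#' Same one-individual-per-pair resampling scheme as
#' [dyad_bootstrap_pca()], applied to the hormone-signal regression:
#' each iteration keeps one uniformly chosen member per pair, refits the
#' OLS on that subsample's scores and predictors, and collects the four
#' coefficients. Percentile 95% intervals are reported.
#'
#' @param records Data frame of PCA-stage records with intact pairs and
#'   columns `t_induced`, `cort_induced`, `svl`.
#' @param scores Named numeric vector of per-individual scores (names =
#'   `individual_id`), e.g. one column of `fit_pca()$scores`.
#' @param n_iter Bootstrap iterations; default 100.
#' @param seed Integer seed.
#' @param response Label for reporting.
#' @return A `dyad_boot` object whose `estimate`, `lower`, `upper` are
#'   named length-4 vectors.
#' @export
dyad_bootstrap_regression <- function(records, scores, n_iter = 100,
                                      seed = NULL, response = "PC") {
  if (is.null(names(scores))) {
    stop("`scores` must be named by individual_id", call. = FALSE)
  }
  soc <- records[records$group == "social", , drop = FALSE]
  miss <- setdiff(soc$individual_id, names(scores))
  if (length(miss)) {
    stop("no score for individual(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  full <- fit_hormone_regression(scores[soc$individual_id], soc$t_induced,
                                 soc$cort_induced, soc$svl,
                                 response = response)
  cn <- names(full$coefficients)
  draws <- matrix(NA_real_, n_iter, length(cn), dimnames = list(NULL, cn))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- sample_one_per_pair(records)
      sub <- records[idx, , drop = FALSE]
      fit <- fit_hormone_regression(scores[sub$individual_id],
                                    sub$t_induced, sub$cort_induced,
                                    sub$svl, response = response)
      draws[it, ] <- fit$coefficients
    }
  })
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  structure(list(reference = full, estimate = full$coefficients,
                 lower = stats::setNames(qs[1L, ], cn),
                 upper = stats::setNames(qs[2L, ], cn),
                 draws = draws, n_iter = n_iter, seed = seed,
                 n_redraws = 0L,
                 what = sprintf("regression coefficients (%s)", response)),
            class = "dyad_boot")
}
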