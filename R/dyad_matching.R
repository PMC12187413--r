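#' Mean within-pair absolute difference
#'
#' The matching statistic: the mean over pairs of \eqn{|v_i - v_j|}.
#' Absolute differences are used because dyad members have no meaningful
#' order, so a signed difference would be direction-meaningless.
#'
#' @param values Named numeric vector (names are individual ids).
#' @param pairing Two-column matrix or data frame of ids, one row per
#'   pair; every id must have a value.
#' @return Nonnegative scalar.
#' @export
pair_mean_difference <- function(values, pairing) {
  pairing <- as.matrix(pairing)
  if (ncol(pairing) != 2L) stop("`pairing` must have two columns",
                                call. = FALSE)
  ids <- as.character(pairing)
  if (anyDuplicated(ids)) stop("an id appears in more than one pair",
                               call. = FALSE)
  v1 <- values[as.character(pairing[, 1L])]
  v2 <- values[as.character(pairing[, 2L])]
  if (anyNA(v1) || anyNA(v2)) {
    stop("missing value for a paired id", call. = FALSE)
  }
  mean(abs(v1 - v2))
}

#' Random perfect matchings
#'
#' Draws `n_perm` uniform random perfect matchings of an even-sized id
#' set: ids are shuffled and consecutive ids paired. The original pairing
#' is not excluded (doing so would bias the null).
#'
#' @param ids Character or numeric vector of ids, even length >= 2.
#' @param n_perm Number of matchings; default 1000.
#' @param seed Integer seed for reproducibility.
#' @return List of `n_perm` two-column character matrices.
#' @export
random_pairings <- function(ids, n_perm = 1000, seed = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 2L || n %% 2L != 0L) {
    stop("need an even number (>= 2) of ids", call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_perm), function(k) {
      s <- sample(ids)
      cbind(s[seq(1L, n, 2L)], s[seq(2L, n, 2L)])
    })
  })
}

#' Permutation test of opponent trait-matching
#'
#' Do dyad members express more similar trait values than random pairs of
#' individuals would? The observed statistic is the mean within-pair
#' absolute difference under the true pairing; the null sample recomputes
#' it under `n_perm` random re-pairings. Because matching means a
#' *smaller* difference than random, the default tail is lower:
#' \deqn{p = \frac{1 + \#\{d_{null} \le d_{obs}\}}{n_{perm} + 1}}
#' (add-one correction, so p is never 0).
#'
#' Two null models are available: `"matching"` (default) draws uniform
#' random perfect matchings of all individuals; `"column"` keeps the
#' first member of every true pair fixed and permutes the second members
#' among pairs (a column permutation of the pair table).
#'
#' @param values Named numeric vector of trait values.
#' @param pairing True pairing: two-column matrix/data frame of ids.
#' @param n_perm Number of permutations; default 1000.
#' @param seed Integer seed.
#' @param alternative `"less"` (default; matching) or `"two.sided"`.
#' @param null Null model, `"matching"` or `"column"`.
#' @return An object of class `matching_test`: list with `trait`,
#'   `observed`, `null` (numeric, length `n_perm`), `p_value`, `n_perm`,
#'   `n_pairs`, `alternative`, `null_model`, `seed`.
#' @export
matching_test <- function(values, pairing, n_perm = 1000, seed = NULL,
                          alternative = c("less", "two.sided"),
                          null = c("matching", "column"), trait = NULL) {
  alternative <- match.arg(alternative)
  null <- match.arg(null)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  pairing <- as.matrix(pairing)
  observed <- pair_mean_difference(values, pairing)
  ids <- as.character(pairing)
  v <- values[ids]
  n <- length(v)
  npair <- n %/% 2L
  i1 <- seq(1L, n, 2L)
  i2 <- seq(2L, n, 2L)
  nulls <- with_seed(seed, {
    if (null == "matching") {
      vapply(seq_len(n_perm), function(k) {
        s <- sample.int(n)
        mean(abs(v[s[i1]] - v[s[i2]]))
      }, numeric(1))
    } else {
      a <- values[as.character(pairing[, 1L])]
      b <- values[as.character(pairing[, 2L])]
      vapply(seq_len(n_perm), function(k) {
        mean(abs(a - b[sample.int(npair)]))
      }, numeric(1))
    }
  })
  p_lower <- (1 + sum(nulls <= observed)) / (n_perm + 1)
  p <- if (alternative == "less") p_lower else {
    p_upper <- (1 + sum(nulls >= observed)) / (n_perm + 1)
    min(1, 2 * min(p_lower, p_upper))
  }
  structure(list(trait = trait, observed = observed, null = nulls,
                 p_value = p, n_perm = n_perm, n_pairs = npair,
                 alternative = alternative, null_model = null,
                 seed = seed),
            class = "matching_test")
}

#' @export
print.matching_test <- function(x, ...) {
  cat(sprintf(
    "Opponent-matching permutation test%s\n",
    if (is.null(x$trait)) "" else paste0(" - ", x$trait)))
  cat(sprintf(
    "observed mean |within-pair diff| = %.4g (null mean %.4g), p = %.4g\n",
    x$observed, mean(x$null), x$p_value))
  cat(sprintf("%d pairs, %d permutations (%s null, %s-tailed)\n",
              x$n_pairs, x$n_perm, x$null_model,
              if (x$alternative == "less") "lower" else "two"))
  invisible(x)
}

#' @export
plot.matching_test <- function(x, ...) {
  graphics::hist(x$null, breaks = 30, main = if (is.null(x$trait))
    "Permutation null" else paste("Permutation null -", x$trait),
    xlab = "mean |within-pair difference|", col = "grey85", border = "white",
    xlim = range(c(x$null, x$observed)), ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  invisible(x)
}

#' Matching tests across traits of a record table
#'
#' Runs [matching_test()] for each named trait over the social pairs in a
#' record table, using only pairs whose both members have the trait
#' (pairwise-complete). Per-trait seeds are derived from `seed` so traits
#' are independent but reproducible.
#'
#' @param records Record data frame (see [apply_exclusions()]).
#' @param traits Character vector of trait column names; `uv_area_total`
#'   is computed on the fly.
#' @param n_perm,seed,alternative,null Passed to [matching_test()].
#' @return Named list of `matching_test` objects.
#' @export
matching_tests <- function(records,
                           traits = c("headbob", "shudder",
                                      "max_dorsal_jnd", "max_lateral_jnd"),
                           n_perm = 1000, seed = NULL,
                           alternative = "less", null = "matching") {
  soc <- records[records$group == "social" & !is.na(records$pair_id), ,
                 drop = FALSE]
  out <- lapply(seq_along(traits), function(ti) {
    tr <- traits[ti]
    vals <- if (tr == "uv_area_total") {
      total_uv_area(soc$uv_area_left, soc$uv_area_right)
    } else soc[[tr]]
    names(vals) <- soc$individual_id
    # keep only intact pairs (both members present, both values observed):
    # upstream exclusions can drop one member of a pair
    full <- tapply(seq_along(vals), soc$pair_id, function(i) {
      length(i) == 2L && !anyNA(vals[i])
    })
    sub <- soc[soc$pair_id %in% names(full)[full], , drop = FALSE]
    pairing <- do.call(rbind, lapply(split(sub$individual_id, sub$pair_id),
                                     function(x) x[1:2]))
    matching_test(vals, pairing, n_perm = n_perm,
                  seed = if (is.null(seed)) NULL else
                    derive_seed(seed, paste0("match_", tr)),
                  alternative = alternative, null = null, trait = tr)
  })
  names(out) <- traits
  out
}
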