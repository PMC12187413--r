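# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# all perfect matchings of an even id set, as a list of 2-column matrices
enumerate_matchings <- function(ids) {
  n <- length(ids)
  if (n == 2L) return(list(matrix(ids, 1L, 2L)))
  first <- ids[1L]
  out <- list()
  for (j in 2:n) {
    rest <- ids[-c(1L, j)]
    for (m in enumerate_matchings(rest)) {
      out[[length(out) + 1L]] <- rbind(c(first, ids[j]), m)
    }
  }
  out
}

# exact lower-tail matching p over the exhaustive null (no add-one term:
# this is the true null probability P(d_null <= d_obs))
exhaustive_matching_p <- function(values, pairing) {
  obs <- mean(abs(values[pairing[, 1L]] - values[pairing[, 2L]]))
  ms <- enumerate_matchings(names(values))
  ds <- vapply(ms, function(m) mean(abs(values[m[, 1L]] - values[m[, 2L]])),
               numeric(1))
  mean(ds <= obs + 1e-12)
}

# direct term-by-term trichromatic RNL formula
trichromat_ds <- function(qa, qb, e) {
  df <- log(qa) - log(qb)
  num <- e[1L]^2 * (df[3L] - df[2L])^2 +
    e[2L]^2 * (df[3L] - df[1L])^2 +
    e[3L]^2 * (df[1L] - df[2L])^2
  den <- (e[1L] * e[2L])^2 + (e[1L] * e[3L])^2 + (e[2L] * e[3L])^2
  unname(sqrt(num / den))
}

# trapezoid quadrature of the product of linear interpolants on a fine grid
fine_grid_catch <- function(reflectance, illuminant, sens, step = 0.1) {
  lo <- max(min(reflectance$wavelengths), min(illuminant$wavelengths),
            min(sens$wavelengths))
  hi <- min(max(reflectance$wavelengths), max(illuminant$wavelengths),
            max(sens$wavelengths))
  x <- seq(lo, hi, by = step)
  f <- stats::approx(reflectance$wavelengths, reflectance$values, x)$y *
    stats::approx(illuminant$wavelengths, illuminant$values, x)$y *
    stats::approx(sens$wavelengths, sens$values, x)$y
  sum(diff(x) * (f[-length(f)] + f[-1L]) / 2)
}

# characteristic-polynomial eigenvalues via Faddeev-LeVerrier + polyroot
charpoly_eigenvalues <- function(S) {
  p <- nrow(S)
  coefs <- numeric(p + 1L)
  coefs[1L] <- 1
  M <- diag(p)
  for (k in seq_len(p)) {
    M <- S %*% M
    c_k <- -sum(diag(M)) / k
    coefs[k + 1L] <- c_k
    M <- M + c_k * diag(p)
  }
  # polyroot takes ascending-order coefficients
  r <- polyroot(rev(coefs))
  sort(Re(r), decreasing = TRUE)
}

# small record table with two clone pairs + optional controls, for
# bootstrap degeneracy tests
make_clone_records <- function(n_pairs = 12, seed = 1) {
  set.seed(seed)
  one <- function(k) {
    tr <- c(headbob = rpois(1, 30), shudder = rpois(1, 20),
            dorsal = runif(1, 3, 9), lateral = runif(1, 3, 9),
            uvl = runif(1, 20, 60), uvr = runif(1, 20, 60))
    do.call(rbind, lapply(1:2, function(m) data.frame(
      individual_id = sprintf("p%02dm%d", k, m),
      pair_id = sprintf("pair%02d", k), group = "social",
      site_id = "site1", svl = 120,
      headbob = tr[["headbob"]], shudder = tr[["shudder"]],
      pushup = 0L, approach = 0L, attack = 0L, bite = 0L,
      max_dorsal_jnd = tr[["dorsal"]], max_lateral_jnd = tr[["lateral"]],
      uv_area_left = tr[["uvl"]], uv_area_right = tr[["uvr"]],
      t_baseline = 200, t_induced = runif(1, 100, 900),
      cort_baseline = 15, cort_induced = runif(1, 10, 90),
      atypical_shudder_flag = FALSE, stringsAsFactors = FALSE)))
  }
  do.call(rbind, lapply(seq_len(n_pairs), one))
}

# intraclass correlation by the double-entry estimator: members are
# unordered, so each pair enters in both orders
double_entry_icc <- function(values) {
  m1 <- values[seq(1, length(values), 2)]
  m2 <- values[seq(2, length(values), 2)]
  stats::cor(c(m1, m2), c(m2, m1))
}

behaviour_block <- c("headbob", "shudder", "uv_area_total")
colour_block <- c("max_dorsal_jnd", "max_lateral_jnd")

# identify the component (of the first two) dominated by each trait block
identify_blocks <- function(loadings) {
  L <- abs(loadings[, 1:2, drop = FALSE])
  pcb <- which.max(colMeans(L[behaviour_block, ]))
  pcc <- which.max(colMeans(L[colour_block, ]))
  separated <- pcb != pcc &&
    mean(L[behaviour_block, pcb]) > mean(L[colour_block, pcb]) &&
    mean(L[colour_block, pcc]) > mean(L[behaviour_block, pcc])
  list(behaviour = pcb, colour = pcc, separated = separated)
}
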