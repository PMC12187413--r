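#' Configuration for a synthetic dyadic study
#'
#' Defines the statistical structure of a simulated staged-contest study:
#' 23 size-matched dyads plus 9 single-lizard controls by default,
#' mirroring the study design the analysis targets. Opponent matching is
#' modelled as shared pair-level variance: for each trait the configured
#' `icc` is the intraclass correlation *of the emitted trait value*. For
#' the continuous traits the latent pair share equals the icc directly;
#' for the Poisson count traits the latent pair share is calibrated
#' analytically (lognormal-Poisson moment inversion) so the count itself
#' carries the configured icc.
#'
#' Each trait's unit-variance latent decomposes into pair share +
#' block-factor share + hormone-driven share + free residual. The
#' behaviour block (headbob, shudder, UV) and the colour block (dorsal,
#' lateral) each share an individual-level factor, and hormones load with
#' the configured signs: testosterone positively on the behaviour+UV
#' block, negatively on the colour block; corticosterone negatively on
#' the colour block only.
#'
#' @param n_pairs Number of dyads; default 23.
#' @param n_controls Number of single-lizard controls; default 9.
#' @param icc Named intraclass correlations per trait, in \[0, 1).
#' @param beta Named standardized hormone effect sizes:
#'   `t_behaviour` (+), `t_colour` (-), `c_colour` (-), `c_behaviour`
#'   (0 by default).
#' @param block_var Named variance shares of the within-block individual
#'   factors (`behaviour`, `colour`).
#' @param pair_cor Correlation, within each block, between the pair-level
#'   components of different traits (a shared "contest intensity": a pair
#'   that escalates does so across its displays). Does not change any
#'   trait's marginal icc.
#' @param counts Count-model parameters: `log_mean` and `slope` per count
#'   trait (Poisson log link), and `dispersion` (gamma overdispersion
#'   variance; 0 = pure Poisson).
#' @param jnd_map Affine maps from latent to JND for dorsal/lateral
#'   (intercept, slope), floored at `floor`.
#' @param uv_map Lognormal map for total UV area (mm^2): `log_median`,
#'   `slope`.
#' @param hormones Lognormal parameters (ng/ml): `t_log_median`,
#'   `t_sdlog`, `c_log_median`, `c_sdlog`, baseline medians and the
#'   baseline-induced correlation `baseline_cor`. Corticosterone baseline
#'   sits below its induced level (a stress response to the trial);
#'   testosterone baseline equals its induced median (no rise).
#' @param svl_range Snout-vent length range in mm; pair members differ by
#'   at most 3 mm.
#' @param control_colour_shift Shift (latent sd units) of control
#'   individuals' colour latents; controls display weaker contrasts.
#' @param exclusions Planted exclusion counts `c(hormone, flag, missing)`;
#'   default `c(0, 0, 0)`.
#' @param seed Default seed used by [generate_dyad_study()] when none is
#'   passed.
#' @return An object of class `study_config` (a validated list).
#' @export
study_config <- function(n_pairs = 23, n_controls = 9,
                         icc = c(headbob = 0.5, shudder = 0.5,
                                 dorsal = 0.5, lateral = 0, uv = 0.2),
                         beta = c(t_behaviour = 0.4, t_colour = -0.4,
                                  c_colour = -0.5, c_behaviour = 0),
                         block_var = c(behaviour = 0.22, colour = 0.08),
                         pair_cor = 0.5,
                         counts = list(
                           headbob = c(log_mean = log(35), slope = 0.5),
                           shudder = c(log_mean = log(20), slope = 0.5),
                           dispersion = 0),
                         jnd_map = list(
                           dorsal = c(intercept = 5.5, slope = 1.6),
                           lateral = c(intercept = 6.5, slope = 1.8),
                           floor = 0.1),
                         uv_map = c(log_median = log(80), slope = 0.35),
                         hormones = c(t_log_median = log(300), t_sdlog = 0.6,
                                      c_log_median = log(40), c_sdlog = 0.5,
                                      t_base_log_median = log(300),
                                      c_base_log_median = log(15),
                                      baseline_cor = 0.5),
                         svl_range = c(112, 137),
                         control_colour_shift = -0.9,
                         exclusions = c(hormone = 0, flag = 0, missing = 0),
                         seed = NULL) {
  cfg <- list(n_pairs = n_pairs, n_controls = n_controls, icc = icc,
              beta = beta, block_var = block_var, pair_cor = pair_cor,
              counts = counts,
              jnd_map = jnd_map, uv_map = uv_map, hormones = hormones,
              svl_range = svl_range,
              control_colour_shift = control_colour_shift,
              exclusions = exclusions, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "study_config")
}

trait_names <- function() c("headbob", "shudder", "dorsal", "lateral", "uv")

# hormone loadings (beta_T, beta_C) per trait given the config
trait_betas <- function(cfg) {
  b <- cfg$beta
  rbind(headbob = c(b[["t_behaviour"]], b[["c_behaviour"]]),
        shudder = c(b[["t_behaviour"]], b[["c_behaviour"]]),
        uv      = c(b[["t_behaviour"]], 0),
        dorsal  = c(b[["t_colour"]], b[["c_colour"]]),
        lateral = c(b[["t_colour"]], b[["c_colour"]]))
}

trait_block <- function() {
  c(headbob = "behaviour", shudder = "behaviour", uv = "behaviour",
    dorsal = "colour", lateral = "colour")
}

# latent pair-variance share giving a count trait the target icc under
# counts = Poisson(exp(a + b * latent)), latent ~ N(0, 1):
#   icc_count = (e^{b^2 rho_lat} - 1) / ((e^{b^2} - 1) + e^{-a - b^2/2})
count_pair_share <- function(rho, a, b) {
  if (rho == 0) return(0)
  log(1 + rho * ((exp(b^2) - 1) + exp(-a - b^2 / 2))) / b^2
}

# per-trait latent variance decomposition for a config
latent_shares <- function(cfg) {
  tb <- trait_betas(cfg)
  blk <- trait_block()
  out <- lapply(trait_names(), function(tr) {
    rho <- cfg$icc[[tr]]
    pair <- if (tr %in% c("headbob", "shudder")) {
      cm <- cfg$counts[[tr]]
      count_pair_share(rho, cm[["log_mean"]], cm[["slope"]])
    } else rho
    hb <- sum(tb[tr, ]^2)
    bv <- cfg$block_var[[blk[[tr]]]]
    resid <- 1 - pair - bv - hb
    c(pair = pair, block = bv, hormone = hb, resid = resid)
  })
  names(out) <- trait_names()
  out
}

validate_config <- function(cfg) {
  if (cfg$n_pairs < 4) stop("need at least 4 pairs", call. = FALSE)
  if (cfg$n_controls < 0) stop("n_controls must be >= 0", call. = FALSE)
  if (!all(trait_names() %in% names(cfg$icc))) {
    stop("icc must name all of: ", paste(trait_names(), collapse = ", "),
         call. = FALSE)
  }
  if (any(cfg$icc < 0 | cfg$icc >= 1)) {
    stop("icc values must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$counts$dispersion < 0) stop("dispersion must be >= 0",
                                      call. = FALSE)
  if (cfg$pair_cor < 0 || cfg$pair_cor > 1) {
    stop("pair_cor must lie in [0, 1]", call. = FALSE)
  }
  sh <- latent_shares(cfg)
  bad <- names(sh)[vapply(sh, function(s) s[["resid"]] < -1e-12, TRUE)]
  if (length(bad)) {
    stop("latent variance over-committed (pair + block + hormone shares ",
         "exceed 1) for trait(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(cfg$svl_range) != 2L || diff(cfg$svl_range) < 3) {
    stop("svl_range must span at least 3 mm", call. = FALSE)
  }
  k <- sum(cfg$exclusions)
  if (k > 2 * cfg$n_pairs) {
    stop("more planted exclusions than social individuals", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic dyadic study
#'
#' Simulates a full record table (social dyads + controls) with the
#' statistical structure described in [study_config()], plus a ground
#' truth sufficient to verify every downstream stage: the latent pair
#' components, per-individual latents, the planted hormone effects, and
#' any planted exclusion ids. Fully deterministic given `seed`.
#'
#' @param config A `study_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List with `records` (data frame in the record schema) and
#'   `truth` (list: `latents`, `pair_components`, `z_t`, `z_c`,
#'   `betas`, `icc`, `planted_exclusions`, `config`).
#' @export
generate_dyad_study <- function(config = study_config(), seed = NULL) {
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    cfg <- config
    n_soc <- 2L * cfg$n_pairs
    n_all <- n_soc + cfg$n_controls
    ids <- sprintf("ind%02d", seq_len(n_all))
    group <- rep(c("social", "control"), c(n_soc, cfg$n_controls))
    pair_id <- c(rep(sprintf("pair%02d", seq_len(cfg$n_pairs)), each = 2L),
                 rep(NA_character_, cfg$n_controls))
    pair_index <- c(rep(seq_len(cfg$n_pairs), each = 2L),
                    rep(NA_integer_, cfg$n_controls))
    site_id <- sprintf("site%d", sample.int(4L, n_all, replace = TRUE))

    shares <- latent_shares(cfg)
    tb <- trait_betas(cfg)
    blk <- trait_block()

    # induced-testosterone z is truncated at +-3 sd so that natural draws
    # can never cross the 2000 ng/ml exclusion cutoff: assay outliers in a
    # synthetic study are exactly the planted ones, keeping the exclusion
    # ground truth well-defined
    z_t <- pmin(pmax(stats::rnorm(n_all), -3), 3)
    z_c <- stats::rnorm(n_all)
    f_block <- list(behaviour = stats::rnorm(n_all),
                    colour = stats::rnorm(n_all))
    # standard-normal pair components; within each block they share a
    # pair-level "contest intensity" factor with correlation pair_cor
    # (escalation couples a pair's displays across traits), across blocks
    # they are independent. Each trait's marginal pair share - hence its
    # icc and the matching test's behaviour - is unaffected.
    r <- cfg$pair_cor
    pair_comp <- matrix(NA_real_, cfg$n_pairs, length(trait_names()),
                        dimnames = list(NULL, trait_names()))
    blk0 <- trait_block()
    for (b in unique(blk0)) {
      g <- stats::rnorm(cfg$n_pairs)
      for (tr in names(blk0)[blk0 == b]) {
        pair_comp[, tr] <- sqrt(r) * g +
          sqrt(1 - r) * stats::rnorm(cfg$n_pairs)
      }
    }

    latents <- sapply(trait_names(), function(tr) {
      s <- shares[[tr]]
      pc <- ifelse(is.na(pair_index), 0,
                   sqrt(s[["pair"]]) * pair_comp[pair_index, tr])
      x <- pc +
        sqrt(s[["block"]]) * f_block[[blk[[tr]]]] +
        tb[tr, 1L] * z_t + tb[tr, 2L] * z_c +
        sqrt(max(s[["resid"]], 0)) * stats::rnorm(n_all)
      if (blk[[tr]] == "colour") {
        x <- x + ifelse(group == "control", cfg$control_colour_shift, 0)
      }
      x
    })

    rpois_od <- function(mu, disp) {
      if (disp > 0) mu <- mu * stats::rgamma(length(mu), shape = 1 / disp,
                                             scale = disp)
      stats::rpois(length(mu), mu)
    }
    cm <- cfg$counts
    headbob <- rpois_od(exp(cm$headbob[["log_mean"]] +
                              cm$headbob[["slope"]] * latents[, "headbob"]),
                        cm$dispersion)
    shudder <- rpois_od(exp(cm$shudder[["log_mean"]] +
                              cm$shudder[["slope"]] * latents[, "shudder"]),
                        cm$dispersion)
    # controls did not display headbobs or shudders
    headbob[group == "control"] <- 0L
    shudder[group == "control"] <- 0L
    # ancillary behaviours: recorded but never analysed
    pushup <- stats::rpois(n_all, 2)
    approach <- stats::rpois(n_all, 3)
    attack <- stats::rpois(n_all, 1)
    bite <- stats::rpois(n_all, 0.3)
    pushup[group == "control"] <- 0L
    approach[group == "control"] <- 0L
    attack[group == "control"] <- 0L
    bite[group == "control"] <- 0L

    jm <- cfg$jnd_map
    dorsal <- pmax(jm$floor, jm$dorsal[["intercept"]] +
                     jm$dorsal[["slope"]] * latents[, "dorsal"])
    lateral <- pmax(jm$floor, jm$lateral[["intercept"]] +
                      jm$lateral[["slope"]] * latents[, "lateral"])

    uv_total <- exp(cfg$uv_map[["log_median"]] +
                      cfg$uv_map[["slope"]] * latents[, "uv"])
    split_frac <- stats::runif(n_all, 0.45, 0.55)
    uv_left <- uv_total * split_frac
    uv_right <- uv_total - uv_left

    h <- cfg$hormones
    zt_base <- h[["baseline_cor"]] * z_t +
      sqrt(1 - h[["baseline_cor"]]^2) * stats::rnorm(n_all)
    zc_base <- h[["baseline_cor"]] * z_c +
      sqrt(1 - h[["baseline_cor"]]^2) * stats::rnorm(n_all)
    t_induced <- exp(h[["t_log_median"]] + h[["t_sdlog"]] * z_t)
    cort_induced <- exp(h[["c_log_median"]] + h[["c_sdlog"]] * z_c)
    t_baseline <- exp(h[["t_base_log_median"]] + h[["t_sdlog"]] * zt_base)
    cort_baseline <- exp(h[["c_base_log_median"]] + h[["c_sdlog"]] * zc_base)

    centre <- stats::runif(cfg$n_pairs, cfg$svl_range[1L] + 1.5,
                           cfg$svl_range[2L] - 1.5)
    svl <- c(rep(centre, each = 2L) + stats::runif(n_soc, -1.5, 1.5),
             stats::runif(cfg$n_controls, cfg$svl_range[1L],
                          cfg$svl_range[2L]))

    records <- data.frame(
      individual_id = ids, pair_id = pair_id, group = group,
      site_id = site_id, svl = svl,
      headbob = headbob, shudder = shudder, pushup = pushup,
      approach = approach, attack = attack, bite = bite,
      max_dorsal_jnd = dorsal, max_lateral_jnd = lateral,
      uv_area_left = uv_left, uv_area_right = uv_right,
      t_baseline = t_baseline, t_induced = t_induced,
      cort_baseline = cort_baseline, cort_induced = cort_induced,
      atypical_shudder_flag = FALSE, stringsAsFactors = FALSE)

    planted <- list(hormone = character(), flag = character(),
                    missing = character())
    if (sum(cfg$exclusions) > 0) {
      pl <- plant_exclusions(records, n_hormone = cfg$exclusions[["hormone"]],
                             n_flag = cfg$exclusions[["flag"]],
                             n_missing = cfg$exclusions[["missing"]],
                             seed = NULL)
      records <- pl$records
      planted <- pl$planted
    }

    truth <- list(latents = latents, pair_components = pair_comp,
                  z_t = z_t, z_c = z_c, betas = tb, icc = cfg$icc,
                  latent_shares = shares, planted_exclusions = planted,
                  config = cfg)
    list(records = records, truth = truth)
  })
}

#' Plant exclusion-rule violations in a record table
#'
#' Overwrites disjoint sets of social individuals to trigger each
#' downstream exclusion rule: induced testosterone above 2000 ng/ml,
#' the atypical-shudder flag, and one missing trait value (left UV area).
#'
#' @param records Record data frame.
#' @param n_hormone,n_flag,n_missing Counts per rule.
#' @param seed Integer seed (`NULL` = use the current RNG stream).
#' @return List with `records` (modified) and `planted` (list of id
#'   vectors `hormone`, `flag`, `missing`).
#' @export
plant_exclusions <- function(records, n_hormone = 3, n_flag = 2,
                             n_missing = 6, seed = NULL) {
  k <- n_hormone + n_flag + n_missing
  soc <- records$individual_id[records$group == "social"]
  if (k > length(soc)) {
    stop("more planted exclusions than social individuals", call. = FALSE)
  }
  with_seed(seed, {
    chosen <- sample(soc, k)
    ih <- chosen[seq_len(n_hormone)]
    ifl <- chosen[n_hormone + seq_len(n_flag)]
    im <- chosen[n_hormone + n_flag + seq_len(n_missing)]
    records$t_induced[records$individual_id %in% ih] <-
      2500 + 100 * seq_len(n_hormone)
    records$atypical_shudder_flag[records$individual_id %in% ifl] <- TRUE
    records$uv_area_left[records$individual_id %in% im] <- NA_real_
    list(records = records,
         planted = list(hormone = ih, flag = ifl, missing = im))
  })
}

#' Generate a synthetic colour-image series
#'
#' Emulates the per-trial photograph sequence: each image's reflectance is
#' a 40% grey baseline plus a Gaussian spectral bump of per-image
#' amplitude, so chromatic contrast against grey rises and falls with the
#' amplitude schedule. The ground-truth argmax is computed by brute force
#' through the visual model itself.
#'
#' @param n_images Number of images; the study took 6-10 per trial.
#' @param amplitudes Optional numeric vector of bump amplitudes (length
#'   `n_images`, nonnegative). Default: uniform draws on \[0.02, 0.25\]
#'   with one planted peak of 0.45 at a random index.
#' @param centre,sigma Bump centre and width in nm; defaults 560, 25.
#' @param seed Integer seed.
#' @param illuminant,sensitivities Viewing context; defaults
#'   [daylight_illuminant()] and [gaussian_sensitivities()].
#' @param noise A `receptor_noise`; default the study's cone ratios
#'   `0.06:0.08:0.15` at Weber fraction 0.05.
#' @param grey Grey reference level; default 0.40.
#' @return List with `reflectances` (list of `spectrum`), `catches`
#'   (list of `cone_catch`), `reference` (grey `cone_catch`), `noise`,
#'   and `truth` (list: `amplitudes`, `jnd`, `argmax`).
#' @export
generate_colour_series <- function(n_images = 8, amplitudes = NULL,
                                   centre = 560, sigma = 25, seed = NULL,
                                   illuminant = daylight_illuminant(),
                                   sensitivities = gaussian_sensitivities(),
                                   noise = receptor_noise(
                                     c(lw = 0.06, mw = 0.08, sw = 0.15)),
                                   grey = 0.40) {
  if (n_images < 1L) stop("need at least one image", call. = FALSE)
  with_seed(seed, {
    if (is.null(amplitudes)) {
      amplitudes <- stats::runif(n_images, 0.02, 0.25)
      amplitudes[sample.int(n_images, 1L)] <- 0.45
    }
    if (length(amplitudes) != n_images || any(amplitudes < 0)) {
      stop("`amplitudes` must be nonnegative, one per image", call. = FALSE)
    }
    wl <- illuminant$wavelengths
    bump <- exp(-((wl - centre)^2) / (2 * sigma^2))
    refl <- lapply(amplitudes, function(a)
      spectrum(wl, pmin(grey + a * bump, 1),
               label = sprintf("image amp %.3f", a)))
    catches <- lapply(refl, quantum_catches, illuminant = illuminant,
                      sensitivities = sensitivities)
    reference <- grey_reference(illuminant, sensitivities, grey)
    jnd <- vapply(catches, chromatic_contrast, numeric(1), b = reference,
                  noise = noise)
    list(reflectances = refl, catches = catches, reference = reference,
         noise = noise,
         truth = list(amplitudes = amplitudes, jnd = jnd,
                      argmax = which.max(jnd)))
  })
}
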