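#' Derive a labelled stage seed from a master seed
#'
#' Deterministic per-stage seed derivation: a labelled hash folded into
#' the master seed, so adding or reordering pipeline stages never shifts
#' another stage's random draws. [run_all()] derives each stage's seed as
#' `derive_seed(seed, "<stage label>")`; standalone stage calls with the
#' same derivation reproduce the pipeline's results exactly.
#'
#' @param master Integer master seed.
#' @param label Character stage label.
#' @return An integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((master %% 2147483647) * 48271 %% 2147483647 + h) %%
    2147483647L
}

#' Build a validated pipeline configuration
#'
#' Collects every fixed constant of the analysis in one place. Defaults
#' equal the study's printed values where one exists: cone ratios
#' 0.06:0.08:0.15, 40% grey reference, induced-testosterone cutoff 2000
#' ng/ml, 100 bootstrap iterations, 1000 permutations.
#'
#' @param records Either a record data frame, a path to a delimited
#'   record file, or `NULL` to simulate from `study`.
#' @param study A [study_config()] used when `records` is `NULL`.
#' @param cone_ratios Relative cone abundances (lw:mw:sw).
#' @param weber Weber fraction; default 0.05.
#' @param grey_reflectance Grey reference level; default 0.40.
#' @param hormone_cutoff Induced-testosterone exclusion cutoff (ng/ml).
#' @param n_boot Bootstrap iterations; default 100.
#' @param n_perm Matching-test permutations; default 1000.
#' @param alpha Gate / reporting level; default 0.05.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(records = NULL, study = study_config(),
                       cone_ratios = c(lw = 0.06, mw = 0.08, sw = 0.15),
                       weber = 0.05, grey_reflectance = 0.40,
                       hormone_cutoff = 2000, n_boot = 100, n_perm = 1000,
                       alpha = 0.05, seed = 1L) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (any(cone_ratios <= 0)) stop("cone ratios must be positive",
                                  call. = FALSE)
  if (weber <= 0 || weber >= 1) stop("weber must be in (0, 1)",
                                     call. = FALSE)
  if (grey_reflectance <= 0 || grey_reflectance > 1) {
    stop("grey_reflectance must be in (0, 1]", call. = FALSE)
  }
  if (hormone_cutoff <= 0) stop("hormone_cutoff must be positive",
                                call. = FALSE)
  structure(list(records = records, study = study,
                 cone_ratios = cone_ratios, weber = weber,
                 grey_reflectance = grey_reflectance,
                 hormone_cutoff = hormone_cutoff, n_boot = n_boot,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override [run_config()] defaults; the `study` block, if
#' present, overrides [study_config()] defaults.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  raw <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  study <- if (!is.null(raw$study)) {
    do.call(study_config, raw$study)
  } else study_config()
  args <- raw[setdiff(names(raw), "study")]
  known <- names(formals(run_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, c(args, list(study = study)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order on real or simulated records:
#' exclusions and trait assembly; normality-gated univariate comparisons
#' of social vs control trials and of baseline vs interaction-induced
#' hormone levels; PCA with Bartlett's sphericity test and the
#' one-per-pair bootstrap of its loadings; hormone-signal regressions on
#' PC1 and PC2 with bootstrapped coefficient intervals; and the
#' opponent-matching permutation tests. A stage that fails records its
#' error in the report and later independent stages still run. Fully
#' deterministic under a fixed master seed.
#'
#' @param config A [run_config()].
#' @return An object of class `dyad_report`: list with elements
#'   `exclusions`, `univariate`, `pca`, `pca_boot`, `regression`,
#'   `matching`, `errors`, `n`, `config`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  errors <- list()
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  records <- if (is.null(config$records)) {
    generate_dyad_study(config$study,
                        seed = derive_seed(config$seed, "simulate"))$records
  } else if (is.character(config$records)) {
    read_records(config$records)
  } else {
    validate_records(config$records)
  }

  excl_uni <- apply_exclusions(records, config$hormone_cutoff,
                               stage = "univariate")
  excl_pca <- apply_exclusions(records, config$hormone_cutoff,
                               stage = "pca")
  uni_rec <- excl_uni$records
  pca_rec <- excl_pca$records

  univariate <- try_stage("univariate", {
    soc <- uni_rec[uni_rec$group == "social", , drop = FALSE]
    ctl <- uni_rec[uni_rec$group == "control", , drop = FALSE]
    cmp <- function(trait) {
      gate <- shapiro_gate(c(soc[[trait]], ctl[[trait]]), config$alpha)
      res <- compare_groups(soc[[trait]], ctl[[trait]], paired = FALSE,
                            parametric = gate == "parametric")
      list(gate = gate, test = res)
    }
    paired_cmp <- function(d, base, ind) {
      compare_groups(d[[ind]], d[[base]], paired = TRUE,
                     parametric = FALSE)
    }
    list(
      dorsal = cmp("max_dorsal_jnd"),
      lateral = cmp("max_lateral_jnd"),
      t_induced = list(test = compare_groups(soc$t_induced, ctl$t_induced,
                                             parametric = FALSE)),
      cort_induced = list(test = compare_groups(soc$cort_induced,
                                                ctl$cort_induced,
                                                parametric = FALSE)),
      t_paired_social = paired_cmp(soc, "t_baseline", "t_induced"),
      cort_paired_social = paired_cmp(soc, "cort_baseline", "cort_induced"))
  })

  soc_pca <- pca_rec[pca_rec$group == "social", , drop = FALSE]
  # bootstrap needs intact pairs: keep pairs whose both members survived
  tab <- table(soc_pca$pair_id)
  soc_paired <- soc_pca[soc_pca$pair_id %in% names(tab)[tab == 2L], ,
                        drop = FALSE]

  pca <- try_stage("pca", fit_pca(build_trait_matrix(soc_pca)))
  pca_boot <- try_stage("pca_boot",
    dyad_bootstrap_pca(soc_paired, n_iter = config$n_boot,
                       seed = derive_seed(config$seed, "pca_boot")))

  regression <- try_stage("regression", {
    sc <- pca$scores
    lapply(stats::setNames(c("PC1", "PC2"), c("PC1", "PC2")), function(pc) {
      scores <- stats::setNames(sc[, pc], rownames(sc))
      list(fit = fit_hormone_regression(scores[soc_pca$individual_id],
                                        soc_pca$t_induced,
                                        soc_pca$cort_induced, soc_pca$svl,
                                        response = pc),
           boot = dyad_bootstrap_regression(
             soc_paired, scores, n_iter = config$n_boot,
             seed = derive_seed(config$seed, paste0("reg_boot_", pc)),
             response = pc))
    })
  })

  matching <- try_stage("matching",
    matching_tests(uni_rec, n_perm = config$n_perm, seed = config$seed))

  structure(list(
    exclusions = list(univariate = excl_uni$log, pca = excl_pca$log),
    univariate = univariate, pca = pca, pca_boot = pca_boot,
    regression = regression, matching = matching, errors = errors,
    n = list(input = nrow(records), univariate = nrow(uni_rec),
             pca = sum(pca_rec$group == "social"),
             pairs_intact = nrow(soc_paired) / 2L),
    config = config), class = "dyad_report")
}

#' @export
print.dyad_report <- function(x, ...) {
  cat("== Dyadic signal-integration analysis ==\n")
  cat(sprintf("records: %d in, %d after exclusions, %d social at PCA stage",
              x$n$input, x$n$univariate, x$n$pca),
      sprintf("(%d intact pairs)\n", x$n$pairs_intact))
  if (nrow(x$exclusions$pca)) {
    cat("exclusions:\n")
    tt <- table(x$exclusions$pca$rule)
    for (r in names(tt)) cat(sprintf("  %s: %d\n", r, tt[[r]]))
  }
  if (!is.null(x$univariate)) {
    cat("\n-- social vs control --\n")
    for (nm in c("dorsal", "lateral")) {
      u <- x$univariate[[nm]]
      cat(sprintf("%s (%s): ", nm, u$gate))
      print(u$test)
    }
  }
  if (!is.null(x$pca)) {
    cat("\n-- composite traits --\n")
    print(x$pca)
  }
  if (!is.null(x$regression)) {
    cat("\n-- hormone regressions --\n")
    for (pc in names(x$regression)) print(x$regression[[pc]]$fit)
  }
  if (!is.null(x$matching)) {
    cat("\n-- opponent matching --\n")
    for (m in x$matching) {
      cat(sprintf("%-16s observed = %8.3f  p = %.4g\n", m$trait,
                  m$observed, m$p_value))
    }
  }
  if (length(x$errors)) {
    cat("\n-- stage errors --\n")
    for (nm in names(x$errors)) cat(sprintf("%s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

#' Serialise a report to JSON
#'
#' Machine-readable dump of the statistics in a `dyad_report` (loadings,
#' variance shares, Bartlett block, coefficient tables with bootstrap
#' intervals, matching p-values, exclusion log).
#'
#' @param report A `dyad_report`.
#' @param file Output path; `NULL` returns the JSON string.
#' @return The file path, or the JSON string when `file` is `NULL`.
#' @export
report_json <- function(report, file = NULL) {
  reg <- lapply(report$regression, function(r) list(
    coefficients = as.list(r$fit$coefficients),
    t_values = as.list(r$fit$t_values),
    p_values = as.list(r$fit$p_values),
    ci_lower = as.list(r$boot$lower), ci_upper = as.list(r$boot$upper)))
  out <- list(
    n = report$n,
    exclusions = report$exclusions$pca,
    univariate = if (!is.null(report$univariate)) lapply(
      report$univariate, function(u) {
        tst <- if (inherits(u, "signal_test")) u else u$test
        list(test = tst$test_name, statistic = tst$statistic,
             p_value = tst$p_value)
      }),
    pca = if (!is.null(report$pca)) list(
      variance_share = report$pca$variance_share,
      loadings = as.data.frame(report$pca$loadings[, 1:report$pca$k]),
      bartlett = report$pca$bartlett),
    regression = reg,
    matching = lapply(report$matching, function(m)
      list(observed = m$observed, p_value = m$p_value,
           n_pairs = m$n_pairs)))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(as.character(js))
  writeLines(js, file)
  invisible(file)
}
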