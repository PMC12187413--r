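#' Total UV patch area
#'
#' UV patch areas are measured separately from left- and right-flank
#' photographs; the individual's trait is their sum.
#'
#' @param left,right Patch areas in mm^2, nonnegative.
#' @return `left + right` (vectorised).
#' @export
total_uv_area <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    stop("patch areas must be nonnegative", call. = FALSE)
  }
  left + right
}

# Columns every record table must carry. `counts` beyond headbob/shudder
# (pushup, approach, attack, bite) are recorded but never enter the trait
# matrix.
record_columns <- function() {
  c("individual_id", "pair_id", "group", "site_id", "svl",
    "headbob", "shudder", "pushup", "approach", "attack", "bite",
    "max_dorsal_jnd", "max_lateral_jnd", "uv_area_left", "uv_area_right",
    "t_baseline", "t_induced", "cort_baseline", "cort_induced",
    "atypical_shudder_flag")
}

trait_columns <- function() {
  c("headbob", "shudder", "uv_area_total", "max_dorsal_jnd",
    "max_lateral_jnd")
}

validate_records <- function(records) {
  miss <- setdiff(record_columns(), names(records))
  if (length(miss)) {
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$individual_id)) {
    stop("duplicated individual_id in records", call. = FALSE)
  }
  soc <- records[records$group == "social", , drop = FALSE]
  if (nrow(soc)) {
    tab <- table(soc$pair_id)
    if (any(tab != 2L)) {
      stop("every social pair_id must occur exactly twice", call. = FALSE)
    }
  }
  invisible(records)
}

#' Apply the study exclusion rules
#'
#' Drops individuals according to the pre-registered rules, in order:
#' \describe{
#'   \item{hormone_outlier}{interaction-induced testosterone above
#'     `hormone_cutoff` (default 2000 ng/ml): physiologically implausible
#'     assay values.}
#'   \item{atypical_shudder}{individuals flagged for atypical shudder
#'     displays. The flag is an input, not a computed rule - no numeric
#'     definition exists, so none is invented.}
#'   \item{missing_traits}{`stage = "pca"` only: listwise deletion of
#'     individuals missing any of the five analysis traits. Univariate
#'     stages keep these rows and use pairwise-complete data.}
#' }
#' Every drop is logged once per triggered rule.
#'
#' @param records Data frame of individual records (see
#'   [synthetic_records()] for the schema).
#' @param hormone_cutoff Induced-testosterone exclusion threshold in
#'   ng/ml; default 2000.
#' @param stage `"univariate"` (default) or `"pca"`; the missing-trait rule
#'   applies only at the PCA stage.
#' @return List with `records` (retained rows) and `log` (data frame
#'   `individual_id`, `rule`, `detail`).
#' @export
apply_exclusions <- function(records, hormone_cutoff = 2000,
                             stage = c("univariate", "pca")) {
  stage <- match.arg(stage)
  validate_records(records)
  log <- data.frame(individual_id = character(), rule = character(),
                    detail = character(), stringsAsFactors = FALSE)
  note <- function(ids, rule, detail) {
    if (length(ids)) {
      rbind(log, data.frame(individual_id = as.character(ids), rule = rule,
                            detail = detail, stringsAsFactors = FALSE))
    } else log
  }

  horm <- !is.na(records$t_induced) & records$t_induced > hormone_cutoff
  log <- note(records$individual_id[horm], "hormone_outlier",
              sprintf("t_induced > %g ng/ml", hormone_cutoff))
  records <- records[!horm, , drop = FALSE]

  flag <- !is.na(records$atypical_shudder_flag) & records$atypical_shudder_flag
  log <- note(records$individual_id[flag], "atypical_shudder",
              "atypical shudder displays")
  records <- records[!flag, , drop = FALSE]

  if (stage == "pca") {
    tm <- cbind(records[c("headbob", "shudder", "max_dorsal_jnd",
                          "max_lateral_jnd")],
                uv_area_total = total_uv_area(records$uv_area_left,
                                              records$uv_area_right))
    inc <- stats::complete.cases(tm)
    log <- note(records$individual_id[!inc], "missing_traits",
                "missing trait value(s)")
    records <- records[inc, , drop = FALSE]
  }
  list(records = records, log = log)
}

#' Assemble the five-trait analysis matrix
#'
#' Builds the per-individual matrix analysed downstream: headbob and
#' shudder counts (the two retained display behaviours), total UV patch
#' area (left + right), and the maximum dorsal and lateral chromatic
#' contrasts. Rows are sorted by `individual_id`. Records must already
#' have passed PCA-stage exclusions: a missing trait here is a contract
#' violation.
#'
#' @param records Data frame of retained individual records.
#' @return Numeric matrix, one row per individual (rownames =
#'   `individual_id`), columns `headbob`, `shudder`, `uv_area_total`,
#'   `max_dorsal_jnd`, `max_lateral_jnd`.
#' @export
build_trait_matrix <- function(records) {
  validate_trait_source(records)
  records <- records[order(records$individual_id), , drop = FALSE]
  m <- cbind(headbob = records$headbob,
             shudder = records$shudder,
             uv_area_total = total_uv_area(records$uv_area_left,
                                           records$uv_area_right),
             max_dorsal_jnd = records$max_dorsal_jnd,
             max_lateral_jnd = records$max_lateral_jnd)
  rownames(m) <- records$individual_id
  if (anyNA(m)) {
    stop("missing trait value in retained records; run apply_exclusions(",
         "stage = \"pca\") first", call. = FALSE)
  }
  m
}

validate_trait_source <- function(records) {
  need <- c("individual_id", "headbob", "shudder", "uv_area_left",
            "uv_area_right", "max_dorsal_jnd", "max_lateral_jnd")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Read / write individual record tables
#'
#' Thin wrappers around delimited text i/o using the record schema.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator, default ",".
#' @return `read_records()`: validated data frame of records.
#' @export
read_records <- function(file, sep = ",") {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  d$individual_id <- as.character(d$individual_id)
  if ("pair_id" %in% names(d)) d$pair_id <- as.character(d$pair_id)
  validate_records(d)
  d
}

#' @param records Data frame of records to write.
#' @rdname read_records
#' @export
write_records <- function(records, file, sep = ",") {
  # serialise doubles at full precision so a write/read round trip is
  # value-identical
  out <- records
  for (cl in names(out)) {
    if (is.double(out[[cl]])) {
      v <- sprintf("%.17g", out[[cl]])
      v[is.na(out[[cl]])] <- NA
      out[[cl]] <- v
    }
  }
  utils::write.table(out, file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
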