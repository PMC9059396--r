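# Cohort model: case and sample records, clinical derivations, manifest I/O.
#
# A cohort is a list with two data.frames:
#   cases   -- one row per patient (clinical course, platinum status)
#   samples -- one row per sequenced tumor sample (timepoint, site, platform)

CASE_COLUMNS <- c("case_id", "stage", "nact_cycles", "total_cycles",
                  "ca125_pre", "ca125_pct_decrease", "residual_disease",
                  "time_to_recurrence", "time_to_death_or_fu",
                  "vital_status", "platinum_status")

SAMPLE_COLUMNS <- c("sample_id", "case_id", "timepoint", "site",
                    "platform", "tumor_cellularity")

RESIDUAL_LEVELS <- c("none", "<=1cm", ">1cm")
VITAL_LEVELS <- c("DOD", "AWD")
PLATINUM_LEVELS <- c("resistant", "sensitive")
TIMEPOINT_LEVELS <- c("pre", "post")

#' Validate a case table
#'
#' Checks the per-patient clinical table against its invariants: required
#' columns present, chemotherapy cycle counts consistent
#' (`nact_cycles <= total_cycles`), non-negative time to recurrence, CA-125
#' percent decrease within \[0, 100\] (a rise is stored on the response scale
#' as a negative number and is allowed), and recognized factor levels.
#' A `censored` column (TRUE when the patient was alive at last follow-up,
#' i.e. `vital_status == "AWD"`) is derived; no survival modelling is done
#' with it.
#'
#' @param df data.frame with columns `case_id`, `stage`, `nact_cycles`,
#'   `total_cycles`, `ca125_pre`, `ca125_pct_decrease`, `residual_disease`
#'   (one of `none`, `<=1cm`, `>1cm`), `time_to_recurrence` (months),
#'   `time_to_death_or_fu` (months), `vital_status` (`DOD`/`AWD`),
#'   `platinum_status` (`resistant`/`sensitive`).
#' @return the validated data.frame with class `case_table` and a derived
#'   `censored` column.
#' @export
as_case_table <- function(df) {
  df <- as.data.frame(df)
  require_columns(df, CASE_COLUMNS, "case table")
  if (anyDuplicated(df$case_id))
    stopf("case table: duplicated case_id")
  if (any(df$nact_cycles > df$total_cycles))
    stopf("case table: nact_cycles exceeds total_cycles for case(s) %s",
          paste(df$case_id[df$nact_cycles > df$total_cycles], collapse = ", "))
  if (any(df$time_to_recurrence < 0))
    stopf("case table: negative time_to_recurrence")
  if (any(df$ca125_pct_decrease > 100))
    stopf("case table: ca125_pct_decrease above 100")
  bad <- !df$residual_disease %in% RESIDUAL_LEVELS
  if (any(bad))
    stopf("case table: unknown residual_disease value(s): %s",
          paste(unique(df$residual_disease[bad]), collapse = ", "))
  if (!all(df$vital_status %in% VITAL_LEVELS))
    stopf("case table: vital_status must be one of %s",
          paste(VITAL_LEVELS, collapse = ", "))
  if (!all(df$platinum_status %in% PLATINUM_LEVELS))
    stopf("case table: platinum_status must be one of %s",
          paste(PLATINUM_LEVELS, collapse = ", "))
  df$censored <- df$vital_status == "AWD"
  class(df) <- c("case_table", "data.frame")
  df
}

#' Validate a sample table
#'
#' @param df data.frame with columns `sample_id`, `case_id`, `timepoint`
#'   (`pre`/`post`), `site`, `platform`, `tumor_cellularity` (in (0, 1\]).
#'   Extra columns (e.g. logical `exome` / `targeted` platform availability
#'   flags) are carried through untouched.
#' @return validated data.frame with class `sample_table`.
#' @export
as_sample_table <- function(df) {
  df <- as.data.frame(df)
  require_columns(df, SAMPLE_COLUMNS, "sample table")
  if (anyDuplicated(df$sample_id))
    stopf("sample table: sample_id must be unique within the cohort")
  if (!all(df$timepoint %in% TIMEPOINT_LEVELS))
    stopf("sample table: timepoint must be 'pre' or 'post'")
  if (any(df$tumor_cellularity <= 0 | df$tumor_cellularity > 1))
    stopf("sample table: tumor_cellularity must be in (0, 1]")
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Classify platinum status from time to recurrence
#'
#' Platinum-resistant disease is recurrence strictly within `cutoff` months of
#' first-line platinum-based chemotherapy; recurrence at `cutoff` months or
#' later is platinum-sensitive. The boundary value itself (exactly 6.0 months
#' under the default) is therefore sensitive.
#'
#' @param time_to_recurrence numeric vector, months; must be non-negative.
#' @param cutoff months; default 6.
#' @return character vector, `"resistant"` or `"sensitive"`.
#' @examples
#' classify_platinum_status(c(4.6, 19.5, 6.0))
#' @export
classify_platinum_status <- function(time_to_recurrence, cutoff = 6) {
  if (any(is.na(time_to_recurrence)))
    stopf("time_to_recurrence contains NA")
  if (any(time_to_recurrence < 0))
    stopf("time_to_recurrence must be non-negative")
  ifelse(time_to_recurrence < cutoff, "resistant", "sensitive")
}

#' CA-125 biochemical response
#'
#' Percent decrease of serum CA-125 from the pre-treatment level, rounded
#' half-up to the nearest integer percent. A rise yields a negative value and
#' is reported as such.
#'
#' @param pre_level CA-125 before the first chemotherapy cycle (U/mL), > 0.
#' @param post_level CA-125 after treatment (U/mL), >= 0.
#' @return integer percent decrease.
#' @examples
#' ca125_response(1634, 32.68)   # 98
#' @export
ca125_response <- function(pre_level, post_level) {
  if (any(is.na(pre_level)) || any(is.na(post_level)))
    stopf("CA-125 levels must be non-missing")
  if (any(pre_level <= 0))
    stopf("pre-treatment CA-125 level must be positive")
  if (any(post_level < 0))
    stopf("post-treatment CA-125 level must be non-negative")
  as.integer(round_half_up(100 * (pre_level - post_level) / pre_level))
}

#' Per-group clinical means
#'
#' Arithmetic mean of time to recurrence and of time to death/last follow-up
#' within each platinum group, rounded half-up to one decimal (the precision
#' used for clinical reporting).
#'
#' @param cases a `case_table` (see [as_case_table()]).
#' @param groups which platinum groups to summarize; each must be non-empty.
#' @return data.frame with columns `platinum_status`, `n`,
#'   `mean_time_to_recurrence`, `mean_time_to_death_or_fu`.
#' @export
cohort_summary <- function(cases, groups = PLATINUM_LEVELS) {
  cases <- as_case_table(cases)
  rows <- lapply(groups, function(g) {
    sub <- cases[cases$platinum_status == g, , drop = FALSE]
    if (nrow(sub) == 0L)
      stopf("cohort_summary: no cases in group '%s'", g)
    data.frame(
      platinum_status = g,
      n = nrow(sub),
      mean_time_to_recurrence = round_half_up(mean(sub$time_to_recurrence), 1),
      mean_time_to_death_or_fu = round_half_up(mean(sub$time_to_death_or_fu), 1),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write a cohort manifest
#'
#' The manifest is two plain tab-separated files with the exact column names
#' of [as_case_table()] and [as_sample_table()].
#'
#' @param cases_path,samples_path paths to `cases.tsv` and `samples.tsv`.
#' @return `read_manifest()`: list with validated `cases` and `samples`.
#' @export
read_manifest <- function(cases_path, samples_path) {
  for (p in c(cases_path, samples_path))
    if (!file.exists(p)) stopf("manifest file not found: %s", p)
  cases <- utils::read.delim(cases_path, stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  list(cases = as_case_table(cases), samples = as_sample_table(samples))
}

#' @rdname read_manifest
#' @param cohort list with `cases` and `samples` data.frames.
#' @param dir output directory (created if needed).
#' @return `write_manifest()`: invisibly, the two file paths.
#' @export
write_manifest <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cases = file.path(dir, "cases.tsv"),
             samples = file.path(dir, "samples.tsv"))
  write_tsv_plain(as.data.frame(cohort$cases), paths[["cases"]])
  write_tsv_plain(as.data.frame(cohort$samples), paths[["samples"]])
  invisible(paths)
}

#' Five-case HGSC study cohort
#'
#' Clinical manifest of a published five-case high-grade serous ovarian
#' carcinoma cohort treated with platinum-based NACT: three platinum-resistant
#' cases (recurrence < 6 months) and two platinum-sensitive cases, each with a
#' chemo-naive pre-NACT biopsy and one or two post-NACT samples taken at
#' interval surgery. Tumor cellularity was enriched to > 80% before
#' extraction; 0.8 is stored as the floor for every sample. The logical
#' `exome` and `targeted` columns record which sequencing platforms each
#' sample was run on; `platform` holds the primary platform.
#'
#' @return list with validated `cases` and `samples` tables.
#' @examples
#' coh <- hgsc_cohort()
#' cohort_summary(coh$cases)
#' @export
hgsc_cohort <- function() {
  cases <- data.frame(
    case_id = paste0("case", 1:5),
    stage = c("IIIa", "IIIc", "IIIb", "IIIb", "IIIc"),
    nact_cycles = c(5L, 5L, 4L, 3L, 3L),
    total_cycles = c(9L, 5L, 7L, 6L, 6L),
    ca125_pre = c(81, 180, 96, 1634, 4659),
    ca125_pct_decrease = c(84L, 62L, 82L, 98L, 96L),
    residual_disease = c("none", ">1cm", "none", ">1cm", "<=1cm"),
    time_to_recurrence = c(4.6, 4.4, 3.6, 19.5, 20.9),
    time_to_death_or_fu = c(21.4, 12.1, 18.1, 47.9, 42.2),
    vital_status = c("DOD", "DOD", "DOD", "AWD", "AWD"),
    platinum_status = c("resistant", "resistant", "resistant",
                        "sensitive", "sensitive"),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("1-1", "1-2", "1-3", "2-1", "2-2",
                  "3-1", "3-2", "3-3", "4-1", "4-2", "5-1", "5-2"),
    case_id = c("case1", "case1", "case1", "case2", "case2",
                "case3", "case3", "case3", "case4", "case4",
                "case5", "case5"),
    timepoint = c("pre", "post", "post", "pre", "post",
                  "pre", "post", "post", "pre", "post", "pre", "post"),
    site = c("omentum", "pelvic_nodule", "omentum", "omentum", "omentum",
             "omentum", "ovary", "omentum", "omentum", "stomach_nodule",
             "unspecified", "bowel_nodule"),
    platform = c("exome", "exome", "targeted", "exome", "exome",
                 "exome", "exome", "exome", "exome", "exome",
                 "exome", "exome"),
    tumor_cellularity = rep(0.8, 12),
    exome = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
              TRUE, TRUE, TRUE, TRUE),
    targeted = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  list(cases = as_case_table(cases), samples = as_sample_table(samples))
}
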