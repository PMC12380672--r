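#' Default column mapping for cohort tables
#'
#' Maps the canonical record fields to the column names expected in the
#' input file. Supply a modified copy to [read_cohort()] when your file
#' uses different headers.
#'
#' @return Named character vector: canonical field -> file column name.
#' @export
#' @examples
#' cohort_col_map(dm_status = "diabetes")
cohort_col_map <- function(patient_id = "patient_id",
                           sex = "sex",
                           age = "age",
                           dm_status = "DM",
                           t_stage = "T_stage",
                           n_stage = "N_stage",
                           m_stage = "M_stage",
                           subtype = "subtype") {
  c(patient_id = patient_id, sex = sex, age = age, dm_status = dm_status,
    t_stage = t_stage, n_stage = n_stage, m_stage = m_stage,
    subtype = subtype)
}

.parse_sex <- function(x) {
  out <- rep(NA_character_, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("male", "m")] <- "male"
  out[lx %in% c("female", "f")] <- "female"
  out
}

.parse_dm <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "yes", "y", "dm")] <- TRUE
  out[lx %in% c("0", "false", "no", "n")] <- FALSE
  out
}

.parse_stage <- function(x) {
  suppressWarnings(v <- as.integer(as.character(x)))
  v[!is.na(v) & v < 0] <- NA_integer_
  v
}

#' Read a patient-level cohort table
#'
#' Reads a delimited file of one row per patient, validates each row, and
#' returns a tibble of clean records. Rows that fail validation (unknown
#' sex, unparseable age or disease status, age outside \[0, 130\]) are
#' dropped and reported with their line numbers; the validation log is
#' attached as the `"validation_log"` attribute and surfaced with a
#' warning. Sex is strictly binary (male/female): any other value rejects
#' the row rather than being coerced. TNM stages are optional and kept as
#' `NA` when absent.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param col_map Named character vector from [cohort_col_map()].
#' @param delim Field delimiter; `NULL` (default) picks "\\t" for `.tsv`
#'   files and "," otherwise.
#' @return Tibble with columns `patient_id`, `sex`, `age`, `dm_status`,
#'   `t_stage`, `n_stage`, `m_stage`, `subtype`.
#' @export
read_cohort <- function(path, col_map = cohort_col_map(), delim = NULL) {
  stopifnot(file.exists(path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)

  required <- col_map[c("sex", "age", "dm_status")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }

  get_col <- function(field) {
    nm <- col_map[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  }

  rec <- tibble::tibble(
    patient_id = get_col("patient_id"),
    sex = .parse_sex(get_col("sex")),
    age = suppressWarnings(as.numeric(get_col("age"))),
    dm_status = .parse_dm(get_col("dm_status")),
    t_stage = .parse_stage(get_col("t_stage")),
    n_stage = .parse_stage(get_col("n_stage")),
    m_stage = .parse_stage(get_col("m_stage")),
    subtype = get_col("subtype")
  )
  if (all(is.na(rec$patient_id))) {
    rec$patient_id <- sprintf("P%04d", seq_len(nrow(rec)))
  }

  bad_sex <- is.na(rec$sex)
  bad_age <- is.na(rec$age) | rec$age < 0 | rec$age > 130
  bad_dm <- is.na(rec$dm_status)
  bad <- bad_sex | bad_age | bad_dm
  log <- character(0)
  if (any(bad)) {
    reason <- dplyr::case_when(
      bad_sex ~ "unparseable sex",
      bad_age ~ "invalid age",
      TRUE ~ "unparseable DM status"
    )
    # +1 for the header row so numbers point at file lines
    log <- sprintf("line %d: %s (record rejected)",
                   which(bad) + 1L, reason[bad])
    warning(sprintf("%d of %d rows rejected; see attr(x, 'validation_log')",
                    sum(bad), nrow(rec)), call. = FALSE)
  }
  out <- rec[!bad, , drop = FALSE]
  out$age <- as.integer(round(out$age))
  attr(out, "validation_log") <- log
  out
}

#' Write a cohort tibble to disk
#'
#' Inverse of [read_cohort()]; used mainly to round-trip synthetic cohorts.
#'
#' @param cohort Tibble of patient records.
#' @param path Output path (`.tsv` gets tab-delimited output, else CSV).
#' @param col_map Column mapping used to rename the header on the way out.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, col_map = cohort_col_map()) {
  out <- cohort
  keep <- intersect(names(col_map), names(out))
  out <- out[, keep, drop = FALSE]
  names(out) <- unname(col_map[keep])
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Summarize a cohort
#'
#' Deterministic baseline summary: counts by sex, disease status within
#' sex, age moments (sample standard deviation, n - 1 denominator), and
#' stage frequency tables.
#'
#' @param cohort Tibble of patient records as returned by [read_cohort()]
#'   or [generate_cohort()].
#' @return Object of class `cohort_summary`: a list with elements
#'   `n`, `by_sex`, `dm_by_sex`, `age_mean`, `age_sd`, `stage_freq`.
#' @export
summarize_cohort <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0) stop("empty cohort")
  by_sex <- cohort |>
    dplyr::count(.data$sex, name = "n") |>
    tidyr::complete(sex = c("male", "female"), fill = list(n = 0L))
  dm_by_sex <- cohort |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(n = dplyr::n(), n_dm = sum(.data$dm_status),
                     .groups = "drop") |>
    tidyr::complete(sex = c("male", "female"),
                    fill = list(n = 0L, n_dm = 0L))
  stage_freq <- lapply(c(t_stage = "t_stage", n_stage = "n_stage",
                         m_stage = "m_stage"), function(col) {
    if (!col %in% names(cohort)) return(tibble::tibble(stage = integer(), n = integer()))
    cohort |>
      dplyr::filter(!is.na(.data[[col]])) |>
      dplyr::count(stage = .data[[col]], name = "n")
  })
  structure(list(
    n = nrow(cohort),
    by_sex = by_sex,
    dm_by_sex = dm_by_sex,
    age_mean = mean(cohort$age),
    age_sd = stats::sd(cohort$age),
    stage_freq = stage_freq
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$n, "patients\n")
  cat(sprintf("  age: mean %.1f, sd %.1f\n", x$age_mean, x$age_sd))
  for (i in seq_len(nrow(x$dm_by_sex))) {
    r <- x$dm_by_sex[i, ]
    cat(sprintf("  %s: %d (%d with DM)\n", r$sex, r$n, r$n_dm))
  }
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  wide <- stats::setNames(x$dm_by_sex$n, x$dm_by_sex$sex)
  dm <- stats::setNames(x$dm_by_sex$n_dm, x$dm_by_sex$sex)
  tibble::tibble(
    n = x$n,
    n_male = unname(wide["male"]), n_female = unname(wide["female"]),
    n_dm = sum(x$dm_by_sex$n_dm),
    n_dm_male = unname(dm["male"]), n_dm_female = unname(dm["female"]),
    age_mean = x$age_mean, age_sd = x$age_sd
  )
}

#' @rdname summarize_cohort
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$dm_by_sex
}

#' Sex-stratified conditional disease proportion
#'
#' Within one sex stratum of an all-case cohort, the proportion of
#' patients carrying the comorbid exposure (here: DM among HNSCC cases).
#' This is the quantity that seeds the population co-occurrence model as
#' the conditional probability of the case disease given the exposure.
#' Note the semantics: because every cohort record is a case, the ratio is
#' computed as a DM proportion among cases; the co-occurrence model uses
#' it as the observed conditional co-occurrence rate.
#'
#' @param cohort Tibble of patient records.
#' @param sex `"male"`, `"female"`, or a vector of both (default) for one
#'   row per stratum.
#' @return Tibble with columns `sex`, `numerator`, `denominator`, `value`.
#'   `value` is the exact ratio; round only for display.
#' @export
#' @examples
#' cohort <- generate_cohort(n_patients = 200, seed = 1)
#' conditional_probability(cohort)
conditional_probability <- function(cohort, sex = c("male", "female")) {
  sex <- match.arg(sex, several.ok = TRUE)
  purrr::map_dfr(sex, function(s) {
    sub <- cohort[cohort$sex == s, , drop = FALSE]
    if (nrow(sub) == 0) stop("no records for stratum: ", s)
    tibble::tibble(sex = s,
                   numerator = sum(sub$dm_status),
                   denominator = nrow(sub),
                   value = sum(sub$dm_status) / nrow(sub))
  })
}
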