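#' Read a subject-level case-control cohort from delimited text
#'
#' The file dialect is UTF-8 comma-separated text with a mandatory
#' header row; an empty string encodes a missing value. The header must
#' name \code{subject_id} and the codebook's outcome variable; a
#' \code{pair_id} column (1:1 matched designs) and an \code{age} column
#' are recognised when present. Every value of a codebook variable is
#' validated against that variable's declared levels; a column whose
#' non-missing values are all \code{0}/\code{1} is accepted as already
#' dichotomized and stored as integer.
#'
#' @param path Path to the CSV file.
#' @param cb A \code{\link{codebook}}.
#' @param quiet Suppress the row-count / missingness log messages.
#' @return A \code{data.frame}, one row per subject, with columns
#'   \code{subject_id}, \code{pair_id} (possibly all \code{NA}),
#'   \code{age} (if present), the codebook variables, and a derived
#'   logical \code{is_case} column.
#' @export
read_cohort <- function(path, cb = default_codebook(), quiet = FALSE) {
  stopifnot(inherits(cb, "codebook"))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  outcome <- outcome_variable(cb)
  for (col in c("subject_id", outcome)) {
    if (!col %in% names(df)) {
      stop(sprintf("format error: mandatory column '%s' is missing", col),
           call. = FALSE)
    }
  }
  df[df == ""] <- NA
  if (anyDuplicated(df$subject_id)) {
    stop("validation error: subject_id values are not unique", call. = FALSE)
  }
  if (!"pair_id" %in% names(df)) df$pair_id <- NA_character_
  if ("age" %in% names(df)) {
    age <- suppressWarnings(as.integer(df$age))
    if (any(!is.na(df$age) & (is.na(age) | age < 0))) {
      stop("validation error: 'age' must be a nonnegative whole number",
           call. = FALSE)
    }
    df$age <- age
  }
  for (v in intersect(variable_names(cb), names(df))) {
    vals <- df[[v]]
    ok <- !is.na(vals)
    if (all(vals[ok] %in% c("0", "1"))) {        # already dichotomized
      df[[v]] <- as.integer(vals)
      next
    }
    bad <- ok & !(vals %in% variable_levels(cb, v))
    if (any(bad)) {
      stop(sprintf(
        "validation error: variable '%s' has undeclared level '%s' (row %d)",
        v, vals[bad][1], which(bad)[1]), call. = FALSE)
    }
  }
  rc <- cb_variable(cb, outcome)$recode
  oc <- df[[outcome]]
  df$is_case <- if (is.integer(oc)) oc == 1L else rc[oc] == 1L
  if (any(is.na(df$is_case))) {
    stop(sprintf("validation error: outcome '%s' has missing values", outcome),
         call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("read_cohort: %d records (%d cases, %d controls)",
                    nrow(df), sum(df$is_case), sum(!df$is_case)))
    for (v in intersect(variable_names(cb), names(df))) {
      n_miss <- sum(is.na(df[[v]]))
      if (n_miss > 0) {
        message(sprintf("read_cohort: '%s' missing in %d records", v, n_miss))
      }
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a cohort back to delimited text
#'
#' Inverse of \code{\link{read_cohort}}: same CSV dialect, missing
#' values written as empty strings. The derived \code{is_case} column is
#' dropped (it is reconstructed on read from the outcome variable).
#'
#' @param records Cohort data frame as returned by \code{read_cohort} or
#'   \code{\link{generate_cohort}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(records, path) {
  out <- records[, setdiff(names(records), "is_case"), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Collapse a categorical exposure to its binary analysis form
#'
#' Applies the codebook's binary recode map to one variable, e.g.
#' collapsing a no / occasionally / regular drinking variable to
#' 0 = no, 1 = occasionally-or-regular. All other columns are returned
#' unchanged. A column already coded 0/1 passes through the identity
#' map, so the operation is idempotent.
#'
#' @param records Cohort data frame.
#' @param variable Name of the variable to recode.
#' @param cb A \code{\link{codebook}} declaring the recode map.
#' @param quiet Suppress the source-level tally log message.
#' @return The cohort with \code{variable} recoded to integer 0/1.
#' @examples
#' cb <- default_codebook()
#' df <- data.frame(subject_id = c("s1", "s2", "s3"),
#'                  hypertension = c("case", "control", "case"),
#'                  drinking = c("occasionally", "no", "regular"),
#'                  is_case = c(TRUE, FALSE, TRUE))
#' dichotomize(df, "drinking", cb)$drinking   # 1 0 1
#' @export
dichotomize <- function(records, variable, cb = default_codebook(),
                        quiet = TRUE) {
  v <- cb_variable(cb, variable)
  if (!variable %in% names(records)) {
    stop(sprintf("variable '%s' is not a column of the cohort", variable),
         call. = FALSE)
  }
  vals <- records[[variable]]
  ok <- !is.na(vals)
  if (all(vals[ok] %in% c(0L, 1L, "0", "1"))) {
    records[[variable]] <- as.integer(vals)   # identity on binary input
    return(records)
  }
  bad <- ok & !(vals %in% v$levels)
  if (any(bad)) {
    stop(sprintf("validation error: variable '%s' has undeclared level '%s'",
                 variable, vals[bad][1]), call. = FALSE)
  }
  if (!quiet) {
    tally <- table(factor(vals[ok], levels = v$levels))
    message(sprintf("dichotomize '%s': %s", variable,
                    paste(sprintf("%s=%d", names(tally), tally),
                          collapse = ", ")))
  }
  out <- rep(NA_integer_, length(vals))
  out[ok] <- v$recode[vals[ok]]
  records[[variable]] <- out
  records
}

#' Descriptive summary of a cohort
#'
#' Per-variable level counts and percentages split by case status, plus
#' mean and SD of age per group. Percentages are over the observed
#' (non-missing) levels of each variable within each group.
#'
#' @param records Cohort data frame with an \code{is_case} column.
#' @return An object of class \code{cohort_summary} with components
#'   \code{n_total}, \code{n_cases}, \code{n_controls}, \code{age}
#'   (per-group mean/sd, or \code{NULL} without an age column) and
#'   \code{levels} (a long data frame of counts and percentages).
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("domain error: cannot summarize an empty cohort", call. = FALSE)
  }
  stopifnot("is_case" %in% names(records))
  n_cases <- sum(records$is_case)
  n_controls <- sum(!records$is_case)
  age <- NULL
  if ("age" %in% names(records)) {
    age <- do.call(rbind, lapply(c(TRUE, FALSE), function(cc) {
      a <- records$age[records$is_case == cc]
      a <- a[!is.na(a)]
      data.frame(group = if (cc) "case" else "control",
                 n = length(a), mean = mean(a), sd = stats::sd(a))
    }))
  }
  skip <- c("subject_id", "pair_id", "age", "is_case")
  vars <- setdiff(names(records), skip)
  rows <- list()
  for (v in vars) {
    vals <- as.character(records[[v]])
    lv <- sort(unique(vals[!is.na(vals)]))
    if (length(lv) == 0L) next
    ca <- table(factor(vals[records$is_case], levels = lv))
    co <- table(factor(vals[!records$is_case], levels = lv))
    rows[[v]] <- data.frame(
      variable = v, level = lv,
      cases_n = as.integer(ca),
      cases_pct = if (sum(ca) > 0) 100 * as.integer(ca) / sum(ca) else NA_real_,
      controls_n = as.integer(co),
      controls_pct = if (sum(co) > 0) 100 * as.integer(co) / sum(co)
                     else NA_real_,
      row.names = NULL)
  }
  structure(list(n_total = nrow(records), n_cases = n_cases,
                 n_controls = n_controls, age = age,
                 levels = if (length(rows)) do.call(rbind, rows) else NULL),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d participants (%d cases, %d controls)\n",
              x$n_total, x$n_cases, x$n_controls))
  if (!is.null(x$age)) {
    for (i in seq_len(nrow(x$age))) {
      cat(sprintf("  age, %s group: mean %.1f (SD %.1f), n = %d\n",
                  x$age$group[i], x$age$mean[i], x$age$sd[i], x$age$n[i]))
    }
  }
  if (!is.null(x$levels)) {
    for (v in unique(x$levels$variable)) {
      sub <- x$levels[x$levels$variable == v, ]
      cat(sprintf("  %s:\n", v))
      for (i in seq_len(nrow(sub))) {
        cat(sprintf("    %-14s cases %4d (%5.1f%%)  controls %4d (%5.1f%%)\n",
                    sub$level[i], sub$cases_n[i], sub$cases_pct[i],
                    sub$controls_n[i], sub$controls_pct[i]))
      }
    }
  }
  invisible(x)
}
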