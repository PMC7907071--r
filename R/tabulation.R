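#' Fourfold (2x2) case-control table
#'
#' The atom of all odds-ratio arithmetic: exposed cases (\code{a}),
#' exposed controls (\code{b}), unexposed cases (\code{c}), unexposed
#' controls (\code{d}).
#'
#' @param a,b,c,d Nonnegative cell counts with a positive total.
#'   Tabulated counts are integers; real values are accepted so that
#'   analytic expected counts (see \code{\link{expected_tables}}) flow
#'   through the same odds-ratio arithmetic.
#' @param label Optional free-text label carried through to reports.
#' @return An object of class \code{fourfold_table}.
#' @examples
#' fourfold_table(106, 53, 42, 84)
#' @export
fourfold_table <- function(a, b, c, d, label = "") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("cell counts must be nonnegative", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("domain error: all-zero fourfold table", call. = FALSE)
  }
  structure(list(a = as.double(a), b = as.double(b),
                 c = as.double(c), d = as.double(d),
                 label = as.character(label)),
            class = "fourfold_table")
}

#' @export
print.fourfold_table <- function(x, ...) {
  if (nzchar(x$label)) cat(x$label, "\n")
  cat("           cases  controls\n")
  cat(sprintf("exposed   %6g  %8g\n", x$a, x$b))
  cat(sprintf("unexposed %6g  %8g\n", x$c, x$d))
  invisible(x)
}

#' Joint (2x2x2) exposure table
#'
#' Case and control counts cross-classified by two binary exposures.
#' The double-unexposed stratum (0,0) is the reference cell by
#' convention; all stratum odds ratios are computed against it.
#'
#' @param cases,controls Numeric vectors of length 4 ordered by stratum
#'   \code{(e1,e2) = (0,0), (0,1), (1,0), (1,1)}.
#' @param exposures Character vector of the two exposure names.
#' @param label Optional label.
#' @return An object of class \code{joint_table}; counts live in a
#'   4-row data frame \code{$counts} with columns \code{e1, e2, cases,
#'   controls}.
#' @examples
#' joint_table(cases = c(42, 10, 257, 106), controls = c(84, 27, 104, 53),
#'             exposures = c("family_history", "drinking"))
#' @export
joint_table <- function(cases, controls,
                        exposures = c("exposure1", "exposure2"),
                        label = "") {
  stopifnot(length(cases) == 4L, length(controls) == 4L,
            length(exposures) == 2L)
  counts <- c(cases, controls)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("cell counts must be nonnegative", call. = FALSE)
  }
  if (exposures[1] == exposures[2]) {
    stop("domain error: the two exposures must be distinct", call. = FALSE)
  }
  structure(list(
    counts = data.frame(e1 = c(0L, 0L, 1L, 1L), e2 = c(0L, 1L, 0L, 1L),
                        cases = as.double(cases),
                        controls = as.double(controls)),
    exposures = as.character(exposures),
    label = as.character(label)), class = "joint_table")
}

#' @export
print.joint_table <- function(x, ...) {
  if (nzchar(x$label)) cat(x$label, "\n")
  cat(sprintf("%s x %s (reference stratum 0,0)\n",
              x$exposures[1], x$exposures[2]))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

joint_cell <- function(joint, e1, e2) {
  i <- which(joint$counts$e1 == e1 & joint$counts$e2 == e2)
  joint$counts[i, ]
}

#' Tabulate one binary exposure against case status
#'
#' @param records Cohort data frame with an \code{is_case} column; the
#'   exposure must already be dichotomized to 0/1 (see
#'   \code{\link{dichotomize}}). Records missing the exposure are
#'   excluded.
#' @param variable Exposure column name.
#' @return A \code{\link{fourfold_table}}.
#' @export
crosstab_single <- function(records, variable) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("domain error: empty cohort", call. = FALSE)
  }
  stopifnot("is_case" %in% names(records))
  v <- records[[variable]]
  if (is.null(v)) {
    stop(sprintf("variable '%s' is not a column of the cohort", variable),
         call. = FALSE)
  }
  if (!all(v[!is.na(v)] %in% c(0L, 1L))) {
    stop(sprintf("domain error: variable '%s' is not binary 0/1; dichotomize first",
                 variable), call. = FALSE)
  }
  keep <- !is.na(v)
  v <- as.integer(v[keep])
  cc <- records$is_case[keep]
  fourfold_table(a = sum(cc & v == 1L), b = sum(!cc & v == 1L),
                 c = sum(cc & v == 0L), d = sum(!cc & v == 0L),
                 label = variable)
}

#' Tabulate two binary exposures jointly against case status
#'
#' Records missing either exposure are excluded, so the eight cells sum
#' to the number of records nonmissing on both variables; marginalizing
#' over either exposure reproduces the corresponding
#' \code{\link{crosstab_single}} table.
#'
#' @param records Cohort data frame.
#' @param variable1,variable2 Dichotomized exposure column names
#'   (distinct).
#' @return A \code{\link{joint_table}}.
#' @export
crosstab_joint <- function(records, variable1, variable2) {
  if (variable1 == variable2) {
    stop("domain error: the two exposures must be distinct", call. = FALSE)
  }
  if (is.null(records) || nrow(records) == 0L) {
    stop("domain error: empty cohort", call. = FALSE)
  }
  for (v in c(variable1, variable2)) {
    vals <- records[[v]]
    if (is.null(vals)) {
      stop(sprintf("variable '%s' is not a column of the cohort", v),
           call. = FALSE)
    }
    if (!all(vals[!is.na(vals)] %in% c(0L, 1L))) {
      stop(sprintf("domain error: variable '%s' is not binary 0/1", v),
           call. = FALSE)
    }
  }
  v1 <- as.integer(records[[variable1]])
  v2 <- as.integer(records[[variable2]])
  keep <- !is.na(v1) & !is.na(v2)
  v1 <- v1[keep]; v2 <- v2[keep]; cc <- records$is_case[keep]
  strata <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  cases <- vapply(strata, function(s) sum(cc & v1 == s[1] & v2 == s[2]),
                  double(1))
  controls <- vapply(strata, function(s) sum(!cc & v1 == s[1] & v2 == s[2]),
                     double(1))
  joint_table(cases, controls, exposures = c(variable1, variable2))
}

#' Collapse a joint-table stratum against the reference cell
#'
#' Builds the 2x2 table whose exposed row is the chosen stratum and
#' whose unexposed row is the double-unexposed reference cell (0,0) —
#' the table whose crude odds ratio is that stratum's OR.
#'
#' @param joint A \code{\link{joint_table}}.
#' @param cell Length-2 integer vector \code{c(e1, e2)}, not
#'   \code{c(0, 0)}.
#' @return A \code{\link{fourfold_table}}.
#' @examples
#' jt <- joint_table(c(30, 22, 175, 187), c(95, 16, 123, 36))
#' collapse_to_fourfold(jt, c(1, 0))
#' @export
collapse_to_fourfold <- function(joint, cell) {
  stopifnot(inherits(joint, "joint_table"), length(cell) == 2L)
  if (all(cell == c(0L, 0L))) {
    stop("domain error: the reference cell has OR 1 by definition",
         call. = FALSE)
  }
  top <- joint_cell(joint, cell[1], cell[2])
  ref <- joint_cell(joint, 0L, 0L)
  fourfold_table(a = top$cases, b = top$controls,
                 c = ref$cases, d = ref$controls,
                 label = sprintf("%s=%d, %s=%d vs reference",
                                 joint$exposures[1], cell[1],
                                 joint$exposures[2], cell[2]))
}

#' Packaged contingency tables from a published hypertension study
#'
#' Cross-classified case/control counts of family history of
#' hypertension against diabetes and five lifestyle exposures, as
#' printed in a 1:1 matched case-control study of hypertension (342
#' cases, 342 controls), together with each row's printed odds ratio and
#' 95\% CI. Counts are stored exactly as printed, including the known
#' internal inconsistencies of the source tables (some printed ORs do
#' not equal the crude OR of their own printed counts, and some column
#' sums exceed the stated sample size); \code{consistent} flags the rows
#' whose printed OR matches the count-derived OR at 3 decimals.
#'
#' @param table Optional table id (\code{"table2"} ... \code{"table7"})
#'   to return a single \code{\link{joint_table}}.
#' @return With \code{table = NULL}, a data frame of all fixture rows
#'   with the derived columns \code{computed_or} and \code{consistent};
#'   otherwise one \code{joint_table}.
#' @examples
#' study_tables("table3")
#' subset(study_tables(), !consistent)
#' @export
study_tables <- function(table = NULL) {
  path <- system.file("extdata", "study_tables.csv", package = "interadd")
  if (!nzchar(path)) stop("packaging error: fixture study_tables.csv missing",
                          call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$computed_or <- NA_real_
  for (tb in unique(df$source_table)) {
    idx <- which(df$source_table == tb)
    ref <- df[idx, ][df$e1[idx] == 0 & df$e2[idx] == 0, ]
    for (i in idx) {
      if (df$e1[i] == 0 && df$e2[i] == 0) {
        df$computed_or[i] <- 1
      } else {
        df$computed_or[i] <- (df$cases[i] * ref$controls) /
          (df$controls[i] * ref$cases)
      }
    }
  }
  df$consistent <- round(df$computed_or, 3) == df$printed_or
  if (is.null(table)) return(df)
  sub <- df[df$source_table == table, ]
  if (nrow(sub) != 4L) {
    stop(sprintf("packaging error: no fixture table '%s'", table),
         call. = FALSE)
  }
  sub <- sub[order(sub$e1, sub$e2), ]
  joint_table(cases = sub$cases, controls = sub$controls,
              exposures = c(sub$exposure1[1], sub$exposure2[1]),
              label = table)
}
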