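#' Crude odds ratio with Woolf confidence interval
#'
#' Point estimate \eqn{(a d)/(b c)} from a fourfold table, with the
#' Woolf log-normal interval
#' \eqn{\exp(\ln OR \mp z \sqrt{1/a + 1/b + 1/c + 1/d})}. If any cell
#' is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied first and the estimate is flagged \code{corrected}.
#'
#' @param table A \code{\link{fourfold_table}}.
#' @param level Confidence level, default 0.95.
#' @return An object of class \code{or_estimate}: \code{point},
#'   \code{ci_low}, \code{ci_high}, \code{level}, \code{method}
#'   (\code{"woolf"}), \code{corrected}.
#' @examples
#' crude_or(fourfold_table(106, 53, 42, 84))   # OR 4.000
#' @export
crude_or <- function(table, level = 0.95) {
  stopifnot(inherits(table, "fourfold_table"))
  assert_prob(level, "level")
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  point <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se_log <- sqrt(sum(1 / cells))
  z <- z_quantile(level)
  structure(list(point = point,
                 ci_low = exp(log(point) - z * se_log),
                 ci_high = exp(log(point) + z * se_log),
                 level = level, method = "woolf", corrected = corrected),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %s (%d%% CI %s-%s, %s%s)\n",
              fmt_num(x$point, 3), round(100 * x$level),
              fmt_num(x$ci_low, 3), fmt_num(x$ci_high, 3), x$method,
              if (isTRUE(x$corrected)) ", zero-cell corrected" else ""))
  invisible(x)
}

#' Pearson chi-square test for a fourfold table
#'
#' The closed-form 2x2 statistic
#' \eqn{N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} on 1 df, without
#' continuity correction.
#'
#' @param table A \code{\link{fourfold_table}} with all four margins
#'   positive.
#' @return A list of class \code{chisq_result}: \code{statistic},
#'   \code{df}, \code{p_value}.
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(inherits(table, "fourfold_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("domain error: chi-square undefined with a zero margin",
         call. = FALSE)
  }
  stat <- n * (a * d - b * c)^2 / prod(margins)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Student's t statistic with the pooled variance estimate and
#' \eqn{n_1 + n_2 - 2} degrees of freedom (two-sided p), the standard
#' comparison of mean age between equal-sized case and control groups.
#'
#' @param values_cases,values_controls Numeric vectors, each with at
#'   least two non-missing values.
#' @return A list of class \code{ttest_result}: \code{statistic},
#'   \code{df}, \code{p_value}.
#' @export
t_test_two_sample <- function(values_cases, values_controls) {
  x <- values_cases[!is.na(values_cases)]
  y <- values_controls[!is.na(values_controls)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    stop("domain error: each group needs at least 2 values", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  structure(list(statistic = stat, df = df,
                 p_value = 2 * stats::pt(abs(stat), df, lower.tail = FALSE)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

# map one covariate column to its numeric score: numeric 0/1 columns
# pass through; codebook ordinal levels become integer scores 0,1,2,...
covariate_scores <- function(records, variable, cb) {
  vals <- records[[variable]]
  if (is.null(vals)) {
    stop(sprintf("variable '%s' is not a column of the cohort", variable),
         call. = FALSE)
  }
  if (is.numeric(vals) || is.logical(vals)) return(as.double(vals))
  lv <- variable_levels(cb, variable)
  bad <- !is.na(vals) & !(vals %in% lv)
  if (any(bad)) {
    stop(sprintf("validation error: variable '%s' has undeclared level '%s'",
                 variable, vals[bad][1]), call. = FALSE)
  }
  as.double(match(vals, lv) - 1L)
}

#' Unconditional logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression fitted by iteratively
#' reweighted least squares (Newton-Raphson on the log-likelihood).
#' Ordinal covariates enter as integer scores (0, 1, 2, ... over their
#' declared level order), giving one coefficient and 1 df per variable.
#' Convergence is declared when the largest absolute score component
#' falls below \code{1e-8} or the largest parameter change below
#' \code{1e-10}, within at most \code{max_iter} iterations; a
#' non-converged fit is returned (not raised) with its diagnostics, as
#' happens under perfect separation.
#'
#' @param records Cohort data frame.
#' @param outcome Outcome column: \code{"is_case"}, a logical column, or
#'   a 0/1-coded column. Rows missing any used column are dropped.
#' @param covariates Character vector of covariate column names, in the
#'   order they should appear in the report.
#' @param adjust_for_sex Append the codebook-coded sex variable as a
#'   final covariate.
#' @param cb A \code{\link{codebook}} (for ordinal level scores).
#' @param level Confidence level for the Wald OR intervals.
#' @param max_iter Iteration cap, default 50.
#' @return An object of class \code{logistic_fit} with a
#'   \code{coefficients} data frame (term, B, SE, wald, df, p, OR,
#'   ci_low, ci_high), \code{converged}, \code{iterations},
#'   \code{log_lik}, \code{n}, \code{max_score}, and \code{separation}
#'   (fitted probabilities at the 0/1 boundary; such a fit is reported
#'   as non-converged).
#' @export
fit_logistic <- function(records, outcome = "is_case", covariates,
                         adjust_for_sex = FALSE, cb = default_codebook(),
                         level = 0.95, max_iter = 50L) {
  assert_prob(level, "level")
  stopifnot(length(covariates) >= 1L)
  if (adjust_for_sex && !"sex" %in% covariates) {
    covariates <- c(covariates, "sex")
  }
  yraw <- if (identical(outcome, "is_case")) records$is_case
          else records[[outcome]]
  if (is.null(yraw)) {
    stop(sprintf("outcome '%s' is not a column of the cohort", outcome),
         call. = FALSE)
  }
  if (is.character(yraw)) {
    stop("outcome must be logical or 0/1-coded; dichotomize it first",
         call. = FALSE)
  }
  y <- as.double(yraw)
  if (!all(y[!is.na(y)] %in% c(0, 1))) {
    stop("domain error: outcome must be binary 0/1", call. = FALSE)
  }
  scores <- lapply(covariates, covariate_scores, records = records, cb = cb)
  X <- cbind(1, do.call(cbind, scores))
  colnames(X) <- c("(Intercept)", covariates)
  keep <- stats::complete.cases(cbind(y, X))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n == 0L) stop("domain error: no complete cases", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("singular design: column(s) %s are collinear or constant",
                 paste(sQuote(dropped), collapse = ", ")), call. = FALSE)
  }

  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  max_score <- Inf
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X, X * w)
    delta <- tryCatch(solve(info, score), error = function(e) {
      stop("singular design: information matrix not invertible",
           call. = FALSE)
    })
    beta <- beta + delta
    max_score <- max(abs(score))
    if (max_score < 1e-8 || max(abs(delta)) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # under (quasi-)separation the score vanishes as the estimates walk to
  # the boundary, which must not pass for ML convergence
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10)
  if (separation) converged <- FALSE
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X, X * w)
  se <- sqrt(diag(solve(info)))
  z <- z_quantile(level)
  wald <- (beta / se)^2
  coefs <- data.frame(
    term = colnames(X), B = beta, SE = se, wald = wald, df = 1L,
    p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
    OR = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    row.names = NULL)
  log_lik <- sum(y * log(pmax(mu, 1e-300)) +
                 (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(list(coefficients = coefs, converged = converged,
                 iterations = iter, log_lik = log_lik, n = n,
                 max_score = max_score, separation = separation,
                 level = level),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Unconditional logistic regression (IRLS), n = %d, %s in %d iterations, logLik = %.3f\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$log_lik))
  co <- x$coefficients
  out <- data.frame(term = co$term,
                    B = fmt_num(co$B, 3), S.E. = fmt_num(co$SE, 3),
                    Wald = fmt_num(co$wald, 3), df = co$df,
                    p = fmt_num(co$p, 4), OR = fmt_num(co$OR, 3),
                    lower = fmt_num(co$ci_low, 3),
                    upper = fmt_num(co$ci_high, 3))
  print(out, row.names = FALSE)
  invisible(x)
}
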