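#' Variable codebook for a case-control cohort
#'
#' A codebook declares, for every variable in a cohort file, its ordered
#' level list, the binary recode map used before interaction analysis,
#' and a role tag. Exactly one variable carries the \code{outcome} role.
#'
#' @param variables A named list; each element is a list with components
#'   \code{levels} (character vector of declared level codes, in order),
#'   \code{recode} (named integer vector mapping every declared level to
#'   0 or 1), and \code{role} (one of \code{"exposure"},
#'   \code{"outcome"}, \code{"matching"}, \code{"descriptive"}).
#' @return An object of class \code{codebook}.
#' @examples
#' cb <- codebook(list(
#'   hypertension = list(levels = c("control", "case"),
#'                       recode = c(control = 0, case = 1),
#'                       role = "outcome"),
#'   drinking = list(levels = c("no", "occasionally", "regular"),
#'                   recode = c(no = 0, occasionally = 1, regular = 1),
#'                   role = "exposure")
#' ))
#' variable_levels(cb, "drinking")
#' @export
codebook <- function(variables) {
  if (!is.list(variables) || is.null(names(variables)) ||
      any(!nzchar(names(variables)))) {
    stop("`variables` must be a named list", call. = FALSE)
  }
  roles <- character(0)
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (!all(c("levels", "recode", "role") %in% names(v))) {
      stop(sprintf("variable '%s' must declare levels, recode and role", nm),
           call. = FALSE)
    }
    if (!v$role %in% c("exposure", "outcome", "matching", "descriptive")) {
      stop(sprintf("variable '%s' has unknown role '%s'", nm, v$role),
           call. = FALSE)
    }
    lv <- as.character(v$levels)
    if (anyDuplicated(lv)) {
      stop(sprintf("variable '%s' has duplicated levels", nm), call. = FALSE)
    }
    rc <- v$recode
    # recode must be total over declared levels with image in {0,1}
    if (is.null(names(rc)) || !setequal(names(rc), lv)) {
      stop(sprintf("recode map of '%s' must cover exactly its declared levels",
                   nm), call. = FALSE)
    }
    if (!all(unlist(rc) %in% c(0, 1))) {
      stop(sprintf("recode map of '%s' must map into {0, 1}", nm),
           call. = FALSE)
    }
    variables[[nm]]$levels <- lv
    rc <- vapply(rc, as.integer, integer(1))[lv]
    variables[[nm]]$recode <- rc
    roles <- c(roles, v$role)
  }
  if (sum(roles == "outcome") != 1L) {
    stop("exactly one variable must have role 'outcome'", call. = FALSE)
  }
  structure(list(variables = variables), class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("Variable codebook: %d variables\n", length(x$variables)))
  for (nm in names(x$variables)) {
    v <- x$variables[[nm]]
    cat(sprintf("  %-16s [%s] levels: %s\n", nm, v$role,
                paste(sprintf("%s=%d", names(v$recode), v$recode),
                      collapse = ", ")))
  }
  invisible(x)
}

cb_variable <- function(cb, variable) {
  stopifnot(inherits(cb, "codebook"))
  v <- cb$variables[[variable]]
  if (is.null(v)) {
    stop(sprintf("variable '%s' is not declared in the codebook", variable),
         call. = FALSE)
  }
  v
}

#' @rdname codebook
#' @param cb A \code{codebook}.
#' @param variable Variable name.
#' @export
variable_levels <- function(cb, variable) cb_variable(cb, variable)$levels

#' @rdname codebook
#' @export
variable_names <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  names(cb$variables)
}

#' @rdname codebook
#' @export
outcome_variable <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  roles <- vapply(cb$variables, `[[`, character(1), "role")
  names(roles)[roles == "outcome"]
}

#' @rdname codebook
#' @export
exposure_variables <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  roles <- vapply(cb$variables, `[[`, character(1), "role")
  names(roles)[roles == "exposure"]
}

#' Default hypertension case-control codebook
#'
#' The codebook shipped with the package covers the variables of a 1:1
#' matched hypertension case-control questionnaire: family history of
#' hypertension, diabetes history, and lifestyle exposures recorded on a
#' three-level scale (no / occasionally / regular and analogues). The
#' binary recode maps collapse the three-level variables for interaction
#' analysis: occasional-or-regular drinking, sport, and smoking count as
#' exposed; salty taste counts as exposed against balanced-or-light;
#' little-or-more work/life pressure counts as exposed against none.
#'
#' @return A \code{codebook}.
#' @examples
#' cb <- default_codebook()
#' outcome_variable(cb)
#' @export
default_codebook <- function() {
  three <- function(l0, l1, l2, one = c(l1, l2)) {
    lv <- c(l0, l1, l2)
    rc <- stats::setNames(as.integer(lv %in% one), lv)
    list(levels = lv, recode = rc, role = "exposure")
  }
  binary_exposure <- list(levels = c("no", "yes"),
                          recode = c(no = 0L, yes = 1L), role = "exposure")
  codebook(list(
    hypertension   = list(levels = c("control", "case"),
                          recode = c(control = 0L, case = 1L),
                          role = "outcome"),
    sex            = list(levels = c("male", "female"),
                          recode = c(male = 0L, female = 1L),
                          role = "matching"),
    family_history = binary_exposure,
    diabetes       = binary_exposure,
    drinking       = three("no", "occasionally", "regular"),
    sports         = three("no", "occasionally", "regular"),
    smoking        = three("no", "occasionally", "regular"),
    taste          = list(levels = c("light", "balance", "salty"),
                          recode = c(light = 0L, balance = 0L, salty = 1L),
                          role = "exposure"),
    pressure       = list(levels = c("none", "little", "more"),
                          recode = c(none = 0L, little = 1L, more = 1L),
                          role = "exposure"),
    education      = list(levels = c("primary", "secondary", "tertiary"),
                          recode = c(primary = 0L, secondary = 1L,
                                     tertiary = 1L),
                          role = "descriptive"),
    occupation     = list(levels = c("manual", "nonmanual", "retired"),
                          recode = c(manual = 0L, nonmanual = 1L,
                                     retired = 1L),
                          role = "descriptive"),
    noise          = binary_exposure,
    sleeping       = list(levels = c("lt6h", "6to8h", "gt8h"),
                          recode = c(lt6h = 1L, "6to8h" = 0L, gt8h = 0L),
                          role = "descriptive")
  ))
}

#' Read or write a codebook as a YAML file
#'
#' The on-disk format is a YAML mapping, nested by variable name, with
#' keys \code{levels}, \code{recode} and \code{role} per variable.
#'
#' @param path File path.
#' @return \code{read_codebook} returns a \code{codebook};
#'   \code{write_codebook} returns \code{path} invisibly.
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  vars <- lapply(raw, function(v) {
    list(levels = as.character(v$levels),
         recode = stats::setNames(as.integer(unlist(v$recode)),
                                  names(v$recode)),
         role = v$role)
  })
  codebook(vars)
}

#' @rdname read_codebook
#' @param cb A \code{codebook} to serialise.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  out <- lapply(cb$variables, function(v) {
    list(levels = as.list(v$levels),
         recode = as.list(stats::setNames(as.integer(v$recode),
                                          names(v$recode))),
         role = v$role)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
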