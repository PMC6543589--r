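#' @title Knowledge bases
#'
#' @description A knowledge base (KB) is the sole driver of all probabilistic
#' processing: a matrix of letter-graded conditional probabilities
#' `P(substantive response on indicator i | category c)` over the cause-of-death
#' categories, together with graded unconditional priors, and two optional
#' parallel blocks of the same shape over pregnancy-status categories and
#' circumstance-of-mortality (COMCAT) categories. Indicators carry their
#' substantive polarity (whether "yes" or "no" is the evidential answer),
#' sex/age applicability, input-format membership and optional mutual
#' exclusivity group; causes carry labels, broad-group membership,
#' applicability and a prior grade.
#'
#' @details The on-disk dialect is a plain UTF-8 CSV. Columns are
#' `indicator,text,substantive,sex,age,group,demog,who2012,tariff2` followed
#' by one column per cause code, then optional `preg:`-prefixed pregnancy
#' category columns and `com:`-prefixed COMCAT category columns. Reserved
#' rows `#LABEL`, `#GROUP`, `#SEX`, `#AGE` describe the cause columns and the
#' reserved row `PRIOR` holds the prior grade of every category column;
#' remaining rows are indicators whose cells are grade tokens. `demog` marks
#' the designated demographic indicators (`age:neonate`, `age:child`,
#' `age:adult`, `sex:male`, `sex:female`) from which each record's age band
#' and sex are resolved.
#'
#' @name knowledge_base
NULL

KB_META_COLS <- c("indicator", "text", "substantive", "sex", "age",
                  "group", "demog", "who2012", "tariff2")
KB_RESERVED <- c("#LABEL", "#GROUP", "#SEX", "#AGE", "PRIOR")
AGE_BANDS <- c("neonate", "child", "adult")

#' Construct a knowledge base object
#'
#' Normally produced by [load_knowledge_base()] or [generate_kb()]; the
#' constructor validates shape, vocabulary and grade resolvability.
#'
#' @param indicators Data frame with columns `code`, `text`, `substantive`
#'   (`"yes"`/`"no"`), `sex` (`any`/`female`/`male`), `age` (`any` or
#'   `|`-separated subset of neonate/child/adult), `group` (exclusivity group
#'   id or `""`), `demog` (demographic role or `""`), `who2012`, `tariff2`
#'   (logical format membership; every indicator is a WHO-2016 member).
#' @param causes Data frame with columns `code`, `label`, `broad_group`,
#'   `sex`, `age`, `prior_grade`.
#' @param conditional Character matrix of grade tokens, indicators x causes.
#' @param pregnancy,comcat Optional lists with elements `categories`,
#'   `prior_grade` and `conditional` (indicators x categories grade matrix),
#'   or `NULL`.
#' @param grade_map Named numeric grade map, see [default_grade_map()].
#' @return An object of class `va_kb`.
#' @export
va_kb <- function(indicators, causes, conditional,
                  pregnancy = NULL, comcat = NULL,
                  grade_map = default_grade_map()) {
  kb <- structure(
    list(indicators = indicators, causes = causes, conditional = conditional,
         pregnancy = pregnancy, comcat = comcat, grade_map = grade_map,
         prior = NULL, prevalence = c(hiv = "high", malaria = "high")),
    class = "va_kb")
  validate_kb(kb)
  kb$prior <- stats::setNames(
    grade_to_probability(causes$prior_grade, grade_map), causes$code)
  kb
}

validate_kb <- function(kb) {
  ind <- kb$indicators
  if (anyDuplicated(ind$code)) {
    dup <- ind$code[duplicated(ind$code)]
    stop("duplicate indicator code(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!all(ind$substantive %in% c("yes", "no")))
    stop("indicator substantive values must be 'yes' or 'no'", call. = FALSE)
  if (anyDuplicated(kb$causes$code))
    stop("duplicate cause code(s)", call. = FALSE)
  if (!identical(dim(kb$conditional),
                 c(nrow(ind), nrow(kb$causes))))
    stop("conditional matrix must be |indicators| x |causes| (",
         nrow(ind), " x ", nrow(kb$causes), ")", call. = FALSE)
  grade_to_probability(unique(c(kb$conditional, kb$causes$prior_grade)),
                       kb$grade_map)
  for (blk in c("pregnancy", "comcat")) {
    b <- kb[[blk]]
    if (is.null(b)) next
    if (!identical(dim(b$conditional),
                   c(nrow(ind), length(b$categories))))
      stop(blk, " block must be |indicators| x |categories|", call. = FALSE)
    grade_to_probability(unique(c(b$conditional, b$prior_grade)), kb$grade_map)
  }
  invisible(kb)
}

#' @export
print.va_kb <- function(x, ...) {
  cat("<va_kb> ", nrow(x$indicators), " indicators x ",
      nrow(x$causes), " causes\n", sep = "")
  if (!is.null(x$pregnancy))
    cat("  pregnancy block: ", paste(x$pregnancy$categories, collapse = ", "),
        "\n", sep = "")
  if (!is.null(x$comcat))
    cat("  COMCAT block: ", length(x$comcat$categories), " categories\n",
        sep = "")
  cat("  prevalence: HIV ", x$prevalence[["hiv"]], ", malaria ",
      x$prevalence[["malaria"]], "\n", sep = "")
  invisible(x)
}

#' Load a knowledge base from CSV
#'
#' Reads and validates a KB file in the dialect described under
#' [knowledge_base]. Malformed files fail loudly: duplicate or missing
#' indicator codes report the offending row, unknown grade tokens are named.
#'
#' @param path Path to the KB CSV file.
#' @param grade_map Grade map used to resolve letter grades.
#' @return A validated [va_kb] object.
#' @examples
#' kb <- generate_kb(sim_config(n_indicators = 12, n_causes = 3, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_kb(kb, f)
#' kb2 <- load_knowledge_base(f)
#' @export
load_knowledge_base <- function(path, grade_map = default_grade_map()) {
  if (!file.exists(path)) stop("KB file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", na.strings = NULL)
  if (!identical(names(raw)[seq_along(KB_META_COLS)], KB_META_COLS))
    stop("KB header must start with columns: ",
         paste(KB_META_COLS, collapse = ","), call. = FALSE)
  cat_cols <- setdiff(names(raw), KB_META_COLS)
  preg_cols <- grep("^preg:", cat_cols, value = TRUE)
  com_cols <- grep("^com:", cat_cols, value = TRUE)
  cause_cols <- setdiff(cat_cols, c(preg_cols, com_cols))
  if (!length(cause_cols))
    stop("KB file declares no cause columns", call. = FALSE)

  take_row <- function(key) {
    i <- which(raw$indicator == key)
    if (length(i) != 1)
      stop("KB file must contain exactly one '", key, "' row", call. = FALSE)
    raw[i, , drop = FALSE]
  }
  lab <- take_row("#LABEL"); grp <- take_row("#GROUP")
  sx <- take_row("#SEX"); ag <- take_row("#AGE")
  pri <- take_row("PRIOR")

  body <- raw[!(raw$indicator %in% KB_RESERVED), , drop = FALSE]
  if (any(!nzchar(body$indicator))) {
    bad <- which(!nzchar(body$indicator))[1]
    stop("missing indicator code at data row ", bad, call. = FALSE)
  }
  if (anyDuplicated(body$indicator)) {
    bad <- which(duplicated(body$indicator))[1]
    stop("duplicate indicator code '", body$indicator[bad],
         "' at data row ", bad, call. = FALSE)
  }

  indicators <- data.frame(
    code = body$indicator, text = body$text,
    substantive = body$substantive, sex = body$sex, age = body$age,
    group = body$group, demog = body$demog,
    who2012 = body$who2012 %in% c("1", "TRUE", "true", "yes"),
    tariff2 = body$tariff2 %in% c("1", "TRUE", "true", "yes"),
    stringsAsFactors = FALSE)

  causes <- data.frame(
    code = cause_cols,
    label = unlist(lab[cause_cols], use.names = FALSE),
    broad_group = unlist(grp[cause_cols], use.names = FALSE),
    sex = unlist(sx[cause_cols], use.names = FALSE),
    age = unlist(ag[cause_cols], use.names = FALSE),
    prior_grade = unlist(pri[cause_cols], use.names = FALSE),
    stringsAsFactors = FALSE)
  causes$sex[!nzchar(causes$sex)] <- "any"
  causes$age[!nzchar(causes$age)] <- "any"

  as_grades <- function(cols) {
    m <- as.matrix(body[, cols, drop = FALSE])
    dimnames(m) <- list(body$indicator, cols)
    m
  }
  block <- function(cols, prefix) {
    if (!length(cols)) return(NULL)
    m <- as_grades(cols)
    cats <- sub(paste0("^", prefix, ":"), "", cols)
    colnames(m) <- cats
    list(categories = cats,
         prior_grade = stats::setNames(
           unlist(pri[cols], use.names = FALSE), cats),
         conditional = m)
  }

  va_kb(indicators, causes, as_grades(cause_cols),
        pregnancy = block(preg_cols, "preg"),
        comcat = block(com_cols, "com"),
        grade_map = grade_map)
}

#' Write a knowledge base to CSV
#'
#' Inverse of [load_knowledge_base()]: the grade matrix round-trips
#' cell-for-cell.
#'
#' @param kb A [va_kb] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  ind <- kb$indicators
  cause_cols <- kb$causes$code
  preg_cols <- if (!is.null(kb$pregnancy))
    paste0("preg:", kb$pregnancy$categories) else character()
  com_cols <- if (!is.null(kb$comcat))
    paste0("com:", kb$comcat$categories) else character()
  all_cols <- c(cause_cols, preg_cols, com_cols)

  blank <- function(x) { x[] <- ""; x }
  meta_row <- function(code, cause_vals, preg_vals, com_vals) {
    stats::setNames(
      as.list(c(code, rep("", length(KB_META_COLS) - 1),
                cause_vals, preg_vals, com_vals)),
      c(KB_META_COLS, all_cols))
  }
  rows <- list(
    meta_row("#LABEL", kb$causes$label, blank(preg_cols), blank(com_cols)),
    meta_row("#GROUP", kb$causes$broad_group, blank(preg_cols), blank(com_cols)),
    meta_row("#SEX", kb$causes$sex, blank(preg_cols), blank(com_cols)),
    meta_row("#AGE", kb$causes$age, blank(preg_cols), blank(com_cols)),
    meta_row("PRIOR", kb$causes$prior_grade,
             if (length(preg_cols)) kb$pregnancy$prior_grade else character(),
             if (length(com_cols)) kb$comcat$prior_grade else character()))
  hdr <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE, check.names = FALSE))

  body <- data.frame(
    indicator = ind$code, text = ind$text, substantive = ind$substantive,
    sex = ind$sex, age = ind$age, group = ind$group, demog = ind$demog,
    who2012 = as.integer(ind$who2012), tariff2 = as.integer(ind$tariff2),
    stringsAsFactors = FALSE, check.names = FALSE)
  body <- cbind(body, as.data.frame(kb$conditional, check.names = FALSE))
  if (length(preg_cols)) {
    p <- as.data.frame(kb$pregnancy$conditional, check.names = FALSE)
    names(p) <- preg_cols; body <- cbind(body, p)
  }
  if (length(com_cols)) {
    p <- as.data.frame(kb$comcat$conditional, check.names = FALSE)
    names(p) <- com_cols; body <- cbind(body, p)
  }
  names(hdr) <- names(body)
  utils::write.csv(rbind(hdr, body), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Set HIV and malaria prevalence levels
#'
#' The epidemiological context is parameterised by two prevalence levels that
#' rescale the unconditional priors of the HIV-related (01.03) and malaria
#' (01.05) cause categories; everything else is untouched. Level `"high"`
#' leaves the prior as graded; `"low"` and `"very low"` down-weight it by the
#' configured multipliers. The operation is idempotent at `"high"` and
#' commutes across the two diseases. Scaled priors are clamped to `[0, 1]`.
#'
#' @param kb A [va_kb].
#' @param hiv,malaria One of `"high"`, `"low"`, `"very low"` (`"h"`, `"l"`,
#'   `"v"` accepted). An omitted level keeps the KB's current setting, so
#'   the two diseases can be set in either order with the same result.
#' @param multipliers Named multipliers for the three levels.
#' @param hiv_cause,malaria_cause Cause codes the levels act on; silently
#'   skipped if the KB does not contain them (e.g. synthetic KBs).
#' @return The KB with rescaled numeric priors and its `prevalence` field
#'   updated.
#' @export
apply_prevalence <- function(kb, hiv = kb$prevalence[["hiv"]],
                             malaria = kb$prevalence[["malaria"]],
                             multipliers = c(high = 1, low = 0.1,
                                             `very low` = 0.01),
                             hiv_cause = "01.03", malaria_cause = "01.05") {
  norm_level <- function(x) {
    x <- tolower(as.character(x))
    full <- c(h = "high", l = "low", v = "very low")
    key <- substr(x, 1, 1)
    if (!(x %in% full || key %in% names(full)))
      stop("unknown prevalence level: ", x, call. = FALSE)
    lev <- if (x %in% full) x else full[[key]]
    if (!lev %in% names(multipliers))
      stop("no multiplier configured for level: ", lev, call. = FALSE)
    lev
  }
  hiv <- norm_level(hiv); malaria <- norm_level(malaria)
  # rescale from the graded baseline so repeated application cannot compound
  base <- stats::setNames(
    grade_to_probability(kb$causes$prior_grade, kb$grade_map),
    kb$causes$code)
  scale1 <- function(prior, code, level) {
    if (code %in% names(prior))
      prior[code] <- min(1, base[[code]] * multipliers[[level]])
    prior
  }
  kb$prior <- scale1(scale1(base, hiv_cause, hiv), malaria_cause, malaria)
  kb$prevalence <- c(hiv = hiv, malaria = malaria)
  kb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numeric view of a knowledge base
#'
#' Resolves every grade in the KB through its grade map, returning numeric
#' matrices ready for likelihood propagation.
#'
#' @param kb A [va_kb].
#' @return List with `conditional` (indicators x causes probability matrix),
#'   `prior` (named, prevalence-adjusted), `substantive` (named `"y"`/`"n"`
#'   per indicator) and, when present, `pregnancy`/`comcat` lists of
#'   `conditional` + `prior`.
#' @export
kb_probabilities <- function(kb) {
  num <- function(g) {
    m <- matrix(grade_to_probability(g, kb$grade_map), nrow(g), ncol(g),
                dimnames = dimnames(g))
    m
  }
  blk <- function(b) if (is.null(b)) NULL else
    list(conditional = num(b$conditional),
         prior = stats::setNames(
           grade_to_probability(b$prior_grade, kb$grade_map), b$categories))
  list(conditional = num(kb$conditional),
       prior = kb$prior,
       substantive = stats::setNames(
         c(yes = "y", no = "n")[kb$indicators$substantive],
         kb$indicators$code),
       pregnancy = blk(kb$pregnancy),
       comcat = blk(kb$comcat))
}

# does an applicability token admit this band/sex?
applies_to <- function(token, value) {
  token == "any" | !nzchar(token) |
    vapply(strsplit(token, "|", fixed = TRUE), function(t) value %in% t,
           logical(1))
}

#' Causes applicable to an age band and sex
#' @param kb A [va_kb].
#' @param age_band One of `"neonate"`, `"child"`, `"adult"`.
#' @param sex `"male"` or `"female"`.
#' @return Logical vector along `kb$causes`.
#' @export
applicable_causes <- function(kb, age_band, sex) {
  applies_to(kb$causes$age, age_band) &
    (kb$causes$sex == "any" | kb$causes$sex == sex)
}
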