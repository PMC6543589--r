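#' Consistency rule set
#'
#' The rule catalogue applied by [check_consistency()]. ERROR-class rules
#' exclude a record from processing; WARNING-class rules repair it (the
#' offending responses become missing) and keep it. The set is configuration:
#' rules can be switched off, and the exclusivity tie-break is explicit.
#'
#' Error rules: `no_age` (no age band asserted), `multi_age` (contradictory
#' age bands), `no_sex`, `multi_sex`. Warning rules: `sex_inapplicable` and
#' `age_inapplicable` (substantive response on an indicator the record's sex
#' or age band cannot answer), `exclusive_group` (more than one yes within a
#' mutually exclusive category bank; the last member in KB order -- by
#' convention the longest duration / most severe band -- is kept).
#'
#' @param errors,warnings Character vectors of enabled rule ids.
#' @return A rule-set object.
#' @export
va_rules <- function(errors = c("no_age", "multi_age", "no_sex", "multi_sex"),
                     warnings = c("sex_inapplicable", "age_inapplicable",
                                  "exclusive_group")) {
  structure(list(errors = errors, warnings = warnings), class = "va_rules")
}

# age band and sex asserted by the designated demographic indicators
resolve_demographics <- function(resp, kb) {
  demog <- kb$indicators$demog
  codes <- kb$indicators$code
  pick <- function(prefix, values) {
    hit <- character()
    for (v in values) {
      idx <- which(demog == paste0(prefix, ":", v))
      if (length(idx) && any(resp[codes[idx]] == "y")) hit <- c(hit, v)
    }
    hit
  }
  list(age = pick("age", AGE_BANDS), sex = pick("sex", c("male", "female")))
}

#' Check records for internal consistency
#'
#' Applies the ERROR and WARNING rules of [va_rules()] to every record.
#' Records violating an error rule are excluded; warning repairs set the
#' offending responses to missing so that a second pass fires no rules at
#' all (the check is idempotent). Every firing is enumerated in the report.
#'
#' @param records A `va_records` object read against `kb`.
#' @param kb The [va_kb].
#' @param rules Rule set from [va_rules()].
#' @return List with `records` (cleaned, excluded rows dropped, per-record
#'   warning flags attached) and `report` (an object with `errors`,
#'   `warnings` data frames and `excluded_ids`).
#' @export
check_consistency <- function(records, kb, rules = va_rules()) {
  n <- length(records$id)
  codes <- kb$indicators$code
  subst <- stats::setNames(c(yes = "y", no = "n")[kb$indicators$substantive],
                           codes)
  err <- list(); wrn <- list()
  note <- function(store, i, rule, msg)
    c(store, list(data.frame(id = records$id[i], rule = rule, message = msg,
                             stringsAsFactors = FALSE)))
  excluded <- logical(n)
  flags <- records$warnings

  groups <- split(seq_along(codes), kb$indicators$group)
  groups <- groups[nzchar(names(groups))]

  for (i in seq_len(n)) {
    resp <- records$responses[i, ]
    demo <- resolve_demographics(resp, kb)

    fire_err <- function(rule, msg) {
      if (rule %in% rules$errors) {
        err <<- note(err, i, rule, msg)
        excluded[i] <<- TRUE
      }
    }
    if (length(demo$age) == 0) fire_err("no_age", "no age band asserted")
    if (length(demo$age) > 1)
      fire_err("multi_age", paste("contradictory age bands:",
                                  paste(demo$age, collapse = "+")))
    if (length(demo$sex) == 0) fire_err("no_sex", "no sex asserted")
    if (length(demo$sex) > 1) fire_err("multi_sex", "both sexes asserted")
    if (excluded[i]) next

    if ("sex_inapplicable" %in% rules$warnings && length(demo$sex) == 1) {
      bad <- kb$indicators$sex != "any" & kb$indicators$sex != demo$sex &
        resp == subst & resp != "-"
      if (any(bad)) {
        wrn <- note(wrn, i, "sex_inapplicable",
                    paste("substantive response on sex-inapplicable:",
                          paste(codes[bad], collapse = ",")))
        records$responses[i, bad] <- "-"
        flags[i] <- paste0(flags[i], "sex_inapplicable;")
      }
    }
    if ("age_inapplicable" %in% rules$warnings && length(demo$age) == 1) {
      ok <- applies_to(kb$indicators$age, demo$age)
      bad <- !ok & resp == subst & resp != "-"
      bad[kb$indicators$demog != ""] <- FALSE
      if (any(bad)) {
        wrn <- note(wrn, i, "age_inapplicable",
                    paste("substantive response on age-inapplicable:",
                          paste(codes[bad], collapse = ",")))
        records$responses[i, bad] <- "-"
        flags[i] <- paste0(flags[i], "age_inapplicable;")
      }
    }
    if ("exclusive_group" %in% rules$warnings) {
      for (g in names(groups)) {
        idx <- groups[[g]]
        yes <- idx[records$responses[i, idx] == "y"]
        if (length(yes) > 1) {
          keep <- max(yes)  # last member in KB order wins
          drop <- setdiff(yes, keep)
          wrn <- note(wrn, i, "exclusive_group",
                      paste0("group '", g, "': kept ", codes[keep],
                             ", dropped ", paste(codes[drop], collapse = ",")))
          records$responses[i, drop] <- "-"
          flags[i] <- paste0(flags[i], "exclusive_group;")
        }
      }
    }
  }

  bind <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(id = character(), rule = character(), message = character(),
               stringsAsFactors = FALSE)
  report <- structure(
    list(errors = bind(err), warnings = bind(wrn),
         excluded_ids = unique(records$id[excluded])),
    class = "va_consistency_report")

  keep <- !excluded
  cleaned <- new_va_records(records$id[keep],
                            records$responses[keep, , drop = FALSE],
                            flags[keep])
  list(records = cleaned, report = report)
}

#' @export
print.va_consistency_report <- function(x, ...) {
  cat("<va_consistency_report> ", nrow(x$errors), " error(s), ",
      nrow(x$warnings), " warning(s), ", length(x$excluded_ids),
      " record(s) excluded\n", sep = "")
  invisible(x)
}

#' Write a consistency report to CSV
#' @param report Report from [check_consistency()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consistency_report <- function(report, path) {
  df <- rbind(
    if (nrow(report$errors)) cbind(class = "ERROR", report$errors),
    if (nrow(report$warnings)) cbind(class = "WARNING", report$warnings))
  if (is.null(df))
    df <- data.frame(class = character(), id = character(),
                     rule = character(), message = character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
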