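# Hand-built miniature knowledge base used across the suite: three causes
# with distinct applicability (an any-age infection, an adult-female
# maternal cause, a neonatal cause), demographic indicators, one
# female-only item with substantive polarity "no", and a two-band duration
# exclusivity group.
toy_kb <- function() {
  indicators <- data.frame(
    code = c("d_neonate", "d_child", "d_adult", "d_male", "d_female",
             "fever", "cough", "placenta", "fdur_short", "fdur_long"),
    text = c("neonate?", "child?", "adult?", "male?", "female?",
             "had fever?", "had cough?", "placenta fully delivered?",
             "fever under a week?", "fever one to two weeks?"),
    substantive = c(rep("yes", 7), "no", "yes", "yes"),
    sex = c(rep("any", 7), "female", "any", "any"),
    age = c(rep("any", 5), "any", "any", "adult", "any", "any"),
    group = c(rep("", 8), "fdur", "fdur"),
    demog = c("age:neonate", "age:child", "age:adult",
              "sex:male", "sex:female", rep("", 5)),
    who2012 = c(rep(TRUE, 7), TRUE, TRUE, FALSE),
    tariff2 = c(rep(TRUE, 7), FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  causes <- data.frame(
    code = c("01.01", "09.03", "10.01"),
    label = c("Sepsis", "Pregnancy-induced hypertension", "Prematurity"),
    broad_group = c("Infections", "Maternal and neonatal causes",
                    "Maternal and neonatal causes"),
    sex = c("any", "female", "any"),
    age = c("any", "adult", "neonate"),
    prior_grade = c("A", "A-", "B+"),
    stringsAsFactors = FALSE)
  cond <- rbind(
    d_neonate = c("A+", "A+", "A+"), d_child = c("A+", "A+", "A+"),
    d_adult = c("A+", "A+", "A+"), d_male = c("A+", "A+", "A+"),
    d_female = c("A+", "A+", "A+"),
    fever = c("A+", "C", "B"), cough = c("A", "B+", "C"),
    placenta = c("C", "A+", "N"),
    fdur_short = c("A", "B", "C"), fdur_long = c("B+", "A", "C"))
  colnames(cond) <- causes$code
  preg <- list(
    categories = c("pregnant", "recently_delivered", "not_pregnant"),
    prior_grade = c(pregnant = "A-", recently_delivered = "B+",
                    not_pregnant = "A+"),
    conditional = {
      m <- matrix("A", nrow(indicators), 3,
                  dimnames = list(indicators$code,
                                  c("pregnant", "recently_delivered",
                                    "not_pregnant")))
      m["placenta", ] <- c("A+", "A", "C")
      m["fever", ] <- c("B+", "B+", "A")
      m
    })
  com <- list(
    categories = c("traditions", "emergency"),
    prior_grade = c(traditions = "A", emergency = "A"),
    conditional = {
      m <- matrix("A", nrow(indicators), 2,
                  dimnames = list(indicators$code,
                                  c("traditions", "emergency")))
      m["cough", ] <- c("A+", "C")
      m
    })
  va_kb(indicators, causes, cond, pregnancy = preg, comcat = com)
}

# a blank (all-missing) response row for a KB, with demographics filled in
blank_record <- function(kb, age = "adult", sex = "male") {
  r <- stats::setNames(rep("-", nrow(kb$indicators)), kb$indicators$code)
  r[paste0("d_", c("neonate", "child", "adult"))] <- "n"
  r[paste0("d_", age)] <- "y"
  r[c("d_male", "d_female")] <- "n"
  r[paste0("d_", sex)] <- "y"
  r
}

records_from_rows <- function(kb, rows, ids = NULL) {
  m <- do.call(rbind, rows)
  colnames(m) <- kb$indicators$code
  vacoder:::new_va_records(ids %||% paste0("r", seq_along(rows)), m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force Bayes oracle: direct product over categories,
# no log-space, no vectorisation
oracle_propagate <- function(resp, prior, cond, subst) {
  w <- prior
  for (ct in names(prior)) {
    for (i in rownames(cond)) {
      if (resp[[i]] != "-" && resp[[i]] == subst[[i]])
        w[ct] <- w[ct] * cond[i, ct]
    }
  }
  if (sum(w) == 0) return(NULL)
  w / sum(w)
}
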