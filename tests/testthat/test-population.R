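make_cls <- function(rows) {
  # rows: list of list(id, cause=c(code=lik,...), indet, age)
  df <- do.call(rbind, lapply(rows, function(r) {
    cs <- r$cause
    pad <- function(k, what) {
      if (length(cs) >= k) {
        if (what == "c") names(cs)[k] else unname(cs[k])
      } else if (what == "c") NA_character_ else NA_real_
    }
    data.frame(ID = r$id, PREG_STATUS = "not_pregnant", PREG_LIK = 1,
               CAUSE1 = pad(1, "c"), LIK1 = pad(1, "l"),
               CAUSE2 = pad(2, "c"), LIK2 = pad(2, "l"),
               CAUSE3 = pad(3, "c"), LIK3 = pad(3, "l"),
               INDET = r$indet, COMCAT = NA_character_,
               COMCAT_LIK = NA_real_, WARNINGS = "",
               AGE_GROUP = r$age %||% "5plus", stringsAsFactors = FALSE)
  }))
  class(df) <- c("va_classifications", "data.frame")
  df
}

test_that("CSMFs are mean assigned likelihoods per stratum", {
  kb <- toy_kb()
  cls <- make_cls(list(
    list(id = "a", cause = c("01.01" = 1.0), indet = 0),
    list(id = "b", cause = c("01.01" = 0.6), indet = 0.4)))
  tab <- aggregate_csmf(cls, kb)
  f <- stats::setNames(tab$fraction, tab$cause)
  expect_equal(unname(f[["01.01"]]), 0.8)
  expect_equal(unname(f[["99"]]), 0.2)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  expect_equal(attr(tab, "n_deaths")[["5plus"]], 2)

  # single case: table equals its likelihood row
  one <- aggregate_csmf(make_cls(list(
    list(id = "x", cause = c("01.01" = 0.7, "09.03" = 0.2), indet = 0.1))), kb)
  f1 <- stats::setNames(one$fraction, one$cause)
  expect_equal(unname(f1[c("01.01", "09.03", "99")]), c(0.7, 0.2, 0.1))

  # strata aggregate independently
  mix <- aggregate_csmf(make_cls(list(
    list(id = "a", cause = c("01.01" = 1), indet = 0, age = "5plus"),
    list(id = "n", cause = c("10.01" = 1), indet = 0, age = "under5"))), kb)
  for (s in c("5plus", "under5"))
    expect_equal(sum(mix$fraction[mix$stratum == s]), 1, tolerance = 1e-9)
})

test_that("indeterminate redistribution is proportional and idempotent", {
  kb <- toy_kb()
  cls <- make_cls(list(
    list(id = "a", cause = c("01.01" = 1), indet = 0),
    list(id = "b", cause = c("01.01" = 0.5, "09.03" = 0.9 - 0.5), indet = 0.1),
    list(id = "c", cause = c("09.03" = 0.7), indet = 0.3)))
  tab <- aggregate_csmf(cls, kb)
  red <- redistribute_indeterminate(tab)
  expect_false("99" %in% red$cause)
  expect_equal(sum(red$fraction), 1, tolerance = 1e-12)
  # proportions preserved among causes
  f0 <- stats::setNames(tab$fraction, tab$cause)
  f1 <- stats::setNames(red$fraction, red$cause)
  expect_equal(unname(f1[["01.01"]] / f1[["09.03"]]),
               unname(f0[["01.01"]] / f0[["09.03"]]), tolerance = 1e-12)
  # direct arithmetic: {0.5, 0.3, indet 0.2} -> {0.625, 0.375}
  simple <- as_csmf_table(data.frame(stratum = "s",
                                     cause = c("A", "B", "99"),
                                     v = c(50, 30, 20)), "v")
  rs <- redistribute_indeterminate(simple)
  expect_equal(rs$fraction, c(0.625, 0.375))
  # idempotent / identity without indeterminate
  expect_equal(redistribute_indeterminate(red)$fraction, red$fraction)
  # fully indeterminate stratum is an error
  allind <- as_csmf_table(data.frame(stratum = "s", cause = c("A", "99"),
                                     v = c(0, 100)), "v")
  expect_error(redistribute_indeterminate(allind), "fully indeterminate")
})

test_that("cause amalgamation sums sources into targets and conserves mass", {
  t <- as_csmf_table(data.frame(
    stratum = "under5",
    cause = c("11.01", "11.02", "01.11", "01.12", "04.01"),
    v = c(18, 4, 0.2, 0.1, 77.7)), "v")
  m <- merge_causes(t, c("11.01" = "11.99", "11.02" = "11.99",
                         "01.12" = "01.11"))
  f <- stats::setNames(m$fraction, m$cause)
  expect_equal(unname(f[["11.99"]]), 0.22)
  expect_equal(unname(f[["01.11"]]), 0.003)
  expect_equal(sum(m$fraction), sum(t$fraction), tolerance = 1e-12)
  expect_false(any(c("11.01", "11.02", "01.12") %in% m$cause))
  # empty map is the identity; cycles are rejected
  expect_identical(merge_causes(t, character(0)), t)
  expect_error(merge_causes(t, c("11.01" = "11.02", "11.02" = "11.01")),
               "cycle")
})

test_that("broad groups sum member causes and conserve stratum totals", {
  kb <- toy_kb()
  cls <- make_cls(list(
    list(id = "a", cause = c("01.01" = 0.8), indet = 0.2),
    list(id = "b", cause = c("09.03" = 0.9), indet = 0.1)))
  tab <- aggregate_csmf(cls, kb)
  g <- broad_groups(tab)
  fg <- stats::setNames(g$fraction, g$cause)
  expect_equal(unname(fg[["Infections"]]), 0.4)
  expect_equal(unname(fg[["Maternal and neonatal causes"]]), 0.45)
  expect_equal(unname(fg[["Indeterminate"]]), 0.15)
  expect_equal(sum(g$fraction), 1, tolerance = 1e-12)

  t2 <- as_csmf_table(data.frame(stratum = "s", cause = c("A", "B"),
                                 v = c(60, 40)), "v")
  t2$broad_group <- ""   # unassigned causes are an error, named
  expect_error(broad_groups(t2), "A, B")
})

test_that("mass is conserved through aggregate -> merge -> group", {
  cfg <- sim_config(n_indicators = 12, n_causes = 4, n_cases = 80, seed = 9)
  kb <- generate_kb(cfg)
  co <- generate_cohort(kb, cfg)
  tab <- aggregate_csmf(classify_cases(co$records, kb), kb)
  m <- merge_causes(tab, c("C01" = "Cmrg", "C02" = "Cmrg"))
  m$broad_group[m$cause == "Cmrg"] <- "Group 1"
  g <- broad_groups(m)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(m$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(g$fraction), 1, tolerance = 1e-9)
})
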