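test_that("propagation follows the Bayes product on substantive responses", {
  cond <- matrix(c(0.8, 0.2), 1, 2, dimnames = list("i1", c("A", "B")))
  prior <- c(A = 0.5, B = 0.5)
  subst <- c(i1 = "y")

  # one substantive-yes indicator recorded yes: posterior is the column
  post <- propagate(c(i1 = "y"), prior, cond, subst)
  expect_equal(unclass(post), c(A = 0.8, B = 0.2), ignore_attr = TRUE)

  # missing response: empty product, normalised prior
  expect_equal(as.numeric(propagate(c(i1 = "-"), prior, cond, subst)),
               c(0.5, 0.5))
  # recorded at the non-substantive pole: no update either
  expect_equal(as.numeric(propagate(c(i1 = "n"), prior, cond, subst)),
               c(0.5, 0.5))
  # substantive "no" polarity updates on a recorded "no"
  post_no <- propagate(c(i1 = "n"), prior, cond, c(i1 = "n"))
  expect_equal(as.numeric(post_no), c(0.8, 0.2))

  expect_error(propagate(c(i1 = "y"), c(X = 1, Y = 1), cond, subst),
               "category axis")
})

test_that("propagation matches the brute-force oracle on all response patterns", {
  # 4 indicators x 3 causes, mixed polarities, zero prior on one cause,
  # one annihilating conditional
  set.seed(42)
  cond <- matrix(round(runif(12, 0.01, 0.9), 3), 4, 3,
                 dimnames = list(paste0("i", 1:4), c("A", "B", "C")))
  cond["i2", "B"] <- 0                     # hard exclusion
  prior <- c(A = 0.6, B = 0.3, C = 0)      # C is inapplicable
  subst <- c(i1 = "y", i2 = "y", i3 = "n", i4 = "y")

  patterns <- expand.grid(rep(list(c("y", "n", "-")), 4),
                          stringsAsFactors = FALSE)
  for (p in seq_len(nrow(patterns))) {
    resp <- stats::setNames(unlist(patterns[p, ]), paste0("i", 1:4))
    got <- propagate(resp, prior, cond, subst)
    want <- oracle_propagate(resp, prior, cond, subst)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-9,
                 info = paste(resp, collapse = ""))
    expect_equal(sum(got), 1, tolerance = 1e-9)
    expect_equal(unname(got[["C"]]), 0)     # zero prior stays zero
  }
})

test_that("posterior is invariant to indicator order and monotone in evidence", {
  set.seed(7)
  cond <- matrix(runif(15, 0.05, 0.95), 5, 3,
                 dimnames = list(paste0("i", 1:5), c("A", "B", "C")))
  prior <- c(A = 0.2, B = 0.5, C = 0.3)
  subst <- stats::setNames(rep("y", 5), paste0("i", 1:5))
  resp <- stats::setNames(c("y", "y", "n", "y", "-"), paste0("i", 1:5))

  base <- propagate(resp, prior, cond, subst)
  for (k in 1:5) {
    perm <- sample(1:5)
    shuffled <- propagate(resp[perm], prior, cond[perm, , drop = FALSE],
                          subst[perm])
    expect_equal(as.numeric(shuffled), as.numeric(base), tolerance = 1e-12)
  }

  # raising P(i1 | A) with i1 observed substantively never lowers A
  for (bump in c(0.05, 0.2, 0.4)) {
    cond2 <- cond
    cond2["i1", "A"] <- min(1, cond["i1", "A"] + bump)
    expect_gte(propagate(resp, prior, cond2, subst)[["A"]], base[["A"]])
  }
})

test_that("all-annihilated posteriors fall back to uniform with a flag", {
  cond <- matrix(0, 1, 2, dimnames = list("i1", c("A", "B")))
  post <- propagate(c(i1 = "y"), c(A = 0.7, B = 0.3), cond, c(i1 = "y"))
  expect_equal(as.numeric(post), c(0.5, 0.5))
  expect_true(attr(post, "fallback"))
})

test_that("cause reporting thresholds follow the top/ratio rule", {
  s <- va_settings()   # top_min 0.4, ratio_min 0.5
  r1 <- select_reported_causes(c(A = 0.9, B = 0.06, C = 0.04), s)
  expect_equal(r1$causes, c(A = 0.9))
  expect_equal(r1$indeterminate, 0.1)

  r2 <- select_reported_causes(c(A = 0.5, B = 0.3, C = 0.2), s)
  expect_equal(names(r2$causes), c("A", "B"))    # 0.3 >= 0.25, 0.2 < 0.25
  expect_equal(r2$indeterminate, 0.2)

  r3 <- select_reported_causes(c(A = 0.35, B = 0.35, C = 0.3), s)
  expect_equal(length(r3$causes), 0)             # top below 0.4
  expect_equal(r3$indeterminate, 1)

  # never more than max_causes even when all qualify
  r4 <- select_reported_causes(c(A = 0.28, B = 0.26, C = 0.24, D = 0.22),
                               va_settings(top_min = 0.1))
  expect_lte(length(r4$causes), 3)
  expect_true(all(diff(r4$causes) < 0))          # strictly descending
  expect_equal(sum(r4$causes) + r4$indeterminate, 1)
})

test_that("pregnancy status gates on sex and age", {
  kb <- toy_kb()
  probs <- kb_probabilities(kb)

  male <- blank_record(kb, sex = "male")
  pm <- vacoder:::classify_pregnancy_one(male, kb, probs)
  expect_equal(pm$status, "not_pregnant")
  expect_equal(pm$lik, 1)

  # female with pregnancy-pointing evidence: placenta NOT fully delivered
  # is the substantive pole and loads the 'pregnant' column (A+)
  fem <- blank_record(kb, sex = "female")
  fem["placenta"] <- "n"
  pf <- vacoder:::classify_pregnancy_one(fem, kb, probs)
  expect_equal(pf$status, "pregnant")
  # brute-force check of the winning likelihood
  want <- oracle_propagate(fem, probs$pregnancy$prior /
                             sum(probs$pregnancy$prior),
                           probs$pregnancy$conditional, probs$substantive)
  expect_equal(pf$lik, max(want), tolerance = 1e-9)

  # all-missing female record: prior argmax (not_pregnant has prior A+)
  fem0 <- blank_record(kb, sex = "female")
  expect_equal(vacoder:::classify_pregnancy_one(fem0, kb, probs)$status,
               "not_pregnant")
})

test_that("cause classification respects applicability and maternal gating", {
  kb <- toy_kb()
  s <- va_settings()

  # adult male: neonatal and maternal causes are impossible
  male <- blank_record(kb, sex = "male")
  male["fever"] <- "y"
  cm <- classify_case(male, kb, s)
  expect_equal(as.numeric(cm$posterior[c("09.03", "10.01")]), c(0, 0))
  expect_equal(names(cm$causes)[1], "01.01")

  # neonate: adult-applicable-only maternal cause impossible, prematurity not
  neo <- blank_record(kb, age = "neonate", sex = "female")
  cn <- classify_case(neo, kb, s)
  expect_equal(unname(cn$posterior[["09.03"]]), 0)
  expect_gt(unname(cn$posterior[["10.01"]]), 0)

  # adult female with strong maternal evidence
  fem <- blank_record(kb, sex = "female")
  fem["placenta"] <- "n"
  cf <- classify_case(fem, kb, s)
  expect_equal(cf$pregnancy$status, "pregnant")
  expect_equal(names(cf$causes)[1], "09.03")

  # same evidence but maternal gating triggered by a not-pregnant status:
  # force it by blanking pregnancy evidence (prior says not_pregnant)
  fem2 <- blank_record(kb, sex = "female")
  fem2["cough"] <- "y"
  cf2 <- classify_case(fem2, kb, s)
  expect_equal(cf2$pregnancy$status, "not_pregnant")
  expect_equal(unname(cf2$posterior[["09.03"]]), 0)   # gated out

  # gating can be disabled
  cf3 <- classify_case(fem2, kb, va_settings(gate_maternal = FALSE))
  expect_gt(unname(cf3$posterior[["09.03"]]), 0)
})

test_that("COMCAT argmax follows the dominant column and ties break by order", {
  kb <- toy_kb()
  probs <- kb_probabilities(kb)
  r <- blank_record(kb)
  # uniform block + no evidence: prior tie, first category wins
  c0 <- vacoder:::classify_comcat_one(r, kb, probs)
  expect_equal(c0$category, "traditions")
  # cough loads 'traditions' (A+ vs C)
  r["cough"] <- "y"
  c1 <- vacoder:::classify_comcat_one(r, kb, probs)
  expect_equal(c1$category, "traditions")
  expect_gt(c1$lik, 0.9)
  # a KB without the block yields no COMCAT
  kb2 <- toy_kb(); kb2$comcat <- NULL
  cls <- classify_cases(records_from_rows(kb2, list(blank_record(kb2))), kb2)
  expect_true(is.na(cls$COMCAT[1]))
})

test_that("per-case output conserves likelihood and is deterministic", {
  cfg <- sim_config(n_indicators = 16, n_causes = 4, n_cases = 60,
                    missingness = 0.3, seed = 5)
  kb <- generate_kb(cfg)
  co <- generate_cohort(kb, cfg)
  cls <- classify_cases(co$records, kb)
  lik <- rowSums(cbind(cls$LIK1, cls$LIK2, cls$LIK3), na.rm = TRUE)
  expect_equal(lik + cls$INDET, rep(1, nrow(cls)), tolerance = 1e-9)
  # LIK1 >= LIK2 >= LIK3 where present
  has2 <- !is.na(cls$LIK2)
  expect_true(all(cls$LIK1[has2] >= cls$LIK2[has2]))
  # identical records give identical classifications
  cls2 <- classify_cases(co$records, kb)
  expect_identical(cls, cls2)
})
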