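#' Simulation configuration
#'
#' Describes a synthetic study: a knowledge base with planted cause
#' signatures and a cohort drawn from a planted CSMF. The generative
#' assumption is conditional independence of indicators given the cause --
#' the same assumption the propagation model makes -- so recovery of the
#' planted CSMF is a well-posed oracle test of the whole pipeline, not a
#' realism claim about field VA data.
#'
#' @param n_indicators Number of symptom indicators (>= `n_causes`; the
#'   generator adds 5 demographic and 2 pregnancy indicators on top).
#' @param n_causes Number of causes.
#' @param n_cases Cohort size.
#' @param csmf Planted cause fractions (named by cause code or unnamed in
#'   cause order); defaults to a fixed decreasing profile, normalised to 1.
#' @param informativeness In `[0, 1]`: separation between on-signature and
#'   off-signature conditional probabilities. On-signature indicators carry
#'   grade `A+` (0.8 under the default map); off-signature cells carry the
#'   grade nearest `0.8 * (1 - informativeness)`. At 0 every cause column is
#'   identical (no signal); at 1 off-signature cells are grade `N`.
#' @param missingness Per-indicator probability that a symptom response is
#'   missing (demographic indicators are always observed so that records
#'   pass consistency checking).
#' @param seed Integer seed; every random draw in the generator flows from
#'   it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_indicators = 48, n_causes = 4, n_cases = 500,
                       csmf = NULL, informativeness = 0.9,
                       missingness = 0.1, seed = 1) {
  if (n_indicators < n_causes)
    stop("n_indicators must be >= n_causes (each cause needs a signature)",
         call. = FALSE)
  stopifnot(informativeness >= 0, informativeness <= 1,
            missingness >= 0, missingness <= 1, n_cases >= 0)
  if (is.null(csmf)) csmf <- rev(seq_len(n_causes))
  if (length(csmf) != n_causes)
    stop("csmf must have one entry per cause", call. = FALSE)
  if (any(csmf < 0) || sum(csmf) <= 0)
    stop("csmf fractions must be nonnegative with positive sum",
         call. = FALSE)
  csmf <- csmf / sum(csmf)
  if (is.null(names(csmf))) names(csmf) <- sprintf("C%02d", seq_len(n_causes))
  structure(list(n_indicators = n_indicators, n_causes = n_causes,
                 n_cases = n_cases, csmf = csmf,
                 informativeness = informativeness,
                 missingness = missingness, seed = as.integer(seed)),
            class = "sim_config")
}

# grade whose probability is closest to p (ties -> higher grade)
nearest_grade <- function(p, map = default_grade_map()) {
  names(map)[which.min(abs(map - p))]
}

#' Generate a synthetic knowledge base
#'
#' Each cause receives a disjoint signature set of indicators (the symptom
#' indicators split as evenly as possible across causes) graded `A+`;
#' off-signature cells get the low grade implied by `informativeness`, and
#' cause priors are the grades nearest the planted CSMF. Demographic
#' indicators (3 age bands, 2 sexes), two female-only pregnancy indicators
#' feeding a 3-category pregnancy block, and a neutral 3-category COMCAT
#' block complete the KB. Every 7th symptom indicator has substantive
#' polarity "no" to exercise both polarities. The construction is
#' deterministic: the same config yields a byte-identical KB.
#'
#' @param config A [sim_config()].
#' @return A [va_kb].
#' @export
generate_kb <- function(config) {
  map <- default_grade_map()
  p_on <- 0.8
  g_on <- "A+"
  g_off <- nearest_grade(p_on * (1 - config$informativeness), map)
  g_neutral <- "A"

  demog <- data.frame(
    code = c("d_neonate", "d_child", "d_adult", "d_male", "d_female"),
    text = c("Aged under 1 month?", "Aged 1 month to under 5 years?",
             "Aged 5 years or more?", "Was the deceased male?",
             "Was the deceased female?"),
    substantive = "yes", sex = "any", age = "any", group = "",
    demog = c("age:neonate", "age:child", "age:adult",
              "sex:male", "sex:female"),
    who2012 = TRUE, tariff2 = TRUE, stringsAsFactors = FALSE)
  preg <- data.frame(
    code = c("p_preg1", "p_preg2"),
    text = c("Was she pregnant at the time of death?",
             "Had she recently delivered?"),
    substantive = "yes", sex = "female", age = "adult", group = "",
    demog = "", who2012 = TRUE, tariff2 = TRUE, stringsAsFactors = FALSE)
  si <- seq_len(config$n_indicators)
  symp <- data.frame(
    code = sprintf("s%03d", si),
    text = sprintf("Synthetic symptom item %d", si),
    substantive = ifelse(si %% 7 == 0, "no", "yes"),
    sex = "any", age = "any", group = "",
    demog = "",
    who2012 = si %% 3 != 0,        # two thirds in the WHO-2012 subset
    tariff2 = si %% 4 != 0,        # three quarters in the Tariff-2 subset
    stringsAsFactors = FALSE)
  indicators <- rbind(demog, preg, symp)

  codes <- names(config$csmf)
  causes <- data.frame(
    code = codes, label = paste("Synthetic cause", seq_along(codes)),
    broad_group = paste0("Group ", (seq_along(codes) - 1) %% 2 + 1),
    sex = "any", age = "any",
    prior_grade = vapply(config$csmf, nearest_grade, "", map = map),
    stringsAsFactors = FALSE)

  cond <- matrix(g_off, nrow(indicators), length(codes),
                 dimnames = list(indicators$code, codes))
  owner <- rep(seq_along(codes), length.out = config$n_indicators)
  for (k in seq_along(codes))
    cond[symp$code[owner == k], k] <- g_on
  cond[demog$code, ] <- g_on           # constant across causes: cancels
  cond[preg$code, ] <- g_neutral

  preg_cats <- c("pregnant", "recently_delivered", "not_pregnant")
  preg_cond <- matrix(g_neutral, nrow(indicators), 3,
                      dimnames = list(indicators$code, preg_cats))
  preg_cond["p_preg1", ] <- c("A+", "A", "C")
  preg_cond["p_preg2", ] <- c("A", "A+", "C")
  preg_block <- list(categories = preg_cats,
                     prior_grade = stats::setNames(c("A-", "B+", "A+"),
                                                   preg_cats),
                     conditional = preg_cond)

  com_cats <- c("traditions", "emergency", "health_systems")
  com_cond <- matrix(g_neutral, nrow(indicators), 3,
                     dimnames = list(indicators$code, com_cats))
  com_block <- list(categories = com_cats,
                    prior_grade = stats::setNames(c("A+", "A", "A"), com_cats),
                    conditional = com_cond)

  va_kb(indicators, causes, cond, pregnancy = preg_block,
        comcat = com_block, grade_map = map)
}

#' Generate a synthetic cohort with known truth
#'
#' Draws each case's cause from the planted CSMF, then draws every symptom
#' response independently: the substantive response occurs with probability
#' `P(indicator | cause)` from the KB (through the grade map), the opposite
#' response otherwise, and the response is blanked to missing with the
#' configured missingness. All cases are adults with a 50/50 sex split;
#' demographic indicators are set deterministically from the drawn
#' demographics. Fully reproducible from `config$seed`.
#'
#' @param kb KB from [generate_kb()] (same config).
#' @param config A [sim_config()].
#' @return List with `records` (a `va_records`) and `truth` (data frame
#'   `id`, `cause`, `sex`).
#' @export
generate_cohort <- function(kb, config) {
  n <- config$n_cases
  codes <- kb$indicators$code
  ids <- sprintf("case%05d", seq_len(n))
  resp <- matrix("-", n, length(codes), dimnames = list(NULL, codes))
  truth <- data.frame(id = ids, cause = character(n), sex = character(n),
                      stringsAsFactors = FALSE)
  if (n == 0)
    return(list(records = new_va_records(character(0), resp), truth = truth))

  set.seed(config$seed)
  cause <- sample(names(config$csmf), n, replace = TRUE, prob = config$csmf)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  truth$cause <- cause; truth$sex <- sex

  resp[, "d_adult"] <- "y"
  resp[, c("d_neonate", "d_child")] <- "n"
  resp[, "d_male"] <- ifelse(sex == "male", "y", "n")
  resp[, "d_female"] <- ifelse(sex == "female", "y", "n")

  probs <- kb_probabilities(kb)
  subst <- probs$substantive
  flip <- c(y = "n", n = "y")
  stochastic <- codes[kb$indicators$demog == ""]
  p_mat <- probs$conditional[stochastic, , drop = FALSE]
  for (i in seq_len(n)) {
    p <- p_mat[, cause[i]]
    hit <- stats::runif(length(p)) < p
    resp[i, stochastic] <- ifelse(hit, subst[stochastic],
                                  flip[subst[stochastic]])
  }
  if (config$missingness > 0) {
    blank <- matrix(stats::runif(n * length(stochastic)) < config$missingness,
                    n, length(stochastic))
    resp[, stochastic][blank] <- "-"
  }
  # male records should not carry female-only pregnancy answers
  resp[sex == "male", c("p_preg1", "p_preg2")] <- "-"
  list(records = new_va_records(ids, resp), truth = truth)
}
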