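#' Engine settings
#'
#' Tunables for per-case classification. A cause is reported only if its
#' normalised likelihood reaches `top_min`; second and third causes must
#' additionally reach `ratio_min` times the top likelihood; at most
#' `max_causes` are reported and the remainder is the indeterminate
#' residual. `gate_maternal` zeroes the maternal cause block (codes starting
#' with the configured prefix) whenever pregnancy status resolves to
#' not-pregnant/not-applicable.
#'
#' @param top_min Minimum likelihood for the top cause (default 0.4).
#' @param ratio_min Minimum fraction of the top likelihood for causes 2-3
#'   (default 0.5).
#' @param max_causes Maximum reported causes (default 3).
#' @param gate_maternal Zero maternal causes for non-pregnant cases.
#' @param maternal_prefix Cause-code prefix identifying the maternal block.
#' @return Settings object.
#' @export
va_settings <- function(top_min = 0.4, ratio_min = 0.5, max_causes = 3,
                        gate_maternal = TRUE, maternal_prefix = "09.") {
  stopifnot(top_min >= 0, top_min <= 1, ratio_min >= 0, ratio_min <= 1,
            max_causes >= 1)
  structure(list(top_min = top_min, ratio_min = ratio_min,
                 max_causes = max_causes, gate_maternal = gate_maternal,
                 maternal_prefix = maternal_prefix),
            class = "va_settings")
}

#' Bayesian likelihood propagation over a category axis
#'
#' The core update: starting from the unconditional prior over categories,
#' each indicator whose recorded response equals its substantive polarity
#' multiplies in its conditional probability column; missing and
#' non-substantive responses contribute no factor. The result is normalised
#' to sum to one. Categories with zero prior stay at zero. Accumulation is
#' in log space so that long products cannot underflow; results agree with
#' the direct product to well under 1e-9.
#'
#' If every category is annihilated (zero posterior mass everywhere), the
#' fallback is a uniform distribution over the categories with nonzero
#' prior, flagged via `attr(, "fallback")`.
#'
#' @param responses Named character vector of `"y"`/`"n"`/`"-"` responses.
#' @param prior Named nonnegative prior over categories (any scale).
#' @param conditional Numeric probability matrix, indicators x categories.
#' @param substantive Named `"y"`/`"n"` polarity per indicator.
#' @return Named posterior summing to 1, with attribute `fallback`.
#' @examples
#' post <- propagate(c(i1 = "y"), c(A = 0.5, B = 0.5),
#'                   matrix(c(0.8, 0.2), 1, 2,
#'                          dimnames = list("i1", c("A", "B"))),
#'                   c(i1 = "y"))
#' @export
propagate <- function(responses, prior, conditional, substantive) {
  if (is.null(colnames(conditional)) || is.null(names(prior)) ||
      !identical(colnames(conditional), names(prior)))
    stop("prior and conditional matrix must share the category axis",
         call. = FALSE)
  codes <- rownames(conditional)
  if (is.null(codes) || !all(codes %in% names(substantive)))
    stop("conditional rows and substantive polarities do not match",
         call. = FALSE)
  resp <- responses[codes]
  active <- !is.na(resp) & resp != "-" & resp == substantive[codes]
  lp <- log(prior)
  if (any(active)) {
    block <- conditional[active, , drop = FALSE]
    lp <- lp + colSums(log(block))
  }
  if (all(!is.finite(lp)) || all(lp == -Inf)) {
    ok <- prior > 0
    post <- ifelse(ok, 1 / sum(ok), 0)
    names(post) <- names(prior)
    attr(post, "fallback") <- TRUE
    return(post)
  }
  lp <- lp - max(lp[is.finite(lp)])
  w <- exp(lp)
  w[prior == 0] <- 0
  post <- w / sum(w)
  attr(post, "fallback") <- FALSE
  post
}

#' Select the reported causes from a posterior
#'
#' Ranks causes by posterior likelihood and applies the reporting rule of
#' [va_settings()]: the top cause is reported iff it reaches `top_min`;
#' subsequent causes (up to `max_causes`) iff they reach `ratio_min` x the
#' top likelihood. Whatever is not reported is the indeterminate residual,
#' so reported + indeterminate always sums to 1.
#'
#' @param posterior Named normalised likelihood vector.
#' @param settings [va_settings()].
#' @return List with `causes` (named numeric, possibly empty, strictly
#'   descending) and `indeterminate`.
#' @export
select_reported_causes <- function(posterior, settings = va_settings()) {
  ord <- order(-posterior)          # ties broken by KB category order
  ranked <- posterior[ord]
  reported <- numeric(0)
  if (length(ranked) && ranked[1] >= settings$top_min) {
    keep <- 1
    for (k in seq(2, length.out = min(settings$max_causes, length(ranked)) - 1))
      if (ranked[k] >= settings$ratio_min * ranked[1]) keep <- c(keep, k)
    reported <- ranked[keep]
  }
  list(causes = reported, indeterminate = 1 - sum(reported))
}

# pregnancy is only assessed for adult females; everyone else is
# not-pregnant/not-applicable with certainty
classify_pregnancy_one <- function(resp, kb, probs) {
  demo <- resolve_demographics(resp, kb)
  na_status <- c(status = "not_pregnant", lik = 1)
  if (is.null(kb$pregnancy)) return(list(status = "not_pregnant", lik = 1))
  if (!identical(demo$sex, "female") || !identical(demo$age, "adult"))
    return(list(status = "not_pregnant", lik = 1))
  post <- propagate(resp, probs$pregnancy$prior / sum(probs$pregnancy$prior),
                    probs$pregnancy$conditional, probs$substantive)
  i <- which.max(post)
  list(status = names(post)[i], lik = unname(post[i]))
}

classify_cause_one <- function(resp, kb, probs, settings, preg_status) {
  demo <- resolve_demographics(resp, kb)
  prior <- probs$prior
  prior[!applicable_causes(kb, demo$age, demo$sex)] <- 0
  if (settings$gate_maternal && preg_status == "not_pregnant")
    prior[startsWith(names(prior), settings$maternal_prefix)] <- 0
  if (all(prior == 0))
    return(list(causes = numeric(0), indeterminate = 1,
                fallback = TRUE, posterior = prior))
  post <- propagate(resp, prior, probs$conditional, probs$substantive)
  sel <- select_reported_causes(post, settings)
  list(causes = sel$causes, indeterminate = sel$indeterminate,
       fallback = isTRUE(attr(post, "fallback")), posterior = post)
}

classify_comcat_one <- function(resp, kb, probs) {
  if (is.null(kb$comcat)) return(NULL)
  post <- propagate(resp, probs$comcat$prior / sum(probs$comcat$prior),
                    probs$comcat$conditional, probs$substantive)
  i <- which.max(post)
  list(category = names(post)[i], lik = unname(post[i]))
}

#' Classify a single record
#'
#' Composes the three per-case classifiers in processing order: pregnancy
#' status, then cause of death (with age/sex applicability and maternal
#' gating applied to the priors), then the circumstance-of-mortality
#' category. The record must already have passed [check_consistency()].
#'
#' @param responses Named `"y"`/`"n"`/`"-"` vector over the KB indicators.
#' @param kb A [va_kb] (prevalence already applied, see
#'   [apply_prevalence()]).
#' @param settings [va_settings()].
#' @param probs Precomputed [kb_probabilities()] (recomputed if omitted).
#' @return List with `pregnancy`, `causes` (named likelihoods),
#'   `indeterminate`, `comcat`, `fallback`.
#' @export
classify_case <- function(responses, kb, settings = va_settings(),
                          probs = kb_probabilities(kb)) {
  preg <- classify_pregnancy_one(responses, kb, probs)
  cause <- classify_cause_one(responses, kb, probs, settings, preg$status)
  com <- classify_comcat_one(responses, kb, probs)
  list(pregnancy = preg, causes = cause$causes,
       indeterminate = cause$indeterminate, comcat = com,
       fallback = cause$fallback, posterior = cause$posterior)
}

#' Classify a batch of records
#'
#' Runs [classify_case()] over every record and assembles the per-case
#' output table with the stable column order
#' `ID, PREG_STATUS, PREG_LIK, CAUSE1, LIK1, CAUSE2, LIK2, CAUSE3, LIK3,
#' INDET, COMCAT, COMCAT_LIK, WARNINGS`, plus an `AGE_GROUP` column used for
#' CSMF stratification (dropped by [write_classifications()]).
#'
#' @param records Cleaned `va_records` from [check_consistency()].
#' @param kb A [va_kb].
#' @param settings [va_settings()].
#' @return Data frame of class `va_classifications`.
#' @export
classify_cases <- function(records, kb, settings = va_settings()) {
  probs <- kb_probabilities(kb)
  n <- length(records$id)
  out <- data.frame(
    ID = records$id, PREG_STATUS = NA_character_, PREG_LIK = NA_real_,
    CAUSE1 = NA_character_, LIK1 = NA_real_, CAUSE2 = NA_character_,
    LIK2 = NA_real_, CAUSE3 = NA_character_, LIK3 = NA_real_,
    INDET = NA_real_, COMCAT = NA_character_, COMCAT_LIK = NA_real_,
    WARNINGS = records$warnings, AGE_GROUP = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    resp <- records$responses[i, ]
    cl <- classify_case(resp, kb, settings, probs)
    out$PREG_STATUS[i] <- cl$pregnancy$status
    out$PREG_LIK[i] <- cl$pregnancy$lik
    cs <- cl$causes
    for (k in seq_len(min(3, length(cs)))) {
      out[[paste0("CAUSE", k)]][i] <- names(cs)[k]
      out[[paste0("LIK", k)]][i] <- unname(cs[k])
    }
    out$INDET[i] <- cl$indeterminate
    if (!is.null(cl$comcat)) {
      out$COMCAT[i] <- cl$comcat$category
      out$COMCAT_LIK[i] <- cl$comcat$lik
    }
    if (cl$fallback)
      out$WARNINGS[i] <- paste0(out$WARNINGS[i], "fallback_uniform;")
    demo <- resolve_demographics(resp, kb)
    out$AGE_GROUP[i] <- if (identical(demo$age, "adult")) "5plus" else "under5"
  }
  class(out) <- c("va_classifications", "data.frame")
  out
}

#' Write the per-case output CSV
#'
#' Emits the contract columns in their stable order (without the internal
#' `AGE_GROUP` stratification helper).
#'
#' @param classifications From [classify_cases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  cols <- c("ID", "PREG_STATUS", "PREG_LIK", "CAUSE1", "LIK1", "CAUSE2",
            "LIK2", "CAUSE3", "LIK3", "INDET", "COMCAT", "COMCAT_LIK",
            "WARNINGS")
  utils::write.csv(as.data.frame(classifications)[, cols], path,
                   row.names = FALSE, na = "")
  invisible(path)
}
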