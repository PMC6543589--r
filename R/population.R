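#' @title CSMF tables
#'
#' @description A cause-specific mortality fraction (CSMF) table assigns each
#' stratum x cause pair the fraction of that stratum's deaths attributed to
#' the cause. Tables are plain data frames with columns `stratum`, `cause`,
#' `label`, `broad_group`, `fraction` and class `csmf_table`; per-stratum
#' death counts live in `attr(, "n_deaths")`. Fractions are proportions
#' internally; rendering as percentages is left to [format_csmf()].
#' @name csmf
NULL

new_csmf_table <- function(df, n_deaths = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("csmf_table", "data.frame"),
            n_deaths = n_deaths)
}

INDET_CODE <- "99"

#' Aggregate case classifications into a CSMF table
#'
#' Population fractions are the mean over cases of the individually assigned
#' likelihoods: for each stratum, `CSMF(c)` is the sum over that stratum's
#' cases of the reported likelihood for cause `c`, divided by the stratum
#' death count. Indeterminate residuals aggregate identically under cause
#' code `"99"`. Only reported (post-threshold) likelihoods enter, so the
#' table is consistent with the per-case output rows. Every KB cause appears
#' in every nonempty stratum, including zero rows. Per stratum,
#' `sum(fractions) == 1` to numerical precision.
#'
#' @param classifications A `va_classifications` data frame.
#' @param kb The [va_kb] (supplies cause vocabulary, labels, broad groups).
#' @param strata Name of the stratification column (default the engine's
#'   `AGE_GROUP`: `under5` vs `5plus`).
#' @return A `csmf_table`.
#' @export
aggregate_csmf <- function(classifications, kb, strata = "AGE_GROUP") {
  if (!nrow(classifications)) stop("no classifications to aggregate",
                                   call. = FALSE)
  cl <- as.data.frame(classifications)
  codes <- c(kb$causes$code, INDET_CODE)
  labels <- c(kb$causes$label, "Indeterminate")
  groups <- c(kb$causes$broad_group, "Indeterminate")
  out <- list(); n_deaths <- c()
  for (s in unique(cl[[strata]])) {
    rows <- cl[cl[[strata]] == s, , drop = FALSE]
    n <- nrow(rows)
    acc <- stats::setNames(numeric(length(codes)), codes)
    for (k in 1:3) {
      cc <- rows[[paste0("CAUSE", k)]]
      lk <- rows[[paste0("LIK", k)]]
      ok <- !is.na(cc)
      if (any(ok)) {
        sums <- tapply(lk[ok], cc[ok], sum)
        acc[names(sums)] <- acc[names(sums)] + sums
      }
    }
    acc[INDET_CODE] <- sum(rows$INDET)
    out[[s]] <- data.frame(stratum = s, cause = codes, label = labels,
                           broad_group = groups,
                           fraction = as.numeric(acc) / n,
                           stringsAsFactors = FALSE)
    n_deaths[s] <- n
  }
  new_csmf_table(do.call(rbind, out), n_deaths)
}

#' Remove the indeterminate fraction by proportional redistribution
#'
#' Within each stratum the indeterminate row is dropped and every cause
#' fraction is scaled by `1 / (1 - indeterminate)`, so causes keep their
#' relative proportions and the stratum again sums to one. A stratum that is
#' entirely indeterminate cannot be rescaled and is an error. Idempotent: a
#' table without an indeterminate row passes through unchanged.
#'
#' @param table A `csmf_table`.
#' @return A `csmf_table` without indeterminate rows.
#' @export
redistribute_indeterminate <- function(table) {
  out <- lapply(split(as.data.frame(table), table$stratum), function(d) {
    ind <- d$cause == INDET_CODE
    if (!any(ind)) return(d)
    p <- sum(d$fraction[ind])
    if (p >= 1 - 1e-12)
      stop("stratum '", d$stratum[1],
           "' is fully indeterminate; nothing to redistribute",
           call. = FALSE)
    d <- d[!ind, , drop = FALSE]
    d$fraction <- d$fraction / (1 - p)
    d
  })
  new_csmf_table(do.call(rbind, out), attr(table, "n_deaths"))
}

#' Merge (amalgamate) cause categories
#'
#' Sums the fractions of source causes into a target cause, e.g. collapsing
#' fresh and macerated stillbirths into a single stillbirth category, or the
#' two haemorrhagic-fever categories into one, when comparing against a
#' source that does not make the distinction. Total mass is conserved.
#'
#' @param table A `csmf_table`.
#' @param merge_map Named character vector `source code -> target code`.
#'   Targets may be existing or new codes; chains/cycles are rejected.
#' @param labels Optional named labels for newly created target codes.
#' @return A `csmf_table`.
#' @export
merge_causes <- function(table, merge_map, labels = NULL) {
  if (!length(merge_map)) return(table)
  if (any(names(merge_map) %in% merge_map))
    stop("merge_map must not chain or cycle", call. = FALSE)
  out <- lapply(split(as.data.frame(table), table$stratum), function(d) {
    for (src in names(merge_map)) {
      tgt <- merge_map[[src]]
      i <- which(d$cause == src)
      if (!length(i)) next
      j <- which(d$cause == tgt)
      if (!length(j)) {
        add <- d[i, , drop = FALSE]
        add$cause <- tgt
        add$label <- if (!is.null(labels) && tgt %in% names(labels))
          labels[[tgt]] else tgt
        d <- rbind(d, add)
        d <- d[-i, , drop = FALSE]
      } else {
        d$fraction[j] <- d$fraction[j] + d$fraction[i]
        d <- d[-i, , drop = FALSE]
      }
    }
    d
  })
  new_csmf_table(do.call(rbind, out), attr(table, "n_deaths"))
}

#' Roll a CSMF table up into broad cause groups
#'
#' Group fractions are the sums of their member causes, conserving the
#' stratum total. Every cause must carry a broad group.
#'
#' @param table A `csmf_table` with a `broad_group` column.
#' @return A `csmf_table` whose `cause` axis is the broad groups.
#' @export
broad_groups <- function(table) {
  d <- as.data.frame(table)
  if (any(is.na(d$broad_group) | !nzchar(d$broad_group))) {
    bad <- unique(d$cause[is.na(d$broad_group) | !nzchar(d$broad_group)])
    stop("cause(s) without a broad group: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(fraction ~ stratum + broad_group, d, sum)
  out <- data.frame(stratum = agg$stratum, cause = agg$broad_group,
                    label = agg$broad_group, broad_group = agg$broad_group,
                    fraction = agg$fraction, stringsAsFactors = FALSE)
  out <- out[order(out$stratum, out$cause), ]
  new_csmf_table(out, attr(table, "n_deaths"))
}

#' Render a CSMF table as percentages
#'
#' @param table A `csmf_table` (fractions as proportions).
#' @param digits Decimal places (default 2, the conventional tabulation).
#' @return Data frame with a `percent` column.
#' @export
format_csmf <- function(table, digits = 2) {
  d <- as.data.frame(table)
  d$percent <- round(100 * d$fraction, digits)
  d$fraction <- NULL
  d
}

#' Write a CSMF table to CSV
#' @param table A `csmf_table`.
#' @param path Output path.
#' @param percent Write percentages (2 dp) instead of proportions.
#' @return `path`, invisibly.
#' @export
write_csmf <- function(table, path, percent = FALSE) {
  d <- if (percent) format_csmf(table) else as.data.frame(table)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
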