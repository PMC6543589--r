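#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with population (n-denominator) moments, the convention of the Stata
#' `concord` command. \eqn{|\rho_c| \le |r|} always, with equality only when
#' the fit is exactly the identity line; a location or scale shift between
#' the vectors lowers \eqn{\rho_c} even at perfect correlation.
#'
#' The default 95\% interval applies the normal approximation on Fisher's z
#' transform with Lin's variance (n - 2 denominator); `ci = "boot"` gives a
#' percentile bootstrap over pairs instead.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing pairs.
#' @param conf_level Confidence level (default 0.95).
#' @param ci `"z"` (Fisher z, default) or `"boot"`.
#' @param n_boot Bootstrap replicates when `ci = "boot"`.
#' @return Object of class `ccc_estimate`: `rho_c`, `ci_low`, `ci_high`,
#'   `n`, plus the Pearson `r` and bias-correction factor `c_b`
#'   (`rho_c = r * c_b`).
#' @examples
#' concordance_correlation(c(1, 2, 3), c(2, 3, 4))  # rho_c = 4/7
#' @export
concordance_correlation <- function(x, y, conf_level = 0.95,
                                    ci = c("z", "boot"), n_boot = 2000) {
  ci <- match.arg(ci)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired points", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed",
                                 call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean(x^2) - mx^2
  sy2 <- mean(y^2) - my^2
  sxy <- mean(x * y) - mx * my
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    stop("both vectors constant with equal means: rho_c undefined",
         call. = FALSE)
  rho <- 2 * sxy / denom

  if (sx2 == 0 || sy2 == 0) {
    r <- NA_real_
    lo <- hi <- NA_real_
  } else {
    r <- sxy / sqrt(sx2 * sy2)
    if (ci == "boot") {
      reps <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        xb <- x[i]; yb <- y[i]
        sxb <- mean(xb^2) - mean(xb)^2; syb <- mean(yb^2) - mean(yb)^2
        d <- sxb + syb + (mean(xb) - mean(yb))^2
        if (d == 0) NA_real_ else
          2 * (mean(xb * yb) - mean(xb) * mean(yb)) / d
      }, numeric(1))
      qs <- stats::quantile(reps, c((1 - conf_level) / 2,
                                    1 - (1 - conf_level) / 2), na.rm = TRUE)
      lo <- qs[[1]]; hi <- qs[[2]]
    } else if (abs(rho) >= 1 - 1e-15 || abs(r) < 1e-15) {
      # degenerate: perfect concordance (or zero correlation) has no
      # finite-z interval; collapse to the point estimate
      lo <- hi <- rho
    } else {
      u <- (mx - my) / (sx2 * sy2)^0.25
      v2 <- (1 - r^2) * rho^2 / ((1 - rho^2) * r^2) +
        2 * rho^3 * (1 - rho) * u^2 / (r * (1 - rho^2)^2) -
        rho^4 * u^4 / (2 * r^2 * (1 - rho^2)^2)
      se_z <- sqrt(v2 / (n - 2))
      z <- atanh(rho)
      q <- stats::qnorm(1 - (1 - conf_level) / 2)
      lo <- tanh(z - q * se_z); hi <- tanh(z + q * se_z)
    }
  }
  structure(list(rho_c = rho, ci_low = lo, ci_high = hi, n = n,
                 r = r, c_b = if (is.na(r) || r == 0) NA_real_ else rho / r,
                 conf_level = conf_level, ci_method = ci),
            class = "ccc_estimate")
}

#' @export
print.ccc_estimate <- function(x, ...) {
  cat(sprintf("Lin's CCC: %.3f (%d%% CI %.3f to %.3f), n = %d\n",
              x$rho_c, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Compare two CSMF tables by concordance
#'
#' Builds paired fraction vectors over the cause categories present in both
#' tables for a stratum (zero fractions on rare causes are retained -- they
#' are informative near-axis points) and computes Lin's CCC on the pairs.
#' The indeterminate row, when both tables carry one, is included as a point
#' by default; post-redistribution tables have none, so the flag is moot
#' there.
#'
#' @param a,b `csmf_table` objects sharing a cause vocabulary.
#' @param stratum Stratum to compare.
#' @param include_indeterminate Include cause code `"99"` as a pair.
#' @param ... Passed to [concordance_correlation()].
#' @return List with `pairs` (cause, x, y, abs_diff) and `ccc`.
#' @export
compare_csmf <- function(a, b, stratum, include_indeterminate = TRUE, ...) {
  pick <- function(t) {
    d <- as.data.frame(t)
    d <- d[d$stratum == stratum, , drop = FALSE]
    stats::setNames(d$fraction, d$cause)
  }
  xa <- pick(a); xb <- pick(b)
  shared <- intersect(names(xa), names(xb))
  if (!include_indeterminate) shared <- setdiff(shared, INDET_CODE)
  if (length(shared) < 3)
    stop("fewer than 3 shared cause categories in stratum '", stratum, "'",
         call. = FALSE)
  pairs <- data.frame(cause = shared, x = unname(xa[shared]),
                      y = unname(xb[shared]),
                      abs_diff = abs(unname(xa[shared] - xb[shared])),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, ccc = concordance_correlation(pairs$x, pairs$y, ...))
}

#' Packaged published CSMF evaluation tables
#'
#' Two CSMF tables from the model's published evaluation, shipped as
#' fixtures so the concordance machinery can be exercised against reported
#' results without any external download. `"phmrc"`: 6130 deaths from the
#' PHMRC verbal-autopsy reference dataset, tertiary-hospital-assigned vs
#' model-assigned CSMFs (columns `phmrc`, `interva5`), indeterminate already
#' redistributed. `"afghanistan"`: 4009 deaths from the Afghanistan national
#' mortality survey processed under the three input formats (columns
#' `who2016`, `who2012`, `tariff2`), indeterminate retained as cause `"99"`.
#' Values are printed percentages (2 dp); both strata `under5` and `5plus`.
#'
#' @param dataset `"phmrc"` or `"afghanistan"`.
#' @param broad Load the published broad-group rows instead of the
#'   per-cause rows.
#' @return A data frame; turn a column into a `csmf_table` with
#'   [as_csmf_table()].
#' @export
load_csmf_fixture <- function(dataset = c("phmrc", "afghanistan"),
                              broad = FALSE) {
  dataset <- match.arg(dataset)
  f <- system.file("extdata",
                   paste0("csmf_", dataset, if (broad) "_broad", ".csv"),
                   package = "vacoder", mustWork = TRUE)
  utils::read.csv(f,
                  colClasses = if (broad) NA else c(cause = "character"),
                  stringsAsFactors = FALSE)
}

#' Coerce one column of a CSMF data frame into a `csmf_table`
#'
#' @param df Data frame with `stratum`, `cause` and the value column; as
#'   from [load_csmf_fixture()].
#' @param value Name of the column holding the fractions.
#' @param percent Is the column in percent (divided by 100 on the way in)?
#' @return A `csmf_table`.
#' @export
as_csmf_table <- function(df, value, percent = TRUE) {
  out <- data.frame(stratum = df$stratum, cause = as.character(df$cause),
                    label = if ("label" %in% names(df)) df$label
                            else as.character(df$cause),
                    broad_group = if ("broad_group" %in% names(df))
                      df$broad_group else "",
                    fraction = df[[value]] / if (percent) 100 else 1,
                    stringsAsFactors = FALSE)
  new_csmf_table(out)
}
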