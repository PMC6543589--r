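#' @title VA record input and format harmonisation
#'
#' @description Records arrive as a CSV with one identifier column followed
#' by one column per KB indicator, one row per death. Responses are ternary:
#' yes / no / missing. The WHO-2012 and Tariff-2 instruments are strict
#' subsets of the WHO-2016 indicator set, so harmonisation is a masking
#' operation: responses outside the target subset become missing.
#'
#' @details Internally responses are coded `"y"`, `"n"`, `"-"` in a character
#' matrix (cases x indicators) wrapped in class `va_records` alongside the
#' identifier vector. The identifier is carried through verbatim and never
#' interpreted.
#' @name records_io
NULL

#' Response token dialect
#'
#' Maps raw CSV tokens to the ternary response scale. The default mirrors
#' the InterVA CSV lineage: `Y`/`y`/`1` are yes, `N`/`n`/`0` are no, `.` and
#' blank are missing; any unrecognised token is normalised to missing.
#'
#' @param yes,no,missing Character vectors of accepted tokens.
#' @return A dialect object for [read_va_csv()].
#' @export
va_dialect <- function(yes = c("Y", "y", "1", "yes"),
                       no = c("N", "n", "0", "no"),
                       missing = c(".", "", "-", "NA")) {
  structure(list(yes = yes, no = no, missing = missing),
            class = "va_dialect")
}

new_va_records <- function(id, responses, warnings = NULL) {
  structure(list(id = id, responses = responses,
                 warnings = warnings %||% rep("", length(id))),
            class = "va_records")
}

#' @export
print.va_records <- function(x, ...) {
  cat("<va_records> ", length(x$id), " records x ",
      ncol(x$responses), " indicators\n", sep = "")
  tab <- table(factor(x$responses, levels = c("y", "n", "-")))
  cat("  responses: yes ", tab[["y"]], ", no ", tab[["n"]],
      ", missing ", tab[["-"]], "\n", sep = "")
  invisible(x)
}

#' @export
length.va_records <- function(x) length(x$id)

#' Read a VA input CSV against a knowledge base
#'
#' The header must consist of one identifier column followed by exactly the
#' KB's indicator codes (any order). Unknown or absent columns are a hard
#' failure naming the mismatches; short rows fail with the row number.
#'
#' @param path Input CSV path.
#' @param kb The [va_kb] the records will be processed against.
#' @param dialect Token dialect, see [va_dialect()].
#' @return A `va_records` object.
#' @export
read_va_csv <- function(path, kb, dialect = va_dialect()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2) stop("input must have an id column plus indicators",
                          call. = FALSE)
  codes <- kb$indicators$code
  got <- names(raw)[-1]
  extra <- setdiff(got, codes)
  absent <- setdiff(codes, got)
  if (length(extra) || length(absent))
    stop("input header does not match KB indicators",
         if (length(extra)) paste0("; unknown column(s): ",
                                   paste(extra, collapse = ", ")),
         if (length(absent)) paste0("; missing column(s): ",
                                    paste(absent, collapse = ", ")),
         call. = FALSE)
  m <- as.matrix(raw[, codes, drop = FALSE])
  norm <- matrix("-", nrow(m), ncol(m), dimnames = list(NULL, codes))
  norm[m %in% dialect$yes] <- "y"
  norm[m %in% dialect$no] <- "n"
  new_va_records(raw[[1]], norm)
}

#' Write VA records back to CSV
#'
#' Uses the canonical tokens `Y`/`N`/`.`; composing with [read_va_csv()] is
#' the identity on the response map.
#'
#' @param records A `va_records` object.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_va_csv <- function(records, path, id_col = "ID") {
  out <- records$responses
  out[out == "y"] <- "Y"; out[out == "n"] <- "N"; out[out == "-"] <- "."
  df <- data.frame(records$id, out, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Indicator format registry
#'
#' Membership of each indicator in the WHO-2016, WHO-2012 and Tariff-2
#' instrument subsets. Every indicator belongs to WHO-2016 by construction;
#' the registry only records the two subset memberships.
#'
#' @param kb A [va_kb] (membership flags live on its indicator table).
#' @return Data frame `code`, `who2016`, `who2012`, `tariff2`.
#' @export
format_registry <- function(kb) {
  data.frame(code = kb$indicators$code, who2016 = TRUE,
             who2012 = kb$indicators$who2012,
             tariff2 = kb$indicators$tariff2,
             stringsAsFactors = FALSE)
}

#' Read a format registry CSV
#'
#' For user-supplied full registries (e.g. the 353/245/241-indicator
#' instrument definitions): columns `code,who2012,tariff2` with 0/1 flags.
#'
#' @param path Registry CSV path.
#' @return Data frame as [format_registry()].
#' @export
read_format_registry <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (!all(c("code", "who2012", "tariff2") %in% names(raw)))
    stop("registry needs columns code, who2012, tariff2", call. = FALSE)
  data.frame(code = raw$code, who2016 = TRUE,
             who2012 = raw$who2012 %in% c("1", "TRUE", "true", "yes"),
             tariff2 = raw$tariff2 %in% c("1", "TRUE", "true", "yes"),
             stringsAsFactors = FALSE)
}

#' Restrict records to an input-format subset
#'
#' Responses on indicators outside the target instrument subset are set to
#' missing; member indicators and identifiers are untouched. Converting to
#' WHO-2016 is the identity; conversion is idempotent.
#'
#' @param records A `va_records` object.
#' @param target `"who2016"`, `"who2012"` or `"tariff2"`.
#' @param registry Registry data frame, defaulting to the KB's own flags
#'   when `kb` is given.
#' @param kb Optional [va_kb] supplying the registry.
#' @return Masked `va_records`.
#' @export
convert_format <- function(records, target = c("who2016", "who2012", "tariff2"),
                           registry = NULL, kb = NULL) {
  target <- match.arg(target)
  if (target == "who2016") return(records)
  if (is.null(registry)) {
    if (is.null(kb)) stop("supply a registry or a kb", call. = FALSE)
    registry <- format_registry(kb)
  }
  member <- stats::setNames(registry[[target]], registry$code)
  codes <- colnames(records$responses)
  out <- !vapply(codes, function(cd) isTRUE(member[[cd]]), logical(1))
  records$responses[, out] <- "-"
  records
}

#' Binarise a continuous measurement into category indicators
#'
#' The input formats represent continuous items (e.g. symptom durations) as
#' banks of mutually exclusive binary category indicators with left-closed,
#' right-open bands. Given `k` cut points there are `k + 1` bands; exactly
#' one is yes, the others no. A missing measurement yields all-missing.
#'
#' @param value Numeric measurement (or `NA`).
#' @param cut_points Strictly increasing numeric thresholds.
#' @param codes Optional indicator codes for the bands (length
#'   `length(cut_points) + 1`).
#' @return Named character vector of responses (`"y"`/`"n"`/`"-"`).
#' @examples
#' # a 10-day fever with week cut points lands in the 1-2 week band
#' binarize_category(10, c(7, 14))
#' @export
binarize_category <- function(value, cut_points, codes = NULL) {
  if (is.unsorted(cut_points, strictly = TRUE))
    stop("cut_points must be strictly increasing", call. = FALSE)
  n_band <- length(cut_points) + 1
  if (is.null(codes)) codes <- paste0("band", seq_len(n_band))
  if (length(codes) != n_band)
    stop("need one code per band (", n_band, ")", call. = FALSE)
  if (is.null(value) || is.na(value))
    return(stats::setNames(rep("-", n_band), codes))
  band <- findInterval(value, cut_points) + 1  # [cut_k, cut_{k+1}) bands
  out <- rep("n", n_band)
  out[band] <- "y"
  stats::setNames(out, codes)
}
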