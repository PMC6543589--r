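#' Letter-grade probability ladder
#'
#' Knowledge bases encode conditional probabilities as letter grades rather
#' than raw numbers, running from `A+` (strongly expected response) down to
#' `E` (barely conceivable) and `N` (no association at all, probability 0).
#' `default_grade_map()` returns the package's default mapping from grade to
#' probability; any strictly decreasing substitute can be supplied wherever a
#' `grade_map` argument is accepted, e.g. to mirror the numeric encoding of a
#' user-supplied published knowledge base.
#'
#' @return Named numeric vector, names are grades in ladder order (`A+` ...
#'   `E`, `N`), values are probabilities in `[0, 1]`, strictly decreasing
#'   down the ladder with `N = 0`.
#' @examples
#' default_grade_map()
#' @export
default_grade_map <- function() {
  c("A+" = 0.8,    "A"  = 0.5,    "A-" = 0.2,
    "B+" = 0.1,    "B"  = 0.05,   "B-" = 0.02,
    "C+" = 0.01,   "C"  = 0.005,  "C-" = 0.002,
    "D+" = 0.001,  "D"  = 0.0005, "D-" = 0.0001,
    "E"  = 0.00001, "N" = 0)
}

#' Canonical grade ladder order
#' @keywords internal
#' @noRd
grade_ladder <- function() names(default_grade_map())

validate_grade_map <- function(map) {
  if (is.null(names(map)) || any(!nzchar(names(map))))
    stop("grade map must be a named numeric vector", call. = FALSE)
  if (any(map < 0 | map > 1))
    stop("grade map probabilities must lie in [0, 1]", call. = FALSE)
  ladder <- intersect(grade_ladder(), names(map))
  probs <- map[ladder]
  non_n <- probs[names(probs) != "N"]
  if (length(non_n) > 1 && any(diff(non_n) >= 0))
    stop("grade map must be strictly decreasing from A+ to E", call. = FALSE)
  if ("N" %in% names(map) && map[["N"]] != 0)
    stop("grade 'N' must map to probability 0", call. = FALSE)
  invisible(map)
}

#' Resolve letter grades to probabilities
#'
#' @param grade Character vector of grade tokens.
#' @param map Named numeric grade map, see [default_grade_map()].
#' @return Numeric vector of probabilities.
#' @examples
#' grade_to_probability(c("A+", "N"))
#' @export
grade_to_probability <- function(grade, map = default_grade_map()) {
  validate_grade_map(map)
  bad <- setdiff(unique(grade), names(map))
  if (length(bad))
    stop("unknown grade token(s): ", paste(shQuote(bad), collapse = ", "),
         call. = FALSE)
  unname(map[grade])
}
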