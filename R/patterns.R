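# The five maltreatment types and the 32 mutually exclusive exposure patterns.

# Canonical type order; it fixes the bit order of the 5-character pattern code.
MALTREATMENT_TYPES <- c(
  physical_abuse = "PA",
  sexual_abuse   = "SA",
  emotional_abuse = "EA",
  neglect        = "N",
  exposure_dv    = "EDV"
)

#' The five maltreatment types
#'
#' @return A tibble with columns `type` (column name used in microdata) and
#'   `abbrev` (PA, SA, EA, N, EDV), in canonical order.
#' @export
maltreatment_types <- function() {
  tibble::tibble(type = names(MALTREATMENT_TYPES),
                 abbrev = unname(MALTREATMENT_TYPES))
}

#' Enumerate the 32 maltreatment patterns
#'
#' Every combination of the five binary maltreatment types (physical abuse,
#' sexual abuse, emotional abuse, neglect, exposure to domestic violence)
#' defines one mutually exclusive exposure pattern. Patterns are identified by
#' a 5-character 0/1 code in bit order PA, SA, EA, N, EDV (PA is the leading
#' character) and ordered by the integer value of that code, so the all-zero
#' (unexposed) pattern comes first.
#'
#' @return A 32-row tibble with columns `pattern` (the string code), one 0/1
#'   column per type, and `n_types` (number of types in the pattern).
#' @export
#' @examples
#' enumerate_patterns()
enumerate_patterns <- function() {
  flags <- t(vapply(0:31, function(i) as.integer(intToBits(i))[5:1], integer(5)))
  colnames(flags) <- names(MALTREATMENT_TYPES)
  out <- tibble::as_tibble(flags)
  out$pattern <- apply(flags, 1, paste, collapse = "")
  out$n_types <- rowSums(flags)
  dplyr::relocate(out, "pattern")
}

#' Build a pattern code from type flags
#'
#' @param data A data frame containing the five 0/1 type columns
#'   (`physical_abuse`, `sexual_abuse`, `emotional_abuse`, `neglect`,
#'   `exposure_dv`).
#' @return Character vector of 5-character pattern codes.
#' @export
pattern_code <- function(data) {
  cols <- names(MALTREATMENT_TYPES)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) stop("missing exposure columns: ", paste(missing, collapse = ", "))
  m <- as.matrix(data[cols])
  if (!all(m %in% c(0, 1))) stop("exposure flags must be 0/1")
  apply(m, 1, paste, collapse = "")
}

#' Parse pattern codes into type flags
#'
#' Inverse of [pattern_code()].
#'
#' @param code Character vector of 5-character 0/1 codes (bit order PA, SA,
#'   EA, N, EDV).
#' @return Tibble with `pattern` and the five 0/1 type columns.
#' @export
parse_pattern <- function(code) {
  if (!all(grepl("^[01]{5}$", code))) stop("pattern codes must be 5-character 0/1 strings")
  flags <- do.call(rbind, lapply(strsplit(code, ""), as.integer))
  colnames(flags) <- names(MALTREATMENT_TYPES)
  dplyr::bind_cols(tibble::tibble(pattern = code), tibble::as_tibble(flags))
}

#' Count maltreatment types in a pattern
#'
#' @param pattern Character vector of pattern codes.
#' @return Integer vector in 0..5 (popcount of the code).
#' @export
count_types <- function(pattern) {
  if (!all(grepl("^[01]{5}$", pattern))) stop("pattern codes must be 5-character 0/1 strings")
  vapply(strsplit(pattern, ""), function(b) sum(as.integer(b)), numeric(1))
}

# The six most common multi-type patterns, which are frequent enough to carry
# their own relative risks; codes in bit order PA,SA,EA,N,EDV.
SIX_COMMON_PATTERNS <- c(
  "11101" = "EDV+EA+PA+SA",
  "10101" = "EDV+EA+PA",
  "00101" = "EDV+EA",
  "11111" = "EDV+EA+PA+SA+N",
  "10001" = "EDV+PA",
  "01001" = "EDV+SA"
)

#' Exposure-level coding of the 32 patterns
#'
#' Maps each of the 32 patterns to the exposure level at which relative risks
#' are estimated. Two codings are supported:
#'
#' * `"count"`: number of maltreatment types experienced, levels `"0"`..`"5"`;
#'   level `"0"` is exactly the unexposed pattern.
#' * `"patterns"`: the six most common multi-type patterns each form their own
#'   level (`"EDV+EA+PA+SA"`, `"EDV+EA+PA"`, `"EDV+EA"`, `"EDV+EA+PA+SA+N"`,
#'   `"EDV+PA"`, `"EDV+SA"`); the remaining 26 patterns occur too rarely to
#'   support pattern-specific risks and fall back to their type count
#'   (`"0"`, `"1"`, `"2_other"`, `"3_other"`, `"4_other"`).
#'
#' Every pattern maps to exactly one level, so the levels partition the 32
#' patterns under either coding.
#'
#' @param mode `"count"` or `"patterns"`.
#' @return A 32-row tibble with columns `pattern`, `level` and `n_types`;
#'   attribute `mode` records the coding.
#' @export
#' @examples
#' exposure_coding("count")
#' dplyr::filter(exposure_coding("patterns"), pattern == "00101")
exposure_coding <- function(mode = c("count", "patterns")) {
  mode <- match.arg(mode)
  pats <- enumerate_patterns()
  level <- as.character(pats$n_types)
  if (mode == "patterns") {
    named <- unname(SIX_COMMON_PATTERNS[pats$pattern])
    fallback <- ifelse(pats$n_types >= 2, paste0(pats$n_types, "_other"), level)
    level <- ifelse(is.na(named), fallback, named)
  }
  out <- tibble::tibble(pattern = pats$pattern, level = level, n_types = pats$n_types)
  attr(out, "mode") <- mode
  out
}

#' Map patterns to exposure levels
#'
#' @param pattern Character vector of pattern codes.
#' @param coding A coding table from [exposure_coding()] (or the mode string).
#' @return Character vector of level labels.
#' @export
map_to_level <- function(pattern, coding = exposure_coding("count")) {
  if (is.character(coding) && length(coding) == 1) coding <- exposure_coding(coding)
  lev <- coding$level[match(pattern, coding$pattern)]
  if (anyNA(lev)) stop("unknown pattern code(s): ",
                       paste(unique(pattern[is.na(lev)]), collapse = ", "))
  unname(lev)
}

# Ordered level labels for a coding (reference first).
coding_levels <- function(coding) {
  ord <- coding[order(coding$n_types, coding$level), ]
  unique(ord$level)
}
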