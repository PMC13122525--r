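# Validated CSV readers/writers for the pipeline's table formats.
#
# Age-group labels are canonical en-dash strings ("20–24"); an ASCII-hyphen
# alias ("20-24") is accepted on input and normalised. Gender labels are
# restricted to "women"/"men" (the analysis excludes other categories by
# scope). All readers fail with the offending row numbers.

#' Read a 32-pattern prevalence table
#'
#' Schema: `gender, age_group, pattern, proportion` (optional
#' `effective_n`, `modelled_count`). Each gender x age-group stratum must
#' contain all 32 patterns exactly once with proportions summing to 1
#' within `1e-6`.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_prevalence_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  require_cols(tab, c("gender", "age_group", "pattern", "proportion"), path)
  tab$gender <- validate_gender(tab$gender)
  tab$age_group <- normalise_age_group(tab$age_group)
  check_age_labels(tab$age_group)
  bad <- which(!grepl("^[01]{5}$", tab$pattern))
  if (length(bad) > 0) stop("invalid pattern code in row(s): ", head_rows(bad))
  bad <- which(!is.finite(tab$proportion) | tab$proportion < 0 | tab$proportion > 1)
  if (length(bad) > 0) stop("proportions must be in [0,1]; bad row(s): ", head_rows(bad))
  chk <- tab |>
    dplyr::group_by(.data$gender, .data$age_group) |>
    dplyr::summarise(n_pat = dplyr::n_distinct(.data$pattern), n = dplyr::n(),
                     total = sum(.data$proportion), .groups = "drop")
  bad <- chk[chk$n_pat != 32 | chk$n != 32 | abs(chk$total - 1) > 1e-6, ]
  if (nrow(bad) > 0) {
    stop("strata must hold the 32 patterns once each with proportions summing to 1: ",
         paste(paste0(bad$gender, "/", bad$age_group,
                      " (n=", bad$n, ", sum=", signif(bad$total, 6), ")"),
               collapse = "; "))
  }
  tab
}

#' Read a relative-risk table
#'
#' Wrapper around [load_rr_table()] for CSVs with schema
#' `outcome, gender, coding, level, rr, lcl, ucl`.
#'
#' @param path CSV path.
#' @return Validated RR tibble (reference level inserted where absent).
#' @export
read_rr_csv <- function(path) load_rr_table(path)

#' Read a burden-of-disease table
#'
#' Schema: `cause, gender, age_group, deaths, yll, yld, daly` (optional
#' `burden_type`). All quantities must be non-negative and
#' `daly = yll + yld` within `1e-6` relative.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_burden_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  require_cols(tab, c("cause", "gender", "age_group", "deaths", "yll", "yld", "daly"), path)
  tab$gender <- validate_gender(tab$gender)
  tab$age_group <- normalise_age_group(tab$age_group)
  num <- c("deaths", "yll", "yld", "daly")
  for (col in num) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] < 0)
    if (length(bad) > 0) stop("column ", col, " must be non-negative; bad row(s): ",
                              head_rows(bad))
  }
  rel <- abs(tab$daly - (tab$yll + tab$yld)) / pmax(tab$daly, 1)
  bad <- which(rel > 1e-6)
  if (length(bad) > 0) stop("daly must equal yll + yld; bad row(s): ", head_rows(bad))
  if (!"burden_type" %in% names(tab)) tab$burden_type <- "total"
  tab
}

#' Write a table as CSV
#'
#' Plain CSV writer used for all pipeline outputs; round-trips through the
#' matching reader.
#'
#' @param x Tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

require_cols <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  }
}

head_rows <- function(idx, k = 5) {
  shown <- utils::head(idx, k)
  paste0(paste(shown, collapse = ", "),
         if (length(idx) > k) sprintf(" (and %d more)", length(idx) - k))
}

check_age_labels <- function(x) {
  allowed <- c(age_group_levels(), "0–4", "5–9", "10–14")
  bad <- setdiff(unique(x), allowed)
  if (length(bad) > 0) stop("unknown age-group label(s): ", paste(bad, collapse = ", "))
}
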