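# Shared helpers: age-group handling, label validation, small assertions.

# Canonical 5-year age bands. The first band is labelled "15-19" (en dash in
# the canonical form) to align with GBD age groups even though survey
# respondents in it are 16-19 years old.
AGE_GROUP_BREAKS <- c(seq(15, 80, by = 5), Inf)

#' Canonical age-group labels
#'
#' Five-year age bands `"15–19"`, `"20–24"`, ..., `"75–79"`,
#' `"80+"` (en dash). ASCII hyphens are accepted on input everywhere and
#' normalised to the en-dash form.
#'
#' @return Character vector of the 14 canonical labels.
#' @export
age_group_levels <- function() {
  lo <- seq(15, 75, by = 5)
  c(sprintf("%d–%d", lo, lo + 4), "80+")
}

#' Assign ages to canonical age groups
#'
#' @param age Numeric vector of ages in years (16 and over).
#' @return Factor with levels [age_group_levels()].
#' @export
assign_age_group <- function(age) {
  stopifnot(is.numeric(age))
  if (any(age < 15 | !is.finite(age))) {
    stop("ages must be finite and >= 15 (the 15–19 band holds 16–19-year-old respondents)")
  }
  idx <- findInterval(age, AGE_GROUP_BREAKS)
  factor(age_group_levels()[idx], levels = age_group_levels())
}

#' Age-group midpoints
#'
#' Midpoint of each band used as the age covariate in smoothing and
#' relative-risk models; `"80+"` is assigned 82.5 and `"15–19"` 17.5.
#'
#' @param age_group Character or factor of canonical labels.
#' @return Numeric vector of midpoints.
#' @export
age_group_midpoint <- function(age_group) {
  labs <- age_group_levels()
  mids <- c(seq(17.5, 77.5, by = 5), 82.5)
  m <- mids[match(normalise_age_group(age_group), labs)]
  if (anyNA(m)) stop("unknown age-group label(s): ",
                     paste(unique(age_group[is.na(m)]), collapse = ", "))
  m
}

#' Normalise age-group labels
#'
#' Accepts ASCII hyphen or en dash ("20-24" or "20–24") and returns the
#' canonical en-dash label.
#'
#' @param x Character or factor of age-group labels.
#' @return Character vector of canonical labels.
#' @export
normalise_age_group <- function(x) {
  gsub("-", "–", as.character(x), fixed = TRUE)
}

GENDER_LEVELS <- c("women", "men")

validate_gender <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), GENDER_LEVELS)
  if (length(bad) > 0) {
    stop("gender labels must be one of ", paste(GENDER_LEVELS, collapse = ", "),
         " (the analysis is restricted to the two modelled genders); got: ",
         paste(bad, collapse = ", "))
  }
  factor(x, levels = GENDER_LEVELS)
}

# Standardise to zero mean / unit sd; constant vectors map to zero (so the
# term drops out rather than producing NaN on degenerate single-stratum fits).
standardise <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Standardised fractional-polynomial basis of age for a given power pair.
# Power 0 denotes log; a repeated power (p, p) uses x^p and x^p * log(x).
fp_basis <- function(age, powers = c(0, 2)) {
  stopifnot(length(powers) == 2)
  f <- function(p) if (p == 0) log(age) else age^p
  t1 <- f(powers[1])
  t2 <- if (powers[1] == powers[2]) f(powers[2]) * log(age) else f(powers[2])
  cbind(fp1 = standardise(t1), fp2 = standardise(t2))
}

FP_POWER_SET <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

`%||%` <- function(x, y) if (is.null(x)) y else x
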