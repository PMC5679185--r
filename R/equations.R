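#' The four-branch GFR estimating equation
#'
#' The estimating equation is a piecewise power law in serum creatinine with
#' an exponential age decay, split by sex and by a sex-specific creatinine
#' threshold (1.2 mg/dl for women, 1.0 mg/dl for men):
#'
#' \deqn{eGFR = k \times (SC / \tau)^{c} \times a^{Age}}
#'
#' where \eqn{SC} is serum creatinine in mg/dl, \eqn{\tau} the threshold,
#' and \eqn{(k, c, a)} branch-specific coefficients.  `gfr_branches()`
#' returns the coefficient table; [select_branch()] resolves a single
#' (sex, creatinine) pair to its branch; [estimate_gfr_regression()]
#' evaluates the equation.
#'
#' Threshold values resolve to the "at or below" branch.  Note one printed
#' quirk of the coefficients that the implementation reproduces on purpose:
#' the male equation jumps upward across its threshold (98 at 1.0 mg/dl
#' versus about 105 immediately above), whereas the female equation steps
#' down (92 at 1.2 mg/dl versus about 79 above).
#'
#' @return A data frame with one row per branch and columns `sex`, `side`
#'   (`"at_or_below"` or `"above"` the threshold), `threshold` (mg/dl),
#'   `scale` (ml/min/1.73 m\eqn{^2}), `exponent` and `age_base`.
#' @export
#' @examples
#' gfr_branches()
gfr_branches <- function() {
  data.frame(
    sex       = c("female", "female", "male", "male"),
    side      = c("at_or_below", "above", "at_or_below", "above"),
    threshold = c(1.2, 1.2, 1.0, 1.0),
    scale     = c(92, 79, 98, 105),
    exponent  = c(-0.534, -0.516, -0.450, -0.640),
    age_base  = c(0.994, 0.994, 0.996, 0.993),
    stringsAsFactors = FALSE
  )
}

## vectorized branch lookup: row index into gfr_branches()
branch_index <- function(sex, scr) {
  ifelse(sex == "female", ifelse(scr <= 1.2, 1L, 2L),
         ifelse(scr <= 1.0, 3L, 4L))
}

#' Select the equation branch for one patient
#'
#' @param sex `"female"` or `"male"` (or `"F"`/`"M"`, case-insensitive).
#' @param scr serum creatinine in mg/dl; must be positive.
#' @return One row of [gfr_branches()] as a list.
#' @export
#' @examples
#' select_branch("female", 1.2)$scale  # 92: threshold resolves downward
#' select_branch("male", 1.01)$scale   # 105
select_branch <- function(sex, scr) {
  stopifnot(length(sex) == 1L, length(scr) == 1L)
  sex <- normalize_sex(sex)
  if (is.na(sex)) stop("`sex` must be 'female' or 'male'", call. = FALSE)
  if (!is.numeric(scr) || !is.finite(scr) || scr <= 0)
    stop("`scr` must be a positive creatinine in mg/dl", call. = FALSE)
  as.list(gfr_branches()[branch_index(sex, scr), ])
}

#' Estimate GFR with the piecewise regression equation
#'
#' Evaluates the four-branch equation described in [gfr_branches()].
#' Vectorized over patients; arguments are recycled to a common length.
#'
#' @param age age in years (non-negative).  Ages outside `[18, 100]` are
#'   mathematically valid but outside the population the coefficients were
#'   fitted on; a warning is emitted unless `warn_age = FALSE`.
#' @param sex sex labels, see [normalize_sex()].
#' @param scr serum creatinine in mg/dl (positive).  Use
#'   [convert_creatinine()] for values reported in µmol/l.
#' @param warn_age logical; warn on ages outside `[18, 100]`.
#' @return Estimated GFR in ml/min/1.73 m\eqn{^2} (never rounded; report
#'   renderers round for display).
#' @export
#' @examples
#' estimate_gfr_regression(age = 50, sex = "female", scr = 1.2)
#' estimate_gfr_regression(age = c(40, 60), sex = c("M", "F"), scr = c(2, 0.9))
estimate_gfr_regression <- function(age, sex, scr, warn_age = TRUE) {
  n <- max(length(age), length(sex), length(scr))
  if (n == 0L) return(numeric(0))
  age <- rep_len(age, n); sex <- rep_len(sex, n); scr <- rep_len(scr, n)
  sex <- normalize_sex(sex)
  if (anyNA(sex)) stop("`sex` must be 'female' or 'male'", call. = FALSE)
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0))
    stop("`age` must be finite and non-negative", call. = FALSE)
  if (!is.numeric(scr) || any(!is.finite(scr)) || any(scr <= 0))
    stop("`scr` must be positive serum creatinine in mg/dl", call. = FALSE)
  if (warn_age && any(age < 18 | age > 100))
    warning("age outside [18, 100]: the equation was developed on adults",
            call. = FALSE)
  b <- gfr_branches()[branch_index(sex, scr), ]
  b$scale * (scr / b$threshold)^b$exponent * b$age_base^age
}

#' Calibrate renal dynamic imaging GFR to the dual plasma sample reference
#'
#' Renal dynamic imaging GFR is mapped onto the dual plasma sample
#' reference scale by the affine calibration
#' `intercept + slope * imaging_gfr`.
#'
#' @param imaging_gfr GFR from renal dynamic imaging, ml/min/1.73
#'   m\eqn{^2}; non-negative.
#' @param intercept calibration intercept (default 0.167).
#' @param slope calibration slope (default 1.057); must be positive.
#' @return Calibrated GFR, ml/min/1.73 m\eqn{^2}.
#' @export
#' @examples
#' calibrate_imaging_gfr(100)
calibrate_imaging_gfr <- function(imaging_gfr, intercept = 0.167,
                                  slope = 1.057) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(slope), length(slope) == 1L, slope > 0)
  if (!is.numeric(imaging_gfr) || any(!is.finite(imaging_gfr)) ||
      any(imaging_gfr < 0))
    stop("`imaging_gfr` must be finite and non-negative", call. = FALSE)
  intercept + slope * imaging_gfr
}

#' Convert serum creatinine to mg/dl
#'
#' mg/dl is the canonical unit throughout the package; µmol/l values are
#' converted with the standard factor 1 mg/dl = 88.4 µmol/l.
#'
#' @param value positive creatinine values.
#' @param unit `"mg_per_dl"` (or `"mg/dl"`) or `"umol_per_l"` (or
#'   `"umol/l"`, `"µmol/l"`).
#' @return Creatinine in mg/dl.
#' @export
#' @examples
#' convert_creatinine(176.8, "umol_per_l")  # 2 mg/dl
convert_creatinine <- function(value, unit = "mg_per_dl") {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
    stop("creatinine values must be finite and positive", call. = FALSE)
  unit <- normalize_scr_unit(unit)
  if (anyNA(unit))
    stop("unknown creatinine unit; use 'mg_per_dl' or 'umol_per_l'",
         call. = FALSE)
  ifelse(unit == "umol_per_l", value / 88.4, value)
}

normalize_scr_unit <- function(unit) {
  u <- tolower(trimws(as.character(unit)))
  out <- rep(NA_character_, length(u))
  out[u %in% c("mg_per_dl", "mg/dl", "mgdl", "mg.dl", "")] <- "mg_per_dl"
  out[u %in% c("umol_per_l", "umol/l", "µmol/l", "umoll")] <- "umol_per_l"
  out
}
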