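`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a top-level seed
#'
#' Every stochastic step in the package (bootstrap resampling, training
#' splits, cohort simulation) is driven by a seed derived deterministically
#' from one top-level seed and a small task index, so that a single `seed`
#' argument makes an entire multi-step analysis reproducible while keeping
#' the random streams of distinct tasks decoupled.
#'
#' The derivation is a linear-congruential mix,
#' `(seed * 1664525 + index * 1013904223) mod (2^31 - 1)`, evaluated in
#' double precision (exact for these magnitudes).
#'
#' @param seed integer top-level seed.
#' @param index non-negative integer task index.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), length(index) == 1L, index >= 0)
  as.integer((abs(seed) * 1664525 + index * 1013904223) %% 2147483647)
}

## doubles serialized as %.17g strings round-trip bit-exactly through text;
## jsonlite's numeric rendering does not
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)

#' Normalize a sex label
#'
#' Accepts `"female"`/`"male"` and the single letters `"F"`/`"M"`,
#' case-insensitively.
#'
#' @param sex character vector of sex labels.
#' @return Character vector with entries `"female"` or `"male"`; labels that
#'   cannot be interpreted become `NA`.
#' @export
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("f", "female")] <- "female"
  out[s %in% c("m", "male")] <- "male"
  out
}

## shared cohort validation: every estimator and metric goes through this
check_cohort <- function(cohort, require_mgfr = FALSE) {
  if (!is.data.frame(cohort))
    stop("`cohort` must be a data frame", call. = FALSE)
  needed <- c("age", "sex", "scr")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(cohort) == 0L) {
    cohort$sex <- character(0)
    if (is.null(cohort$id)) cohort$id <- character(0)
    if (is.null(cohort$mgfr)) cohort$mgfr <- numeric(0)
    return(cohort)
  }
  cohort$sex <- normalize_sex(cohort$sex)
  if (anyNA(cohort$sex))
    stop("cohort contains unrecognized sex labels", call. = FALSE)
  if (!is.numeric(cohort$age) || any(!is.finite(cohort$age)) ||
      any(cohort$age < 0))
    stop("cohort ages must be finite and non-negative", call. = FALSE)
  if (!is.numeric(cohort$scr) || any(!is.finite(cohort$scr)) ||
      any(cohort$scr <= 0))
    stop("cohort serum creatinine must be finite and positive", call. = FALSE)
  if (is.null(cohort$id)) cohort$id <- as.character(seq_len(nrow(cohort)))
  if (anyDuplicated(cohort$id))
    stop("cohort ids must be unique", call. = FALSE)
  if (require_mgfr) {
    if (is.null(cohort$mgfr) || anyNA(cohort$mgfr))
      stop("every record must carry a measured GFR (`mgfr`)", call. = FALSE)
    if (any(!is.finite(cohort$mgfr)) || any(cohort$mgfr <= 0))
      stop("measured GFR must be finite and positive", call. = FALSE)
  }
  cohort
}
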