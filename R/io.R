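#' Read a patient cohort from a delimited text file
#'
#' The cohort file is comma-separated (configurable), UTF-8, with a header
#' row and columns `id`, `age`, `sex`, `scr`, optionally `scr_unit`
#' (`mg/dl` assumed when absent or empty; `umol/l` converted with factor
#' 88.4) and optionally `mgfr` (empty allowed).  `sex` accepts
#' `F`/`M`/`female`/`male` case-insensitively.
#'
#' Rows that fail validation (unparseable sex, non-positive creatinine,
#' negative age, non-positive measured GFR, unknown unit) are collected
#' into a reject report attached as `attr(cohort, "rejects")` and reported
#' with a warning — they are never silently dropped.  With
#' `strict = TRUE` any rejected row is an error instead.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @param strict promote rejected rows to an error.
#' @param quiet suppress the informational messages.
#' @return A cohort data frame with columns `id`, `age`, `sex`, `scr`
#'   (mg/dl) and `mgfr` (`NA` when not measured), with the reject report
#'   as attribute `"rejects"` (a data frame with `row`, `id`, `reason`).
#' @export
read_cohort <- function(path, sep = ",", strict = FALSE, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fill = TRUE)
  required <- c("id", "age", "sex", "scr")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n <- nrow(raw)
  rejects <- data.frame(row = integer(0), id = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    if (!quiet) warning("cohort file has a header but no data rows",
                        call. = FALSE)
    out <- data.frame(id = character(0), age = numeric(0),
                      sex = character(0), scr = numeric(0),
                      mgfr = numeric(0))
    attr(out, "rejects") <- rejects
    return(out)
  }
  age <- suppressWarnings(as.numeric(raw$age))
  sex <- normalize_sex(raw$sex)
  scr_in <- suppressWarnings(as.numeric(raw$scr))
  unit <- if ("scr_unit" %in% names(raw))
    normalize_scr_unit(raw$scr_unit) else rep("mg_per_dl", n)
  mgfr <- if ("mgfr" %in% names(raw))
    suppressWarnings(as.numeric(raw$mgfr)) else rep(NA_real_, n)
  mgfr[!is.na(raw$mgfr %||% NA) & !nzchar(trimws(raw$mgfr %||% ""))] <-
    NA_real_
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(age) | !is.finite(age), "unparseable age")
  flag(!is.na(age) & age < 0, "negative age")
  flag(is.na(sex), "unrecognized sex label")
  flag(is.na(unit), "unknown creatinine unit")
  flag(is.na(scr_in) | !is.finite(scr_in), "unparseable creatinine")
  flag(!is.na(scr_in) & scr_in <= 0, "non-positive creatinine")
  has_mgfr <- "mgfr" %in% names(raw) & nzchar(trimws(raw$mgfr %||% ""))
  flag(has_mgfr & (is.na(mgfr) | !is.finite(mgfr)), "unparseable mgfr")
  flag(has_mgfr & !is.na(mgfr) & mgfr <= 0, "non-positive mgfr")
  bad <- !is.na(reason)
  if (any(bad)) {
    rejects <- data.frame(row = which(bad), id = raw$id[bad],
                          reason = reason[bad], stringsAsFactors = FALSE)
    if (strict)
      stop(sum(bad), " cohort row(s) failed validation; first reason: ",
           rejects$reason[1L], call. = FALSE)
    warning(sum(bad), " cohort row(s) failed validation and were ",
            "routed to the reject report (attr(x, 'rejects'))",
            call. = FALSE)
  }
  keep <- which(!bad)
  scr <- scr_in[keep]
  umol <- unit[keep] == "umol_per_l"
  scr[umol] <- scr[umol] / 88.4
  out <- data.frame(id = raw$id[keep], age = age[keep], sex = sex[keep],
                    scr = scr, mgfr = mgfr[keep], stringsAsFactors = FALSE)
  if (!quiet)
    message("read ", length(keep), " cohort record(s) from ", path,
            if (any(bad)) paste0(" (", sum(bad), " rejected)") else "")
  attr(out, "rejects") <- rejects
  out
}

#' Write a cohort to the standard CSV schema
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- check_cohort(cohort)
  out <- data.frame(id = cohort$id, age = cohort$age, sex = cohort$sex,
                    scr = cohort$scr, scr_unit = "mg/dl",
                    mgfr = cohort$mgfr %||% NA_real_)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

fmt1 <- function(x) ifelse(is.na(x), "-", formatC(x, format = "f",
                                                  digits = 1))
fmt_ci <- function(est, lo, hi, pct = FALSE) {
  f <- if (pct) function(v) fmt1(100 * v) else fmt1
  sep <- ifelse(!is.na(lo) & (lo < 0 | hi < 0), " to ", "-")
  ifelse(is.na(est), "-",
         ifelse(is.na(lo), f(est),
                paste0(f(est), " (", f(lo), sep, f(hi), ")")))
}

#' Render a validation report as a table
#'
#' Lays the report out like the standard equation-validation table: one
#' block per metric (bias, precision, P30 accuracy as a percentage), one
#' row per model, one column per subgroup, cells formatted as
#' `estimate (95% CI)` at one decimal, with a dagger on cells whose
#' paired comparison against the benchmark is significant at p < 0.05.  A
#' second table lists the comparison p-values at three decimals.
#'
#' @param report a `"gfr_report"` from [evaluate_models()].
#' @param format `"markdown"` or `"tsv"`.
#' @return Character vector of table lines.
#' @export
render_report <- function(report, format = c("markdown", "tsv")) {
  format <- match.arg(format)
  s <- report$summaries
  cmp <- report$comparisons
  groups <- unique(s$subgroup)
  models <- unique(s$model)
  sig_mark <- function(model, group, metric) {
    if (model == report$meta$benchmark || nrow(cmp) == 0L) return("")
    row <- cmp[cmp$candidate == model & cmp$subgroup == group, ]
    if (nrow(row) == 0L) return("")
    if (isTRUE(row[[paste0("significant_", metric)]])) " ‡" else ""
  }
  blocks <- list(
    c(metric = "bias", title = "Bias = median difference (95% CI)"),
    c(metric = "precision",
      title = "Precision = IQR of the difference (95% CI)"),
    c(metric = "accuracy", title = "Accuracy = 30% accuracy, % (95% CI)"))
  mk_row <- function(cells) {
    if (format == "tsv") paste(cells, collapse = "\t")
    else paste0("| ", paste(cells, collapse = " | "), " |")
  }
  lines <- character(0)
  header <- mk_row(c("Model", groups))
  rule <- mk_row(c("---", rep("---", length(groups))))
  for (bl in blocks) {
    lines <- c(lines, bl[["title"]], header,
               if (format == "markdown") rule)
    for (m in models) {
      cells <- vapply(groups, function(g) {
        r <- s[s$model == m & s$subgroup == g, ]
        cell <- fmt_ci(r[[bl[["metric"]]]],
                       r[[paste0(bl[["metric"]], "_lo")]],
                       r[[paste0(bl[["metric"]], "_hi")]],
                       pct = bl[["metric"]] == "accuracy")
        paste0(cell, sig_mark(m, g, bl[["metric"]]))
      }, character(1))
      lines <- c(lines, mk_row(c(m, cells)))
    }
    lines <- c(lines, "")
  }
  if (nrow(cmp)) {
    lines <- c(lines,
               paste0("Paired comparisons vs benchmark '",
                      report$meta$benchmark,
                      "' (‡ p < 0.05; p at 3 decimals)"),
               mk_row(c("Candidate", "Subgroup", "p bias", "p precision",
                        "p accuracy")),
               if (format == "markdown") mk_row(rep("---", 5)))
    fmt_p <- function(p) ifelse(is.na(p), "-",
                                formatC(p, format = "f", digits = 3))
    for (k in seq_len(nrow(cmp)))
      lines <- c(lines, mk_row(c(cmp$candidate[k], cmp$subgroup[k],
                                 fmt_p(cmp$p_bias[k]),
                                 fmt_p(cmp$p_precision[k]),
                                 fmt_p(cmp$p_accuracy[k]))))
  }
  lines
}

#' Write and re-read validation reports
#'
#' `write_report` serializes a report to structured JSON (the canonical,
#' lossless form that `read_report` round-trips) or to a rendered
#' TSV/Markdown table (see [render_report()]).
#'
#' @param report a `"gfr_report"`.
#' @param path output path.
#' @param format `"json"`, `"tsv"` or `"markdown"`.
#' @return `path` invisibly; `read_report` returns the restored
#'   `"gfr_report"`.
#' @export
write_report <- function(report, path, format = c("json", "tsv",
                                                  "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "gfr_report"))
  if (format == "json") {
    payload <- list(summaries = df_to_text(report$summaries),
                    comparisons = df_to_text(report$comparisons),
                    meta = report$meta)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    writeLines(render_report(report, format = format), path)
  }
  invisible(path)
}

## numeric columns as %.17g strings so the JSON form is lossless
df_to_text <- function(df) {
  for (col in names(df))
    if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
      df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                          num_to_chr(df[[col]]))
  df
}

df_from_text <- function(df, numeric_cols, logical_cols = character(0)) {
  for (col in intersect(numeric_cols, names(df)))
    df[[col]] <- chr_to_num(df[[col]])
  for (col in intersect(logical_cols, names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$summaries) || is.null(x$meta))
    stop("not a serialized gfr_report: ", path, call. = FALSE)
  num_s <- c("bias", "bias_lo", "bias_hi", "precision", "precision_lo",
             "precision_hi", "accuracy", "accuracy_lo", "accuracy_hi")
  s <- df_from_text(as.data.frame(x$summaries), num_s)
  s$n <- as.integer(s$n)
  cmp <- as.data.frame(x$comparisons)
  if (nrow(cmp)) {
    cmp <- df_from_text(cmp, c("p_bias", "p_precision", "p_accuracy"),
                        c("significant_bias", "significant_precision",
                          "significant_accuracy"))
    cmp$n <- as.integer(cmp$n)
  } else {
    cmp <- data.frame(candidate = character(0), benchmark = character(0),
                      subgroup = character(0), n = integer(0),
                      p_bias = numeric(0), p_precision = numeric(0),
                      p_accuracy = numeric(0),
                      significant_bias = logical(0),
                      significant_precision = logical(0),
                      significant_accuracy = logical(0))
  }
  meta <- x$meta
  meta$B <- as.integer(meta$B)
  meta$seed <- as.integer(meta$seed)
  meta$n <- as.integer(meta$n)
  meta$breaks <- as.numeric(meta$breaks)
  structure(list(summaries = s, comparisons = cmp, meta = meta),
            class = "gfr_report")
}
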