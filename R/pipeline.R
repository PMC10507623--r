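#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis (screen -> prevalence ->
#' G-study -> D-study -> report) with the defaults used throughout the
#' package: reliability threshold 0.90 and the 10-to-100-raters-by-10
#' optimization grid at 10 items.
#'
#' @param ratings path to the ratings CSV.
#' @param format `"long"` or `"wide"` (see [read_ratings_long()],
#'   [read_ratings_wide()]).
#' @param columns long-format column map (see [read_ratings_long()]).
#' @param meta optional path to a screening-flags CSV (columns `person`,
#'   `is_core`, `is_duplicate`, `is_inconsistent`).
#' @param roster optional path to an expected/received roster CSV.
#' @param score_range optional instrument range for consistency screening.
#' @param threshold reliability cutoff in (0, 1).
#' @param raters D-study rater grid.
#' @param n_items D-study item count; defaults to the table's item count.
#' @param out_dir directory for the artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ratings, format = c("long", "wide"),
                            columns = default_columns(), meta = NULL,
                            roster = NULL, score_range = NULL,
                            threshold = 0.90, raters = seq(10, 100, 10),
                            n_items = NULL, out_dir = ".") {
  format <- match.arg(format)
  stopifnot(threshold > 0, threshold < 1, all(raters >= 1))
  out <- list(ratings = ratings, format = format, columns = columns,
              meta = meta, roster = roster, score_range = score_range,
              threshold = threshold, raters = as.integer(raters),
              n_items = n_items, out_dir = out_dir)
  class(out) <- "pipeline_config"
  out
}

#' Run the full screening / prevalence / G-study / D-study pipeline
#'
#' Reads and validates the ratings, applies the screening rules, computes
#' the response-prevalence ledger when a roster is supplied, estimates the
#' variance components, evaluates the D-study curve and the minimum rater
#' count reaching the threshold, and writes every artifact to `out_dir`:
#' `ledger.csv`, `screening_report.json`, `anova_table.csv`,
#' `variance_components.json`, `dstudy_curve.csv` and `summary.txt`.
#' Every number in the summary is re-derivable from the serialized
#' artifacts.  Inputs are deterministic, so rerunning a config reproduces
#' the artifacts byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted objects (`table`, `screening`,
#'   `ledger`, `gstudy`, `curve`, `min_raters`) and `paths` to the written
#'   artifacts.  Errors are re-signalled with the failing stage's name.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!file.exists(config$ratings)) {
    stop("pipeline stage 'read': file not found: ", config$ratings,
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  table <- stage("read", {
    if (config$format == "long") {
      read_ratings_long(config$ratings, config$columns)
    } else {
      read_ratings_wide(config$ratings)
    }
  })

  meta <- NULL
  if (!is.null(config$meta)) {
    meta <- stage("meta", utils::read.csv(config$meta,
                                          stringsAsFactors = FALSE))
  }
  screened <- stage("screen",
                    apply_screens(table, meta, config$score_range))
  if (is.null(screened$table)) {
    stop("pipeline stage 'screen': no persons survive screening",
         call. = FALSE)
  }
  paths$screening <- file.path(config$out_dir, "screening_report.json")
  jsonlite::write_json(unclass(screened$report), paths$screening,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ledger <- NULL
  if (!is.null(config$roster)) {
    ledger <- stage("prevalence", {
      classify_nonresponse(read_roster(config$roster))
    })
    paths$ledger <- file.path(config$out_dir, "ledger.csv")
    utils::write.csv(as.data.frame(ledger), paths$ledger, row.names = FALSE,
                     quote = FALSE)
  }

  fit <- stage("gstudy", gstudy(screened$table))
  paths$anova <- file.path(config$out_dir, "anova_table.csv")
  utils::write.csv(as.data.frame(fit$anova), paths$anova, row.names = FALSE,
                   quote = FALSE)
  paths$components <- file.path(config$out_dir, "variance_components.json")
  comp <- as_components(fit)
  jsonlite::write_json(
    list(components = as.list(comp),
         raw = as.list(attr(fit$components, "raw")),
         clipped = as.list(attr(fit$components, "clipped")),
         percent = as.list(attr(fit$components, "percent"))),
    paths$components, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  n_items <- if (is.null(config$n_items)) screened$table$counts$n_i else
    config$n_items
  curve <- stage("dstudy",
                 dstudy_curve(fit, n_items = n_items,
                              raters = config$raters,
                              threshold = config$threshold))
  paths$curve <- file.path(config$out_dir, "dstudy_curve.csv")
  write_dstudy_curve(curve, paths$curve)
  minr <- min_raters_for_threshold(fit, n_items = n_items,
                                   threshold = config$threshold,
                                   raters = config$raters)

  mean_nr <- round(mean(screened$table$counts$n_r_by_person))
  co_mean <- gphi_coefficients(fit, max(1L, mean_nr), n_items)

  paths$summary <- file.path(config$out_dir, "summary.txt")
  lines <- c("Generalizability analysis summary",
             "=================================",
             sprintf("retained persons: %d  raters: %d  items: %d",
                     screened$table$counts$n_p, screened$table$counts$N,
                     n_items),
             "",
             render_gstudy(fit),
             "",
             render_dstudy(curve),
             "",
             sprintf("g / phi at the mean observed rater count (%d): %.3f / %.3f",
                     mean_nr, co_mean[["g"]], co_mean[["phi"]]),
             sprintf("minimum raters on the grid with phi >= %.2f: %s",
                     config$threshold,
                     if (is.na(minr)) "not attained" else as.character(minr)))
  if (!is.null(ledger)) {
    ov <- ledger[ledger$stratum == "Overall", ]
    lines <- c(lines,
               sprintf("overall response ratio: %.3f (%.1f%%)",
                       ov$ratio, 100 * ov$ratio))
  }
  writeLines(lines, paths$summary)

  invisible(list(table = screened$table, screening = screened$report,
                 ledger = ledger, gstudy = fit, curve = curve,
                 min_raters = minr, paths = paths))
}

fmt_table <- function(header, rows) {
  mat <- rbind(header, rows)
  widths <- apply(nchar(mat), 2L, max)
  apply(mat, 1L, function(r) {
    paste(mapply(formatC, r, width = widths,
                 MoreArgs = list(flag = "-")), collapse = "  ")
  })
}

#' Render a G-study fit as a fixed-width table
#'
#' Columns mirror the conventional G-study report: df, SS, MS, variance and
#' variance percentage per source (MS at 2 dp, components at 3 dp,
#' percentages at 1 dp).
#'
#' @param fit a [gstudy()] object.
#' @return Character vector of table lines.
#' @export
render_gstudy <- function(fit) {
  stopifnot(inherits(fit, "gstudy"))
  an <- fit$anova
  comp <- as_components(fit)
  pc <- attr(fit$components, "percent")
  rows <- cbind(source_labels()[an$source],
                formatC(an$df, format = "d"),
                formatC(round(an$SS), format = "d"),
                formatC(an$MS, format = "f", digits = 2L),
                formatC(comp[an$source], format = "f", digits = 3L),
                formatC(pc[an$source], format = "f", digits = 1L))
  header <- c("Sources of variation", "df", "SS", "MS", "Variance",
              "Variance percentage")
  fmt_table(header, rows)
}

#' Render a D-study curve as a fixed-width table
#'
#' @param curve a [dstudy_curve()].
#' @return Character vector of table lines (header
#'   `No. of raters / Absolute error / Relative error / Phi / G`, values at
#'   3 dp); a header-only table for an empty curve.
#' @export
render_dstudy <- function(curve) {
  stopifnot(inherits(curve, "dstudy_curve"))
  header <- c("No. of raters", "Absolute error", "Relative error", "Phi",
              "G")
  if (nrow(curve) == 0L) {
    return(paste(header, collapse = "  "))
  }
  rows <- cbind(formatC(curve$n_raters, format = "d"),
                formatC(curve$abs_error, format = "f", digits = 3L),
                formatC(curve$rel_error, format = "f", digits = 3L),
                formatC(curve$phi, format = "f", digits = 3L),
                formatC(curve$g, format = "f", digits = 3L))
  fmt_table(header, rows)
}
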