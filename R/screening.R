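#' Response-ratio ledger for unit non-response prevalence
#'
#' Computes received/expected response ratios per stratum and overall.  The
#' ratio is close to 1 when non-response is rare and close to 0 when it is
#' prevalent.  Following the reporting convention of institutional response
#' tables, per-stratum ratios are rounded to 2 decimal places, the overall
#' ratio to 3, and percentages to 1.
#'
#' @param rows data frame with columns `stratum`, `expected`, `received`.
#' @param overall append an `Overall` totals row (ratio of the summed
#'   counts)?  Default `TRUE`.
#' @return A data frame of class `response_ledger` with columns `stratum`,
#'   `expected`, `received`, `ratio` (exact), `ratio_printed` (rounded as
#'   above), `percent` (1 dp) and `flagged` (`TRUE` when `expected == 0` or
#'   `received > expected`).
#' @export
#' @examples
#' compute_ratios(data.frame(stratum = c("100", "200"),
#'                           expected = c(45722, 48316),
#'                           received = c(27588, 11945)))
compute_ratios <- function(rows, overall = TRUE) {
  stopifnot(is.data.frame(rows),
            all(c("stratum", "expected", "received") %in% names(rows)))
  out <- data.frame(stratum  = as.character(rows$stratum),
                    expected = as.numeric(rows$expected),
                    received = as.numeric(rows$received),
                    stringsAsFactors = FALSE)
  if (any(out$expected < 0 | out$received < 0)) {
    stop("expected/received counts must be nonnegative", call. = FALSE)
  }
  flagged <- out$expected == 0 | out$received > out$expected
  if (any(out$received > out$expected)) {
    warning("received > expected for stratum: ",
            paste(out$stratum[out$received > out$expected], collapse = ", "),
            call. = FALSE)
  }
  ratio <- ifelse(out$expected > 0, out$received / out$expected, NA_real_)
  out$ratio <- ratio
  out$ratio_printed <- round(ratio, 2L)
  out$percent <- round(100 * ratio, 1L)
  out$flagged <- flagged
  if (overall) {
    te <- sum(out$expected)
    tr <- sum(out$received)
    orat <- if (te > 0) tr / te else NA_real_
    tot <- data.frame(stratum = "Overall", expected = te, received = tr,
                      ratio = orat, ratio_printed = round(orat, 3L),
                      percent = round(100 * orat, 1L),
                      flagged = te == 0 || tr > te,
                      stringsAsFactors = FALSE)
    out <- rbind(out, tot)
  }
  class(out) <- c("response_ledger", "data.frame")
  out
}

#' Label strata by non-response severity
#'
#' A stratum with response ratio below the cutoff is labelled
#' `"high-non-response"`; at or above the cutoff, `"low-non-response"` (a
#' ratio close to 1 reflects low non-response).
#'
#' @param ledger a [compute_ratios()] ledger (or any data frame with a
#'   `ratio` column).
#' @param cutoff response-ratio threshold in (0, 1); default 0.50.
#' @return The ledger with an added `label` column.
#' @export
classify_nonresponse <- function(ledger, cutoff = 0.50) {
  stopifnot(is.data.frame(ledger), "ratio" %in% names(ledger))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff >= 1) {
    stop("cutoff must be a single number in (0, 1)", call. = FALSE)
  }
  ledger$label <- ifelse(is.na(ledger$ratio), NA_character_,
                         ifelse(ledger$ratio < cutoff,
                                "high-non-response", "low-non-response"))
  ledger
}

#' Screen a rating table before G-study analysis
#'
#' Applies the four screening rules in order: (1) persons with exactly one
#' rater are removed, since a single response carries no between-rater
#' variance; (2) core/general courses are removed (ratings of several
#' instructors merged under one label would confound the person effect);
#' (3) duplicated courses are removed; (4) courses flagged as inconsistent
#' are removed.  Rules (2)-(4) are driven by the `meta` flags; optionally,
#' scores falling outside `score_range` mark a person as inconsistent.
#' A person removed by several rules is reported under the first one.
#'
#' @param table a [rating_table()].
#' @param meta optional data frame with columns `person` and any of
#'   `is_core`, `is_duplicate`, `is_inconsistent` (logical).  Persons absent
#'   from `meta` are treated as non-core, non-duplicate, consistent.
#' @param score_range optional numeric length-2 vector; persons with any
#'   score outside the closed range are flagged inconsistent.
#' @return A list with `table` (the screened [rating_table()], or `NULL`
#'   when nothing survives) and `report` (class `screening_report`):
#'   per-rule removal lists plus retained person/rater counts.
#' @export
apply_screens <- function(table, meta = NULL, score_range = NULL) {
  stopifnot(inherits(table, "rating_table"))
  persons <- names(table$counts$n_r_by_person)

  flag_of <- function(col) {
    if (is.null(meta) || !col %in% names(meta)) {
      return(character(0))
    }
    as.character(meta$person[!is.na(meta[[col]]) & meta[[col]]])
  }
  single <- persons[table$counts$n_r_by_person == 1L]
  core <- intersect(persons, flag_of("is_core"))
  dup <- intersect(persons, flag_of("is_duplicate"))
  incons <- intersect(persons, flag_of("is_inconsistent"))
  if (!is.null(score_range)) {
    stopifnot(length(score_range) == 2L)
    sc <- table$scores
    bad <- sc$score < min(score_range) | sc$score > max(score_range)
    incons <- union(incons, unique(sc$person[bad]))
  }

  # first-rule attribution for the report; the retained set is order-free
  rm1 <- single
  rm2 <- setdiff(core, rm1)
  rm3 <- setdiff(dup, c(rm1, rm2))
  rm4 <- setdiff(incons, c(rm1, rm2, rm3))
  removed <- c(rm1, rm2, rm3, rm4)
  kept <- setdiff(persons, removed)

  out_table <- NULL
  retained_raters <- 0L
  if (length(kept) > 0L) {
    sc <- table$scores[table$scores$person %in% kept, , drop = FALSE]
    out_table <- rating_table(sc, items = table$items, validate = FALSE)
    retained_raters <- out_table$counts$N
  }
  report <- list(removed_single_response = rm1,
                 removed_core = rm2,
                 removed_duplicate = rm3,
                 removed_inconsistent = rm4,
                 retained_persons = length(kept),
                 retained_raters = retained_raters)
  class(report) <- "screening_report"
  list(table = out_table, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening report\n")
  cat("  removed (single response): ", length(x$removed_single_response), "\n")
  cat("  removed (core course):     ", length(x$removed_core), "\n")
  cat("  removed (duplicate):       ", length(x$removed_duplicate), "\n")
  cat("  removed (inconsistent):    ", length(x$removed_inconsistent), "\n")
  cat("  retained persons:          ", x$retained_persons, "\n")
  cat("  retained raters:           ", x$retained_raters, "\n")
  invisible(x)
}
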