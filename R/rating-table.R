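#' Rating tables for the (r:p) x i measurement design
#'
#' A `rating_table` holds one score per (person, rater, item) triple for the
#' two-facet partially nested random design: raters (students) are nested in
#' persons (course-instructors, the objects of measurement) and crossed with
#' items.  Every rater present in the table must have a score for every item
#' (the instrument forces complete submissions, so there is no item-level
#' missingness; non-response is always unit-level, i.e. a whole rater).
#'
#' @param scores data frame with columns `person`, `rater`, `item`, `score`.
#'   `rater` identifiers need only be unique within a person; the same label
#'   under two persons denotes two different raters.
#' @param items optional character vector fixing the item set and its order;
#'   defaults to the sorted distinct items present in `scores`.
#' @param validate if `FALSE`, skip invariant checks (for trusted inputs such
#'   as generator output, where the invariants hold by construction).
#'
#' @return An object of class `rating_table`: a list with elements
#'   `scores` (the long data frame), `items` (ordered item identifiers) and
#'   `counts` (see [design_counts()]).
#'
#' @details Invariants enforced on construction: (person, rater, item) triples
#' are unique; scores are finite numbers; the item set is identical across
#' persons; each (person, rater) pair has a complete item rectangle.
#'
#' @seealso [read_ratings_long()], [read_ratings_wide()], [gstudy()]
#' @export
#' @examples
#' df <- expand.grid(person = c("P1", "P2"), rater = c("r1", "r2"),
#'                   item = c("i1", "i2"), stringsAsFactors = FALSE)
#' df$score <- c(3, 2, 4, 3, 3, 3, 2, 4)
#' rt <- rating_table(df)
#' rt$counts$N
rating_table <- function(scores, items = NULL, validate = TRUE) {
  stopifnot(is.data.frame(scores))
  required <- c("person", "rater", "item", "score")
  missing_cols <- setdiff(required, names(scores))
  if (length(missing_cols) > 0L) {
    stop("rating table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  scores <- data.frame(person = as.character(scores$person),
                       rater  = as.character(scores$rater),
                       item   = as.character(scores$item),
                       score  = as.numeric(scores$score),
                       stringsAsFactors = FALSE)
  if (is.null(items)) {
    items <- sort(unique(scores$item))
  } else {
    items <- as.character(items)
  }
  if (validate) {
    if (nrow(scores) == 0L) {
      stop("rating table has no observations", call. = FALSE)
    }
    if (any(!is.finite(scores$score))) {
      stop("non-finite or missing scores present", call. = FALSE)
    }
    key <- paste(scores$person, scores$rater, scores$item, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- scores[duplicated(key), c("person", "rater", "item")]
      stop("duplicate (person, rater, item) triple(s), e.g. (",
           paste(unlist(dup[1L, ]), collapse = ", "), ")", call. = FALSE)
    }
    extra <- setdiff(unique(scores$item), items)
    if (length(extra) > 0L) {
      stop("items present in data but not in item set: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    # complete rater x item rectangles: each (person, rater) must carry
    # exactly the full item set
    pr <- paste(scores$person, scores$rater, sep = "\r")
    n_by_pr <- table(pr)
    bad <- names(n_by_pr)[n_by_pr != length(items)]
    if (length(bad) > 0L) {
      lab <- sub("\r", ", ", bad[seq_len(min(5L, length(bad)))])
      stop("incomplete rater-by-item rectangle for (person, rater): (",
           paste(lab, collapse = "), ("), ")", call. = FALSE)
    }
  }
  out <- list(scores = scores, items = items, counts = NULL)
  out$counts <- design_counts_df(scores, items)
  class(out) <- "rating_table"
  out
}

design_counts_df <- function(scores, items) {
  if (nrow(scores) == 0L) {
    out <- list(n_p = 0L, n_i = length(items),
                n_r_by_person = integer(0), N = 0L)
    class(out) <- "design_counts"
    return(out)
  }
  pr <- unique(scores[, c("person", "rater")])
  tab <- table(factor(pr$person, levels = unique(scores$person)))
  n_r <- as.integer(tab)
  names(n_r) <- names(tab)
  out <- list(n_p = length(n_r), n_i = length(items),
              n_r_by_person = n_r, N = sum(n_r))
  class(out) <- "design_counts"
  out
}

#' Design counts of a rating table
#'
#' Returns the observed design sizes: number of persons `n_p`, number of
#' items `n_i`, the per-person rater counts `n_r_by_person` (the unbalanced
#' nesting pattern n_r(p)), and the total number of raters `N`.
#'
#' @param table a [rating_table()].
#' @return An object of class `design_counts`.
#' @export
design_counts <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  table$counts
}

#' @export
print.design_counts <- function(x, ...) {
  cat("Design counts: n_p =", x$n_p, " n_i =", x$n_i, " N =", x$N, "\n")
  if (x$n_p > 0L) {
    cat("raters per person: min", min(x$n_r_by_person),
        " mean", round(mean(x$n_r_by_person), 2),
        " max", max(x$n_r_by_person), "\n")
  }
  invisible(x)
}

#' @export
print.rating_table <- function(x, ...) {
  cat("Rating table ((r:p) x i design)\n")
  print(x$counts)
  cat("observations:", nrow(x$scores), "\n")
  invisible(x)
}

default_columns <- function() {
  c(person = "person", rater = "rater", item = "item", score = "score")
}

#' Read a long-format rating table from CSV
#'
#' The long format has one row per (person, rater, item) score.  Column names
#' default to `person,rater,item,score` and can be remapped.
#'
#' @param path CSV file path (UTF-8, comma-delimited, header row).
#' @param columns named character vector mapping the canonical names
#'   `person`, `rater`, `item`, `score` to the file's column names.
#' @return A validated [rating_table()].
#' @export
read_ratings_long <- function(path, columns = default_columns()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  columns <- utils::modifyList(as.list(default_columns()), as.list(columns))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (canon in c("person", "rater", "item", "score")) {
    col <- columns[[canon]]
    if (!col %in% names(df)) {
      stop("column '", col, "' (mapped to '", canon,
           "') not found in ", path, call. = FALSE)
    }
  }
  out <- data.frame(person = df[[columns$person]],
                    rater  = df[[columns$rater]],
                    item   = df[[columns$item]],
                    score  = df[[columns$score]],
                    stringsAsFactors = FALSE)
  if (!is.numeric(out$score)) {
    parsed <- suppressWarnings(as.numeric(out$score))
    if (any(is.na(parsed) & !is.na(out$score))) {
      stop("score column contains non-numeric values", call. = FALSE)
    }
    out$score <- parsed
  }
  rating_table(out)
}

#' Write a rating table as long-format CSV
#'
#' @param table a [rating_table()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ratings_long <- function(table, path) {
  stopifnot(inherits(table, "rating_table"))
  utils::write.csv(table$scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide-format rating table from CSV
#'
#' The wide format has one row per (person, rater) and one column per item;
#' every column other than `person` and `rater` is taken as an item.
#'
#' @param path CSV file path.
#' @return A [rating_table()] identical to the one obtained by reading the
#'   same data in long form.
#' @export
read_ratings_wide <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("person", "rater") %in% names(df))) {
    stop("wide format requires 'person' and 'rater' columns", call. = FALSE)
  }
  item_cols <- setdiff(names(df), c("person", "rater"))
  if (nrow(df) == 0L || length(item_cols) == 0L) {
    stop("empty data section: no (person, rater) rows or no item columns",
         call. = FALSE)
  }
  vals <- df[item_cols]
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1)))) {
    stop("ragged item columns: missing cell(s) in the wide layout",
         call. = FALSE)
  }
  long <- data.frame(
    person = rep(as.character(df$person), times = length(item_cols)),
    rater  = rep(as.character(df$rater), times = length(item_cols)),
    item   = rep(item_cols, each = nrow(df)),
    score  = as.numeric(unlist(vals, use.names = FALSE)),
    stringsAsFactors = FALSE)
  rating_table(long, items = item_cols)
}

#' Write a rating table as wide-format CSV
#'
#' @inheritParams write_ratings_long
#' @return Invisibly, `path`.
#' @export
write_ratings_wide <- function(table, path) {
  stopifnot(inherits(table, "rating_table"))
  sc <- table$scores
  pr <- unique(sc[, c("person", "rater")])
  key <- paste(sc$person, sc$rater, sep = "\r")
  prkey <- paste(pr$person, pr$rater, sep = "\r")
  wide <- pr
  for (it in table$items) {
    sub <- sc[sc$item == it, ]
    wide[[it]] <- sub$score[match(prkey, paste(sub$person, sub$rater,
                                               sep = "\r"))]
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expected-versus-received response roster
#'
#' A roster records, per stratum (level of study or course pseudonym), how
#' many responses were expected and how many were actually received.  The
#' response ratio received/expected is computed per stratum and a totals row
#' is appended; see [compute_ratios()] for the rounding conventions.
#'
#' @param path CSV with columns `stratum`, `expected`, `received`.
#' @return A response-ledger data frame (see [compute_ratios()]).
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("stratum", "expected", "received"), names(df))
  if (length(miss) > 0L) {
    stop("roster is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  compute_ratios(df)
}
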