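#' D-study error variances for hypothetical rater and item counts
#'
#' Projects the G-study components onto a mean score over `n_raters`
#' hypothetical raters and `n_items` items.  The relative error variance
#' (affecting rank-order decisions) collects the components that interact
#' with the object of measurement, each divided by its D-study sample size:
#'
#'   sigma2(delta) = s2pi/n'i + s2rp/n'r + s2res/(n'r n'i)
#'
#' and the absolute error variance (criterion-referenced decisions) adds the
#' item main effect:
#'
#'   sigma2(Delta) = sigma2(delta) + s2i/n'i.
#'
#' At n'r = n'i = 1 these reduce to the undivided single-observation sums.
#'
#' @param components a [gstudy()] fit, `variance_components` object, or
#'   named numeric vector `p, i, pi, rp, res` of nonnegative components.
#' @param n_raters,n_items positive D-study sample sizes (may be vectors of
#'   equal or broadcastable length).
#' @return Named numeric (or matrix for vector input) with `rel` and `abs`.
#' @export
#' @examples
#' comp <- c(p = 0.150, i = 0.011, pi = 0.063, rp = 0.250, res = 1.167)
#' error_variances(comp, n_raters = 100, n_items = 10)
error_variances <- function(components, n_raters, n_items) {
  v <- as_components(components)
  if (any(n_raters < 1) || any(n_items < 1)) {
    stop("n_raters and n_items must be >= 1", call. = FALSE)
  }
  rel <- v[["pi"]] / n_items + v[["rp"]] / n_raters +
    v[["res"]] / (n_raters * n_items)
  abs_ <- rel + v[["i"]] / n_items
  if (length(rel) == 1L) {
    c(rel = rel, abs = abs_)
  } else {
    cbind(rel = rel, abs = abs_)
  }
}

#' Generalizability (g) and dependability (phi) coefficients
#'
#' g = s2p / (s2p + sigma2(delta)) for relative decisions and
#' phi = s2p / (s2p + sigma2(Delta)) for absolute decisions; both are
#' intraclass-correlation-like indices in \[0, 1\] with phi <= g (equality
#' iff the item component is zero).
#'
#' @inheritParams error_variances
#' @return Named numeric (or matrix) with `g` and `phi`.
#' @export
#' @examples
#' comp <- c(p = 0.150, i = 0.011, pi = 0.063, rp = 0.250, res = 1.167)
#' round(gphi_coefficients(comp, 100, 10), 3)
gphi_coefficients <- function(components, n_raters, n_items) {
  v <- as_components(components)
  ev <- error_variances(v, n_raters, n_items)
  if (is.matrix(ev)) {
    rel <- ev[, "rel"]; abs_ <- ev[, "abs"]
  } else {
    rel <- ev[["rel"]]; abs_ <- ev[["abs"]]
  }
  s2p <- v[["p"]]
  if (s2p <= 0 && all(abs_ <= 0)) {
    stop("g and phi undefined: zero person variance and zero error",
         call. = FALSE)
  }
  g <- s2p / (s2p + rel)
  phi <- s2p / (s2p + abs_)
  if (length(g) == 1L) c(g = g, phi = phi) else cbind(g = g, phi = phi)
}

#' D-study curve over a grid of rater counts
#'
#' Evaluates the four D-study indicators at each rater count of `raters`
#' with the item count held fixed, the optimization the reliability analyst
#' runs to see how many raters a course needs.  Along an increasing grid the
#' error variances are nonincreasing and g and phi nondecreasing (strictly,
#' whenever any rater-indexed component is positive).
#'
#' @inheritParams error_variances
#' @param n_items fixed number of items (default 10).
#' @param raters strictly increasing grid of positive integer rater counts;
#'   default `seq(10, 100, by = 10)`, the 10-rater-interval schedule.
#' @param threshold reliability cutoff attached to the curve (default 0.90).
#' @return A data frame of class `dstudy_curve` with columns `n_raters`,
#'   `abs_error`, `rel_error`, `phi`, `g`; attributes `n_items`, `threshold`.
#' @export
#' @examples
#' comp <- c(p = 0.150, i = 0.011, pi = 0.063, rp = 0.250, res = 1.167)
#' dstudy_curve(comp, n_items = 10)
dstudy_curve <- function(components, n_items = 10, raters = seq(10, 100, 10),
                         threshold = 0.90) {
  v <- as_components(components)
  raters <- as.integer(raters)
  if (length(raters) == 0L) stop("empty rater grid", call. = FALSE)
  if (any(raters < 1)) stop("rater counts must be >= 1", call. = FALSE)
  if (is.unsorted(raters, strictly = TRUE)) {
    stop("rater grid must be strictly increasing", call. = FALSE)
  }
  ev <- error_variances(v, raters, n_items)
  co <- gphi_coefficients(v, raters, n_items)
  if (!is.matrix(ev)) ev <- rbind(ev)
  if (!is.matrix(co)) co <- rbind(co)
  out <- data.frame(n_raters = raters,
                    abs_error = ev[, "abs"],
                    rel_error = ev[, "rel"],
                    phi = co[, "phi"],
                    g = co[, "g"],
                    row.names = NULL)
  stopifnot(!is.unsorted(-out$abs_error), !is.unsorted(-out$rel_error),
            !is.unsorted(out$phi), !is.unsorted(out$g))
  attr(out, "n_items") <- n_items
  attr(out, "threshold") <- threshold
  attr(out, "components") <- v
  class(out) <- c("dstudy_curve", "data.frame")
  out
}

#' Rater grid descending from a class size by the mean non-response
#'
#' Builds the schedule that walks a class of `class_size` raters down in
#' steps of `mean_nonresponse` (the average number of non-responding
#' students per class), stopping above zero: class_size, class_size - k,
#' class_size - 2k, ... >= 1, then evaluates the D-study curve on the
#' increasing version of that grid.
#'
#' @inheritParams dstudy_curve
#' @param class_size number of enrolled raters (>= 1).
#' @param mean_nonresponse step size k >= 1; if k >= class_size the grid
#'   degenerates to the single point `class_size` (with a warning).
#' @return A `dstudy_curve` (see [dstudy_curve()]).
#' @export
#' @examples
#' comp <- c(p = 0.150, i = 0.011, pi = 0.063, rp = 0.250, res = 1.167)
#' nonresponse_schedule(comp, n_items = 10, class_size = 236,
#'                      mean_nonresponse = 47)$n_raters
nonresponse_schedule <- function(components, n_items = 10, class_size,
                                 mean_nonresponse, threshold = 0.90) {
  stopifnot(class_size >= 1, mean_nonresponse >= 1)
  if (mean_nonresponse >= class_size) {
    warning("mean non-response >= class size: single-point grid",
            call. = FALSE)
    grid <- class_size
  } else {
    grid <- seq(class_size, 1, by = -mean_nonresponse)
  }
  dstudy_curve(components, n_items = n_items, raters = sort(grid),
               threshold = threshold)
}

#' Smallest rater count on a grid reaching a reliability threshold
#'
#' Scans the D-study curve and returns the smallest grid value whose phi
#' coefficient (the stricter, absolute-decision index) meets the threshold;
#' g at the same point is reported as an attribute.
#'
#' @inheritParams dstudy_curve
#' @param threshold reliability cutoff in (0, 1); default 0.90.
#' @return The smallest qualifying rater count as an integer (with
#'   attributes `phi` and `g`), or `NA` if the threshold is not attained on
#'   the grid.
#' @export
min_raters_for_threshold <- function(components, n_items = 10,
                                     threshold = 0.90,
                                     raters = seq(10, 100, 10)) {
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must be in [0, 1)", call. = FALSE)
  }
  curve <- dstudy_curve(components, n_items = n_items, raters = raters,
                        threshold = threshold)
  ok <- which(curve$phi >= threshold)
  if (length(ok) == 0L) return(NA_integer_)
  k <- ok[1L]
  out <- curve$n_raters[k]
  attr(out, "phi") <- curve$phi[k]
  attr(out, "g") <- curve$g[k]
  out
}

#' Export a D-study curve as CSV
#'
#' Writes columns `n_raters, abs_error, rel_error, phi, g` rounded to 3
#' decimal places, mirroring the standard D-study table layout.
#'
#' @param curve a [dstudy_curve()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dstudy_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dstudy_curve"))
  out <- curve
  for (col in c("abs_error", "rel_error", "phi", "g")) {
    out[[col]] <- round(out[[col]], 3L)
  }
  utils::write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.dstudy_curve <- function(x, ...) {
  cat("D-study curve (n_i =", attr(x, "n_items"), ")\n")
  cat(render_dstudy(x), sep = "\n")
  invisible(x)
}
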