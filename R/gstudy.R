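#' G-study variance-component estimation for the unbalanced (r:p) x i design
#'
#' The observed score of rater r (nested in person p) on item i decomposes
#' into a grand mean plus five zero-mean random effects,
#'
#'   X_pri = mu + a_p + b_i + c_pi + d_r:p + e_pri,
#'
#' with variances sigma2_p, sigma2_i, sigma2_pi, sigma2_r:p and the residual
#' sigma2_(r:p)i,e (the rater-by-item interaction confounded with all
#' remaining error).  `gstudy()` estimates the five components by analogous
#' ANOVA (Henderson Method 1): the observed sums of squares are equated to
#' their exact expectations under the observed, possibly unequal, per-person
#' rater counts, and the resulting 5 x 5 linear system is solved.
#'
#' @param table a validated [rating_table()].
#' @return An object of class `gstudy`: a list with `anova` (the
#'   [ss_decomposition()] table), `components` (a `variance_components`
#'   object, see [solve_components()]) and `counts`.
#' @seealso [error_variances()], [dstudy_curve()] for D-study projections.
#' @export
#' @examples
#' spec <- simulation_spec(n_p = 20, n_i = 5, raters = 8, seed = 1)
#' fit <- gstudy(generate_complete(spec))
#' fit
gstudy <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  totals <- uncorrected_totals(table)
  an <- ss_decomposition(totals)
  solve_components(an)
}

source_names <- function() c("p", "i", "pi", "rp", "res")

source_labels <- function() {
  c(p = "person (p)", i = "item (i)", pi = "person x item (pi)",
    rp = "rater:person (r:p)", res = "(rater:person) x item (r:p)i,e")
}

#' Uncorrected totals (quadratic forms) of a rating table
#'
#' The building blocks of the analogous-ANOVA decomposition: squared totals
#' divided by the number of observations contributing to each total.
#' `T_mu` = (grand total)^2 / (N n_i); `T_p` = sum over persons of
#' (person total)^2 / (n_r(p) n_i); `T_i` = sum over items of
#' (item total)^2 / N; `T_pi` = sum over (person, item) cells of
#' (cell total)^2 / n_r(p); `T_r` = sum over raters of
#' (rater total)^2 / n_i; `T_pri` = sum of squared scores.
#'
#' @param table a [rating_table()].
#' @return Named numeric vector `T_mu, T_p, T_i, T_pi, T_r, T_pri`, with the
#'   design counts attached as attribute `counts`.
#' @export
uncorrected_totals <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  counts <- table$counts
  if (counts$N == 0L) stop("empty rating table", call. = FALSE)
  sc <- table$scores
  ni <- counts$n_i
  N <- counts$N
  x <- sc$score
  p <- factor(sc$person, levels = names(counts$n_r_by_person))
  i <- factor(sc$item, levels = table$items)
  pid <- as.integer(p)
  iid <- as.integer(i)
  nrp <- as.numeric(counts$n_r_by_person)

  G <- sum(x)
  pt <- rowsum(x, pid, reorder = TRUE)[, 1L]              # person totals
  it <- rowsum(x, iid, reorder = TRUE)[, 1L]              # item totals
  cellid <- (pid - 1L) * ni + iid
  cellt <- numeric(counts$n_p * ni)
  agg <- rowsum(x, cellid, reorder = TRUE)
  cellt[as.integer(rownames(agg))] <- agg[, 1L]           # (p, i) cell totals
  rfac <- factor(paste(sc$person, sc$rater, sep = "\r"))
  rt <- rowsum(x, as.integer(rfac), reorder = TRUE)[, 1L] # rater totals

  nrp_cell <- rep(nrp, each = ni)
  out <- c(T_mu  = G^2 / (N * ni),
           T_p   = sum(pt^2 / (nrp * ni)),
           T_i   = sum(it^2) / N,
           T_pi  = sum(cellt^2 / nrp_cell),
           T_r   = sum(rt^2) / ni,
           T_pri = sum(x^2))
  attr(out, "counts") <- counts
  out
}

#' ANOVA decomposition (df, SS, MS) from the uncorrected totals
#'
#' Sums of squares for the five sources of the (r:p) x i design:
#' SS_p = T_p - T_mu; SS_i = T_i - T_mu; SS_pi = T_pi - T_p - T_i + T_mu;
#' SS_r:p = T_r - T_p; SS_res = T_pri - T_pi - T_r + T_p.  Degrees of
#' freedom: n_p - 1, n_i - 1, (n_p - 1)(n_i - 1), N - n_p and
#' (N - n_p)(n_i - 1).  Tiny negative SS from floating-point cancellation
#' (within 1e-9 of zero, relative to T_pri) are clamped to zero.
#'
#' @param totals output of [uncorrected_totals()].
#' @return An object of class `anova_table`: a data frame with columns
#'   `source`, `df`, `SS`, `MS`, carrying the expected-sum-of-squares
#'   coefficient matrix (see [ems_coefficients()]) as attribute `ems` and
#'   the design counts as attribute `counts`.
#' @export
ss_decomposition <- function(totals) {
  counts <- attr(totals, "counts")
  if (is.null(counts)) {
    stop("totals must come from uncorrected_totals()", call. = FALSE)
  }
  n_p <- counts$n_p
  n_i <- counts$n_i
  N <- counts$N
  df <- c(p = n_p - 1L, i = n_i - 1L, pi = (n_p - 1L) * (n_i - 1L),
          rp = N - n_p, res = (N - n_p) * (n_i - 1L))
  if (any(df == 0L)) {
    stop("degenerate design: zero degrees of freedom for source(s) ",
         paste(names(df)[df == 0L], collapse = ", "),
         " (need n_p >= 2, n_i >= 2 and at least one person with >= 2 raters)",
         call. = FALSE)
  }
  tt <- as.numeric(totals)
  names(tt) <- names(totals)
  ss <- c(p   = tt[["T_p"]] - tt[["T_mu"]],
          i   = tt[["T_i"]] - tt[["T_mu"]],
          pi  = tt[["T_pi"]] - tt[["T_p"]] - tt[["T_i"]] + tt[["T_mu"]],
          rp  = tt[["T_r"]] - tt[["T_p"]],
          res = tt[["T_pri"]] - tt[["T_pi"]] - tt[["T_r"]] + tt[["T_p"]])
  tol <- 1e-9 * max(1, tt[["T_pri"]])
  if (any(ss < -tol)) {
    stop("negative sum of squares beyond numerical tolerance", call. = FALSE)
  }
  ss <- pmax(ss, 0)
  out <- data.frame(source = source_names(), df = as.integer(df), SS = ss,
                    MS = ss / df, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "ems") <- ems_coefficients(counts)
  attr(out, "counts") <- counts
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Expected-sum-of-squares coefficients under the random model
#'
#' Row s of the returned matrix gives E[SS_s] as a linear form in
#' (sigma2_p, sigma2_i, sigma2_pi, sigma2_r:p, sigma2_res), computed exactly
#' from the observed per-person rater counts.  The unbalance enters through
#' the k-coefficient S2/N with S2 = sum of n_r(p)^2.  With r = S2/N:
#'
#' \preformatted{
#'   E[SS_p]   = n_i (N - r) s2p + (N - r) s2pi
#'               + (n_p - 1) n_i s2rp + (n_p - 1) s2res
#'   E[SS_i]   = N (n_i - 1) s2i + (n_i - 1) r s2pi + (n_i - 1) s2res
#'   E[SS_pi]  = (N - r)(n_i - 1) s2pi + (n_p - 1)(n_i - 1) s2res
#'   E[SS_r:p] = (N - n_p) n_i s2rp + (N - n_p) s2res
#'   E[SS_res] = (N - n_p)(n_i - 1) s2res
#' }
#'
#' For a balanced design (all n_r(p) = n_r), dividing each row by its
#' degrees of freedom recovers the familiar expected mean squares, e.g.
#' EMS(pi) = n_r s2pi + s2res and EMS(r:p) = n_i s2rp + s2res, with EMS(p)
#' carrying the n_r s2pi cross term of the standard (r:p) x i derivation.
#'
#' @param counts a `design_counts` object (see [design_counts()]).
#' @return 5 x 5 numeric matrix, rows = sources (p, i, pi, rp, res),
#'   columns = variance components; nonsingular for any valid design.
#' @export
ems_coefficients <- function(counts) {
  stopifnot(inherits(counts, "design_counts"))
  n_p <- counts$n_p
  n_i <- counts$n_i
  N <- counts$N
  r <- sum(as.numeric(counts$n_r_by_person)^2) / N   # k-coefficient S2/N
  m <- matrix(0, 5L, 5L, dimnames = list(source_names(), source_names()))
  m["p", ]   <- c(n_i * (N - r), 0, N - r, (n_p - 1) * n_i, n_p - 1)
  m["i", ]   <- c(0, N * (n_i - 1), (n_i - 1) * r, 0, n_i - 1)
  m["pi", ]  <- c(0, 0, (N - r) * (n_i - 1), 0, (n_p - 1) * (n_i - 1))
  m["rp", ]  <- c(0, 0, 0, (N - n_p) * n_i, N - n_p)
  m["res", ] <- c(0, 0, 0, 0, (N - n_p) * (n_i - 1))
  m
}

#' Solve the analogous-ANOVA equations for the variance components
#'
#' Equates the five observed sums of squares to their expectations and
#' solves the linear system.  Negative solutions (possible whenever a true
#' component is near zero) are clipped to 0 and flagged; the unclipped
#' estimates are retained in the `raw` attribute.  Percentage shares are
#' computed from the clipped values.
#'
#' @param anova an [ss_decomposition()] table (as produced within
#'   [gstudy()]), carrying its `ems` coefficient matrix.
#' @return An object of class `gstudy`: list with `anova`, `components`
#'   (class `variance_components`: named numeric `p, i, pi, rp, res` with
#'   attributes `raw`, `clipped`, `percent`) and `counts`.
#' @export
solve_components <- function(anova) {
  stopifnot(inherits(anova, "anova_table"))
  C <- attr(anova, "ems")
  qrC <- qr(C)
  if (qrC$rank < 5L) {
    stop("degenerate design: singular expected-mean-square system",
         call. = FALSE)
  }
  raw <- as.numeric(solve(qrC, anova$SS))
  names(raw) <- source_names()
  comp <- pmax(raw, 0)
  clipped <- raw < 0
  components <- comp
  attr(components, "raw") <- raw
  attr(components, "clipped") <- clipped
  attr(components, "percent") <- if (sum(comp) > 0) {
    variance_percentages(comp)
  } else {
    stats::setNames(rep(NA_real_, 5L), source_names())
  }
  class(components) <- "variance_components"
  out <- list(anova = anova, components = components,
              counts = attr(anova, "counts"))
  class(out) <- "gstudy"
  out
}

#' Percentage share of each variance component
#'
#' @param components named numeric vector (or `variance_components`) of
#'   nonnegative component estimates.
#' @return Named numeric vector: 100 * component / total.
#' @export
variance_percentages <- function(components) {
  v <- as_components(components)
  tot <- sum(v)
  if (tot <= 0) {
    stop("all components are zero: percentages undefined", call. = FALSE)
  }
  100 * v / tot
}

# Accept a gstudy fit, a variance_components object, or a named numeric
# vector with names p, i, pi, rp, res (any order).
as_components <- function(x) {
  if (inherits(x, "gstudy")) x <- x$components
  if (inherits(x, "variance_components")) {
    v <- unclass(x)
    attributes(v) <- list(names = names(v))
    return(v)
  }
  if (is.numeric(x) && !is.null(names(x)) &&
      setequal(names(x), source_names())) {
    v <- as.numeric(x[source_names()])
    names(v) <- source_names()
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("variance components must be finite and nonnegative",
           call. = FALSE)
    }
    return(v)
  }
  stop("expected a gstudy fit, a variance_components object, or a named ",
       "numeric vector with names p, i, pi, rp, res", call. = FALSE)
}

#' @export
print.variance_components <- function(x, ...) {
  v <- as_components(x)
  pc <- attr(x, "percent")
  df <- data.frame(source = source_labels()[names(v)],
                   variance = round(v, 3L),
                   percent = if (!is.null(pc)) round(pc, 1L)
                             else round(variance_percentages(v), 1L),
                   row.names = NULL)
  print(df)
  cl <- attr(x, "clipped")
  if (!is.null(cl) && any(cl)) {
    cat("note: negative estimate(s) clipped to 0 for:",
        paste(names(v)[cl], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.gstudy <- function(x, ...) {
  cat("G-study for the unbalanced (r:p) x i random design\n")
  cat("n_p =", x$counts$n_p, " n_i =", x$counts$n_i,
      " N =", x$counts$N, "raters\n\n")
  cat(render_gstudy(x), sep = "\n")
  invisible(x)
}

#' Closed-form component estimates for a balanced design
#'
#' For equal rater counts the analogous-ANOVA system reduces to mean-square
#' differencing: sigma2_res = MS_res; sigma2_r:p = (MS_r:p - MS_res)/n_i;
#' sigma2_pi = (MS_pi - MS_res)/n_r; sigma2_i = (MS_i - n_r sigma2_pi -
#' MS_res)/(n_p n_r); sigma2_p = (MS_p - n_r sigma2_pi - n_i sigma2_r:p -
#' MS_res)/(n_r n_i).  Exposed mainly as an independent cross-check of the
#' general solver and for desk calculations from printed mean squares.
#'
#' @param ms named numeric vector of mean squares `p, i, pi, rp, res`.
#' @param n_p,n_r,n_i balanced design sizes.
#' @return Named numeric vector of the five (unclipped) estimates.
#' @export
#' @examples
#' # rater:person component from printed mean squares, 10 items:
#' balanced_closed_form(c(p = 32.47, i = 33.28, pi = 2.33,
#'                        rp = 9374 / 2556, res = 1.167),
#'                      n_p = 145, n_r = 18, n_i = 10)[["rp"]]
balanced_closed_form <- function(ms, n_p, n_r, n_i) {
  stopifnot(setequal(names(ms), source_names()))
  res <- ms[["res"]]
  rp <- (ms[["rp"]] - res) / n_i
  pi_ <- (ms[["pi"]] - res) / n_r
  i_ <- (ms[["i"]] - n_r * pi_ - res) / (n_p * n_r)
  p_ <- (ms[["p"]] - n_r * pi_ - n_i * rp - res) / (n_r * n_i)
  c(p = p_, i = i_, pi = pi_, rp = rp, res = res)
}
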