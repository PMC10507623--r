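# Minimal 2 persons x 2 raters x 2 items design with hand-checkable totals:
#   P1/r1: i1=1 i2=2   P1/r2: i1=3 i2=4
#   P2/r1: i1=2 i2=3   P2/r2: i1=4 i2=5
toy_scores <- function() {
  data.frame(
    person = rep(c("P1", "P1", "P2", "P2"), each = 2L),
    rater  = rep(c("r1", "r2", "r1", "r2"), each = 2L),
    item   = rep(c("i1", "i2"), times = 4L),
    score  = c(1, 2, 3, 4, 2, 3, 4, 5),
    stringsAsFactors = FALSE)
}

toy_table <- function() rating_table(toy_scores())

# constant-score table on an unbalanced design
constant_table <- function(value = 3, nrp = c(2L, 3L, 4L), n_i = 3L) {
  person <- rep(sprintf("P%d", seq_along(nrp)), times = nrp)
  rater <- unlist(lapply(nrp, function(k) sprintf("r%d", seq_len(k))))
  df <- expand.grid(idx = seq_along(person), item = sprintf("i%d", 1:n_i),
                    stringsAsFactors = FALSE)
  data.frame(person = person[df$idx], rater = rater[df$idx],
             item = df$item, score = value,
             stringsAsFactors = FALSE) |> rating_table()
}

# published expected/received response counts per level of study
levels_roster <- function() {
  data.frame(
    stratum  = c("100", "200", "300", "400", "500", "600", "700", "800",
                 "900"),
    expected = c(45722, 48316, 32692, 21443, 280, 149, 5, 3665, 386),
    received = c(27588, 11945, 13745, 18113, 101, 141, 4, 2121, 148),
    stringsAsFactors = FALSE)
}

# published G-study variance components used for D-study checks
table4_components <- function() {
  c(p = 0.150, i = 0.011, pi = 0.063, rp = 0.250, res = 1.167)
}

# naive mean-deviation sums of squares for a *balanced* (r:p) x i design;
# independent of the quadratic-form path used by the package
mean_deviation_ss <- function(scores) {
  x <- scores$score
  gm <- mean(x)
  n_r <- length(unique(scores$rater))
  n_i <- length(unique(scores$item))
  pm <- tapply(x, scores$person, mean)
  im <- tapply(x, scores$item, mean)
  pim <- tapply(x, list(scores$person, scores$item), mean)
  prm <- tapply(x, list(scores$person, scores$rater), mean)
  p_of <- scores$person
  ss_p <- n_r * n_i * sum((pm - gm)^2)
  ss_i <- length(pm) * n_r * sum((im - gm)^2)
  ss_pi <- n_r * sum((sweep(sweep(pim, 1, pm), 2, im) + gm)^2)
  ss_rp <- n_i * sum((sweep(prm, 1, pm[rownames(prm)]))^2)
  resid <- x - pim[cbind(p_of, scores$item)] -
    prm[cbind(p_of, scores$rater)] + pm[p_of]
  ss_res <- sum(resid^2)
  c(p = ss_p, i = ss_i, pi = ss_pi, rp = ss_rp, res = ss_res)
}
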