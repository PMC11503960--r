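# Cohort-level statistics: tie-corrected Kruskal-Wallis, exact Wilcoxon
# signed-rank (full sign-enumeration at small n), and two-proportion
# trial sample-size / power with dropout inflation.

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based H with the tie correction
#' `H / (1 - sum(t^3 - t) / (N^3 - N))`; the p-value uses the chi-square
#' approximation with g-1 degrees of freedom regardless of n (the
#' convention of the common numerical-computing implementations).
#'
#' @param groups list of >= 2 numeric vectors (all nonempty).
#' @return list: `chi_squared`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  if (N < 3) stop("need total n >= 3")
  rk <- rank(x)
  R <- tapply(rk, g, sum)
  n_g <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(R^2 / n_g) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H <- H / corr
  df <- length(groups) - 1
  list(chi_squared = H, p = stats::pchisq(H, df, lower.tail = FALSE),
       df = df, n = N)
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test. Zero differences are dropped; ranks of |d| use
#' average ties. For n <= 15 the null distribution of W+ is obtained by
#' full enumeration of the 2^n sign assignments over the observed ranks
#' (so ties are handled exactly); the two-sided p is twice the smaller
#' tail, capped at 1. Larger n uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b paired numeric vectors.
#' @return list: `w_plus`, `w_minus`, `p`, `n` (nonzero pairs), `exact`.
#' @export
wilcoxon_signrank_exact <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(w_plus = 0, w_minus = 0, p = 1, n = 0, exact = TRUE,
                all_zero = TRUE))
  }
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  w_minus <- sum(rk[d < 0])
  if (n <= 15) {
    sums <- 0
    for (r in rk) sums <- c(sums, sums + r)   # all 2^n subset sums
    eps <- 1e-9
    p_le <- mean(sums <= w_plus + eps)
    p_ge <- mean(sums >= w_plus - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(w_plus = w_plus, w_minus = w_minus, p = p, n = n, exact = exact)
}

#' Two-proportion trial sample size (unpooled two-sided Z-test)
#'
#' `n = ceil((z[1-alpha/2] + z[power])^2 * (p1*q1 + p2*q2) / (p2 - p1)^2)`
#' per arm.
#'
#' @param p_control,p_active arm proportions (must differ).
#' @param alpha two-sided level.
#' @param power target power.
#' @return integer patients per arm.
#' @export
two_proportion_sample_size <- function(p_control, p_active, alpha = 0.05,
                                       power = 0.80) {
  stopifnot(p_control > 0, p_control < 1, p_active > 0, p_active < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  delta <- p_active - p_control
  if (delta == 0) stop("proportions must differ")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  v <- p_control * (1 - p_control) + p_active * (1 - p_active)
  as.integer(ceiling(z^2 * v / delta^2))
}

#' Analytic power of the unpooled two-proportion Z-test
#'
#' @param n per-arm sample size.
#' @inheritParams two_proportion_sample_size
#' @return power in \[0, 1\].
#' @export
two_proportion_power <- function(n, p_control, p_active, alpha = 0.05) {
  se <- sqrt((p_control * (1 - p_control) + p_active * (1 - p_active)) / n)
  z_a <- stats::qnorm(1 - alpha / 2)
  delta <- abs(p_active - p_control)
  stats::pnorm(delta / se - z_a) + stats::pnorm(-delta / se - z_a)
}

#' Inflate enrolment for expected dropout
#'
#' `ceil(n / (1 - dropout))`.
#'
#' @param n completers needed per arm.
#' @param dropout expected dropout proportion in \[0, 1).
#' @return integer enrolment.
#' @export
dropout_inflate <- function(n, dropout) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  as.integer(ceiling(n / (1 - dropout)))
}
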