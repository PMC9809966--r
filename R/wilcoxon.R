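# Paired Wilcoxon signed-rank test with an exact null for small n.
#
# The exact null distribution of the positive-rank sum W+ is obtained by
# dynamic programming over the 2^n equiprobable sign assignments of the
# (tie-averaged) ranks; ranks are doubled so tied average ranks become
# integers. Above `exact_max_n` paired observations a normal approximation
# with tie-corrected variance (Var W+ = sum r_i^2 / 4) and a 0.5 continuity
# correction is used.

.signedRankNull <- function(ranks2) {
  # distribution of 2*W+ over sign assignments; ranks2 are doubled ranks
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f / sum(f)
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares paired measurements (for instance, per-cell coefficients of
#' variation from two quantification methods). Zero differences are dropped
#' by default (Wilcoxon's treatment); the Pratt variant ranks them first and
#' then discards their ranks. Tied absolute differences receive average
#' ranks. For up to \code{exact_max_n} non-zero pairs the p-value is exact
#' (full sign-assignment null via dynamic programming); beyond that a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alternative \code{"two.sided"}, \code{"greater"} (a tends to
#'   exceed b) or \code{"less"}.
#' @param zero_method \code{"wilcox"} (drop zero differences) or
#'   \code{"pratt"}.
#' @param exact_max_n largest number of non-zero pairs for which the exact
#'   null is enumerated (default 25).
#' @return list with \code{statistic} (W+, the positive-rank sum),
#'   \code{w_minus}, \code{p.value}, \code{n} (non-zero pairs),
#'   \code{method} ("exact" or "normal"), \code{alternative}.
#' @export
#' @examples
#' pairedWilcoxon(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))$p.value # 2/64
pairedWilcoxon <- function(a, b,
                           alternative = c("two.sided", "greater", "less"),
                           zero_method = c("wilcox", "pratt"),
                           exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- as.numeric(a) - as.numeric(b)
  d <- d[!is.na(d)]
  if (zero_method == "wilcox") d <- d[d != 0]
  if (length(d) == 0 || all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, w_minus = 0, p.value = 1,
                n = 0L, method = "degenerate", alternative = alternative))
  }
  r <- rank(abs(d))           # zeros included here under pratt
  keep <- d != 0
  r <- r[keep]
  d <- d[keep]
  n <- length(d)
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])

  if (n <= exact_max_n) {
    ranks2 <- as.integer(round(2 * rank(abs(d))))
    if (zero_method == "pratt") {
      # null must use the ranks as assigned with zeros present
      ranks2 <- as.integer(round(2 * r))
    }
    null <- .signedRankNull(ranks2)
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(null[seq_len(w2 + 1L)])
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    cc <- 0.5
    z_ge <- (w_plus - mu - cc) / sigma
    z_le <- (w_plus - mu + cc) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(z_ge, lower.tail = FALSE),
                less = stats::pnorm(z_le),
                two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                           stats::pnorm(z_ge,
                                                        lower.tail = FALSE))))
    method <- "normal"
  }
  list(statistic = w_plus, w_minus = w_minus, p.value = p, n = n,
       method = method, alternative = alternative)
}
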